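#' Free-form deformation registration configuration
#'
#' Masked multiresolution cubic B-spline registration driven by mutual
#' information with stochastic sampling: at each iteration a fresh random
#' subset of voxels inside the dilated mask is drawn, the Parzen-window MI
#' and its analytic gradient with respect to the control-point displacements
#' are evaluated, and a gradient-ascent step with decaying step size
#' `a / (t + A)` is taken.
#'
#' @param levels number of multiresolution levels (default 4).
#' @param grid_spacings control-point spacing in mm per level, strictly
#'   decreasing (default 64, 32, 16, 8; these assume a CT-scale field of
#'   view and are auto-scaled down for small volumes, keeping at least four
#'   control intervals per axis at the finest level).
#' @param samples_per_iter random samples per iteration (default 2000,
#'   minimum 100).
#' @param iters_per_level gradient iterations per level (default 200).
#' @param mask_dilation_mm dilation of the registration mask (default 10).
#' @param histogram_bins joint-histogram bins (default 32).
#' @param step_decay_A offset `A` of the `a/(t + A)` step schedule
#'   (default 20).
#' @param seed integer driving the sampling stream.
#' @return object of class `ffd_config`.
#' @export
ffd_config <- function(levels = 4, grid_spacings = c(64, 32, 16, 8),
                       samples_per_iter = 2000, iters_per_level = 200,
                       mask_dilation_mm = 10, histogram_bins = 32,
                       step_decay_A = 20, seed = 1L) {
  if (length(grid_spacings) != levels)
    stop("grid_spacings must have one entry per level")
  if (any(diff(grid_spacings) >= 0)) stop("grid_spacings must be strictly decreasing")
  if (samples_per_iter < 100) stop("samples_per_iter must be >= 100")
  structure(list(levels = as.integer(levels), grid_spacings = grid_spacings,
                 samples_per_iter = as.integer(samples_per_iter),
                 iters_per_level = as.integer(iters_per_level),
                 mask_dilation_mm = mask_dilation_mm,
                 histogram_bins = as.integer(histogram_bins),
                 step_decay_A = step_decay_A, seed = as.integer(seed)),
            class = "ffd_config")
}

# control lattice covering world box [lo, hi] with one margin row
make_lattice <- function(lo, hi, spacing_mm) {
  n_int <- pmax(ceiling((hi - lo) / spacing_mm), 1)
  ldim <- as.integer(n_int + 4)
  lorigin <- lo - spacing_mm
  list(ldim = ldim, lorigin = lorigin,
       lspacing = rep_len(spacing_mm, 3L))
}

ffd_field <- function(coef, lattice, domain) {
  structure(list(coef = coef, ldim = lattice$ldim,
                 lorigin = lattice$lorigin, lspacing = lattice$lspacing,
                 domain = domain),
            class = "ffd_field")
}

#' @export
print.ffd_field <- function(x, ...) {
  cat(sprintf("<ffd_field> lattice %s, spacing %s mm, max |disp| %.2f mm\n",
              paste(x$ldim, collapse = "x"),
              paste(signif(x$lspacing, 4), collapse = "x"),
              max(abs(x$coef))))
  invisible(x)
}

#' Displacement of an FFD field at world points
#'
#' @param field an `ffd_field`.
#' @param pts n x 3 world coordinates (mm).
#' @return n x 3 matrix of displacements (mm).
#' @export
ffd_displacement <- function(field, pts) {
  cpp_ffd_disp(field$coef, field$ldim, field$lorigin, field$lspacing,
               matrix(pts, ncol = 3))
}

#' Mutual information between two volumes
#'
#' Parzen-window joint-histogram estimate in nats, from intensity pairs at
#' the given sample points (trilinear interpolation) or, when `samples` is
#' `NULL`, from all voxels of the common grid. Deterministic given the
#' sample set.
#'
#' @param fixed,moving [volume_grid()] objects; on a common grid if
#'   `samples` is `NULL`.
#' @param samples optional n x 3 matrix of world sample coordinates
#'   (at least 100 rows must fall inside both fields of view).
#' @param bins histogram bins per axis (default 32).
#' @return MI estimate in nats.
#' @export
mutual_information <- function(fixed, moving, samples = NULL, bins = 32) {
  if (is.null(samples)) {
    stopifnot_same_grid(fixed, moving)
    f <- as.numeric(fixed$values); m <- as.numeric(moving$values)
  } else {
    samples <- matrix(samples, ncol = 3)
    fg <- cpp_sample_grad(as.numeric(fixed$values),
                          as.integer(dim(fixed$values)), fixed$spacing,
                          fixed$origin, samples, NA_real_)
    mg <- cpp_sample_grad(as.numeric(moving$values),
                          as.integer(dim(moving$values)), moving$spacing,
                          moving$origin, samples, NA_real_)
    ok <- fg[, 5] > 0 & mg[, 5] > 0
    if (sum(ok) < 100)
      stop("fewer than 100 sample points fall inside both fields of view")
    f <- fg[ok, 1]; m <- mg[ok, 1]
  }
  res <- cpp_mi_grad(f, m, as.integer(bins),
                     min(f), max(f) + 1e-9, min(m), max(m) + 1e-9, FALSE)
  res$mi
}

#' Masked multiresolution B-spline registration by stochastic MI ascent
#'
#' Estimates a cubic B-spline displacement field (fixed-domain world
#' coordinates to moving-domain world coordinates, as a displacement added
#' to the identity) that maximises the mutual information between the fixed
#' image and the warped moving image. Random intensity samples are drawn
#' only inside the dilated mask, each level smooths both images with a
#' Gaussian matched to its control spacing, and control points whose
#' support does not touch the dilated mask are frozen at zero, so the
#' displacement vanishes away from the mask. Fully reproducible from
#' `config$seed`.
#'
#' @param fixed target [volume_grid()].
#' @param moving pre-affinely-aligned [volume_grid()] on the fixed grid's
#'   world frame.
#' @param mask nonempty [label_volume()] on the fixed grid restricting the
#'   registration domain.
#' @param config an [ffd_config()].
#' @return an `ffd_field` with diagnostics attributes `mi_before` and
#'   `mi_after`.
#' @export
register_ffd <- function(fixed, moving, mask, config = ffd_config()) {
  if (sum(mask$values) == 0) stop("registration mask is empty")
  dmask <- dilate_mask(mask, config$mask_dilation_mm)
  cand <- which(dmask$values > 0)
  d <- dim(fixed$values)
  co <- arrayInd(cand, d) - 1L
  W <- sweep(sweep(co, 2, fixed$spacing, "*"), 2, fixed$origin, "+")
  extent <- (d - 1) * fixed$spacing
  ratio <- min(1, max(extent) / 400)
  spacings <- config$grid_spacings * ratio
  lo <- apply(W, 2, min); hi <- apply(W, 2, max)
  finest_cap <- max(min(hi - lo) / 4, 2 * max(fixed$spacing))
  spacings[config$levels] <- min(spacings[config$levels], finest_cap)
  mrange <- range(moving$values)
  mpad <- c(mrange[1] - 1e-9, mrange[2] + 1e-9)
  bins <- config$histogram_bins
  withr::with_seed(config$seed, {
    field <- NULL
    for (lev in seq_len(config$levels)) {
      lat <- make_lattice(lo, hi, spacings[lev])
      ncp <- prod(lat$ldim)
      coef <- matrix(0, ncp, 3)
      if (!is.null(field)) {
        cp_pts <- lattice_cp_world(lat)
        coef <- ffd_displacement(field, cp_pts)
      }
      # freeze control points whose support misses the dilated mask
      occ <- cpp_ffd_accum(lat$ldim, lat$lorigin, lat$lspacing, W,
                           matrix(1, nrow(W), 3))
      active <- occ[, 1] > 0
      coef[!active, ] <- 0
      sig_mm <- spacings[lev] / 4
      fx_s <- gaussian_smooth(fixed$values, sig_mm / fixed$spacing)
      mv_s <- gaussian_smooth(moving$values, sig_mm / moving$spacing)
      fvals_all <- as.numeric(fx_s)[cand]
      frange <- range(fvals_all) + c(-1e-9, 1e-9)
      mv_vec <- as.numeric(mv_s)
      a_step <- NA_real_
      for (t in seq_len(config$iters_per_level)) {
        pick <- sample.int(length(cand), min(config$samples_per_iter,
                                             length(cand)))
        pts <- W[pick, , drop = FALSE]
        disp <- cpp_ffd_disp(coef, lat$ldim, lat$lorigin, lat$lspacing, pts)
        sg <- cpp_sample_grad(mv_vec, as.integer(d), moving$spacing,
                              moving$origin, pts + disp, mrange[1])
        mi <- cpp_mi_grad(fvals_all[pick], sg[, 1], bins,
                          frange[1], frange[2], mpad[1], mpad[2], TRUE)
        vec <- sg[, 2:4] * mi$dmi_dm
        grad <- cpp_ffd_accum(lat$ldim, lat$lorigin, lat$lspacing, pts, vec)
        grad[!active, ] <- 0
        gmax <- max(abs(grad))
        if (gmax < 1e-14) next
        if (is.na(a_step))
          a_step <- (spacings[lev] / 8) * (config$step_decay_A + 1) / gmax
        coef <- coef + (a_step / (t + config$step_decay_A)) * grad
      }
      field <- ffd_field(coef, lat, grid_meta(fixed))
    }
    n_eval <- min(8000L, length(cand))
    eval_idx <- sample.int(length(cand), n_eval)
    eval_pts <- W[eval_idx, , drop = FALSE]
    f_eval <- fvals_all[eval_idx] # finest-level smoothing
    mi_pair <- function(pts_m) {
      mv <- cpp_sample_points(mv_vec, as.integer(d), moving$spacing,
                              moving$origin, pts_m, FALSE, mrange[1])
      cpp_mi_grad(f_eval, mv, bins, frange[1], frange[2],
                  mpad[1], mpad[2], FALSE)$mi
    }
    attr(field, "mi_before") <- mi_pair(eval_pts)
    attr(field, "mi_after") <- mi_pair(eval_pts + ffd_displacement(field, eval_pts))
    if (!is.finite(attr(field, "mi_after"))) stop("non-finite registration metric")
    field
  })
}

lattice_cp_world <- function(lat) {
  idx <- cbind(
    rep.int(seq_len(lat$ldim[1]) - 1L, lat$ldim[2] * lat$ldim[3]),
    rep.int(rep(seq_len(lat$ldim[2]) - 1L, each = lat$ldim[1]), lat$ldim[3]),
    rep(seq_len(lat$ldim[3]) - 1L, each = lat$ldim[1] * lat$ldim[2])
  )
  sweep(sweep(idx, 2, lat$lspacing, "*"), 2, lat$lorigin, "+")
}

#' Warp a volume through an FFD field
#'
#' Resamples onto the field's fixed-domain grid: each output voxel samples
#' the input at its world position plus the B-spline displacement. Labels
#' are warped nearest-neighbour, images trilinearly. A zero-coefficient
#' field is the identity.
#'
#' @param volume [volume_grid()] or [label_volume()] to warp (the moving
#'   volume).
#' @param field an `ffd_field` from [register_ffd()].
#' @param interpolation `"linear"` or `"nearest"` (labels always nearest).
#' @return warped volume on the field's domain grid.
#' @export
apply_ffd <- function(volume, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is_label(volume)) interpolation <- "nearest"
  dom <- field$domain
  ref <- volume_grid(array(0, dom$dim), dom$spacing, dom$origin)
  pts <- voxel_world_coords(ref)
  disp <- ffd_displacement(field, pts)
  fill <- if (is_label(volume)) 0 else min(volume$values)
  vals <- cpp_sample_points(as.numeric(volume$values),
                            as.integer(dim(volume$values)), volume$spacing,
                            volume$origin, pts + disp,
                            interpolation == "nearest", fill)
  if (is_label(volume))
    label_volume(array(vals, dom$dim), dom$spacing, dom$origin)
  else volume_grid(array(vals, dom$dim), dom$spacing, dom$origin)
}

#' Serialize / load an FFD field
#'
#' Coefficients are written as three NIfTI volumes (one per displacement
#' component on the control lattice) plus a JSON lattice descriptor.
#'
#' @param field an `ffd_field`.
#' @param dir output directory.
#' @return `dir` invisibly; `read_ffd()` returns the field.
#' @export
write_ffd <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in 1:3) {
    write_volume(volume_grid(array(field$coef[, a], field$ldim),
                             field$lspacing, field$lorigin),
                 file.path(dir, sprintf("coef_%d.nii.gz", a)))
  }
  jsonlite::write_json(list(ldim = field$ldim, lorigin = field$lorigin,
                            lspacing = field$lspacing, domain = field$domain),
                       file.path(dir, "lattice.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_ffd
#' @export
read_ffd <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "lattice.json"),
                              simplifyVector = TRUE)
  coef <- sapply(1:3, function(a)
    as.numeric(read_volume(file.path(dir, sprintf("coef_%d.nii.gz", a)))$values))
  dom <- list(dim = as.integer(side$domain$dim),
              spacing = as.numeric(side$domain$spacing),
              origin = as.numeric(side$domain$origin))
  ffd_field(coef, list(ldim = as.integer(side$ldim),
                       lorigin = as.numeric(side$lorigin),
                       lspacing = as.numeric(side$lspacing)), dom)
}
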