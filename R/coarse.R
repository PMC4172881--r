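#' Configuration of the coarse registration-segmentation loop
#'
#' @param k_iters number of segmentation/affine-registration iterations,
#'   in 1..10 (default 4; `k_iters = 1` is the classical single propagation
#'   of the probabilistic atlas).
#' @param sigma_s atlas smoothing scale in voxels used when the atlas is
#'   built (default 2); carried for bookkeeping.
#' @param crf a [crf_config()] (defaults lambda1 = 10, lambda2 = 4).
#' @param downsample run the loop at half resolution (default TRUE).
#' @param convergence_dice early-stop threshold on the DICE between
#'   consecutive segmentations (default 0.999).
#' @return object of class `coarse_config`.
#' @export
coarse_config <- function(k_iters = 4, sigma_s = 2, crf = crf_config(),
                          downsample = TRUE, convergence_dice = 0.999) {
  if (k_iters < 1 || k_iters > 10) stop("k_iters must be in [1, 10]")
  structure(list(k_iters = as.integer(k_iters), sigma_s = sigma_s, crf = crf,
                 downsample = downsample, convergence_dice = convergence_dice),
            class = "coarse_config")
}

#' Build the probabilistic atlas for the coarse stage
#'
#' Optionally downsamples every atlas by a factor of two, normalises the set
#' into the reference atlas frame by moment alignment, and computes the
#' statistical parameter maps.
#'
#' @param atlases list of `list(image, label)` pairs.
#' @param reference_index reference atlas (default 1).
#' @param sigma_s smoothing scale in voxels (default 2).
#' @param downsample halve the resolution first (default TRUE).
#' @return list with `aligned` ([normalize_atlases()] result) and `maps`
#'   ([build_stat_maps()] result).
#' @export
build_probabilistic_atlas <- function(atlases, reference_index = 1L,
                                      sigma_s = 2, downsample = TRUE) {
  if (downsample)
    atlases <- lapply(atlases, function(a)
      list(image = downsample2(a$image), label = downsample2(a$label)))
  aligned <- normalize_atlases(atlases, reference_index)
  list(aligned = aligned, maps = build_stat_maps(aligned, sigma_s))
}

#' Coarse segmentation by iterative affine registration and graph cut
#'
#' Alternates, for up to `k_iters` iterations: moment-align the current
#' target mask to the atlas reference frame, resample the target image into
#' that frame, segment it by graph cut against the probabilistic atlas, and
#' map the segmentation back (nearest-neighbour) onto the native grid. The
#' loop stops early when two consecutive segmentations agree to
#' `convergence_dice`. Two numerical stabilisers act on the affine update:
#' it is under-relaxed (averaged 50/50 with the previous transform), which
#' suppresses period-2 registration/segmentation oscillation, and updates
#' displacing the reference frame by less than half its voxel size are
#' frozen, giving the discrete iteration a well-defined fixed point. When `config$downsample` is on
#' the target image is halved before entering the loop (the maps must then
#' be built from downsampled atlases, see [build_probabilistic_atlas()]),
#' while the evolving mask always stays at native resolution.
#'
#' @param target native-space [volume_grid()].
#' @param s0 nonempty initial [label_volume()] on the target grid.
#' @param maps [build_stat_maps()] result in the atlas reference frame.
#' @param aligned_ref the [normalize_atlases()] result the maps were built
#'   from (supplies the reference label map).
#' @param config a [coarse_config()].
#' @return list with `mask` (the coarse segmentation, native grid) and
#'   `diagnostics` (per-iteration DICE to the previous mask, energies,
#'   iterations used, convergence flag, per-iteration native-space masks).
#' @export
coarse_segment <- function(target, s0, maps, aligned_ref,
                           config = coarse_config()) {
  if (sum(s0$values) == 0) stop("initial mask is empty")
  work_target <- if (config$downsample) downsample2(target) else target
  if (!identical(maps$dim, dim(aligned_ref$labels[[1]]$values)))
    stop("maps and aligned reference set are on different grids")
  ref_label <- aligned_ref$labels[[aligned_ref$reference_index]]
  ref_grid <- grid_meta(ref_label)
  # registration updates that displace the region of interest by less than
  # half of the working voxel carry no information at this resolution;
  # freezing them (after damping, below) gives the discrete loop a
  # well-defined fixed point
  step_tol <- 0.5 * min(ref_grid$spacing)
  ref_box <- bbox_corners_world(ref_label)
  s_k <- s0                     # native full-resolution mask throughout
  dice_prev <- numeric(0); energies <- numeric(0)
  masks <- list()
  converged <- FALSE
  t_k <- NULL
  for (k in seq_len(config$k_iters)) {
    t_new <- align_by_moments(s_k, ref_label)
    if (!is.null(t_k)) {
      # damped fixed-point update: under-relaxation suppresses the period-2
      # registration/segmentation oscillation of the discrete iteration
      t_new <- affine_transform(
        0.5 * t_new$linear + 0.5 * t_k$linear,
        0.5 * t_new$translation + 0.5 * t_k$translation)
      if (transform_max_displacement(t_new, t_k, ref_box) < step_tol)
        t_new <- t_k
    }
    t_k <- t_new
    img_ref <- resample(work_target, t_k, ref_grid, "linear")
    energy <- build_energy(img_ref, maps, config$crf)
    s_ref <- minimize_energy(energy)
    if (sum(s_ref$values) == 0)
      stop("segmentation collapsed: graph cut returned an empty mask ",
           "(atlas/target mismatch) at iteration ", k)
    s_new <- resample(s_ref, affine_invert(t_k), grid_meta(target), "nearest")
    if (sum(s_new$values) == 0)
      stop("segmentation collapsed when mapped back to native space ",
           "at iteration ", k)
    dc <- dice(s_new, s_k)
    dice_prev <- c(dice_prev, dc)
    energies <- c(energies, energy_of_labeling(
      energy, crop_to_box(s_ref$values, energy$box)))
    s_k <- s_new
    masks[[k]] <- s_k
    if (dc >= config$convergence_dice) { converged <- TRUE; break }
  }
  list(mask = s_k,
       diagnostics = list(dice_to_previous = dice_prev, energies = energies,
                          iterations = length(dice_prev),
                          converged = converged, masks = masks,
                          final_transform = t_k))
}

# world coordinates of the 8 corners of a mask's full grid
bbox_corners_world <- function(vol) {
  d <- dim(vol$values)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  sweep(sweep(corners, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# largest displacement difference between two affines over a set of points
transform_max_displacement <- function(a, b, pts) {
  da <- affine_apply(a, pts) - affine_apply(b, pts)
  max(sqrt(rowSums(da^2)))
}

crop_to_box <- function(arr, box) {
  arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]]
}
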