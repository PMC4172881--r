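#' Specification for synthetic 3-D phantoms
#'
#' Describes the study conditions the generator emulates: an organ-like
#' superellipsoid with interpatient shape variability (smooth random warps
#' plus random affine jitter), an organ/background intensity contrast, an
#' adjacent confounder blob whose intensity is confusable with the organ
#' (emulating an adjacent structure of nearly equal intensity), and additive
#' Gaussian noise on an anisotropic CT-like grid.
#'
#' @param shape grid dimensions (default 64 x 64 x 48 voxels).
#' @param spacing voxel size in mm (default 2, 2, 3 — anisotropic like CT).
#' @param organ_mean,background_mean,confounder_mean region intensities.
#'   The confounder mean must lie within `noise_sd` of the organ mean.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param deform_sd RMS magnitude (mm) of the smooth random warps.
#' @param affine_jitter list with `rot_deg` (max per-axis rotation),
#'   `scale` (two-sided per-axis scale range) and `trans_mm` (max per-axis
#'   translation).
#' @param seed integer; every random draw flows from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), spacing = c(2, 2, 3),
                         organ_mean = 1.2, background_mean = 0.7,
                         confounder_mean = 1.16, noise_sd = 0.08,
                         deform_sd = 3,
                         affine_jitter = list(rot_deg = 8,
                                              scale = c(0.92, 1.08),
                                              trans_mm = 6),
                         seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 8L)) stop("shape must be 3 dims >= 8")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (organ_mean == background_mean)
    stop("organ_mean must differ from background_mean")
  if (abs(confounder_mean - organ_mean) > noise_sd + 1e-12)
    stop("confounder_mean must lie within noise_sd of organ_mean")
  structure(list(shape = shape, spacing = spacing, organ_mean = organ_mean,
                 background_mean = background_mean,
                 confounder_mean = confounder_mean, noise_sd = noise_sd,
                 deform_sd = deform_sd, affine_jitter = affine_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# base organ: superellipsoid, exponent 2.5, asymmetric semi-axes per sign so
# third-order moments are nontrivial (exercises the moment sign convention).
# The three principal extents are kept well separated so the second-moment
# eigenvalue ordering is stable under the random shape jitter: moment
# alignment (like the anatomy it models) assumes distinct principal axes.
phantom_base_semiaxes <- function() {
  list(pos = c(46, 32, 22), neg = c(34, 32, 26))
}

phantom_center <- function(spec) {
  spec$spacing * (spec$shape - 1) / 2
}

# implicit superellipsoid membership at centered coordinates u (n x 3, mm)
superellipsoid_inside <- function(u, exponent = 2.5) {
  ax <- phantom_base_semiaxes()
  f <- 0
  for (a in 1:3) {
    semi <- ifelse(u[, a] >= 0, ax$pos[a], ax$neg[a])
    f <- f + abs(u[, a] / semi)^exponent
  }
  f <= 1
}

# smooth random displacement field on the grid: Gaussian-filtered white noise
# per component (filter sigma in voxels), scaled to RMS magnitude `rms_mm`
smooth_displacement <- function(shape, rms_mm, filter_sigma = 8) {
  if (rms_mm <= 0) return(lapply(1:3, function(a) array(0, shape)))
  comps <- lapply(1:3, function(a)
    gaussian_smooth(array(stats::rnorm(prod(shape)), shape), filter_sigma))
  mag2 <- Reduce(`+`, lapply(comps, function(c) c^2))
  sc <- rms_mm / sqrt(mean(mag2))
  lapply(comps, function(c) c * sc)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# one phantom; must run inside an active seeded RNG context
make_phantom_impl <- function(spec) {
  shape <- spec$shape
  jit <- spec$affine_jitter
  rot <- if (jit$rot_deg > 0) stats::runif(3, -jit$rot_deg, jit$rot_deg) else c(0, 0, 0)
  scl <- if (diff(range(jit$scale)) > 0 || any(jit$scale != 1))
    stats::runif(3, jit$scale[1], jit$scale[2]) else c(1, 1, 1)
  trl <- if (jit$trans_mm > 0) stats::runif(3, -jit$trans_mm, jit$trans_mm) else c(0, 0, 0)
  disp <- smooth_displacement(shape, spec$deform_sd)
  ctr <- phantom_center(spec)
  ref <- volume_grid(array(0, shape), spec$spacing, c(0, 0, 0))
  W <- voxel_world_coords(ref)
  Wq <- W + cbind(as.numeric(disp[[1]]), as.numeric(disp[[2]]),
                  as.numeric(disp[[3]]))
  # jitter affine about the center: base -> world is R S + t, invert it
  A <- rotation_matrix(rot) %*% diag(scl)
  Ainv <- solve(A)
  U <- sweep(Wq, 2, ctr + trl, "-") %*% t(Ainv)
  inside <- superellipsoid_inside(U)
  label <- label_volume(array(as.numeric(inside), shape), spec$spacing,
                        c(0, 0, 0))
  # confounder blob: sphere just outside the +x face of the organ bbox,
  # carved so it never intersects the organ support
  fg <- which(label$values > 0)
  img_vals <- array(spec$background_mean, shape)
  if (length(fg)) {
    idx <- arrayInd(fg, shape) - 1L
    wfg <- sweep(sweep(idx, 2, spec$spacing, "*"), 2, c(0, 0, 0), "+")
    xmax <- max(wfg[, 1]); cy <- mean(wfg[, 2]); cz <- mean(wfg[, 3])
    r_conf <- 18
    cc <- c(xmax + 0.7 * r_conf, cy, cz)
    dist2 <- (W[, 1] - cc[1])^2 + (W[, 2] - cc[2])^2 + (W[, 3] - cc[3])^2
    sphere <- dist2 <= r_conf^2
    organ_dil <- dilate_mask(label, max(spec$spacing))
    conf <- sphere & !(organ_dil$values > 0)
    img_vals[label$values > 0] <- spec$organ_mean
    img_vals[conf] <- spec$confounder_mean
  }
  if (spec$noise_sd > 0)
    img_vals <- img_vals + stats::rnorm(length(img_vals), 0, spec$noise_sd)
  image <- volume_grid(img_vals, spec$spacing, c(0, 0, 0))
  list(image = image, label = label)
}

#' Generate a reproducible set of atlases
#'
#' Each atlas is the base organ deformed by a random smooth displacement
#' field and a random affine, rendered as piecewise-constant intensities
#' (organ, background, adjacent confounder) plus i.i.d. Gaussian noise.
#' All randomness flows from `spec$seed`.
#'
#' @param n number of atlases (>= 2, statistics need at least two samples).
#' @param spec a [phantom_spec()].
#' @return list of `n` elements, each `list(image = volume_grid,
#'   label = label_volume)`.
#' @export
generate_atlas_set <- function(n, spec = phantom_spec()) {
  if (n < 2) stop("an atlas set needs n >= 2")
  subseeds <- withr::with_seed(spec$seed,
                               sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i)
    withr::with_seed(subseeds[i], make_phantom_impl(spec)))
}

#' Generate a target phantom with ground truth and an imperfect initial mask
#'
#' The target is drawn from the same generative process as the atlases. The
#' initial mask emulates the output of a rough low-level pipeline: the truth
#' is perturbed by a boundary-deforming smooth warp plus a random erosion or
#' dilation (radius about 2 voxels), with the perturbation amplitude adapted
#' deterministically until `DICE(initial, truth)` falls in `[0.85, 0.97]`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` ([volume_grid()]), `truth` and `initial`
#'   (both [label_volume()]).
#' @export
generate_target <- function(spec = phantom_spec()) {
  subseeds <- withr::with_seed(spec$seed + 104729L,
                               sample.int(.Machine$integer.max - 1L, 2))
  ph <- withr::with_seed(subseeds[1], make_phantom_impl(spec))
  truth <- ph$label
  amp <- if (spec$deform_sd > 0 || spec$noise_sd > 0) 3.5 else 0
  initial <- truth
  if (amp > 0) {
    for (try in 1:30) {
      initial <- withr::with_seed(subseeds[2] + try,
                                  perturb_mask(truth, amp))
      if (sum(initial$values) == 0) { amp <- amp * 0.7; next }
      dc <- dice(initial, truth)
      if (dc < 0.85) amp <- amp * 0.8
      else if (dc > 0.97) amp <- amp * 1.25
      else break
    }
  }
  list(image = ph$image, truth = truth, initial = initial)
}

# warp + random erosion/dilation perturbation of a mask; runs under the
# caller's seed
perturb_mask <- function(truth, amp_mm) {
  shape <- dim(truth$values)
  disp <- smooth_displacement(shape, amp_mm, filter_sigma = 6)
  W <- voxel_world_coords(truth)
  Wq <- W + cbind(as.numeric(disp[[1]]), as.numeric(disp[[2]]),
                  as.numeric(disp[[3]]))
  ci <- round(sweep(Wq, 2, truth$origin, "-") %*% diag(1 / truth$spacing)) + 1
  ok <- ci[, 1] >= 1 & ci[, 1] <= shape[1] &
        ci[, 2] >= 1 & ci[, 2] <= shape[2] &
        ci[, 3] >= 1 & ci[, 3] <= shape[3]
  vals <- numeric(nrow(ci))
  vals[ok] <- truth$values[ci[ok, , drop = FALSE]]
  out <- label_volume(array(vals, shape), truth$spacing, truth$origin)
  radius <- stats::runif(1, 0.5, 2) * mean(truth$spacing)
  if (stats::runif(1) < 0.5) erode_mask(out, radius) else dilate_mask(out, radius)
}
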