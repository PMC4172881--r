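#' Geometric moments of a binary mask
#'
#' Spacing-aware moments of the foreground support: volume (mm^3), world
#' centroid (mm), the 3x3 matrix of second-order central moments (mm^2), its
#' principal axes (orthonormal columns, eigenvalues descending, determinant
#' +1) and the axis lengths (square roots of the eigenvalues, mm).
#'
#' Eigenvector sign and ordering are made deterministic: eigenvalues are
#' sorted descending; an axis whose standardized skewness is clearly nonzero
#' (|g1| > 0.2) is oriented so the skewness is positive, all other axes keep
#' the sign closest to the corresponding canonical axis; the basis is forced
#' to determinant +1 by flipping the last axis if necessary. The skewness
#' threshold is deliberately coarse: a sign that tracked small sample
#' fluctuations would flip between near-identical masks and destabilise
#' iterated registration.
#'
#' @param mask nonempty [label_volume()].
#' @return list with `volume`, `centroid`, `second_central`,
#'   `principal_axes`, `axis_lengths`.
#' @export
compute_moments <- function(mask) {
  fg <- which(mask$values > 0)
  if (length(fg) == 0L) stop("cannot compute moments of an empty mask")
  d <- dim(mask$values)
  idx <- arrayInd(fg, d) - 1L
  w <- sweep(sweep(idx, 2, mask$spacing, "*"), 2, mask$origin, "+")
  voxvol <- prod(mask$spacing)
  volume <- length(fg) * voxvol
  centroid <- colMeans(w)
  wc <- sweep(w, 2, centroid, "-")
  second <- crossprod(wc) / nrow(wc)
  eg <- eigen(second, symmetric = TRUE)  # eigenvalues already descending
  axes <- eg$vectors
  for (j in 1:3) {
    proj <- wc %*% axes[, j]
    # standardized skewness; only a clearly asymmetric axis may set the sign,
    # otherwise small sample fluctuations would flip it between near-identical
    # masks and destabilise iterated alignment
    g1 <- mean(proj^3) / max(mean(proj^2)^1.5, .Machine$double.eps)
    if (abs(g1) > 0.2) {
      if (g1 < 0) axes[, j] <- -axes[, j]
    } else if (axes[j, j] < 0) {
      axes[, j] <- -axes[, j]      # closest to the identity orientation
    }
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  list(volume = volume, centroid = centroid, second_central = second,
       principal_axes = axes,
       axis_lengths = sqrt(pmax(eg$values, 0)))
}

#' Affine alignment of two masks from geometric moments
#'
#' Returns the affine transform `T` mapping fixed-space world coordinates to
#' moving-space world coordinates, built from centroid translation, rotation
#' between principal-axis frames and per-principal-axis anisotropic scaling:
#' `T(x) = R_m S R_f^T (x - c_f) + c_m` with
#' `S = diag(axis_lengths_moving / axis_lengths_fixed)`. Resampling the
#' moving mask through `T` onto the fixed grid overlays it onto the fixed
#' mask. No shear component exists in this family (it is unidentifiable from
#' second moments).
#'
#' @param moving,fixed nonempty [label_volume()] objects.
#' @return an [affine_transform()] (fixed world -> moving world).
#' @export
align_by_moments <- function(moving, fixed) {
  mm <- compute_moments(moving)
  mf <- compute_moments(fixed)
  rel <- 1e-8 * max(mm$axis_lengths, mf$axis_lengths)
  if (any(mm$axis_lengths < rel) || any(mf$axis_lengths < rel))
    stop("degenerate moments: mask is (near-)planar, cannot align")
  S <- diag(mm$axis_lengths / mf$axis_lengths)
  L <- mm$principal_axes %*% S %*% t(mf$principal_axes)
  affine_transform(L, mm$centroid - as.numeric(L %*% mf$centroid))
}
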