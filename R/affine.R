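#' World-coordinate affine transform
#'
#' Acts on world coordinates (mm) as `x -> linear %*% x + translation`. In
#' registration use the transform maps *fixed*-space world coordinates into
#' *moving*-space world coordinates (the pull-back convention), so that
#' [resample()] with this transform overlays the moving volume onto the
#' fixed grid.
#'
#' @param linear 3x3 numeric matrix with positive determinant.
#' @param translation numeric length-3 (mm).
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must have length 3")
  if (!all(is.finite(linear)) || !all(is.finite(translation)))
    stop("affine components must be finite")
  if (det(linear) <= 0) stop("affine transform must be orientation-preserving (det > 0)")
  structure(list(linear = linear, translation = translation),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> x -> L x + t (world mm)\n")
  m <- cbind(x$linear, x$translation)
  dimnames(m) <- list(c("x", "y", "z"), c("Lx", "Ly", "Lz", "t"))
  print(signif(m, 6))
  invisible(x)
}

#' Invert / compose affine transforms
#'
#' `affine_compose(a, b)` returns the transform `x -> a(b(x))`.
#'
#' @param a,b [affine_transform()] objects.
#' @return an [affine_transform()].
#' @export
affine_invert <- function(a) {
  li <- solve(a$linear)
  affine_transform(li, -li %*% a$translation)
}

#' @rdname affine_invert
#' @export
affine_compose <- function(a, b) {
  affine_transform(a$linear %*% b$linear,
                   as.numeric(a$linear %*% b$translation) + a$translation)
}

#' Apply an affine transform to world points
#'
#' @param a an [affine_transform()].
#' @param pts n x 3 matrix of world coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
affine_apply <- function(a, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(a$linear), 2, a$translation, "+")
}

#' Serialize an affine transform to / from JSON
#'
#' The JSON carries the 3x3 linear part row-major, the translation, and the
#' convention tag `"fixed_world_to_moving_world"`.
#'
#' @param a an [affine_transform()].
#' @param path output (input) file path.
#' @return `path` invisibly; `read_affine_json()` returns the transform.
#' @export
write_affine_json <- function(a, path) {
  jsonlite::write_json(list(linear = as.numeric(t(a$linear)),
                            translation = a$translation,
                            convention = "fixed_world_to_moving_world"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(obj$linear, 3, 3, byrow = TRUE), obj$translation)
}

#' Resample a volume through an affine transform onto a reference grid
#'
#' For every voxel of the reference grid the world coordinate is mapped by
#' `transform` into the input volume's world space and the input is
#' interpolated there. Label volumes are always resampled nearest-neighbour;
#' images default to trilinear. Out-of-field voxels receive `fill`
#' (default: background 0 for labels, the input minimum for images).
#'
#' @param volume a [volume_grid()] or [label_volume()].
#' @param transform an [affine_transform()] mapping reference world
#'   coordinates to `volume` world coordinates.
#' @param reference grid metadata ([grid_meta()] of a volume, or a volume).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill out-of-field fill value.
#' @return resampled volume of the same type on the reference grid.
#' @export
resample <- function(volume, transform = affine_transform(), reference = volume,
                     interpolation = c("linear", "nearest"), fill = NULL) {
  if (inherits(reference, "volume_grid")) reference <- grid_meta(reference)
  interpolation <- match.arg(interpolation)
  if (is_label(volume)) interpolation <- "nearest"
  if (is.null(fill)) fill <- if (is_label(volume)) 0 else min(volume$values)
  if (abs(det(transform$linear)) < 1e-12) stop("singular affine transform")
  out <- cpp_affine_resample(
    as.numeric(volume$values), as.integer(dim(volume$values)),
    volume$spacing, volume$origin, transform$linear, transform$translation,
    as.integer(reference$dim), reference$spacing, reference$origin,
    interpolation == "nearest", fill)
  out <- array(out, dim = reference$dim)
  if (is_label(volume)) label_volume(out, reference$spacing, reference$origin)
  else volume_grid(out, reference$spacing, reference$origin)
}

#' Downsample a volume by a factor of two per axis
#'
#' Image blocks of 2x2x2 voxels are averaged; label blocks take the majority
#' vote with ties resolved to foreground (1). Spacing doubles; the origin
#' moves to the center of the first block so voxel centers stay consistent.
#'
#' @param volume a [volume_grid()] or [label_volume()].
#' @return downsampled volume of the same type.
#' @export
downsample2 <- function(volume) {
  d <- dim(volume$values)
  if (any(d < 2L)) stop("downsample2 needs at least 2 voxels per axis")
  dout <- as.integer(ceiling(d / 2))
  dpad <- dout * 2L
  arr <- volume$values
  if (!all(dpad == d)) { # pad by edge replication
    pad <- array(0, dpad)
    pad[1:d[1], 1:d[2], 1:d[3]] <- arr
    if (dpad[1] > d[1]) pad[dpad[1], , ] <- pad[d[1], , ]
    if (dpad[2] > d[2]) pad[, dpad[2], ] <- pad[, d[2], ]
    if (dpad[3] > d[3]) pad[, , dpad[3]] <- pad[, , d[3]]
    arr <- pad
  }
  block_sum <- arr[seq(1, dpad[1], 2), , , drop = FALSE] +
               arr[seq(2, dpad[1], 2), , , drop = FALSE]
  block_sum <- block_sum[, seq(1, dpad[2], 2), , drop = FALSE] +
               block_sum[, seq(2, dpad[2], 2), , drop = FALSE]
  block_sum <- block_sum[, , seq(1, dpad[3], 2), drop = FALSE] +
               block_sum[, , seq(2, dpad[3], 2), drop = FALSE]
  origin <- volume$origin + volume$spacing / 2
  spacing <- volume$spacing * 2
  if (is_label(volume)) {
    label_volume(array(as.numeric(block_sum >= 4), dout), spacing, origin)
  } else {
    volume_grid(block_sum / 8, spacing, origin)
  }
}
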