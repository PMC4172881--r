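#' 3-D scalar volume with grid metadata
#'
#' A `volume_grid` couples a 3-D array of intensities with the physical grid
#' it lives on: voxel spacing in mm and the world coordinate of voxel
#' (1,1,1) (the origin). Grids are axis-aligned; the world coordinate of
#' 0-based voxel index v is `origin + v * spacing`.
#'
#' @param values 3-D numeric array of intensities (finite).
#' @param spacing numeric length-3, voxel size in mm along x, y, z; all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary label volume
#'
#' Same grid semantics as [volume_grid()], but values are restricted to
#' \{0, 1\} (1 = object, 0 = background).
#'
#' @inheritParams volume_grid
#' @return An object of class `c("label_volume", "volume_grid")`.
#' @export
label_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (!all(values %in% c(0, 1))) stop("label values must be exactly 0 or 1")
  v <- volume_grid(values, spacing, origin)
  class(v) <- c("label_volume", "volume_grid")
  v
}

is_label <- function(x) inherits(x, "label_volume")

#' @export
print.volume_grid <- function(x, ...) {
  kind <- if (is_label(x)) "label_volume" else "volume_grid"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              kind, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (is_label(x)) {
    cat(sprintf("  foreground voxels: %d\n", sum(x$values > 0)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Grid metadata of a volume
#'
#' @param x a [volume_grid()] or [label_volume()].
#' @return list with `dim`, `spacing`, `origin`.
#' @export
grid_meta <- function(x) list(dim = dim(x$values), spacing = x$spacing,
                              origin = x$origin)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' World coordinates of all voxel centers
#'
#' @param x a volume.
#' @return n-voxel x 3 matrix of world mm coordinates, in array order.
#' @export
voxel_world_coords <- function(x) {
  d <- dim(x$values)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  sweep(sweep(idx, 2, x$spacing, "*"), 2, x$origin, "+")
}

# new volume on the same grid with different values
with_values <- function(x, values, label = is_label(x)) {
  values <- array(values, dim = dim(x$values))
  if (label) label_volume(values, x$spacing, x$origin)
  else volume_grid(values, x$spacing, x$origin)
}

#' Separable Gaussian smoothing with reflective boundaries
#'
#' Convolves a 3-D array with an isotropic (in voxel units) Gaussian kernel,
#' axis by axis, using half-sample reflection at the boundaries (the discrete
#' analogue of linear diffusion with Neumann boundary conditions). The kernel
#' is normalised, so constant fields are fixed points and the volume mean is
#' conserved.
#'
#' @param arr 3-D numeric array.
#' @param sigma standard deviation in voxels; 0 returns the input unchanged.
#'   May be length 3 for per-axis scales.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(arr, sigma) {
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (all(sigma <= 0)) return(arr)
  d <- dim(arr)
  out <- as.numeric(arr)
  for (axis in 0:2) {
    s <- sigma[axis + 1]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(4 * s)))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    out <- cpp_conv_axis(out, as.integer(d), k, axis)
  }
  array(out, dim = d)
}

# Gaussian first-derivative filtering along one axis (voxel units), reflect bc
gaussian_derivative_axis <- function(arr, sigma, axis) {
  d <- dim(arr)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  xs <- -half:half
  g <- exp(-0.5 * (xs / sigma)^2)
  g <- g / sum(g)
  dk <- -xs / sigma^2 * g            # d/dx of the normalised Gaussian
  dk <- rev(dk)                      # convolution (not correlation) orientation
  # normalise so a unit-slope ramp differentiates to exactly 1
  dk <- dk / sum(dk * ((seq_along(dk) - 1) - half))
  out <- as.numeric(arr)
  for (ax in setdiff(0:2, axis)) {
    k <- exp(-0.5 * (xs / sigma)^2); k <- k / sum(k)
    out <- cpp_conv_axis(out, as.integer(d), k, ax)
  }
  array(cpp_conv_axis(out, as.integer(d), dk, axis), dim = d)
}

#' Image gradient by Gaussian derivatives
#'
#' @param image a [volume_grid()].
#' @param scale derivative scale in voxels (default 1).
#' @return list of three arrays `gx`, `gy`, `gz` in intensity per mm.
#' @export
image_gradient <- function(image, scale = 1) {
  stopifnot(scale > 0)
  list(
    gx = gaussian_derivative_axis(image$values, scale, 0L) / image$spacing[1],
    gy = gaussian_derivative_axis(image$values, scale, 1L) / image$spacing[2],
    gz = gaussian_derivative_axis(image$values, scale, 2L) / image$spacing[3]
  )
}

#' Euclidean distance map to a mask (mm)
#'
#' Exact distance from each voxel center to the nearest foreground voxel
#' center, respecting anisotropic spacing.
#'
#' @param mask a [label_volume()].
#' @return 3-D array of distances in mm (`Inf` where the mask is empty).
#' @export
distance_map <- function(mask) {
  array(cpp_edt(as.numeric(mask$values), as.integer(dim(mask$values)),
                mask$spacing), dim = dim(mask$values))
}

#' Morphological dilation / erosion of a mask by a metric ball
#'
#' Implemented through exact Euclidean distance maps so the structuring
#' element is a sphere of radius `r` mm, honouring anisotropic spacing.
#'
#' @param mask a [label_volume()].
#' @param r radius in mm.
#' @return dilated or eroded [label_volume()].
#' @export
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- distance_map(mask)
  with_values(mask, as.numeric(d <= r), label = TRUE)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  inv <- with_values(mask, 1 - mask$values, label = TRUE)
  d <- distance_map(inv)
  with_values(mask, as.numeric(mask$values > 0 & d > r), label = TRUE)
}

#' Number of 6-connected foreground components
#'
#' @param mask a [label_volume()].
#' @return integer component count.
#' @export
n_components6 <- function(mask) {
  d <- dim(mask$values)
  fg <- which(mask$values > 0)
  if (length(fg) == 0L) return(0L)
  lab <- integer(length(fg))
  names(lab) <- fg
  id <- array(0L, d)
  id[fg] <- seq_along(fg)
  edges <- list()
  arr <- mask$values > 0
  # forward neighbours along each axis
  e1 <- which(arr[-d[1], , , drop = FALSE] & arr[-1, , , drop = FALSE])
  if (length(e1)) {
    co <- arrayInd(e1, d - c(1L, 0L, 0L))
    a <- id[co]; b <- id[co + matrix(c(1L, 0L, 0L), length(e1), 3, byrow = TRUE)]
    edges[[1]] <- cbind(a, b)
  }
  e2 <- which(arr[, -d[2], , drop = FALSE] & arr[, -1, , drop = FALSE])
  if (length(e2)) {
    co <- arrayInd(e2, d - c(0L, 1L, 0L))
    a <- id[co]; b <- id[co + matrix(c(0L, 1L, 0L), length(e2), 3, byrow = TRUE)]
    edges[[2]] <- cbind(a, b)
  }
  e3 <- which(arr[, , -d[3], drop = FALSE] & arr[, , -1, drop = FALSE])
  if (length(e3)) {
    co <- arrayInd(e3, d - c(0L, 0L, 1L))
    a <- id[co]; b <- id[co + matrix(c(0L, 0L, 1L), length(e3), 3, byrow = TRUE)]
    edges[[3]] <- cbind(a, b)
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && nrow(em))
    g <- igraph::add_edges(g, t(em))
  igraph::count_components(g)
}
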