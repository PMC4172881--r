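#' CRF segmentation configuration
#'
#' Parameters of the conditional random field energy: `lambda1` weights the
#' Riemannian (edge-strength-weighted surface area) term, `lambda2` the
#' antisymmetric flow term that is sensitive to the orientation of the
#' boundary relative to the image gradient. The neighbourhood is the fixed
#' 6-neighbourhood of the voxel grid. `gamma` scales the edge-stopping
#' function `g(x) = exp(-x / gamma)^(1/3)`; `"auto"` estimates it as the
#' mean gradient magnitude over the region of interest.
#'
#' @param lambda1 Riemannian weight, >= 0 (default 10; required for
#'   submodularity of the assembled energy).
#' @param lambda2 flow weight (default 4; may be negative).
#' @param gradient_scale Gaussian-derivative scale in voxels (default 1).
#' @param gamma positive scale of the edge-stopping function, or `"auto"`.
#' @param roi_dilate_vox how far (voxels) the region-of-interest bounding
#'   box is dilated before graph construction (default 8).
#' @return object of class `crf_config`.
#' @export
crf_config <- function(lambda1 = 10, lambda2 = 4, gradient_scale = 1,
                       gamma = "auto", roi_dilate_vox = 8) {
  if (lambda1 < 0) stop("lambda1 must be >= 0 (submodularity)")
  if (gradient_scale <= 0) stop("gradient_scale must be > 0")
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be positive or \"auto\"")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 gradient_scale = gradient_scale, gamma = gamma,
                 roi_dilate_vox = roi_dilate_vox),
            class = "crf_config")
}

g_edge_stop <- function(gradmag, gamma) exp(-gradmag / gamma)^(1 / 3)

#' Riemannian and flow pairwise weights
#'
#' For an ordered pair of 6-neighbour voxels (x, y): the Riemannian weight
#' is `g(||grad I(x)||) / ||x - y||` with distances in mm, and the flow
#' weight is the dot product of the image gradient at x with the unit mm
#' vector from x to y. Both evaluate the gradient at x, so the flow weight
#' is not antisymmetric under swapping x and y in general (the Finsler
#' construction); the energy carries both orderings as directed terms.
#'
#' @param image a [volume_grid()].
#' @param x,y voxel indices (1-based, length-3) that are 6-neighbours.
#' @param gradient_scale Gaussian-derivative scale in voxels.
#' @param gamma positive scale, or `"auto"` for the mean gradient magnitude
#'   over the image.
#' @return a nonnegative scalar (`riemannian_weight`) or a signed scalar
#'   (`flow_weight`).
#' @export
riemannian_weight <- function(image, x, y, gradient_scale = 1, gamma = "auto") {
  pw <- pairwise_weight_fields(image, gradient_scale, gamma)
  stopifnot(sum(abs(x - y)) == 1)
  axis <- which(x != y)
  g_at_x <- pw$g[matrix(x, 1)]
  g_at_x / (image$spacing[axis])
}

#' @rdname riemannian_weight
#' @export
flow_weight <- function(image, x, y, gradient_scale = 1, gamma = "auto") {
  pw <- pairwise_weight_fields(image, gradient_scale, gamma)
  stopifnot(sum(abs(x - y)) == 1)
  axis <- which(x != y)
  sgn <- sign(y[axis] - x[axis])
  grad_ax <- pw$grad[[axis]][matrix(x, 1)]
  sgn * grad_ax
}

pairwise_weight_fields <- function(image, gradient_scale, gamma,
                                   roi_idx = NULL) {
  gr <- image_gradient(image, gradient_scale)
  mag <- sqrt(gr$gx^2 + gr$gy^2 + gr$gz^2)
  if (identical(gamma, "auto")) {
    gamma <- if (is.null(roi_idx)) mean(mag) else mean(mag[roi_idx])
    if (gamma <= 0) gamma <- 1e-12
  }
  if (gamma <= 0) stop("gamma must be positive")
  list(g = g_edge_stop(mag, gamma), grad = list(gr$gx, gr$gy, gr$gz),
       gamma = gamma)
}

# bounding box (list of 1-based index ranges) of nonzero voxels, dilated
roi_bounding_box <- function(arr, dilate = 0L) {
  d <- dim(arr)
  fg <- which(arr > 0)
  if (!length(fg)) stop("empty region of interest")
  co <- arrayInd(fg, d)
  lo <- pmax(apply(co, 2, min) - dilate, 1L)
  hi <- pmin(apply(co, 2, max) + dilate, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Assemble the CRF energy over a region of interest
#'
#' Unary potentials are `-log` of the clamped posterior factors (appearance
#' likelihood times voting prior; the intensity-marginal denominator is
#' constant in the labelling and dropped). Pairwise potentials follow the
#' Finsler construction: for each ordered 6-neighbour pair (x, y) the cost
#' of the cut configuration S(x)=0, S(y)=1 is
#' `lambda1 * wR_x(y) - lambda2 * wf_x(y)` and of S(x)=1, S(y)=0 is
#' `lambda2 * wf_x(y)`; equal-label configurations cost zero. The graph is
#' restricted to the bounding box of `roi` dilated by
#' `config$roi_dilate_vox`; voxels outside are fixed to background and
#' cross-boundary edges are dropped.
#'
#' @param image target [volume_grid()] on the maps' grid.
#' @param maps a [build_stat_maps()] result on the same grid.
#' @param config a [crf_config()].
#' @param roi binary array (or [label_volume()]) seeding the region of
#'   interest; defaults to the atlas prior support (`count1 > 0`).
#' @return object of class `crf_energy`: `unary` (n x 2 matrix, columns =
#'   cost of label 0/1), `edges` (data frame `from`, `to`, `w01`, `w10` of
#'   ordered pairs), the box, grid metadata and `gamma` used.
#' @export
build_energy <- function(image, maps, config = crf_config(), roi = NULL) {
  if (!identical(dim(image$values), maps$dim))
    stop("image grid does not match the statistical maps")
  if (is.null(roi)) roi <- maps$count1
  if (inherits(roi, "volume_grid")) roi <- roi$values
  box <- roi_bounding_box(roi, config$roi_dilate_vox)
  sub <- function(a) a[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                       box$lo[3]:box$hi[3], drop = FALSE]
  dims <- box$hi - box$lo + 1L
  lik <- label_likelihood(maps, image)
  p0 <- pmax(sub(lik$p0) * (1 - sub(maps$prior1)), 1e-12)
  p1 <- pmax(sub(lik$p1) * sub(maps$prior1), 1e-12)
  unary <- cbind(-log(as.numeric(p0)), -log(as.numeric(p1)))
  # pairwise fields on the full grid, then restricted to the box
  roi_lin <- which(sub_mask_full(dim(image$values), box))
  pw <- pairwise_weight_fields(image, config$gradient_scale, config$gamma,
                               roi_idx = roi_lin)
  g_box <- sub(pw$g)
  grads <- lapply(pw$grad, sub)
  nvox <- prod(dims)
  lin <- array(seq_len(nvox), dims)
  edges <- vector("list", 6L)
  k <- 0L
  for (axis in 1:3) {
    da <- dims[axis]
    if (da < 2L) next
    idx_a <- slice_indices(dims, axis, 1L:(da - 1L))
    idx_b <- slice_indices(dims, axis, 2L:da)
    from <- as.integer(lin[idx_a]); to <- as.integer(lin[idx_b])
    sp <- image$spacing[axis]
    # ordered pair (from, to): +axis direction
    wR_f <- as.numeric(g_box[idx_a]) / sp
    wf_f <- as.numeric(grads[[axis]][idx_a])      # dot with +unit axis
    k <- k + 1L
    edges[[k]] <- data.frame(from = from, to = to,
                             w01 = config$lambda1 * wR_f - config$lambda2 * wf_f,
                             w10 = config$lambda2 * wf_f)
    # ordered pair (to, from): -axis direction, gradient evaluated at `to`
    wR_b <- as.numeric(g_box[idx_b]) / sp
    wf_b <- -as.numeric(grads[[axis]][idx_b])
    k <- k + 1L
    edges[[k]] <- data.frame(from = to, to = from,
                             w01 = config$lambda1 * wR_b - config$lambda2 * wf_b,
                             w10 = config$lambda2 * wf_b)
  }
  structure(list(unary = unary, edges = do.call(rbind, edges[seq_len(k)]),
                 box = box, dims = dims, full_dim = dim(image$values),
                 spacing = image$spacing, origin = image$origin,
                 gamma = pw$gamma),
            class = "crf_energy")
}

# logical mask of the box within the full grid, in full-array linear order
sub_mask_full <- function(full_dim, box) {
  m <- array(FALSE, full_dim)
  m[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- TRUE
  m
}

# index list selecting a slab of a 3-D array along `axis`
slice_indices <- function(dims, axis, range) {
  args <- list(TRUE, TRUE, TRUE)
  args[[axis]] <- range
  m <- array(FALSE, dims)
  do.call(`[<-`, c(list(m), args, list(value = TRUE)))
}

#' @export
print.crf_energy <- function(x, ...) {
  cat(sprintf("<crf_energy> %d voxels (%s box), %d directed pairwise terms\n",
              nrow(x$unary), paste(x$dims, collapse = "x"), nrow(x$edges)))
  invisible(x)
}

#' Evaluate the CRF energy of a labelling
#'
#' Plain sum of unary costs and ordered pairwise terms; the evaluation
#' oracle used by the tests.
#'
#' @param energy a [build_energy()] result.
#' @param labeling vector/array of \{0,1\} over the energy's voxel box.
#' @return the scalar energy.
#' @export
energy_of_labeling <- function(energy, labeling) {
  s <- as.numeric(labeling)
  if (length(s) != nrow(energy$unary)) stop("labelling size mismatch")
  u <- sum(energy$unary[cbind(seq_along(s), s + 1)])
  e <- energy$edges
  u + sum(e$w01 * (1 - s[e$from]) * s[e$to]) +
      sum(e$w10 * s[e$from] * (1 - s[e$to]))
}

#' Exact global minimisation of the CRF energy by min-cut/max-flow
#'
#' Each ordered pairwise term is reparameterised into unary offsets plus a
#' single nonnegative arc (the cost of cutting the pair with S(from)=0,
#' S(to)=1); per 6-neighbour pair the two ordered arcs sum to
#' `lambda1 * (wR_x(y) + wR_y(x)) >= 0`, so the pseudo-Boolean function is
#' submodular and the min cut is the exact global minimiser. Unary ties for
#' isolated voxels resolve to background.
#'
#' @param energy a [build_energy()] result.
#' @return [label_volume()] on the full grid (zeros outside the box).
#' @export
minimize_energy <- function(energy) {
  n <- nrow(energy$unary)
  u0 <- energy$unary[, 1]; u1 <- energy$unary[, 2]
  e <- energy$edges
  cap <- numeric(0); efrom <- integer(0); eto <- integer(0)
  if (!is.null(e) && nrow(e)) {
    # ordered term: w01*[S(from)=0]S(to) + w10*S(from)[S(to)=0]
    #  = w10*S(from) - w10*S(to) + (w01 + w10)*[S(from)=0]S(to)
    u1 <- u1 + tab_sum(e$from, e$w10, n) - tab_sum(e$to, e$w10, n)
    arc <- e$w01 + e$w10
    if (any(arc < -1e-9)) stop("non-submodular pairwise term after assembly")
    arc <- pmax(arc, 0)
    keep <- arc > 0
    # arc cut when from is background (sink side) and to is object (source)
    efrom <- e$to[keep]; eto <- e$from[keep]; cap <- arc[keep]
    }
  base <- pmin(u0, u1)
  a0 <- u0 - base; a1 <- u1 - base
  src <- n + 1L; snk <- n + 2L
  has0 <- which(a0 > 0); has1 <- which(a1 > 0)
  efrom <- c(efrom, rep(src, length(has0)), has1)
  eto <- c(eto, has0, rep(snk, length(has1)))
  cap <- c(cap, a0[has0], a1[has1])
  fl <- cpp_mincut(n + 2L, as.integer(efrom) - 1L, as.integer(eto) - 1L,
                   as.numeric(cap), src - 1L, snk - 1L)
  lab <- as.numeric(fl$source_side[seq_len(n)])
  # deterministic tie-break: voxels with no incident pairwise arc take the
  # unary argmin, ties resolving to background
  touched <- logical(n)
  if (length(efrom)) {
    pv <- c(efrom, eto)
    touched[pv[pv <= n]] <- TRUE
  }
  iso <- which(!touched)
  lab[iso] <- as.numeric(a1[iso] < a0[iso])
  full <- array(0, energy$full_dim)
  box <- energy$box
  full[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
    array(lab, energy$dims)
  label_volume(full, energy$spacing, energy$origin)
}

tab_sum <- function(idx, w, n) {
  out <- numeric(n)
  t <- rowsum(w, idx)
  out[as.integer(rownames(t))] <- as.numeric(t)
  out
}
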