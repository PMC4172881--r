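#' DICE overlap coefficient
#'
#' `2|X n Y| / (|X| + |Y|)` between two binary masks on the same grid.
#'
#' @param x,y [label_volume()] objects on a common grid.
#' @return overlap in `[0, 1]`.
#' @export
dice <- function(x, y) {
  stopifnot_same_grid(x, y)
  nx <- sum(x$values); ny <- sum(y$values)
  if (nx + ny == 0) stop("DICE undefined: both masks are empty")
  2 * sum(x$values * y$values) / (nx + ny)
}

# boundary voxels: foreground with a 6-neighbour background voxel or on the
# volume border
boundary_mask <- function(mask) {
  arr <- mask$values > 0
  d <- dim(arr)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
            pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
            pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  with_values(mask, as.numeric(core & !nb_all), label = TRUE)
}

#' Symmetric surface distances between two masks
#'
#' Distances (mm, spacing-aware, between voxel centers) from every boundary
#' voxel of each mask to the nearest boundary voxel of the other, pooled over
#' both directions. The boundary is the set of foreground voxels with at
#' least one 6-neighbour background voxel (volume borders count as
#' background).
#'
#' @param x,y nonempty [label_volume()] objects on a common grid.
#' @return numeric vector of pooled distances in mm.
#' @export
surface_distances <- function(x, y) {
  stopifnot_same_grid(x, y)
  if (sum(x$values) == 0 || sum(y$values) == 0)
    stop("surface distances need two nonempty masks")
  bx <- boundary_mask(x); by <- boundary_mask(y)
  dx <- distance_map(by)[bx$values > 0]  # x-boundary -> y-surface
  dy <- distance_map(bx)[by$values > 0]  # y-boundary -> x-surface
  c(dx, dy)
}

#' The five segmentation error measures
#'
#' Computes, for a reference mask `x` and an automatic segmentation `y`:
#' volumetric overlap error `m1` (%), signed relative volume difference
#' `m2` (%), and the average (`m3`), root-mean-square (`m4`) and maximum
#' (`m5`) symmetric surface distances in mm.
#'
#' @param x reference (manual) [label_volume()], nonempty.
#' @param y automatic segmentation [label_volume()], nonempty, same grid.
#' @return named list `m1..m5`.
#' @export
seg_measures <- function(x, y) {
  stopifnot_same_grid(x, y)
  nx <- sum(x$values); ny <- sum(y$values)
  if (nx == 0) stop("empty reference mask")
  if (ny == 0) stop("empty automatic mask")
  inter <- sum(x$values * y$values)
  uni <- nx + ny - inter
  m1 <- (1 - inter / uni) * 100
  m2 <- 100 * (ny - nx) / nx
  sd_pool <- surface_distances(x, y)
  list(m1 = m1, m2 = m2,
       m3 = mean(sd_pool),
       m4 = sqrt(mean(sd_pool^2)),
       m5 = max(sd_pool))
}

#' Default per-measure reference values
#'
#' Benchmark-convention reference magnitudes used to convert each error
#' measure to the 0-100 score scale; override them for any particular
#' dataset.
#'
#' @return named numeric vector `r1..r5`.
#' @export
default_reference_values <- function() {
  c(r1 = 6.4, r2 = 4.7, r3 = 1.0, r4 = 1.8, r5 = 19.0)
}

#' Convert an error measure to a 0-100 score
#'
#' `score = max(100 - 25 * |m| / r, 0)`: a measure of zero scores 100
#' (perfect match), a measure equal to its reference value scores 75
#' (human-expert performance), and measures of at least four references
#' clamp at 0. The signed volume difference is scored on its magnitude.
#'
#' @param m measure value (may be signed).
#' @param r strictly positive reference value in the same units.
#' @return score in `[0, 100]`.
#' @export
score_measure <- function(m, r) {
  if (any(r <= 0)) stop("reference value must be > 0")
  pmax(100 - 25 * abs(m) / r, 0)
}

#' Aggregate score
#'
#' Unweighted mean of the five per-measure scores (weight 0.2 each).
#'
#' @param scores numeric length-5, each in `[0, 100]`.
#' @return the aggregate score.
#' @export
aggregate_score <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) != 5L) stop("expected five per-measure scores")
  if (any(scores < 0 | scores > 100)) stop("scores must lie in [0, 100]")
  mean(scores)
}

#' Full evaluation report for a segmentation
#'
#' Convenience wrapper: measures, per-measure scores, aggregate score and
#' DICE in one list (the CLI `evaluate` output).
#'
#' @inheritParams seg_measures
#' @param refvals reference values `r1..r5` (default
#'   [default_reference_values()]).
#' @return list with `m1..m5`, `a1..a5`, `alpha`, `dice`.
#' @export
evaluate_segmentation <- function(x, y, refvals = default_reference_values()) {
  m <- seg_measures(x, y)
  a <- mapply(score_measure, unlist(m), as.numeric(refvals))
  names(a) <- paste0("a", 1:5)
  c(m, as.list(a), list(alpha = aggregate_score(a), dice = dice(x, y)))
}
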