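test_that("dice matches hand counts and handles degenerate inputs", {
  X <- cube_mask()                               # 8-voxel cube
  Y <- cube_mask(from = c(4, 3, 3), to = c(5, 4, 4)) # shifted 1 voxel in x
  expect_equal(dice(X, X), 1)
  expect_equal(dice(X, Y), 0.5)                  # 2*4 / 16
  Z <- cube_mask(from = c(7, 7, 7), to = c(8, 8, 8))
  expect_equal(dice(X, Z), 0)
  empty <- label_volume(array(0, c(10, 10, 10)))
  expect_error(dice(empty, empty), "empty")
  expect_error(dice(X, cube_mask(dim = c(9, 9, 9))), "grid")
})

test_that("the five measures match counting and hand-distance oracles", {
  X <- cube_mask(); Y <- cube_mask(from = c(4, 3, 3), to = c(5, 4, 4))
  m <- seg_measures(X, Y)
  expect_equal(m$m1, (1 - 4 / 12) * 100)
  expect_equal(m$m2, 0)

  m0 <- seg_measures(X, X)
  expect_equal(unlist(m0), c(m1 = 0, m2 = 0, m3 = 0, m4 = 0, m5 = 0))

  # single voxels 3 mm apart along z on an anisotropic grid
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  b <- array(0, c(5, 5, 5)); b[3, 3, 4] <- 1
  ms <- seg_measures(label_volume(a, c(1, 1, 3)), label_volume(b, c(1, 1, 3)))
  expect_equal(c(ms$m3, ms$m4, ms$m5), c(3, 3, 3))

  # signed volume difference
  big <- cube_mask(from = c(3, 3, 3), to = c(5, 4, 4)) # 12 voxels vs 8
  expect_equal(seg_measures(X, big)$m2, 50)
  expect_equal(seg_measures(big, X)$m2, -100 * 4 / 12)

  expect_error(seg_measures(label_volume(array(0, c(5, 5, 5))), X))
})

test_that("surface distances agree with the all-pairs boundary oracle", {
  withr::local_seed(11)
  for (rep in 1:5) {
    dm <- c(8, 8, 8); sp <- runif(3, 0.5, 3)
    mk <- function() {
      arr <- array(0, dm)
      f <- sort(sample(2:7, 2)); g <- sort(sample(2:7, 2)); h <- sort(sample(2:7, 2))
      arr[f[1]:f[2], g[1]:g[2], h[1]:h[2]] <- 1
      label_volume(arr, sp)
    }
    X <- mk(); Y <- mk()
    got <- sort(surface_distances(X, Y))
    # oracle: exhaustive pairwise distances between boundary voxel centers
    bnd <- function(m) {
      b <- atlascut:::boundary_mask(m)
      co <- which(b$values > 0, arr.ind = TRUE) - 1
      sweep(co, 2, sp, "*")
    }
    bx <- bnd(X); by <- bnd(Y)
    d2 <- function(A, B) {
      apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2))))
    }
    oracle <- sort(c(d2(bx, by), d2(by, bx)))
    expect_lt(max(abs(got - oracle)), 1e-9)
  }
})

test_that("measures and dice are invariant under common translation and m1/m3/m4/m5 are ordered", {
  withr::local_seed(4)
  X <- cube_mask(from = c(3, 3, 3), to = c(6, 5, 4), spacing = c(1, 2, 1.5))
  Y <- cube_mask(from = c(4, 3, 3), to = c(6, 6, 5), spacing = c(1, 2, 1.5))
  m <- seg_measures(X, Y)
  # translate both masks identically (shift origin)
  X2 <- label_volume(X$values, X$spacing, origin = c(7, -3, 2))
  Y2 <- label_volume(Y$values, Y$spacing, origin = c(7, -3, 2))
  expect_equal(unlist(seg_measures(X2, Y2)), unlist(m))
  expect_equal(dice(X2, Y2), dice(X, Y))
  expect_true(m$m3 <= m$m4 && m$m4 <= m$m5)
  # growing the symmetric difference never decreases m1
  Ybig <- label_volume(pmin(Y$values + cube_mask(from = c(8, 8, 8),
                                                 to = c(9, 9, 9))$values, 1),
                       Y$spacing)
  expect_gte(seg_measures(X, Ybig)$m1, m$m1)
})

test_that("score conversion follows the 25-per-reference rule with clamping", {
  expect_equal(score_measure(0, 1), 100)
  expect_equal(score_measure(0, 19), 100)
  expect_equal(score_measure(5, 5), 75)    # human-expert level
  expect_equal(score_measure(4 * 2.5, 2.5), 0)
  expect_equal(score_measure(100, 1), 0)   # clamped below at 0
  expect_equal(score_measure(-3, 3), 75)   # signed measures scored on |m|
  expect_error(score_measure(1, 0), "> 0")
})

test_that("aggregate score is the plain mean of the five per-measure scores", {
  expect_equal(aggregate_score(c(100, 100, 100, 100, 100)), 100)
  expect_equal(aggregate_score(c(0, 0, 0, 0, 0)), 0)
  expect_equal(aggregate_score(c(37, 56, 21, 19, 39)), 34.4)
  expect_error(aggregate_score(c(10, 20, 30, 40)), "five")
  expect_error(aggregate_score(c(10, 20, 30, 40, 101)))
})

test_that("evaluate_segmentation assembles a coherent report", {
  X <- cube_mask(); Y <- cube_mask(from = c(4, 3, 3), to = c(5, 4, 4))
  rep <- evaluate_segmentation(X, Y)
  expect_named(rep, c("m1", "m2", "m3", "m4", "m5",
                      "a1", "a2", "a3", "a4", "a5", "alpha", "dice"))
  expect_equal(rep$alpha, mean(unlist(rep[paste0("a", 1:5)])))
  expect_equal(rep$dice, 0.5)
  perfect <- evaluate_segmentation(X, X)
  expect_equal(perfect$alpha, 100)
})
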