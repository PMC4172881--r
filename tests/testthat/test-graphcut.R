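test_that("edge weights match scalar formulas on constant, ramp and edge images", {
  # constant image: g(0) = 1, weight = 1 / spacing along the edge axis
  cimg <- volume_grid(array(5, c(4, 4, 4)), spacing = c(2, 2, 3))
  expect_equal(riemannian_weight(cimg, c(2, 2, 2), c(3, 2, 2), gamma = 1), 1 / 2)
  expect_equal(riemannian_weight(cimg, c(2, 2, 2), c(2, 2, 3), gamma = 1), 1 / 3)
  expect_equal(flow_weight(cimg, c(2, 2, 2), c(3, 2, 2)), 0)

  # g at the automatic scale: ||grad|| = gamma gives exp(-1/3)
  expect_equal(atlascut:::g_edge_stop(3, 3), exp(-1 / 3)^1)
  expect_equal(atlascut:::g_edge_stop(1, 1), exp(-1)^(1 / 3), tolerance = 1e-12)

  # linear ramp along z: flow weight is +slope along +z, -slope along -z,
  # zero across the gradient (interior voxel, away from the reflected rim)
  dm <- c(12, 12, 12); sp <- c(1, 1, 2)
  W <- voxel_world_coords(volume_grid(array(0, dm), sp))
  ramp <- volume_grid(array(0.5 * W[, 3], dm), sp)
  x <- c(6, 6, 6)
  expect_equal(flow_weight(ramp, x, c(6, 6, 7)), 0.5, tolerance = 1e-6)
  expect_equal(flow_weight(ramp, x, c(6, 6, 5)), -0.5, tolerance = 1e-6)
  expect_equal(flow_weight(ramp, x, c(7, 6, 6)), 0, tolerance = 1e-9)

  # monotonicity: stronger gradients shrink the Riemannian weight
  g <- atlascut:::g_edge_stop(c(0, 1, 2, 5, 10), 2)
  expect_true(all(diff(g) < 0))
})

test_that("build_energy realises the Finsler pairwise structure", {
  withr::local_seed(21)
  dm <- c(3, 3, 3)
  img <- volume_grid(array(rnorm(prod(dm), 1, 0.3), dm), c(1, 2, 1.5))
  mp <- tiny_maps(dm, spacing = img$spacing)
  cfg <- crf_config(lambda1 = 3, lambda2 = 2, roi_dilate_vox = 0)
  en <- build_energy(img, mp, cfg, roi = array(1, dm))
  e <- en$edges
  # submodularity identity: the two ordered terms of every pair sum to
  # lambda1 * (wR_x(y) + wR_y(x)) >= 0; the flow parts cancel
  expect_true(all(e$w01 + e$w10 >= -1e-12))
  # lambda = 0 kills all pairwise terms
  en0 <- build_energy(img, mp, crf_config(lambda1 = 0, lambda2 = 0,
                                          roi_dilate_vox = 0),
                      roi = array(1, dm))
  expect_true(all(abs(en0$edges$w01) < 1e-12 & abs(en0$edges$w10) < 1e-12))
  # grid mismatch is rejected
  expect_error(build_energy(volume_grid(array(0, c(4, 4, 4))), mp),
               "grid|match")
  # confident prior + likelihood ordering shows in the unaries
  mp2 <- mp; mp2$prior1[] <- mp$epsilon; mp2$prior1[14] <- 1 - mp$epsilon
  mp2$mu1[] <- 5; mp2$mu0[] <- -5; mp2$var0[] <- 1; mp2$var1[] <- 1
  en2 <- build_energy(volume_grid(array(5, dm), img$spacing), mp2,
                      cfg, roi = array(1, dm))
  expect_lt(en2$unary[14, 2], en2$unary[14, 1])
})

test_that("a two-voxel energy reproduces the hand expansion of the CRF model", {
  withr::local_seed(22)
  dm <- c(2, 1, 1)
  img <- volume_grid(array(c(1, 2), dm), c(2, 2, 2))
  mp <- tiny_maps(dm, spacing = img$spacing)
  cfg <- crf_config(lambda1 = 1.5, lambda2 = 0.8, roi_dilate_vox = 0,
                    gamma = 1)
  en <- build_energy(img, mp, cfg, roi = array(1, dm))
  gr <- image_gradient(img, 1)
  gmag <- sqrt(gr$gx^2 + gr$gy^2 + gr$gz^2)
  g <- atlascut:::g_edge_stop(gmag, 1)
  lik <- label_likelihood(mp, img$values)
  u <- function(x, l) {
    p <- if (l == 1) lik$p1[x] * mp$prior1[x] else lik$p0[x] * (1 - mp$prior1[x])
    -log(max(p, 1e-12))
  }
  wR12 <- g[1] / 2; wR21 <- g[2] / 2
  wf12 <- gr$gx[1]; wf21 <- -gr$gx[2]
  psi <- function(s1, s2) {
    cfg$lambda1 * wR12 * (1 - s1) * s2 +
      cfg$lambda2 * wf12 * (s1 * (1 - s2) - s2 * (1 - s1)) +
      cfg$lambda1 * wR21 * (1 - s2) * s1 +
      cfg$lambda2 * wf21 * (s2 * (1 - s1) - s1 * (1 - s2))
  }
  for (s1 in 0:1) for (s2 in 0:1) {
    expect_equal(energy_of_labeling(en, c(s1, s2)),
                 u(1, s1) + u(2, s2) + psi(s1, s2),
                 tolerance = 1e-9,
                 label = sprintf("labeling (%d,%d)", s1, s2))
  }
})

test_that("minimize returns the exact global minimum on exhaustively checkable grids", {
  withr::local_seed(23)
  for (rep in 1:40) {
    dm <- sample(1:3, 3, replace = TRUE)
    while (prod(dm) > 12 || prod(dm) < 2) dm <- sample(1:3, 3, replace = TRUE)
    img <- volume_grid(array(rnorm(prod(dm), 1, 0.4), dm),
                       spacing = runif(3, 0.5, 3))
    mp <- tiny_maps(dm, spacing = img$spacing)
    cfg <- crf_config(lambda1 = runif(1, 0, 8), lambda2 = runif(1, -4, 4),
                      roi_dilate_vox = 0)
    en <- build_energy(img, mp, cfg, roi = array(1, dm))
    lab <- minimize_energy(en)
    expect_equal(energy_of_labeling(en, lab$values), enumerate_min(en),
                 tolerance = 1e-9)
  }
})

test_that("minimize handles degenerate unary-dominated instances deterministically", {
  withr::local_seed(24)
  dm <- c(2, 2, 2)
  img <- volume_grid(array(rnorm(8), dm))
  mp <- tiny_maps(dm)
  en <- build_energy(img, mp, crf_config(lambda1 = 0, lambda2 = 0,
                                         roi_dilate_vox = 0),
                     roi = array(1, dm))
  en$unary[, 1] <- 1; en$unary[, 2] <- 1
  expect_true(all(minimize_energy(en)$values == 0))  # ties to background
  en$unary[, 2] <- -5
  expect_true(all(minimize_energy(en)$values == 1))
  en$unary[, 2] <- c(1, 1, 0.5, 1, 1, 0.5, 1, 1)
  lab <- minimize_energy(en)
  expect_equal(as.numeric(lab$values), as.numeric(en$unary[, 2] < 1))
})

test_that("energy evaluation matches simple closed forms and dominates random labelings", {
  withr::local_seed(25)
  dm <- c(3, 3, 2)
  img <- volume_grid(array(rnorm(prod(dm), 1, 0.3), dm))
  mp <- tiny_maps(dm)
  en <- build_energy(img, mp, crf_config(roi_dilate_vox = 0),
                     roi = array(1, dm))
  expect_equal(energy_of_labeling(en, rep(0, prod(dm))), sum(en$unary[, 1]))
  expect_equal(energy_of_labeling(en, rep(1, prod(dm))), sum(en$unary[, 2]))

  # complement symmetry of the Riemannian part on a constant image
  cimg <- volume_grid(array(2, dm))
  enr <- build_energy(cimg, mp, crf_config(lambda2 = 0, roi_dilate_vox = 0),
                      roi = array(1, dm))
  s <- sample(0:1, prod(dm), TRUE)
  pair_cost <- function(en, s) {
    e <- en$edges
    sum(e$w01 * (1 - s[e$from]) * s[e$to]) + sum(e$w10 * s[e$from] * (1 - s[e$to]))
  }
  expect_equal(pair_cost(enr, s), pair_cost(enr, 1 - s), tolerance = 1e-12)

  # sampled dominance: the minimizer beats 200 random labelings
  lab <- minimize_energy(en)
  emin <- energy_of_labeling(en, lab$values)
  rand <- replicate(200, energy_of_labeling(en, sample(0:1, prod(dm), TRUE)))
  expect_true(all(emin <= rand + 1e-9))
})

test_that("config validation enforces the submodularity precondition", {
  expect_error(crf_config(lambda1 = -1), "lambda1")
  expect_error(crf_config(gradient_scale = 0), "gradient_scale")
  expect_error(crf_config(gamma = -2), "gamma")
  expect_silent(crf_config(lambda2 = -4))  # negative flow weight is legal
})
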