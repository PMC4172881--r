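test_that("statistics at a voxel match the hand-computed three-atlas case", {
  dm <- c(4, 4, 4)
  al <- list(images = lapply(c(10, 12, 14), function(v)
                               volume_grid(array(v, dm))),
             labels = rep(list(label_volume(array(1, dm))), 3))
  mp <- build_stat_maps(al, sigma_s = 0)
  expect_true(all(mp$mu1 == 12))
  expect_true(all(mp$var1 == 4))               # unbiased, denominator 2
  expect_true(all(mp$prior1 == 1 - 1 / 6))     # clamped at 1 - eps, eps = 1/2N
  expect_true(all(mp$count0 + mp$count1 == 3))
})

test_that("stat maps equal a brute-force per-voxel oracle on 8^3 inputs", {
  withr::local_seed(8)
  dm <- c(8, 8, 8); N <- 5
  al <- list(images = lapply(1:N, function(i)
                               volume_grid(array(rnorm(prod(dm), 1, 0.2), dm))),
             labels = lapply(1:N, function(i)
                               label_volume(array(sample(0:1, prod(dm), TRUE), dm))))
  mp <- build_stat_maps(al, sigma_s = 0)
  I <- sapply(al$images, function(v) as.numeric(v$values))
  L <- sapply(al$labels, function(v) as.numeric(v$values))
  rng <- range(I); floor_v <- (0.01 * (rng[2] - rng[1]))^2
  for (lab in 0:1) {
    sel_g <- L == lab
    gmu <- mean(I[sel_g]); gvar <- var(I[sel_g])
    mu_o <- var_o <- numeric(prod(dm))
    for (x in seq_len(prod(dm))) {
      vals <- I[x, L[x, ] == lab]
      mu_o[x] <- if (length(vals) >= 1) mean(vals) else gmu
      var_o[x] <- if (length(vals) >= 2) var(vals) else gvar
    }
    var_o <- pmax(var_o, floor_v)
    expect_equal(as.numeric(mp[[paste0("mu", lab)]]), mu_o, tolerance = 1e-12)
    expect_equal(as.numeric(mp[[paste0("var", lab)]]), var_o, tolerance = 1e-12)
  }
  expect_equal(as.numeric(mp$prior1),
               pmin(pmax(rowSums(L) / N, 1 / (2 * N)), 1 - 1 / (2 * N)))
  expect_true(all(mp$count0 + mp$count1 == N))
})

test_that("sigma_s = 0 is the exact unsmoothed limit and constants are diffusion fixed points", {
  withr::local_seed(9)
  dm <- c(6, 6, 6)
  al <- list(images = lapply(1:3, function(i)
                               volume_grid(array(rnorm(prod(dm)), dm))),
             labels = lapply(1:3, function(i)
                               label_volume(array(sample(0:1, prod(dm), TRUE), dm))))
  m0 <- build_stat_maps(al, sigma_s = 0)
  m0b <- build_stat_maps(al, sigma_s = 0)
  expect_identical(m0$mu1, m0b$mu1)

  # identical noise-free atlases: organ statistics constant, smoothing inert
  cube <- cube_mask(dim = c(8, 8, 8), from = c(3, 3, 3), to = c(6, 6, 6))
  img <- with(list(v = array(0.7, c(8, 8, 8))), {
    v[cube$values > 0] <- 1.2; volume_grid(v) })
  al2 <- list(images = rep(list(img), 3), labels = rep(list(cube), 3))
  msm <- build_stat_maps(al2, sigma_s = 2)
  expect_true(all(abs(msm$mu1 - 1.2) < 1e-9))
  expect_true(all(abs(msm$mu0 - 0.7) < 1e-9))
  expect_true(all(msm$var1 == msm$var_floor))  # zero variance floored
})

test_that("Gaussian smoothing conserves the volume mean (Neumann boundaries)", {
  withr::local_seed(10)
  arr <- array(rnorm(16 * 12 * 8), c(16, 12, 8))
  for (s in c(0.7, 2, 4)) {
    sm <- gaussian_smooth(arr, s)
    expect_lt(abs(mean(sm) - mean(arr)) / abs(mean(arr) + 1e-9), 1e-6)
  }
  expect_identical(gaussian_smooth(arr, 0), arr)
})

test_that("label likelihoods are normalised and match scalar evaluations", {
  withr::local_seed(12)
  dm <- c(5, 5, 5)
  mp <- tiny_maps(dm)
  img <- array(rnorm(prod(dm), 100, 15), dm)
  lk <- label_likelihood(mp, img)
  expect_true(all(abs(lk$p0 + lk$p1 - 1) < 1e-12))
  expect_true(all(lk$p0 >= 0 & lk$p1 >= 0))

  # equal means and variances: exactly 1/2 each
  mp$mu0[] <- 3; mp$mu1[] <- 3; mp$var0[] <- 2; mp$var1[] <- 2
  lk2 <- label_likelihood(mp, array(rnorm(prod(dm)), dm))
  expect_true(all(abs(lk2$p0 - 0.5) < 1e-12))

  # scalar case mu0 = 0, mu1 = 2, unit variances, I = 0
  mp$mu0[] <- 0; mp$mu1[] <- 2; mp$var0[] <- 1; mp$var1[] <- 1
  lk3 <- label_likelihood(mp, array(0, dm))
  expect_equal(lk3$p0[1], exp(0) / (exp(0) + exp(-2)), tolerance = 1e-12)
  lk4 <- label_likelihood(mp, array(1, dm))
  expect_equal(lk4$p1[1], 0.5, tolerance = 1e-12)

  # strongly separated means: near-certain assignment
  mp$mu0[] <- 10; mp$mu1[] <- 0; mp$var0[] <- 1; mp$var1[] <- 1
  lk5 <- label_likelihood(mp, array(0, dm))
  expect_true(all(lk5$p1 > 1 - 1e-9))
})

test_that("normalisation aligns translated copies onto the reference", {
  tg <- generate_target(phantom_spec(seed = 61))
  base <- list(image = tg$image, label = tg$truth)
  shifted <- function(t) list(
    image = volume_grid(base$image$values, base$image$spacing,
                        base$image$origin + t),
    label = label_volume(base$label$values, base$label$spacing,
                         base$label$origin + t))
  atlases <- list(base, shifted(c(4, -2, 3)), shifted(c(-6, 2, -3)))
  al <- normalize_atlases(atlases, reference_index = 1)
  expect_lt(max(abs(al$transforms[[1]]$linear - diag(3))), 1e-12)
  expect_lt(max(abs(al$transforms[[1]]$translation)), 1e-12)
  for (i in 2:3) expect_gte(dice(al$labels[[i]], al$labels[[1]]), 0.99)
  expect_error(normalize_atlases(atlases[1]), "at least 2")
})

test_that("stat maps persist to disk and back", {
  withr::local_seed(13)
  mp <- tiny_maps(c(4, 4, 4))
  dir <- file.path(withr::local_tempdir(), "maps")
  write_stat_maps(mp, dir)
  mp2 <- read_stat_maps(dir)
  expect_equal(mp2$mu1, mp$mu1, tolerance = 1e-12)
  expect_equal(mp2$prior1, mp$prior1, tolerance = 1e-12)
  expect_identical(mp2$count1, mp$count1)
  expect_equal(mp2$n_atlases, mp$n_atlases)
})
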