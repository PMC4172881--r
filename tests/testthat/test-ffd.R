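test_that("mutual information behaves like an information measure", {
  withr::local_seed(81)
  dm <- c(16, 16, 12)
  img <- volume_grid(array(rnorm(prod(dm), 1, 0.3), dm), c(2, 2, 3))
  # self-MI dominates MI with an independently shuffled copy
  shuffled <- volume_grid(array(sample(img$values), dm), img$spacing)
  expect_gt(mutual_information(img, img), mutual_information(img, shuffled))
  # constant moving image: zero information
  const <- volume_grid(array(1, dm), img$spacing)
  expect_lt(abs(mutual_information(img, const)), 0.05)
  # invariance to a constant intensity offset (bin-aligned)
  offset <- volume_grid(img$values + 10, img$spacing)
  expect_equal(mutual_information(img, offset), mutual_information(img, img),
               tolerance = 1e-9)
  # too few in-field samples
  far <- matrix(rep(c(1e4, 1e4, 1e4), 150), ncol = 3, byrow = TRUE)
  expect_error(mutual_information(img, img, samples = far), "100")
})

test_that("registering an image to itself stays near the identity", {
  tg <- generate_target(phantom_spec(seed = 82))
  cfg <- ffd_config(levels = 2, grid_spacings = c(32, 16),
                    iters_per_level = 50, samples_per_iter = 800, seed = 5)
  f <- register_ffd(tg$image, tg$image, tg$truth, cfg)
  expect_lte(mean(abs(f$coef)), 0.5)
  expect_gte(attr(f, "mi_after"), attr(f, "mi_before") - 0.05)
  f2 <- register_ffd(tg$image, tg$image, tg$truth, cfg)
  expect_identical(f$coef, f2$coef)            # seeded determinism
  expect_error(register_ffd(tg$image, tg$image,
                            label_volume(array(0, dim(tg$image$values)),
                                         tg$image$spacing),
                            cfg),
               "empty")
})

test_that("a known synthetic warp is substantially recovered", {
  tg <- generate_target(phantom_spec(seed = 83))
  img <- tg$image; mask <- tg$truth
  dmask <- dilate_mask(mask, 10)
  co <- which(dmask$values > 0, arr.ind = TRUE) - 1
  W <- sweep(sweep(co, 2, img$spacing, "*"), 2, img$origin, "+")
  lat <- atlascut:::make_lattice(apply(W, 2, min), apply(W, 2, max), 24)
  withr::local_seed(77)
  coef_true <- matrix(runif(prod(lat$ldim) * 3, -4, 4), ncol = 3)
  fld_true <- atlascut:::ffd_field(coef_true, lat, grid_meta(img))
  moving <- apply_ffd(img, fld_true, "linear")

  emask <- erode_mask(mask, 6)
  lm <- which(emask$values > 0, arr.ind = TRUE) - 1
  LM <- sweep(sweep(lm[round(seq(1, nrow(lm), length.out = 150)), ],
                    2, img$spacing, "*"), 2, img$origin, "+")
  init_err <- mean(sqrt(rowSums(ffd_displacement(fld_true, LM)^2)))

  cfg <- ffd_config(levels = 3, grid_spacings = c(48, 24, 12),
                    iters_per_level = 80, samples_per_iter = 2000, seed = 5)
  fld <- register_ffd(img, moving, mask, cfg)
  d_est <- ffd_displacement(fld, LM)
  res_err <- sqrt(rowSums((d_est + ffd_displacement(fld_true, LM + d_est))^2))
  expect_lte(mean(res_err), 0.5 * init_err)
  expect_gt(attr(fld, "mi_after"), attr(fld, "mi_before"))

  # displacement support: identically zero beyond the dilated mask plus the
  # cubic support radius of the finest lattice
  margin <- cfg$mask_dilation_mm + 4 * sqrt(3) * max(fld$lspacing)
  outside <- which(dilate_mask(mask, margin)$values == 0, arr.ind = TRUE) - 1
  if (nrow(outside) > 0) {
    OP <- sweep(sweep(outside[round(seq(1, nrow(outside),
                                        length.out = min(400, nrow(outside)))), ,
                              drop = FALSE],
                      2, img$spacing, "*"), 2, img$origin, "+")
    expect_equal(max(abs(ffd_displacement(fld, OP))), 0)
  }
})

test_that("apply_ffd reproduces translations and inverts approximately", {
  tg <- generate_target(phantom_spec(seed = 84))
  img <- tg$image
  lat <- atlascut:::make_lattice(c(0, 0, 0),
                                 (dim(img$values) - 1) * img$spacing, 40)
  # pure translation field: every coefficient set to t
  t_mm <- c(4, -2, 6)
  coef <- matrix(rep(t_mm, each = prod(lat$ldim)), ncol = 3)
  fld <- atlascut:::ffd_field(coef, lat, grid_meta(img))
  warped <- apply_ffd(img, fld, "linear")
  shifted <- resample(img, affine_transform(diag(3), t_mm), img, "linear")
  inb <- shifted$values != min(img$values) & warped$values != min(img$values)
  expect_lt(max(abs(warped$values - shifted$values)[inb]), 1e-6)

  # zero coefficients: exact identity
  fld0 <- atlascut:::ffd_field(matrix(0, prod(lat$ldim), 3), lat,
                               grid_meta(img))
  expect_equal(apply_ffd(img, fld0, "linear")$values, img$values,
               tolerance = 1e-12)
  # labels warp nearest and stay binary
  wl <- apply_ffd(tg$truth, fld, "nearest")
  expect_true(all(wl$values %in% c(0, 1)))

  # warp then inverse-warp a smooth blob: high overlap for moderate warps
  withr::local_seed(85)
  lat2 <- atlascut:::make_lattice(c(0, 0, 0),
                                  (dim(img$values) - 1) * img$spacing, 32)
  cf <- matrix(runif(prod(lat2$ldim) * 3, -4, 4), ncol = 3)
  fw <- atlascut:::ffd_field(cf, lat2, grid_meta(img))
  bw <- atlascut:::ffd_field(-cf, lat2, grid_meta(img))
  blob <- tg$truth
  roundtrip <- apply_ffd(apply_ffd(blob, fw), bw)
  expect_gte(dice(roundtrip, blob), 0.97)
})

test_that("FFD fields serialize to disk and back", {
  lat <- atlascut:::make_lattice(c(0, 0, 0), c(60, 60, 60), 20)
  coef <- matrix(rnorm(prod(lat$ldim) * 3), ncol = 3)
  fld <- atlascut:::ffd_field(coef, lat,
                              list(dim = c(10L, 10L, 10L),
                                   spacing = c(2, 2, 3), origin = c(0, 0, 0)))
  dir <- file.path(withr::local_tempdir(), "ffd")
  write_ffd(fld, dir)
  fld2 <- read_ffd(dir)
  expect_equal(fld2$coef, fld$coef, tolerance = 1e-12)
  expect_equal(fld2$ldim, fld$ldim)
  expect_equal(fld2$domain$spacing, fld$domain$spacing)
})

test_that("ffd_config validates its schedule", {
  expect_error(ffd_config(levels = 3, grid_spacings = c(32, 16)), "per level")
  expect_error(ffd_config(levels = 2, grid_spacings = c(16, 32)), "decreasing")
  expect_error(ffd_config(samples_per_iter = 50), "100")
})
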