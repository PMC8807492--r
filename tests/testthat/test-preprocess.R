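test_that("denoise honors its identity and variance contracts", {
  ph <- test_phantom(seed = 1, noise_sigma = 10, noise_model = "gaussian")
  expect_identical(denoise(ph$image, strength = 0), ph$image)
  const <- intensity_volume(matrix(5, 40, 40), c(90, 90))
  expect_equal(denoise(const, strength = 2)$data, const$data, tolerance = 1e-12)
  # variance oracle before/after
  v0 <- var(ph$image$data[ph$image$mask])
  for (m in c("gaussian", "nlm")) {
    sm <- denoise(ph$image, m, strength = if (m == "gaussian") 1 else 10)
    expect_identical(dim(sm$data), dim(ph$image$data))
    expect_lt(var(sm$data[sm$mask]), v0)
  }
  expect_error(denoise(ph$image, "median"), "arg")
})

test_that("bias correction recovers a flat field on a constant image", {
  const <- intensity_volume(matrix(50, 48, 48), c(90, 90))
  bc <- correct_bias_field(const)
  expect_true(all(abs(bc$field - 1) < 0.01))
  expect_error(correct_bias_field(intensity_volume(matrix(0, 40, 40), c(90, 90))),
               "indeterminate")
})

test_that("bias correction recovers a known ramp on a contrast-free phantom", {
  # uniform tissue mean isolates field recovery from anatomy leakage
  ph <- test_phantom(seed = 3, noise_sigma = 0, bias_field_type = "ramp",
                     stroma_mean_SI = 100, fat_mean_SI = 100)
  bc <- correct_bias_field(ph$image)
  msk <- ph$image$mask
  expect_gt(cor(bc$field[msk], ph$bias_field[msk]), 0.95)
  # normalization contract: masked mean preserved within 0.5%
  expect_lt(abs(mean(bc$volume$data[msk]) / mean(ph$image$data[msk]) - 1),
            0.005)
  expect_true(all(bc$field > 0))
})

test_that("isotropic resampling obeys extent arithmetic", {
  ph <- test_phantom(seed = 2, shape = c(48, 48, 6))  # 90 x 90 x 180 um
  expect_identical(resample_isotropic(ph$image, 90)[c("spacing")]$spacing,
                   rep(90, 3))
  rs <- resample_isotropic(ph$image, 90)
  expect_identical(dim(rs$data)[1:2], dim(ph$image$data)[1:2])
  # axis-3 size doubles within one voxel
  expect_lte(abs(dim(rs$data)[3] - 2 * dim(ph$image$data)[3]), 1)
  # already-isotropic input is returned untouched
  iso <- intensity_volume(matrix(rnorm(100), 10, 10), c(90, 90))
  expect_identical(resample_isotropic(iso, 90), iso)
  # constants stay constant
  const <- intensity_volume(array(3, dim = c(20, 20, 4)), c(90, 90, 180))
  expect_true(all(abs(resample_isotropic(const)$data - 3) < 1e-12))
})

test_that("outlier filtering removes exactly the three-sigma tails", {
  const <- intensity_volume(matrix(2, 30, 30), c(90, 90))
  expect_identical(filter_outliers(const)$mask, const$mask)
  # counting oracle on a seeded standard-normal field
  set.seed(42)
  vol <- intensity_volume(matrix(rnorm(10000), 100, 100), c(90, 90))
  fo <- filter_outliers(vol)
  frac <- 1 - sum(fo$mask) / sum(vol$mask)
  expect_gt(frac, 0.0005)
  expect_lt(frac, 0.006)
  expect_identical(fo$data, vol$data)  # intensities untouched
  # hand arithmetic: one spike among twenty uniform values (a single outlier
  # among n values can reach z = (n-1)/sqrt(n) at most, so n must exceed 9)
  v <- c(rep(1, 19), 1000)
  mu <- mean(v); s <- sd(v)
  vol20 <- intensity_volume(matrix(v, 4, 5), c(1, 1))
  fo20 <- filter_outliers(vol20)
  expect_identical(as.vector(fo20$mask), v >= mu - 3 * s & v <= mu + 3 * s)
  expect_false(fo20$mask[4, 5])
})

test_that("the full chain is idempotent up to tolerance and keeps spacing sane", {
  ph <- test_phantom(seed = 9)
  p1 <- preprocess(ph$image)
  p2 <- preprocess(p1$volume)
  m1 <- mean(p1$volume$data[p1$volume$mask])
  m2 <- mean(p2$volume$data[p2$volume$mask])
  expect_lt(abs(m2 - m1) / m1, 0.01)
  expect_identical(p1$volume$spacing, ph$image$spacing)
  expect_identical(nrow(p1$stages), 5L)
  # masked intensities lie within the 3-sigma band of the pre-filter stats
  pre <- preprocess(ph$image, denoise_strength = 0.5)
  before <- resample_isotropic(correct_bias_field(denoise(ph$image))$volume)
  v <- before$data[before$mask]
  expect_true(all(pre$volume$data[pre$volume$mask] >= mean(v) - 3 * sd(v) &
                    pre$volume$data[pre$volume$mask] <= mean(v) + 3 * sd(v)))
})
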