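test_that("quantization follows the fixed-bin-number formula", {
  # hand arithmetic over [0, 128] at G = 64
  vals <- c(0, 63.9, 64, 128)
  vol <- intensity_volume(matrix(vals, 2, 2), c(1, 1))
  q <- quantize(vol, 64)
  expect_identical(as.vector(q$levels), c(0L, 31L, 32L, 63L))
  # constant image degenerates to level 0 with a warning
  expect_warning(q0 <- quantize(intensity_volume(matrix(7, 4, 4), c(1, 1))),
                 "constant")
  expect_true(all(q0$levels == 0L))
  # invalid pixels stay unquantized
  m <- matrix(TRUE, 2, 2); m[1, 1] <- FALSE
  qm <- quantize(intensity_volume(matrix(vals, 2, 2), c(1, 1), m), 64)
  expect_true(is.na(qm$levels[1, 1]))
  expect_error(quantize(vol, 1), ">= 2")
})

test_that("windowed GLCM matches hand enumeration and brute force", {
  # 2x2 image [[0,0],[1,1]], horizontal pairs only
  lev <- rbind(c(0L, 0L), c(1L, 1L))
  q <- qv_from_levels(lev, 2)
  p <- glcm_window(q, c(1L, 1L), radius = 3, offsets = rbind(c(0L, 1L)))
  expect_equal(unclass(p)[1:2, 1:2], rbind(c(0.5, 0), c(0, 0.5)),
               ignore_attr = TRUE)
  # constant window: single entry equal to 1
  qc <- qv_from_levels(matrix(3L, 5, 5), 8)
  pc <- glcm_window(qc, c(3L, 3L), radius = 2)
  expect_equal(pc[4, 4], 1)
  expect_equal(sum(pc), 1)
  # brute-force oracle on random 7x7 windows: normalization and symmetry
  set.seed(10)
  for (rep in 1:3) {
    lev7 <- matrix(sample(0:3, 49, replace = TRUE), 7, 7)
    lev7[sample(49, 6)] <- NA
    q7 <- qv_from_levels(lev7, 4)
    p7 <- glcm_window(q7, c(4L, 4L), radius = 3)
    C <- Reduce(`+`, lapply(1:4, function(o) {
      off <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1))[o, ]
      ref_glcm_counts(lev7, 4, 4, 3, off[1], off[2], 4)
    }))
    expect_equal(unclass(p7), C / sum(C), ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(sum(p7), 1, tolerance = 1e-9)
    expect_equal(unclass(p7), t(unclass(p7)), ignore_attr = TRUE)
  }
})

test_that("Haralick features obey their closed forms", {
  # degenerate single-entry distribution at level a = 3
  p1 <- matrix(0, 8, 8); p1[4, 4] <- 1
  f1 <- haralick_features(p1)
  expect_equal(f1[["energy"]], 1)
  expect_equal(f1[["entropy"]], 0)
  expect_equal(f1[["contrast"]], 0)
  expect_equal(f1[["homogeneity"]], 1)
  expect_equal(f1[["dissimilarity"]], 0)
  expect_equal(f1[["autocorrelation"]], 9)  # a^2 with a = 3
  # two-point diagonal distribution
  p2 <- rbind(c(0.5, 0), c(0, 0.5))
  f2 <- haralick_features(p2)
  expect_equal(f2[["energy"]], 0.5)
  expect_equal(f2[["entropy"]], 1)
  expect_equal(f2[["contrast"]], 0)
  expect_equal(f2[["correlation"]], 1)
  expect_equal(f2[["sum_average"]], 1)  # p_{x+y}(0) = p_{x+y}(2) = 0.5
  # uniform over G^2 = 16 cells
  f3 <- haralick_features(matrix(1 / 16, 4, 4))
  expect_equal(f3[["entropy"]], 4)
  expect_equal(f3[["energy"]], 1 / 16)
  expect_error(haralick_features(matrix(1, 2, 2)), "normalized")
})

test_that("texture maps of a constant image hit the closed-form limits", {
  vol <- intensity_volume(matrix(5, 24, 24), c(90, 90))
  q <- suppressWarnings(quantize(vol))
  stack <- texture_map(q)
  expect_true(all(stack$mask))
  expect_true(all(stack$maps$entropy == 0))
  expect_true(all(stack$maps$energy == 1))
  expect_true(all(stack$maps$homogeneity == 1))
  expect_true(all(stack$maps$contrast == 0))
})

test_that("windowed maps match the naive per-pixel reference exactly", {
  set.seed(33)
  lev <- matrix(sample(0:7, 32 * 32, replace = TRUE), 32, 32)
  lev[sample(length(lev), 30)] <- NA
  q <- qv_from_levels(lev, 8)
  stack <- texture_map(q)
  ref <- ref_texture_maps(lev, 8)
  for (fn in haralick_feature_names())
    expect_equal(stack$maps[[fn]], ref[, , fn], tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("feature bounds hold over phantom-driven maps", {
  ph <- test_phantom(seed = 12)
  mp <- phantom_maps(ph)
  st <- mp$stack
  ok <- st$mask
  expect_true(all(st$maps$energy[ok] > 0 & st$maps$energy[ok] <= 1))
  expect_true(all(st$maps$homogeneity[ok] > 0 & st$maps$homogeneity[ok] <= 1))
  expect_true(all(st$maps$entropy[ok] >= 0 &
                    st$maps$entropy[ok] <= 2 * log2(st$G)))
  expect_true(all(abs(st$maps$correlation[ok]) <= 1 + 1e-12))
  expect_true(all(st$maps$contrast[ok] >= 0))
})

test_that("interior feature values are translation invariant", {
  set.seed(8)
  base <- matrix(sample(0:5, 20 * 20, replace = TRUE), 20, 20)
  shifted <- matrix(NA_integer_, 27, 27)
  shifted[8:27, 8:27] <- base
  s1 <- texture_map(qv_from_levels(base, 6))
  s2 <- texture_map(qv_from_levels(shifted, 6))
  for (fn in haralick_feature_names())
    expect_equal(s1$maps[[fn]], s2$maps[[fn]][8:27, 8:27],
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("stroma entropy exceeds tumor entropy and grows with heterogeneity", {
  # amplitudes below entropy saturation at the global dynamic range
  means <- vapply(c(0.1, 0.2, 0.35), function(amp) {
    ph <- test_phantom(seed = 14, stroma_texture_scale = amp)
    mp <- phantom_maps(ph)
    ent <- mp$stack$maps$entropy
    lab <- resample_labels(ph$labels, dim(ent), mp$stack$spacing)$labels
    sel_s <- lab == 2L & mp$stack$mask
    sel_t <- lab == 1L & mp$stack$mask
    c(stroma = mean(ent[sel_s]), tumor = mean(ent[sel_t]))
  }, numeric(2))
  expect_true(all(diff(means["stroma", ]) > 0))   # monotone heterogeneity
  expect_gt(means["stroma", 2], means["tumor", 2]) # two-region contrast
})

test_that("the 3D 13-direction mode runs and respects the mask", {
  ph <- test_phantom(seed = 15, shape = c(40, 40, 4))
  pp <- preprocess(ph$image, target_spacing = 90)
  q <- quantize(pp$volume, G = 16)
  st <- texture_map(q, radius = 2, mode = "3d-13dir")
  expect_identical(dim(st$mask), dim(q$levels))
  expect_true(all(is.na(st$maps$entropy[!st$mask])))
  expect_error(texture_map(quantize(intensity_volume(matrix(rnorm(64), 8, 8),
                                                     c(1, 1)), 4),
                           mode = "3d-13dir"), "3D")
})
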