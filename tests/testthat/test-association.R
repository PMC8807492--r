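test_that("binning by stromal proportion follows the 10-point increments", {
  tab <- data.frame(proportion = c(5, 15, 95), entropy = c(1, 2, 10))
  b <- bin_by_proportion(tab, "entropy")
  expect_equal(b$centers, seq(5, 95, 10))
  expect_equal(b$counts, c(1, 1, rep(0, 7), 1))
  expect_equal(b$means[c(1, 2, 10), "entropy"], c(1, 2, 10),
               ignore_attr = TRUE)
  # boundary membership: [0,10), ..., [90,100]
  expect_equal(stromatex:::prop_bin_index(c(0, 9.999, 10, 90, 100)),
               c(1L, 1L, 2L, 10L, 10L))
})

test_that("bin means equal a direct group-by recomputation on a phantom table", {
  mp <- phantom_maps(test_phantom(seed = 5))
  tab <- pixel_feature_table(mp$stack, mp$prop)
  b <- bin_by_proportion(tab)
  idx <- pmin(floor(tab$proportion / 10), 9) + 1
  for (fn in c("SI", "entropy", "energy")) {
    ref <- tapply(tab[[fn]], factor(idx, levels = 1:10), mean)
    expect_equal(unname(b$means[, fn]), unname(as.vector(ref)))
  }
  expect_equal(sum(b$counts), nrow(tab))
})

test_that("pearson matches hand computation and handles degeneracy", {
  x10 <- seq(5, 95, 10)
  expect_equal(pearson(x10, 2 * x10 + 1)$r, 1)
  expect_equal(pearson(x10, -x10)$r, -1)
  # hand sums for x = 1:4, y = (1,3,2,5): r = 5.5 / sqrt(5 * 8.75)
  pr <- pearson(1:4, c(1, 3, 2, 5))
  expect_equal(pr$r, 5.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(pr$p, 2 * pt(-abs(pr$r * sqrt(2 / (1 - pr$r^2))), df = 2))
  # zero variance: undefined, not zero
  expect_true(is.na(pearson(x10, rep(1, 10))$r))
  expect_true(is.na(pearson(c(1, 2), c(3, 4))$r))
})

test_that("association report is skipped gracefully below 3 bins", {
  tab <- data.frame(proportion = rep(5, 50), entropy = rnorm(50))
  expect_warning(a <- association_report(table = tab), "fewer than 3")
  expect_true(is.na(a$report$r[a$report$feature == "entropy"]))
})

test_that("a feature copying the proportion correlates perfectly", {
  set.seed(1)
  tab <- data.frame(proportion = runif(500, 0, 100))
  tab$entropy <- tab$proportion
  # binning replaces centers by within-bin means, so r is 1 up to the
  # sub-bin-width discrepancy
  a <- association_report(table = tab)
  expect_equal(a$report$r[a$report$feature == "entropy"], 1, tolerance = 1e-3)
})

test_that("the report is invariant under joint row permutation", {
  mp <- phantom_maps(test_phantom(seed = 6))
  tab <- pixel_feature_table(mp$stack, mp$prop)
  set.seed(2)
  perm <- sample(nrow(tab))
  a1 <- association_report(table = tab)
  a2 <- association_report(table = tab[perm, ])
  expect_equal(a1$report, a2$report)
})

test_that("binned r equals a brute-force recomputation from the raw table", {
  mp <- phantom_maps(test_phantom(seed = 7))
  tab <- pixel_feature_table(mp$stack, mp$prop)
  a <- association_report(table = tab)
  idx <- pmin(floor(tab$proportion / 10), 9) + 1
  for (fn in c("SI", "entropy", "homogeneity")) {
    means <- tapply(tab[[fn]], factor(idx, levels = 1:10), mean)
    keep <- !is.na(means)
    r_ref <- cor(seq(5, 95, 10)[keep], as.vector(means[keep]))
    expect_equal(a$report$r[a$report$feature == fn], r_ref,
                 tolerance = 1e-12)
  }
})

test_that("misaligned grids are rejected", {
  mp <- phantom_maps(test_phantom(seed = 5))
  small <- mp$prop
  small$proportion <- small$proportion[1:50, 1:50]
  small$mask <- small$mask[1:50, 1:50]
  expect_error(pixel_feature_table(mp$stack, small), "misaligned")
})
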