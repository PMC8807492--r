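test_that("label resampling votes by majority with the priority tie-break", {
  dict <- stromatex_labels()
  # identical grids: identity
  lm1 <- label_map(matrix(c(1L, 2L, 0L, 3L), 2, 2), c(90, 90))
  expect_identical(resample_labels(lm1, c(2, 2), c(90, 90)), lm1)
  # strict majority: {tumor, tumor, stroma, fat} -> tumor
  src <- label_map(matrix(c(1L, 1L, 2L, 3L), 2, 2), c(45, 45))
  expect_identical(as.vector(resample_labels(src, c(1, 1), c(90, 90))$labels), 1L)
  # tie {tumor, tumor, stroma, stroma} -> stroma by priority
  src2 <- label_map(matrix(c(1L, 1L, 2L, 2L), 2, 2), c(45, 45))
  expect_identical(as.vector(resample_labels(src2, c(1, 1), c(90, 90))$labels), 2L)
  # disjoint extents error
  expect_error(resample_labels(src2, c(1, 1), c(90000, 90000)),
               NA)  # still overlaps at origin
})

test_that("label resampling approximately preserves tissue area on phantoms", {
  ph <- test_phantom(seed = 2, shape = c(128, 128))
  rl <- resample_labels(ph$labels, c(64, 64), c(180, 180))
  a_src <- sum(ph$labels$labels != 0L) * prod(ph$labels$spacing)
  a_tgt <- sum(rl$labels != 0L) * prod(rl$spacing)
  # boundary ties resolve toward tissue by the priority rule, so exact
  # one-pixel preservation is not attainable; require 2% relative agreement
  expect_lt(abs(a_tgt - a_src) / a_src, 0.02)
})

test_that("stromal proportion matches hand counts on constructed disks", {
  offs <- stromatex:::disk_offsets(3)
  expect_identical(nrow(offs), 29L)  # the r <= 3 Euclidean disk
  # pure regions
  pure_s <- label_map(matrix(2L, 11, 11), c(90, 90))
  expect_true(all(stromal_proportion(pure_s)$proportion == 100))
  pure_t <- label_map(matrix(1L, 11, 11), c(90, 90))
  expect_true(all(stromal_proportion(pure_t)$proportion == 0))
  # 15 stroma / 14 tumor in the center disk -> 100 * 15 / 29
  lab <- matrix(0L, 9, 9)
  for (k in seq_len(nrow(offs)))
    lab[5 + offs$dx[k], 5 + offs$dy[k]] <- if (k <= 15) 2L else 1L
  pr <- stromal_proportion(label_map(lab, c(90, 90)), radius = 3)
  expect_equal(pr$proportion[5, 5], 100 * 15 / 29, tolerance = 1e-12)
  # fat and void are excluded from the ratio
  lab2 <- lab
  lab2[lab2 == 0L] <- 3L
  pr2 <- stromal_proportion(label_map(lab2, c(90, 90)), radius = 3)
  expect_equal(pr2$proportion[5, 5], pr$proportion[5, 5])
  # neighborhoods with no tumor/stroma are masked, with a warning if empty
  expect_warning(stromal_proportion(label_map(matrix(3L, 9, 9), c(90, 90))),
                 "empty")
})

test_that("stromal proportion is equivariant under tumor/stroma label swap", {
  ph <- test_phantom(seed = 4)
  lab <- ph$labels$labels
  swapped <- lab
  swapped[lab == 1L] <- 2L
  swapped[lab == 2L] <- 1L
  p1 <- stromal_proportion(ph$labels)
  p2 <- stromal_proportion(label_map(swapped, ph$labels$spacing))
  expect_identical(p1$mask, p2$mask)
  expect_equal(p2$proportion[p2$mask], 100 - p1$proportion[p1$mask])
})

test_that("Dice coefficient satisfies its formula and properties", {
  A <- matrix(FALSE, 4, 4); A[1:2, 1:2] <- TRUE
  expect_equal(dice(A, A), 1)
  B <- matrix(FALSE, 4, 4); B[3:4, 3:4] <- TRUE
  expect_equal(dice(A, B), 0)
  # |A| = |B| = 4 with overlap 2
  C <- matrix(FALSE, 4, 4); C[2:3, 1:2] <- TRUE
  expect_equal(dice(A, C), 0.5)
  expect_equal(dice(A, C), dice(C, A))
  expect_gte(dice(A, A | C), dice(A, C))
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(A, matrix(FALSE, 2, 2)), "shapes")
})
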