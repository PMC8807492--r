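# tiny labeled table helper: two Gaussian blobs in feature space
blob_table <- function(n = 200, sep = 4, seed = 1, features = c("entropy", "energy")) {
  with_seed <- stromatex:::with_seed
  with_seed(seed, {
    half <- n %/% 2
    cls <- factor(rep(c("poor", "rich"), each = half), levels = c("poor", "rich"))
    tab <- data.frame(tumor = 1L, x = seq_len(2 * half), y = 1L)
    for (f in features)
      tab[[f]] <- rnorm(2 * half) + ifelse(cls == "rich", sep, 0)
    # remaining feature columns constant-noise so the default set exists
    for (f in setdiff(haralick_feature_names(), features))
      tab[[f]] <- rnorm(2 * half)
    tab$proportion <- ifelse(cls == "rich", 80, 20)
    tab$class <- cls
    tab
  })
}

test_that("pixel labeling thresholds and excludes the boundary", {
  prop <- structure(list(proportion = matrix(c(100, 0, 50, 73.2), 2, 2),
                         mask = matrix(TRUE, 2, 2), spacing = c(90, 90),
                         radius = 3),
                    class = "stromal_proportion_map")
  lab <- label_pixels(prop)
  expect_identical(as.character(lab[1, 1]), "rich")
  expect_identical(as.character(lab[2, 1]), "poor")
  expect_true(is.na(lab[1, 2]))
  expect_identical(attr(lab, "n_excluded"), 1L)
  expect_error(label_pixels(prop, threshold = 0), "in \\(0,100\\)")
})

test_that("sampling and splitting follow the stated fractions and balance", {
  tab <- blob_table(n = 1000, seed = 3)
  sp <- sample_and_split(tab, sample_frac = 0.30, train_frac = 0.50, seed = 5)
  expect_identical(sp$n_sampled, 300L)
  expect_identical(sp$n_test, 150L)
  expect_lte(sp$n_train, 150L)                     # balancing only removes rows
  cnt <- table(sp$train$class)
  expect_identical(unname(cnt[1]), unname(cnt[2])) # balanced training set
  # train/test disjointness
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  # determinism over seeds
  sp2 <- sample_and_split(tab, seed = 5)
  expect_identical(sp$train, sp2$train)
  sp3 <- sample_and_split(tab, seed = 6)
  expect_false(identical(sp$test, sp3$test))
  # single-class input fails loudly
  one <- tab[tab$class == "rich", ]
  expect_error(sample_and_split(one), "both classes")
})

test_that("the SVM separates blobs, is deterministic, and drops dead features", {
  tab <- blob_table(n = 240, sep = 4, seed = 7)
  m <- train_svm(tab, folds = 20, seed = 1)
  expect_gt(m$cv_accuracy, 95)
  m2 <- train_svm(tab, folds = 20, seed = 1)
  expect_identical(m$cv_accuracy, m2$cv_accuracy)
  # zero-variance feature dropped with a warning
  tab$entropy <- 1
  expect_warning(mz <- train_svm(tab, folds = 5, seed = 1), "zero-variance")
  expect_false("entropy" %in% mz$features)
})

test_that("permuted labels drive CV accuracy to chance", {
  accs <- vapply(1:10, function(s) {
    tab <- blob_table(n = 200, sep = 4, seed = s)
    tab$class <- stromatex:::with_seed(100 + s, sample(tab$class))
    train_svm(tab, folds = 5, seed = s)$cv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("confusion rates match hand arithmetic and their identities", {
  truth <- factor(rep(c("rich", "poor"), c(100, 100)), levels = c("poor", "rich"))
  pred <- truth
  pred[1:30] <- "poor"            # 30 FN
  pred[101:138] <- "rich"         # 38 FP
  cr <- confusion_rates(truth, pred)
  expect_identical(unname(cr$counts), c(70L, 30L, 62L, 38L))
  expect_equal(unname(cr$rates["accuracy"]), 66)
  expect_equal(unname(cr$rates["TPR"]), 70)
  expect_equal(unname(cr$rates["TNR"]), 62)
  expect_equal(unname(cr$rates["TPR"] + cr$rates["FNR"]), 100)
  expect_equal(unname(cr$rates["TNR"] + cr$rates["FPR"]), 100)
  # perfect and all-poor predictors
  expect_equal(unname(confusion_rates(truth, truth)$rates[c("accuracy", "FPR", "FNR")]),
               c(100, 0, 0))
  allpoor <- factor(rep("poor", 200), levels = c("poor", "rich"))
  expect_equal(unname(confusion_rates(truth, allpoor)$rates[c("accuracy", "TPR", "TNR")]),
               c(50, 0, 100))
})

test_that("swapping the class encoding swaps TPR and TNR", {
  tab <- blob_table(n = 300, sep = 2, seed = 9)
  sp <- sample_and_split(tab, sample_frac = 0.8, seed = 2)
  m <- train_svm(sp$train, folds = 5, seed = 2)
  ev <- evaluate(m, sp$test)
  flip <- function(f) factor(ifelse(f == "rich", "poor", "rich"),
                             levels = c("poor", "rich"))
  cr_sw <- confusion_rates(flip(sp$test$class), flip(ev$pred))
  expect_equal(unname(cr_sw$rates["TPR"]), unname(ev$rates["TNR"]))
  expect_equal(unname(cr_sw$rates["TNR"]), unname(ev$rates["TPR"]))
  expect_equal(unname(cr_sw$rates["accuracy"]), unname(ev$rates["accuracy"]))
})

test_that("predicted maps agree with evaluate and reject mismatched features", {
  mp <- phantom_maps(test_phantom(seed = 8))
  tab <- pixel_feature_table(mp$stack, mp$prop)
  sp <- sample_and_split(tab, sample_frac = 0.4, seed = 3)
  m <- train_svm(sp$train, folds = 5, seed = 3)
  pm <- predict_map(m, mp$stack, mp$prop)
  # evaluation-map correct fraction equals the reported accuracy
  expect_equal(100 * mean(pm$evaluation[!is.na(pm$evaluation)]),
               unname(pm$rates["accuracy"]))
  # above the majority-class baseline on the phantom
  base <- max(table(pm$truth)) / length(pm$truth) * 100
  expect_gt(unname(pm$rates["accuracy"]), base)
  bad <- m
  bad$features <- c(bad$features, "not_a_feature")
  expect_error(predict(bad, tab), "mismatch")
})
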