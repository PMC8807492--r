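label_pixels_vec <- function(p, threshold = 50) {
  cls <- rep(NA_character_, length(p))
  cls[p > threshold] <- "rich"
  cls[p < threshold] <- "poor"
  factor(cls, levels = c("poor", "rich"))
}

#' Stroma-rich / stroma-poor pixel labeling
#'
#' Thresholds a stromal proportion map into classes: proportion above the
#' threshold is stroma-rich, below is stroma-poor, exactly at the threshold
#' is excluded (`NA`) since neither class is defined there; the number of
#' excluded pixels is reported as an attribute.
#'
#' @param prop A `stromal_proportion_map`.
#' @param threshold Percent, in (0, 100); default 50.
#' @return Factor array (levels poor/rich) with attribute `n_excluded`.
#' @export
label_pixels <- function(prop, threshold = 50) {
  if (!inherits(prop, "stromal_proportion_map"))
    stop("`prop` must be a stromal_proportion_map")
  if (threshold <= 0 || threshold >= 100) stop("`threshold` must be in (0,100)")
  cls <- label_pixels_vec(as.vector(prop$proportion), threshold)
  out <- array(cls, dim = dim(prop$proportion))
  attr(out, "n_excluded") <- sum(prop$mask & prop$proportion == threshold)
  out
}

#' Sample pixels and split into balanced train / unbalanced test sets
#'
#' Randomly samples a fraction of all labeled pixels (pooled across tumors),
#' splits the sample into disjoint train and test halves, then balances the
#' training half by random undersampling of the majority class. The test set
#' is left at its natural class mix.
#'
#' @param table A [pixel_feature_table()] (rows with `NA` class are dropped).
#' @param sample_frac Fraction of pixels sampled (default 0.30).
#' @param train_frac Fraction of the sample used for training (default 0.50).
#' @param seed Integer seed driving sampling, splitting and undersampling.
#' @return List with `train` (balanced), `test`, and bookkeeping counts.
#' @export
sample_and_split <- function(table, sample_frac = 0.30, train_frac = 0.50,
                             seed = 1L) {
  tab <- table[!is.na(table$class), , drop = FALSE]
  if (nlevels(droplevels(tab$class)) < 2)
    stop("both classes must be present before sampling; counts: ",
         paste(table(tab$class), collapse = "/"))
  with_seed(seed, {
    n <- nrow(tab)
    samp <- sort(sample.int(n, size = floor(sample_frac * n)))
    stab <- tab[samp, , drop = FALSE]
    ntr <- floor(train_frac * nrow(stab))
    tr_idx <- sort(sample.int(nrow(stab), size = ntr))
    train <- stab[tr_idx, , drop = FALSE]
    test <- stab[-tr_idx, , drop = FALSE]
    cnt <- table(train$class)
    if (any(cnt == 0))
      stop("a class vanished from the training sample; counts: ",
           paste(cnt, collapse = "/"))
    m <- min(cnt)
    keep <- unlist(lapply(levels(train$class), function(l) {
      ix <- which(train$class == l)
      if (length(ix) > m) sample(ix, m) else ix
    }))
    train <- train[sort(keep), , drop = FALSE]
    list(train = train, test = test,
         n_total = n, n_sampled = nrow(stab),
         n_train = nrow(train), n_test = nrow(test), seed = seed)
  })
}

svm_feature_columns <- function(with_si = FALSE) {
  c(if (with_si) "SI", haralick_feature_names())
}

fit_svm_once <- function(X, y01, C, gamma, kernel, eps = 1e-3) {
  yy <- ifelse(y01 == 1, 1, -1)
  fit <- svm_train_cpp(X, yy, C, gamma, if (kernel == "linear") 0L else 1L,
                       eps, max_iter = 200L * nrow(X) + 10000L)
  sv <- which(fit$alpha > 1e-8)
  list(Xsv = X[sv, , drop = FALSE], coef = fit$alpha[sv] * yy[sv],
       b = fit$b, gamma = gamma, kernel = kernel,
       iterations = fit$iterations)
}

svm_decide <- function(model, X) {
  svm_decision_cpp(model$Xsv, model$coef, model$b, model$gamma,
                   if (model$kernel == "linear") 0L else 1L, X)
}

#' Train the stroma classifier (SVM with cross-validation)
#'
#' Standardizes the features with the training-set mean and standard
#' deviation (zero-variance features are dropped with a warning), estimates
#' the stratified k-fold cross-validation accuracy (default 20 folds), and
#' refits the final support vector machine on the full training set. The SVM
#' is a C-support vector classifier solved by sequential minimal
#' optimization; the default kernel is RBF with `gamma = 1 / n_features`
#' on the standardized features and `C = 1`.
#'
#' @param train A balanced training table from [sample_and_split()].
#' @param folds Cross-validation folds (default 20).
#' @param seed Integer seed for fold assignment.
#' @param with_si Include signal intensity as a 14th input (default `FALSE`:
#'   the 13 texture features only).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C Soft-margin cost (default 1).
#' @param gamma RBF width; default `1 / n_features`.
#' @return A `stromatex_svm` model: standardization parameters, support
#'   vectors, coefficients, CV accuracy (percent) and configuration.
#' @export
train_svm <- function(train, folds = 20L, seed = 1L, with_si = FALSE,
                      kernel = c("rbf", "linear"), C = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  cols <- svm_feature_columns(with_si)
  missing_cols <- setdiff(cols, names(train))
  if (length(missing_cols))
    stop("training table lacks feature columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(train) < 2 * folds)
    stop("need at least 2 rows per fold")
  y01 <- as.integer(train$class == "rich")
  if (length(unique(y01)) < 2) stop("training set must contain both classes")
  X <- as.matrix(train[, cols, drop = FALSE])
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  drop <- sdev == 0 | !is.finite(sdev)
  if (any(drop)) {
    warning("dropping zero-variance features: ",
            paste(cols[drop], collapse = ", "))
    cols <- cols[!drop]; X <- X[, !drop, drop = FALSE]
    mu <- mu[!drop]; sdev <- sdev[!drop]
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)

  cv_acc <- with_seed(seed, {
    fold_of <- integer(nrow(Xs))
    for (cl in unique(y01)) {            # stratified fold assignment
      ix <- which(y01 == cl)
      fold_of[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      if (length(unique(y01[tr])) < 2 || !any(!tr)) next
      mdl <- fit_svm_once(Xs[tr, , drop = FALSE], y01[tr], C, gamma, kernel)
      pred <- as.integer(svm_decide(mdl, Xs[!tr, , drop = FALSE]) > 0)
      correct <- correct + sum(pred == y01[!tr])
    }
    100 * correct / nrow(Xs)
  })

  final <- fit_svm_once(Xs, y01, C, gamma, kernel)
  structure(list(features = cols, center = mu, scale = sdev,
                 Xsv = final$Xsv, coef = final$coef, b = final$b,
                 gamma = gamma, kernel = kernel, C = C,
                 cv_accuracy = cv_acc, folds = folds, seed = seed,
                 n_train = nrow(Xs)),
            class = "stromatex_svm")
}

#' @export
print.stromatex_svm <- function(x, ...) {
  cat(sprintf("<stromatex_svm> %s kernel, %d features, %d SVs, %d-fold CV accuracy %.1f%%\n",
              x$kernel, length(x$features), nrow(x$Xsv), x$folds,
              x$cv_accuracy))
  invisible(x)
}

#' Predict stroma-rich/poor classes for a feature table
#'
#' @param object A `stromatex_svm`.
#' @param newdata Data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes (levels poor/rich).
#' @export
predict.stromatex_svm <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols))
    stop("feature-set mismatch; missing: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  factor(ifelse(svm_decide(object, Xs) > 0, "rich", "poor"),
         levels = c("poor", "rich"))
}

#' Confusion-matrix rates
#'
#' Builds the confusion counts with stroma-rich as the positive class and
#' derives accuracy, true/false positive and negative rates, all in percent.
#' The identities TPR + FNR = 100 and TNR + FPR = 100 hold exactly; rates
#' with an empty reference class are `NA`.
#'
#' @param truth,pred Factors with levels poor/rich.
#' @return List with `counts` (TP, FN, TN, FP) and `rates` (accuracy, TPR,
#'   TNR, FPR, FNR, percent).
#' @export
confusion_rates <- function(truth, pred) {
  ok <- !is.na(truth) & !is.na(pred)
  truth <- truth[ok]; pred <- pred[ok]
  tp <- sum(truth == "rich" & pred == "rich")
  fn <- sum(truth == "rich" & pred == "poor")
  tn <- sum(truth == "poor" & pred == "poor")
  fp <- sum(truth == "poor" & pred == "rich")
  pos <- tp + fn; neg <- tn + fp
  rates <- c(accuracy = if (pos + neg > 0) 100 * (tp + tn) / (pos + neg) else NA_real_,
             TPR = if (pos > 0) 100 * tp / pos else NA_real_,
             TNR = if (neg > 0) 100 * tn / neg else NA_real_,
             FPR = if (neg > 0) 100 * fp / neg else NA_real_,
             FNR = if (pos > 0) 100 * fn / pos else NA_real_)
  list(counts = c(TP = tp, FN = fn, TN = tn, FP = fp), rates = rates)
}

#' Evaluate a trained model on held-out pixels
#'
#' @param model A `stromatex_svm`.
#' @param test Held-out [pixel_feature_table()] rows (disjoint from
#'   training).
#' @return A `classification_result`: predictions, confusion counts and
#'   rates (see [confusion_rates()]).
#' @export
evaluate <- function(model, test) {
  pred <- predict(model, test)
  cr <- confusion_rates(test$class, pred)
  structure(c(list(pred = pred, n_test = nrow(test)), cr),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> n=%d  acc %.1f%%  TPR %.1f%%  TNR %.1f%%  FPR %.1f%%  FNR %.1f%%\n",
              x$n_test, x$rates["accuracy"], x$rates["TPR"], x$rates["TNR"],
              x$rates["FPR"], x$rates["FNR"]))
  invisible(x)
}

#' Predicted and evaluation segmentation maps
#'
#' Classifies every valid pixel of a specimen's texture map stack and renders
#' two label rasters: the predicted segmentation (stroma-rich vs stroma-poor)
#' and the evaluation map marking each pixel correct or incorrect against the
#' histology-derived class. Per-specimen accuracy is attached.
#'
#' @param model A `stromatex_svm`.
#' @param stack A `texture_map_stack`.
#' @param prop The matching `stromal_proportion_map`.
#' @param threshold Class threshold, percent (default 50).
#' @return List with `predicted` (integer array: `NA` invalid, 0 poor,
#'   1 rich), `evaluation` (`NA` invalid, 0 incorrect, 1 correct), `truth`,
#'   and `rates` from [confusion_rates()].
#' @export
predict_map <- function(model, stack, prop, threshold = 50) {
  tab <- pixel_feature_table(stack, prop, threshold = threshold)
  tab <- tab[!is.na(tab$class), , drop = FALSE]
  pred <- predict(model, tab)
  d <- dim(stack$mask)
  idx <- if (ncol(tab) >= 4 && "z" %in% names(tab)) {
    cbind(tab$x, tab$y, tab$z)
  } else {
    cbind(tab$x, tab$y)
  }
  flat <- if (is.matrix(idx) && ncol(idx) == 3)
    idx[, 1] + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2]
  else idx[, 1] + (idx[, 2] - 1) * d[1]
  predicted <- array(NA_integer_, dim = d)
  predicted[flat] <- as.integer(pred == "rich")
  evaluation <- array(NA_integer_, dim = d)
  evaluation[flat] <- as.integer(pred == tab$class)
  cr <- confusion_rates(tab$class, pred)
  list(predicted = predicted, evaluation = evaluation,
       truth = tab$class, counts = cr$counts, rates = cr$rates)
}
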