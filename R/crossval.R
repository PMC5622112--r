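#' Stratified k-fold cross-validated accuracy of the linear SVM
#'
#' Folds are stratified by class with a fixed seed. The standardizer and
#' the SVM are fitted inside each training fold only, so no information
#' leaks from the test fold. Class balance is enforced by seeded
#' downsampling of the larger class before folding. The standard error is
#' `sd(per-fold accuracies) / sqrt(k)`.
#'
#' @param x feature matrix (cells x features).
#' @param y two-class labels; each class must have at least `k` members.
#' @param k number of folds (default 10; `k = n` gives leave-one-out on
#'   balanced input).
#' @param C SVM regularization constant.
#' @param seed seed controlling downsampling, fold assignment and solver
#'   order.
#' @param standardize z-score per training fold (default TRUE).
#' @param balance downsample the larger class (default TRUE).
#' @return object of class `cv_result`: list with `accuracy` (mean),
#'   `se`, `fold_accuracy`, `folds`, `k`, `n`.
#' @export
cross_validate <- function(x, y, k = 10, C = 1, seed = 1,
                           standardize = TRUE, balance = TRUE) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  lv <- sort(unique(y))
  if (length(lv) != 2) stop("need exactly 2 classes")
  idx <- .with_seed(seed, {
    i1 <- which(y == lv[1]); i2 <- which(y == lv[2])
    if (balance) {
      m <- min(length(i1), length(i2))
      i1 <- sort(sample(i1, m)); i2 <- sort(sample(i2, m))
    }
    loo <- k == length(i1) + length(i2)   # leave-one-out: one point/fold
    if (loo)
      list(i1 = i1, i2 = i2, loo = TRUE,
           f = sample(seq_len(k)))
    else
      list(i1 = i1, i2 = i2, loo = FALSE,
           f1 = sample(rep_len(seq_len(k), length(i1))),
           f2 = sample(rep_len(seq_len(k), length(i2))))
  })
  if (!idx$loo && min(length(idx$i1), length(idx$i2)) < k)
    stop("each class needs at least k = ", k, " members")
  fold <- integer(nrow(x))
  if (idx$loo) {
    fold[c(idx$i1, idx$i2)] <- idx$f
  } else {
    fold[idx$i1] <- idx$f1
    fold[idx$i2] <- idx$f2
  }
  use <- c(idx$i1, idx$i2)
  acc <- vapply(seq_len(k), function(f) {
    tr <- use[fold[use] != f]
    te <- use[fold[use] == f]
    m <- linear_svm(x[tr, , drop = FALSE], y[tr], C = C,
                    standardize = standardize, seed = seed + f)
    pr <- predict(m, x[te, , drop = FALSE])
    classification_accuracy(pr, y[te])$A
  }, numeric(1))
  structure(list(accuracy = mean(acc),
                 se = stats::sd(acc) / sqrt(k),
                 fold_accuracy = acc, folds = fold, k = k,
                 n = length(use), seed = seed),
            class = "cv_result")
}

#' Cross-validated accuracy when both classes share one distribution
#'
#' Draws two classes of `n_per_class` rows each from the identical
#' zero-effect feature distribution (548 independent standard-normal
#' features), runs stratified k-fold cross-validation, and repeats over
#' `n_seeds` independent datasets. Under this null the expected accuracy
#' is 50%; the study quantifies how close the pipeline's estimate stays
#' to chance.
#'
#' @param n_per_class rows per class per dataset.
#' @param n_seeds number of independent repetitions.
#' @param k folds.
#' @param C SVM regularization constant.
#' @param base_seed seed of the first repetition (repetition i uses
#'   `base_seed + i - 1`).
#' @return list with `mean_accuracy`, `accuracies` (per seed), `n_total`
#'   (test points over all repetitions).
#' @export
null_accuracy_study <- function(n_per_class = 2000, n_seeds = 20, k = 10,
                                C = 1, base_seed = 1) {
  model <- dose_response_model()
  acc <- vapply(seq_len(n_seeds), function(i) {
    s <- (base_seed + i - 1) %% 2147483647
    a <- generate_feature_table(model, 0, 24, n_per_class, seed = s,
                                experiment = 1L)
    b <- generate_feature_table(model, 0, 24, n_per_class,
                                seed = (s + 500009) %% 2147483647,
                                experiment = 2L)
    x <- rbind(feature_matrix(a)$x, feature_matrix(b)$x)
    y <- rep(c("control", "treated"), each = n_per_class)
    cross_validate(x, y, k = k, C = C, seed = s)$accuracy
  }, numeric(1))
  list(mean_accuracy = mean(acc), accuracies = acc,
       n_total = 2 * n_per_class * n_seeds)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy: %.4f +/- %.4f (SE), n = %d\n",
              x$k, x$accuracy, x$se, x$n))
  invisible(x)
}
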