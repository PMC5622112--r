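#' Fit a per-feature standardizer
#'
#' Learns per-feature mean and scale (sd) on training rows only. Applying
#' it z-scores each feature; zero-variance features map to 0 (scale is
#' kept at 1 internally to avoid division by zero).
#'
#' @param x numeric matrix (rows = cells).
#' @return object of class `standardizer` with `center` and `scale`.
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- !is.finite(scl) | scl <= 0
  scl[zero] <- 1
  structure(list(center = ctr, scale = scl, zero_variance = zero),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a `standardizer` from [standardize_fit()].
#' @param x numeric matrix with the same columns as the training data.
#' @return standardized matrix; zero-variance training features are 0.
#' @export
standardize_apply <- function(std, x) {
  stopifnot(inherits(std, "standardizer"))
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(std$center))
  z <- sweep(sweep(x, 2, std$center), 2, std$scale, "/")
  if (any(std$zero_variance)) z[, std$zero_variance] <- 0
  z
}

#' Train a linear support vector machine
#'
#' Fits a max-margin linear decision function \eqn{Y = w \cdot x + b} by
#' dual coordinate descent on the L2-regularized hinge loss. Features are
#' z-scored with a standardizer fitted on the training rows (configurable
#' off); `w` is expressed in standardized units and `predict()` applies
#' the stored standardizer automatically. The fit is deterministic given
#' `(x, y, C, seed)`.
#'
#' @param x numeric matrix of training rows (cells x features).
#' @param y labels: factor, character or numeric with exactly 2 levels.
#'   The *first* sorted level is coded -1 (control side), the second +1.
#' @param C soft-margin regularization constant.
#' @param standardize fit and store a z-score standardizer (default TRUE).
#' @param seed integer seed for the solver's coordinate order.
#' @param tol dual gradient-violation tolerance.
#' @param max_epochs cap on coordinate-descent epochs.
#' @param meta optional training metadata (dose, duration, experiment)
#'   stored in the model.
#' @return object of class `linear_svm` with elements `w`, `b`,
#'   `standardizer`, `levels`, `meta`.
#' @export
linear_svm <- function(x, y, C = 1, standardize = TRUE, seed = 1,
                       tol = 0.1, max_epochs = 300, meta = list()) {
  x <- as.matrix(x)
  lv <- sort(unique(as.character(y)))
  if (length(lv) != 2)
    stop("training labels must contain exactly 2 classes, got ",
         length(lv))
  yy <- ifelse(as.character(y) == lv[2], 1, -1)
  stopifnot(nrow(x) == length(yy), C > 0)
  std <- NULL
  z <- x
  if (standardize) {
    std <- standardize_fit(x)
    z <- standardize_apply(std, x)
  }
  fit <- svm_dcd(t(z), yy, C = C, tol = tol,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed))
  structure(list(w = stats::setNames(fit$w, colnames(x)), b = fit$b,
                 standardizer = std, levels = lv, C = C, seed = seed,
                 epochs = fit$epochs, meta = meta),
            class = "linear_svm")
}

#' Linear classification score Y = w.x + b
#'
#' @param model a `linear_svm`.
#' @param x matrix (or vector) of *standardized* feature rows when
#'   `apply_standardizer = FALSE`, raw rows otherwise.
#' @param apply_standardizer apply the model's stored standardizer first.
#' @return numeric vector of scores Y.
#' @export
svm_score <- function(model, x, apply_standardizer = TRUE) {
  stopifnot(inherits(model, "linear_svm"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$w))
    stop("dimension mismatch: model has ", length(model$w),
         " features, data has ", ncol(x))
  if (apply_standardizer && !is.null(model$standardizer))
    x <- standardize_apply(model$standardizer, x)
  drop(x %*% model$w + model$b)
}

#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "score"),
                               ...) {
  type <- match.arg(type)
  s <- svm_score(object, newdata)
  if (type == "score") return(s)
  # tie scores (Y = 0) go to the first (control-side) class
  factor(ifelse(s > 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' @export
coef.linear_svm <- function(object, ...) {
  c("(bias)" = object$b, object$w)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("Linear SVM: %d features, C = %g, b = %.4g (%d epochs)\n",
              length(x$w), x$C, x$b, x$epochs))
  cat("  classes: ", x$levels[1], " (Y < 0) vs ", x$levels[2],
      " (Y > 0)\n", sep = "")
  if (length(x$meta)) {
    m <- x$meta
    cat("  trained on:",
        paste(names(m), vapply(m, function(v) paste(format(v), collapse = "/"),
                               ""), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classification accuracy A = (X1 + X2) / N
#'
#' Per-class counts of correctly assigned incidences X1 (first level) and
#' X2 (second level) over the test size N; A ranges from 0.5 (chance, for
#' balanced classes) to 1 (perfect).
#'
#' @param predictions predicted labels.
#' @param labels true labels (same length, nonempty).
#' @return object of class `classification_result`: list with `A`, `X1`,
#'   `X2`, `N`, `levels`.
#' @export
classification_accuracy <- function(predictions, labels) {
  if (length(labels) == 0) stop("empty input")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  p <- as.character(predictions); l <- as.character(labels)
  lv <- sort(unique(l))
  x1 <- sum(p == l & l == lv[1])
  x2 <- if (length(lv) > 1) sum(p == l & l == lv[2]) else 0L
  n <- length(l)
  structure(list(A = (x1 + x2) / n, X1 = x1, X2 = x2, N = n, levels = lv),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("accuracy A = (X1 + X2)/N = (%d + %d)/%d = %.4f\n",
              x$X1, x$X2, x$N, x$A))
  invisible(x)
}

#' Histogram of classification scores per class
#'
#' Bins the decision scores Y of a dataset over shared bin edges, one
#' count vector per class; counts sum to the class sizes.
#'
#' @param model a `linear_svm`.
#' @param x feature matrix.
#' @param y class labels.
#' @param bins number of bins (shared edges across classes).
#' @return list with `breaks`, `mids` and `counts` (named list per class).
#' @export
score_histogram <- function(model, x, y, bins = 30) {
  s <- svm_score(model, x)
  rng <- range(s)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  cls <- sort(unique(as.character(y)))
  counts <- lapply(cls, function(cl) {
    sc <- s[as.character(y) == cl]
    bin <- pmin(pmax(findInterval(sc, breaks, rightmost.closed = TRUE), 1L),
                bins)
    tabulate(bin, nbins = bins)
  })
  names(counts) <- cls
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts)
}
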