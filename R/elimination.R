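#' MMD-guided feature-elimination curve
#'
#' Starting from a per-feature MMD ranking, retains only the top-`r`
#' features for each `r` in a descending, logarithmically spaced grid and
#' reports the stratified k-fold cross-validated accuracy at each point
#' (same folds and seed at every grid point, so the full-feature entry
#' equals the unrestricted cross-validation exactly). Lower-MMD features
#' are thus removed first.
#'
#' @param x feature matrix (cells x features).
#' @param y two-class labels.
#' @param ranking a `feature_mmd_ranking` covering all columns of `x`
#'   (from [per_feature_mmd()]).
#' @param retain_grid descending counts of retained features; default a
#'   log-spaced grid from all features down to 1. Values above the feature
#'   count are clipped with a warning.
#' @param k folds.
#' @param C SVM regularization constant.
#' @param seed fold/solver seed (shared across grid points).
#' @return object of class `elimination_curve`: data.frame with
#'   `n_features`, `accuracy`, `se`.
#' @export
elimination_curve <- function(x, y, ranking, retain_grid = NULL, k = 10,
                              C = 1, seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(inherits(ranking, "feature_mmd_ranking"), nrow(ranking) == p)
  if (is.null(retain_grid))
    retain_grid <- sort(unique(round(exp(seq(log(p), log(1),
                                             length.out = 12)))),
                        decreasing = TRUE)
  if (any(retain_grid > p)) {
    warning("retain_grid values above ", p, " clipped")
    retain_grid <- sort(unique(pmin(retain_grid, p)), decreasing = TRUE)
  }
  stopifnot(all(retain_grid >= 1))
  ord <- order(ranking$rank)          # feature indices, best first
  rows <- lapply(retain_grid, function(r) {
    keep <- ord[seq_len(r)]
    cv <- cross_validate(x[, keep, drop = FALSE], y, k = k, C = C,
                         seed = seed)
    data.frame(n_features = r, accuracy = cv$accuracy, se = cv$se)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("elimination_curve", class(out))
  out
}
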