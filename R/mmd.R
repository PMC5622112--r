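#' Gaussian kernel k(x, y) = exp(-||x - y||^2 / (2 sigma^2))
#'
#' @param x,y numeric vectors of equal length (single points).
#' @param sigma bandwidth (> 0).
#' @return kernel value in (0, 1\].
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(x) != length(y)) stop("x and y must have equal dimension")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' Median-heuristic kernel bandwidth
#'
#' Sigma is the median of the pairwise Euclidean distances over the pooled
#' sample (zero self-distances excluded). If the median is 0, the smallest
#' nonzero distance is used; if every distance is 0 the sample is
#' degenerate and an error is raised.
#'
#' @param X numeric matrix (rows = points) or vector.
#' @param Y optional second sample pooled with `X`.
#' @return bandwidth sigma (> 0).
#' @export
median_heuristic_bandwidth <- function(X, Y = NULL) {
  Z <- rbind(.as_row_matrix(X), if (!is.null(Y)) .as_row_matrix(Y))
  if (nrow(Z) < 2) stop("pooled sample must have >= 2 rows")
  d <- as.vector(dist(Z))
  d <- d[d > 0]
  if (length(d) == 0)
    stop("all points are identical; bandwidth undefined")
  m <- median(d)
  if (m > 0) m else min(d)
}

.as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

# squared Euclidean cross-distance matrix
.sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Unbiased empirical estimate of squared MMD
#'
#' Two-sample statistic
#' \deqn{MMD^2 = \frac{1}{m(m-1)}\sum_{i \ne j} k(x_i, x_j)
#'   + \frac{1}{n(n-1)}\sum_{i \ne j} k(y_i, y_j)
#'   - \frac{2}{mn}\sum_{i,j} k(x_i, y_j)}
#' with a Gaussian kernel. Within-sample sums exclude the diagonal; the
#' cross term uses all m*n pairs by default (`convention = "all-pairs"`,
#' the standard unbiased estimator). `convention = "printed"` additionally
#' drops the j = i cross pairs, a literal reading of the estimator as it
#' is sometimes typeset. The estimate may be negative under the null; the
#' reported `mmd_score` is \eqn{\sqrt{\max(0, MMD^2)}}.
#'
#' @param X,Y numeric matrices (rows = observations) or vectors; both need
#'   at least 2 rows.
#' @param sigma Gaussian bandwidth; default the pooled median heuristic.
#' @param convention `"all-pairs"` (default) or `"printed"`.
#' @return object of class `mmd_result`: list with `mmd2`, `mmd_score`,
#'   `sigma`, `m`, `n`, `convention`.
#' @examples
#' mmd2_unbiased(c(0, 1), c(0, 1), sigma = 1)  # exp(-1/2) - 1
#' @export
mmd2_unbiased <- function(X, Y, sigma = NULL,
                          convention = c("all-pairs", "printed")) {
  convention <- match.arg(convention)
  X <- .as_row_matrix(X); Y <- .as_row_matrix(Y)
  m <- nrow(X); n <- nrow(Y)
  if (m < 2 || n < 2) stop("both samples need at least 2 rows (m, n >= 2)")
  if (ncol(X) != ncol(Y)) stop("X and Y must share columns")
  if (is.null(sigma)) sigma <- median_heuristic_bandwidth(X, Y)
  if (sigma <= 0) stop("sigma must be > 0")
  g <- 1 / (2 * sigma^2)
  Kxx <- exp(-.sqdist(X, X) * g)
  Kyy <- exp(-.sqdist(Y, Y) * g)
  Kxy <- exp(-.sqdist(X, Y) * g)
  cross <- sum(Kxy)
  if (convention == "printed") {
    di <- seq_len(min(m, n))
    cross <- cross - sum(Kxy[cbind(di, di)])
  }
  mmd2 <- (sum(Kxx) - m) / (m * (m - 1)) +
    (sum(Kyy) - n) / (n * (n - 1)) -
    2 * cross / (m * n)
  structure(list(mmd2 = mmd2, mmd_score = sqrt(max(0, mmd2)),
                 sigma = sigma, m = m, n = n, convention = convention),
            class = "mmd_result")
}

#' @export
print.mmd_result <- function(x, ...) {
  cat(sprintf("MMD^2 (unbiased, %s) = %.6g  [MMD = %.6g], sigma = %.4g, m = %d, n = %d\n",
              x$convention, x$mmd2, x$mmd_score, x$sigma, x$m, x$n))
  invisible(x)
}

#' Per-feature MMD scores and ranking
#'
#' For every registry feature, computes the 1-D unbiased squared MMD
#' between the two samples' values of that feature, after standardizing by
#' the pooled mean and sd, with a per-feature median-heuristic bandwidth.
#' Constant features score 0. Features are ranked by descending
#' `mmd_score`, ties broken by ascending registry index. For tables larger
#' than `max_n` rows per sample, a seeded subsample bounds the quadratic
#' cost.
#'
#' @param X,Y feature tables (data.frames in feature-table layout) or
#'   plain n x 548 matrices.
#' @param max_n per-sample subsample cap (the estimator is O(n^2) per
#'   feature).
#' @param seed subsampling seed.
#' @param convention cross-term convention, as in [mmd2_unbiased()].
#' @return object of class `feature_mmd_ranking`: data.frame with columns
#'   `index`, `name`, `category`, `mmd2`, `mmd_score`, `sigma`, `rank`,
#'   ordered by registry index.
#' @export
per_feature_mmd <- function(X, Y, max_n = 500, seed = 1,
                            convention = c("all-pairs", "printed")) {
  convention <- match.arg(convention)
  Xm <- .table_or_matrix(X); Ym <- .table_or_matrix(Y)
  stopifnot(ncol(Xm) == ncol(Ym))
  if (nrow(Xm) < 2 || nrow(Ym) < 2) stop("m, n >= 2 required")
  .sub <- function(M, s) {
    if (nrow(M) <= max_n) return(M)
    .with_seed(s, M[sort(sample(nrow(M), max_n)), , drop = FALSE])
  }
  Xm <- .sub(Xm, seed); Ym <- .sub(Ym, seed + 1)
  res <- mmd1d_columns(Xm, Ym, printed = identical(convention, "printed"))
  reg <- feature_registry()[seq_len(ncol(Xm)), , drop = FALSE]
  out <- data.frame(index = reg$index, name = reg$name,
                    category = reg$category,
                    mmd2 = res[, 1], mmd_score = sqrt(pmax(0, res[, 1])),
                    sigma = res[, 2], stringsAsFactors = FALSE)
  # descending score, ties by ascending index
  o <- order(-out$mmd_score, out$index)
  out$rank <- integer(nrow(out))
  out$rank[o] <- seq_len(nrow(out))
  class(out) <- c("feature_mmd_ranking", class(out))
  out
}

.table_or_matrix <- function(X) {
  if (is.data.frame(X) && all(.feature_colnames() %in% names(X)))
    feature_matrix(X)$x
  else as.matrix(X)
}

#' @export
print.feature_mmd_ranking <- function(x, ...) {
  cat("Per-feature MMD ranking (", nrow(x), " features)\n", sep = "")
  top <- x[order(x$rank), ][seq_len(min(10, nrow(x))), ]
  print(data.frame(rank = top$rank, index = top$index, name = top$name,
                   category = top$category,
                   mmd_score = round(top$mmd_score, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Whole-space MMD per dose
#'
#' Computes the unbiased squared MMD (on standardized features, pooled
#' per comparison) between the control population and each treated
#' population of a feature table, per duration and experiment — the
#' unsupervised analogue of the dose-response accuracy curve.
#'
#' @param table combined feature table.
#' @param max_n per-class subsample cap (quadratic cost), seeded.
#' @param seed subsampling seed.
#' @param sigma fixed bandwidth; default per-comparison median heuristic.
#' @return data.frame with `duration_h`, `experiment`, `dose_M`, `mmd2`,
#'   `mmd_score`, `sigma`, `m`, `n`.
#' @export
mmd_dose_curve <- function(table, max_n = 1000, seed = 1, sigma = NULL) {
  fm <- feature_matrix(table)
  meta <- fm$meta
  rows <- list()
  for (dur in sort(unique(meta$duration_h)))
    for (e in sort(unique(meta$experiment[meta$duration_h == dur]))) {
      ic <- which(meta$duration_h == dur & meta$experiment == e &
                    meta$dose_M == 0)
      if (length(ic) < 2) next
      for (dose in sort(setdiff(
        unique(meta$dose_M[meta$duration_h == dur &
                             meta$experiment == e]), 0))) {
        it <- which(meta$duration_h == dur & meta$experiment == e &
                      meta$dose_M == dose)
        if (length(it) < 2) next
        .sub <- function(ii, s)
          if (length(ii) <= max_n) ii
          else .with_seed(s, sort(sample(ii, max_n)))
        ic2 <- .sub(ic, seed); it2 <- .sub(it, seed + 1)
        std <- standardize_fit(fm$x[c(ic2, it2), , drop = FALSE])
        Xs <- standardize_apply(std, fm$x[ic2, , drop = FALSE])
        Ys <- standardize_apply(std, fm$x[it2, , drop = FALSE])
        r <- mmd2_unbiased(Xs, Ys, sigma = sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          duration_h = dur, experiment = e, dose_M = dose,
          mmd2 = r$mmd2, mmd_score = r$mmd_score, sigma = r$sigma,
          m = r$m, n = r$n)
      }
    }
  do.call(rbind, rows)
}
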