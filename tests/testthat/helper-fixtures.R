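# programmatic fixtures shared across test files

# binary disk mask of radius r centred in an n x n frame
disk_mask <- function(r, n = 64, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  yy <- row(matrix(0, n, n)) - cy
  xx <- col(matrix(0, n, n)) - cx
  (xx^2 + yy^2) <= r^2
}

# binary axis-aligned ellipse mask with semi-axes a (cols) and b (rows)
ellipse_mask <- function(a, b, n = 64) {
  c0 <- (n + 1) / 2
  yy <- row(matrix(0, n, n)) - c0
  xx <- col(matrix(0, n, n)) - c0
  (xx^2 / a^2 + yy^2 / b^2) <= 1
}

# piecewise-constant frame: object value `fg` on mask, `bg` elsewhere
flat_frame <- function(mask, fg = 0.6, bg = 0.1) {
  f <- matrix(bg, nrow(mask), ncol(mask))
  f[mask] <- fg
  f
}

# independent pixel-moment oracle: centroid, axis lengths and ratio from
# raw second moments of a mask (no package code)
moment_oracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  mu20 <- mean((idx[, 2] - cx)^2) + 1 / 12
  mu02 <- mean((idx[, 1] - cy)^2) + 1 / 12
  mu11 <- mean((idx[, 2] - cx) * (idx[, 1] - cy))
  com <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + com) / 2
  l2 <- (mu20 + mu02 - com) / 2
  list(area = nrow(idx), centroid = c(cy, cx),
       major = 4 * sqrt(l1), minor = 4 * sqrt(max(l2, 0)),
       ratio = sqrt(l1 / max(l2, 1e-12)))
}

# brute-force unbiased squared-MMD oracle (triple double-loop, Gaussian
# kernel), independent of the package implementation
mmd2_oracle <- function(X, Y, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); n <- nrow(Y)
  k <- function(u, v) exp(-sum((u - v)^2) / (2 * sigma^2))
  sxx <- 0
  for (i in 1:m) for (j in 1:m) if (i != j) sxx <- sxx + k(X[i, ], X[j, ])
  syy <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) syy <- syy + k(Y[i, ], Y[j, ])
  sxy <- 0
  for (i in 1:m) for (j in 1:n) sxy <- sxy + k(X[i, ], Y[j, ])
  sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
}

# two-class Gaussian blobs in `p` dimensions separated on feature 1
make_blobs <- function(n_per_class, delta = 2, sd = 0.1, p = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p, sd = sd), 2 * n_per_class, p)
  X[, 1] <- X[, 1] + rep(c(-delta / 2, delta / 2), each = n_per_class)
  list(x = X, y = rep(c("control", "treated"), each = n_per_class))
}
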