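test_that("the Gaussian kernel obeys its closed forms and limits", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), sigma = 3), 1)
  expect_equal(gaussian_kernel(0, 1, sigma = 1), exp(-0.5))
  expect_lt(gaussian_kernel(0, 100, sigma = 1), 1e-300)
  expect_error(gaussian_kernel(0, 1, sigma = 0), "sigma")
  expect_error(gaussian_kernel(c(0, 1), 1, sigma = 1), "dimension")
})

test_that("the median heuristic enumerates pairwise distances correctly", {
  # points {0, 1, 2}: distances {1, 1, 2}, median 1
  expect_equal(median_heuristic_bandwidth(c(0, 1, 2)), 1)
  # homogeneity: scaling the data scales sigma
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  expect_equal(median_heuristic_bandwidth(3 * X),
               3 * median_heuristic_bandwidth(X))
  expect_error(median_heuristic_bandwidth(rep(1, 5)), "identical")
})

test_that("MMD^2 matches its analytic value on the two-point example", {
  # X = {0, 1}, Y = {0, 1}, sigma = 1: within terms e^{-1/2} each, cross
  # term (2 + 2 e^{-1/2})/4 doubled -> mmd2 = e^{-1/2} - 1
  r <- mmd2_unbiased(c(0, 1), c(0, 1), sigma = 1)
  expect_equal(r$mmd2, exp(-0.5) - 1)
  expect_equal(r$mmd_score, 0)       # negative mmd2 maps to score 0
  expect_error(mmd2_unbiased(1, c(0, 1), sigma = 1), "m, n >= 2")
})

test_that("MMD^2 equals a brute-force double-loop oracle on random tables", {
  set.seed(10)
  for (rep in 1:5) {
    X <- matrix(rnorm(100), 20, 5)
    Y <- matrix(rnorm(100, mean = 0.2), 20, 5)
    sig <- median_heuristic_bandwidth(X, Y)
    expect_equal(mmd2_unbiased(X, Y, sig)$mmd2, mmd2_oracle(X, Y, sig),
                 tolerance = 1e-10)
  }
})

test_that("MMD^2 is symmetric and invariant to row permutations", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3); Y <- matrix(rnorm(45, 1), 15, 3)
  sig <- 1.3
  a <- mmd2_unbiased(X, Y, sig)$mmd2
  expect_equal(mmd2_unbiased(Y, X, sig)$mmd2, a)
  expect_equal(mmd2_unbiased(X[sample(20), ], Y[sample(15), ], sig)$mmd2, a)
})

test_that("the printed convention differs by exactly the diagonal cross terms", {
  set.seed(13)
  X <- matrix(rnorm(24), 8, 3); Y <- matrix(rnorm(36), 12, 3)
  sig <- 0.9
  ap <- mmd2_unbiased(X, Y, sig)$mmd2
  pr <- mmd2_unbiased(X, Y, sig, convention = "printed")$mmd2
  diag_terms <- sum(sapply(1:8, function(i)
    exp(-sum((X[i, ] - Y[i, ])^2) / (2 * sig^2))))
  expect_equal(pr - ap, 2 * diag_terms / (8 * 12))
})

test_that("the estimator is unbiased under the null", {
  set.seed(14)
  vals <- replicate(400, {
    Z <- matrix(rnorm(40), 20, 2)
    mmd2_unbiased(Z[1:10, ], Z[11:20, ], sigma = 1)$mmd2
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("MMD^2 grows with the separation of two normal populations", {
  prev <- -Inf
  for (delta in c(0, 0.5, 1, 2)) {
    set.seed(15)
    cur <- mean(replicate(20, {
      X <- matrix(rnorm(500), 250, 2)
      Y <- matrix(rnorm(500, mean = delta), 250, 2)
      mmd2_unbiased(X, Y, sigma = 2)$mmd2
    }))
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("per-feature MMD scores vanish on identical tables and rank a shifted feature first", {
  set.seed(16)
  X <- matrix(rnorm(200 * 10), 200, 10)
  pf0 <- per_feature_mmd(X, X)
  expect_true(all(pf0$mmd_score == 0))
  hits <- sapply(1:20, function(s) {
    set.seed(100 + s)
    A <- matrix(rnorm(150 * 10), 150, 10)
    B <- matrix(rnorm(150 * 10), 150, 10)
    B[, 7] <- B[, 7] + 1.5
    pf <- per_feature_mmd(A, B, seed = s)
    pf$rank[7] == 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a constant feature scores 0 instead of erroring", {
  set.seed(17)
  A <- cbind(rnorm(50), rep(1, 50))
  B <- cbind(rnorm(50), rep(1, 50))
  pf <- per_feature_mmd(A, B)
  expect_identical(pf$mmd2[2], 0)
  expect_true(is.na(pf$sigma[2]))
})

test_that("per-feature scores replicate across independent experiments", {
  m <- dose_response_model()
  sh <- default_shift()
  t1c <- generate_feature_table(m, 0, 24, 400, seed = 31, experiment = 1)
  t1t <- generate_feature_table(m, 1e-6, 24, 400, seed = 32, experiment = 1)
  t2c <- generate_feature_table(m, 0, 24, 400, seed = 33, experiment = 2)
  t2t <- generate_feature_table(m, 1e-6, 24, 400, seed = 34, experiment = 2)
  p1 <- per_feature_mmd(t1c, t1t, seed = 1)
  p2 <- per_feature_mmd(t2c, t2t, seed = 2)
  top <- p1$rank <= 55                      # top decile of 548
  expect_gt(cor(p1$mmd_score[top], p2$mmd_score[top]), 0.5)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(18)
  Z <- matrix(rnorm(120), 60, 2)
  obs <- mmd2_unbiased(Z[1:30, ], Z[31:60, ], sigma = 1)$mmd2
  perm <- replicate(300, {
    i <- sample(60, 30)
    mmd2_unbiased(Z[i, ], Z[-i, ], sigma = 1)$mmd2
  })
  p <- mean(perm >= obs)
  expect_gt(p, 0.005)
  expect_lt(p, 0.995)
})
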