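test_that("standardization centres and scales, and degenerates safely", {
  set.seed(1)
  x <- cbind(rnorm(50, 5, 2), rnorm(50, -1, 0.1), rep(3, 50))
  std <- standardize_fit(x)
  z <- standardize_apply(std, x)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_equal(unname(apply(z[, 1:2], 2, sd)), c(1, 1))
  expect_true(all(z[, 3] == 0))      # zero-variance column, no NaN
  # a shift applied to test data is preserved in standardized units
  z2 <- standardize_apply(std, sweep(x, 2, c(2, 0, 0), "+"))
  expect_equal(mean(z2[, 1]) - mean(z[, 1]), 2 / std$scale[1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("well-separated blobs are classified perfectly; training is deterministic", {
  bl <- make_blobs(200, delta = 2, sd = 0.1)
  m1 <- linear_svm(bl$x, bl$y, seed = 1)
  m2 <- linear_svm(bl$x, bl$y, seed = 1)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$b, m2$b)
  ho <- make_blobs(100, delta = 2, sd = 0.1, seed = 99)
  expect_equal(classification_accuracy(predict(m1, ho$x), ho$y)$A, 1.0)
  expect_error(linear_svm(bl$x, rep("a", 400)), "2 classes")
})

test_that("the decision score is exactly w.x + b", {
  set.seed(7)
  w <- rnorm(548); b <- rnorm(1)
  model <- structure(list(w = w, b = b, standardizer = NULL,
                          levels = c("control", "treated")),
                     class = "linear_svm")
  x <- matrix(rnorm(5 * 548), 5)
  # independent brute-force summation oracle
  oracle <- sapply(1:5, function(i) {
    s <- b
    for (j in 1:548) s <- s + w[j] * x[i, j]
    s
  })
  expect_equal(svm_score(model, x), oracle, tolerance = 1e-12)
  expect_equal(svm_score(model, rep(0, 548)), b)       # x = 0 -> Y = b
  e1 <- c(1, rep(0, 547))
  model$w <- e1
  model$b <- 0
  expect_equal(svm_score(model, 2 * e1), 2)
  expect_error(svm_score(model, rep(0, 10)), "dimension mismatch")
})

test_that("the accuracy statistic follows its definition", {
  y <- rep(c("a", "b"), each = 50)
  p <- y
  p[1:4] <- "b"; p[51:54] <- "a"                 # 46 + 46 correct of 100
  r <- classification_accuracy(p, y)
  expect_identical(r$X1, 46L); expect_identical(r$X2, 46L)
  expect_equal(r$A, 0.92)
  expect_equal(classification_accuracy(y, y)$A, 1.0)
  # 3-vs-1 toy vector, hand-counted: 2 of 3 "a" right, 1 of 1 "b" right
  r2 <- classification_accuracy(c("a", "b", "a", "b"), c("a", "a", "a", "b"))
  expect_identical(r2$X1, 2L); expect_identical(r2$X2, 1L)
  expect_equal(r2$A, 0.75)
  expect_error(classification_accuracy(character(0), character(0)),
               "empty")
})

test_that("our solver agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  bl <- make_blobs(150, delta = 1, sd = 0.5, p = 5, seed = 3)
  m <- linear_svm(bl$x, bl$y, C = 1, seed = 1)
  ref <- e1071::svm(scale(bl$x), factor(bl$y), kernel = "linear",
                    cost = 1, scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  # e1071 codes the first factor level +1; align sign before comparing
  sgn <- sign(sum(w_ref * m$w))
  cosang <- sum(w_ref * sgn * m$w) /
    sqrt(sum(w_ref^2) * sum(m$w^2))
  expect_gt(cosang, 0.95)
  ho <- make_blobs(200, delta = 1, sd = 0.5, p = 5, seed = 4)
  acc_ours <- classification_accuracy(predict(m, ho$x), ho$y)$A
  acc_ref <- mean(predict(ref, scale(ho$x, attr(scale(bl$x), "scaled:center"),
                                     attr(scale(bl$x), "scaled:scale"))) ==
                    factor(ho$y))
  expect_lt(abs(acc_ours - acc_ref), 0.03)
})

test_that("cross-validation is perfect on separable data and honest under the null", {
  bl <- make_blobs(100, delta = 2, sd = 0.1)
  cv <- cross_validate(bl$x, bl$y, k = 10, seed = 1)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(cv$se, 0)
  # permuted labels: accuracy within the binomial 99% CI of 0.5
  set.seed(11)
  yperm <- sample(bl$y)
  cvp <- cross_validate(bl$x, yperm, k = 10, seed = 1)
  ci <- 2.576 * sqrt(0.25 / length(yperm))
  expect_lt(abs(cvp$accuracy - 0.5), ci + 0.01)
})

test_that("k = n cross-validation matches a brute-force leave-one-out loop", {
  bl <- make_blobs(10, delta = 1.2, sd = 0.6, seed = 5)
  cv <- cross_validate(bl$x, bl$y, k = 20, seed = 2)
  # exhaustive LOO oracle over the same fold assignment (one point per fold)
  fold <- cv$folds
  acc <- sapply(1:20, function(f) {
    tr <- which(fold != f & fold > 0); te <- which(fold == f)
    m <- linear_svm(bl$x[tr, , drop = FALSE], bl$y[tr], seed = 2 + f)
    mean(as.character(predict(m, bl$x[te, , drop = FALSE])) == bl$y[te])
  })
  expect_equal(cv$fold_accuracy, acc)
  expect_equal(cv$accuracy, mean(acc))
})

test_that("test labels never influence the trained model (no leakage)", {
  bl <- make_blobs(50, delta = 1, sd = 0.4, seed = 6)
  tr <- 1:60; te <- 61:100
  m1 <- linear_svm(bl$x[tr, ], bl$y[tr], seed = 3)
  # shuffling the held-out labels cannot change the fit
  m2 <- linear_svm(bl$x[tr, ], bl$y[tr], seed = 3)
  expect_identical(m1$w, m2$w)
  s1 <- svm_score(m1, bl$x[te, ])
  expect_identical(s1, svm_score(m2, bl$x[te, ]))
})

test_that("score histograms conserve class counts and separate separable data", {
  bl <- make_blobs(100, delta = 2, sd = 0.1)
  m <- linear_svm(bl$x, bl$y, seed = 1)
  h <- score_histogram(m, bl$x, bl$y, bins = 20)
  expect_identical(sum(h$counts$control), 100L)
  expect_identical(sum(h$counts$treated), 100L)
  # zero overlap: no bin occupied by both classes
  expect_identical(sum(h$counts$control > 0 & h$counts$treated > 0), 0L)
  # degenerate: all scores identical occupy a single bin
  mm <- structure(list(w = c(0, 0), b = 1, standardizer = NULL,
                       levels = c("control", "treated")),
                  class = "linear_svm")
  h2 <- score_histogram(mm, bl$x, bl$y, bins = 10)
  expect_identical(sum(unlist(h2$counts) > 0), 2L)  # one bin per class
})
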