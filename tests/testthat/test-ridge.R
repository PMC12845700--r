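test_that("ridge solution satisfies the normal equations and matches an independent solver", {
  set.seed(12)
  D <- matrix(rnorm(40 * 8), 40, 8)
  y <- rep(1:4, each = 10)
  alpha <- 0.039
  model <- fit_ridge(D, y, alpha = alpha, standardize = FALSE)
  Y <- outer(y, sort(unique(y)), "==") * 1
  # normal-equations residual
  res <- norm(crossprod(D) %*% model$W + alpha * model$W - crossprod(D, Y), "F")
  expect_lt(res, 1e-8 * norm(crossprod(D, Y), "F"))
  # independent oracle: augmented least squares via QR
  W_qr <- qr.solve(rbind(D, sqrt(alpha) * diag(8)),
                   rbind(Y, matrix(0, 8, 4)))
  expect_equal(unname(model$W), unname(W_qr), tolerance = 1e-8)
})

test_that("dual-form solution (n < d) equals the primal closed form", {
  set.seed(13)
  D <- matrix(rnorm(15 * 40), 15, 40)
  y <- rep(1:3, each = 5)
  alpha <- 0.5
  dual <- fit_ridge(D, y, alpha = alpha, standardize = FALSE)   # n < d path
  Y <- outer(y, 1:3, "==") * 1
  primal <- solve(crossprod(D) + diag(alpha, 40), crossprod(D, Y))
  expect_equal(unname(dual$W), unname(primal), tolerance = 1e-8)
})

test_that("interpolation, shrinkage, and prediction rules hold", {
  set.seed(3)
  D <- matrix(rnorm(6 * 6), 6, 6)
  y <- c(1, 1, 2, 2, 3, 3)
  m0 <- fit_ridge(D, y, alpha = 0, standardize = FALSE)
  expect_equal(predict(m0, D), y)

  # ||W|| shrinks monotonically with alpha
  norms <- sapply(c(0.01, 1, 100, 1e4, 1e9), function(a)
    norm(fit_ridge(D, y, alpha = a, standardize = FALSE)$W, "F"))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 1e-6)

  # tie rule: all-zero feature row scores 0 for every class -> lowest class
  m <- fit_ridge(D, y, alpha = 0.1, standardize = FALSE)
  expect_equal(predict(m, rep(0, 6)), 1)

  # permutation equivariance of argmax under permuted score columns
  perm <- c(3, 1, 2)
  m_perm <- m; m_perm$W <- m$W[, perm]; m_perm$classes <- m$classes
  pred <- predict(m, D)
  pred_perm <- predict(m_perm, D)
  # label i under m_perm corresponds to position of old label in perm
  expect_equal(pred_perm, match(pred, perm))

  expect_error(predict(m, rep(0, 5)), "dimension")
  expect_error(fit_ridge(D, rep(1, 6)), "2 classes")
})

test_that("evaluation metrics match hand-evaluated formulas", {
  perfect <- evaluate(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$f1, 100)
  expect_equal(perfect$mcc, 100)

  # binary confusion TP=3, FN=1, FP=2, TN=4 (class 1 = positive)
  truth <- c(rep(1, 4), rep(2, 6))
  pred <- c(1, 1, 1, 2, 1, 1, 2, 2, 2, 2)
  ev <- evaluate(pred, truth)
  expect_equal(sum(ev$confusion), 10)
  expect_equal(ev$acc, 100 * 7 / 10)
  pre1 <- 3 / 5; rec1 <- 3 / 4; pre2 <- 4 / 5; rec2 <- 4 / 6
  expect_equal(ev$pre, 100 * (pre1 + pre2) / 2)
  expect_equal(ev$rec, 100 * (rec1 + rec2) / 2)
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(ev$f1, 100 * (f1(pre1, rec1) + f1(pre2, rec2)) / 2)
  expect_equal(ev$mcc, 100 * (3 * 4 - 2 * 1) / sqrt(5 * 4 * 6 * 5))

  # permutation invariance to sample order
  o <- sample(10)
  ev2 <- evaluate(pred[o], truth[o])
  expect_equal(ev2$acc, ev$acc); expect_equal(ev2$mcc, ev$mcc)

  expect_error(evaluate(c(1, 9), c(1, 2), classes = 1:2), "class set")
})

test_that("random predictions on balanced labels give near-zero MCC", {
  mccs <- sapply(1:50, function(s) {
    set.seed(s)
    truth <- rep(1:4, each = 25)
    pred <- sample(1:4, 100, replace = TRUE)
    evaluate(pred, truth)$mcc / 100
  })
  expect_lt(abs(mean(mccs)), 0.1)
})

test_that("exact McNemar matches binomial-tail enumeration and is symmetric", {
  truth <- rep(1, 10)
  # b = 5 (A right, B wrong), c = 1
  pred_a <- c(rep(1, 9), 2)
  pred_b <- c(rep(2, 5), rep(1, 4), 1)
  res <- mcnemar_exact(pred_a, pred_b, truth)
  expect_equal(res$b, 5); expect_equal(res$c, 1)
  # oracle: exact enumeration of the binomial tail
  n <- 6; k <- 1
  p_oracle <- min(1, 2 * sum(choose(n, 0:k)) / 2^n)
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$p_value, 0.21875)
  # symmetry
  expect_equal(mcnemar_exact(pred_b, pred_a, truth)$p_value, res$p_value)
  # no discordant pairs
  expect_equal(mcnemar_exact(pred_a, pred_a, truth)$p_value, 1)
})

test_that("Holm adjustment reproduces the hand step-down and its invariants", {
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})
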