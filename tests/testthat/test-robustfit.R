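# Closed-form OLS oracle for y = b0 + b1 x
oracle_ols <- function(y, x) {
  n <- length(y)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  r <- y - b0 - b1 * x
  s2 <- sum(r^2) / (n - 2)
  se1 <- sqrt(s2 / sum((x - mean(x))^2))
  list(b0 = b0, b1 = b1, se1 = se1, t = b1 / se1)
}

# Hand-iterated IRLS oracle using lm.wfit, independent of the implementation
oracle_irls <- function(y, x, iters = 50, tuning = 4.685) {
  X <- cbind(1, x)
  beta <- as.numeric(qr.coef(qr(X), y))
  w <- rep(1, length(y))
  for (i in seq_len(iters)) {
    r <- as.numeric(y - X %*% beta)
    s <- median(abs(r)) / 0.6745
    if (s == 0) break
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    beta_new <- as.numeric(stats::lm.wfit(X, y, w)$coefficients)
    if (max(abs(beta_new - beta)) < 1e-6) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(beta = as.numeric(beta), w = w)
}

test_that("an exact linear relation is recovered with unit weights", {
  x <- seq(0, 1, length.out = 275)
  f <- robust_fit(1 + 2 * x, x)
  expect_equal(f$beta1, 2, tolerance = 1e-9)
  expect_equal(f$beta0, 1, tolerance = 1e-9)
  expect_true(all(f$weights == 1))
  expect_equal(f$df, 273)
  expect_lt(f$p, 0.05)
})

test_that("clean Gaussian data matches closed-form OLS within 1%", {
  set.seed(31)
  x <- seq(0, 1, length.out = 200)
  y <- x + rnorm(200, 0, 0.1)
  f <- robust_fit(y, x)
  o <- oracle_ols(y, x)
  expect_equal(f$beta1, o$b1, tolerance = 0.01)
  expect_equal(f$beta0, o$b0, tolerance = 0.02)
})

test_that("a 20x inflated residual is downweighted below 0.05", {
  set.seed(31)
  x <- seq(0, 1, length.out = 200)
  y <- x + rnorm(200, 0, 0.1)
  idx <- which.max(abs(y - x))        # inflate a substantive residual
  y_out <- y
  y_out[idx] <- x[idx] + (y[idx] - x[idx]) * 20
  f <- robust_fit(y_out, x)
  expect_lt(f$weights[idx], 0.05)
  o <- oracle_ols(y_out, x)
  expect_lt(abs(f$beta1 - 1), abs(o$b1 - 1))     # more accurate than OLS
  # and the whole fit agrees with a hand-iterated IRLS oracle
  ho <- oracle_irls(y_out, x)
  expect_equal(f$beta1, ho$beta[2], tolerance = 1e-5)
  expect_equal(f$weights, as.numeric(ho$w), tolerance = 1e-3)
})

test_that("bisquare fit agrees with an established robust regression", {
  skip_if_not_installed("MASS")
  set.seed(8)
  x <- seq(0, 2, length.out = 150)
  y <- 0.5 + 1.5 * x + rnorm(150, 0, 0.2)
  y[c(10, 80)] <- y[c(10, 80)] + 4
  f <- robust_fit(y, x)
  m <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(f$beta1, unname(coef(m)[2]), tolerance = 1e-3)
})

test_that("the OLS limit equals textbook formulas to 1e-9", {
  set.seed(12)
  x <- runif(60); y <- 2 - x + rnorm(60, 0, 0.3)
  f <- robust_fit(y, x, method = "ols")
  o <- oracle_ols(y, x)
  expect_equal(f$beta1, o$b1, tolerance = 1e-9)
  expect_equal(f$se1, o$se1, tolerance = 1e-9)
  expect_equal(f$t, o$t, tolerance = 1e-9)
  expect_true(all(f$weights == 1))
})

test_that("p-values are one-sided upper tail", {
  set.seed(5)
  x <- seq(0, 1, length.out = 100)
  f_neg <- robust_fit(-x + rnorm(100, 0, 0.1), x)
  expect_lt(f_neg$t, 0)
  expect_gt(f_neg$p, 0.5)
  f_pos <- robust_fit(x + rnorm(100, 0, 0.1), x)
  expect_equal(f_pos$p, pt(f_pos$t, f_pos$df, lower.tail = FALSE))
})

test_that("degenerate designs raise informative errors", {
  expect_error(robust_fit(1:10, rep(1, 10)), "singular")
  expect_error(robust_fit(1:3, 1:3), "insufficient")
})

test_that("df convention is switchable", {
  set.seed(3)
  x <- runif(50); y <- x + rnorm(50, 0, 0.1)
  expect_equal(robust_fit(y, x)$df, 48)
  expect_equal(robust_fit(y, x, df = "n-1")$df, 49)
})
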