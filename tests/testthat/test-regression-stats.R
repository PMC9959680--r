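test_that("OLS recovers exact and hand-computed fits and flags collinearity", {
  # y = 2x + 1 exactly
  X <- matrix(0:3, ncol = 1, dimnames = list(NULL, "X1"))
  fit <- pyrroqsar:::ols_core(X, 2 * (0:3) + 1)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  # hand-solved normal equations
  le <- line_example()
  fit2 <- pyrroqsar:::ols_core(le$x, le$y)
  expect_equal(unname(fit2$coefficients), 1.6, tolerance = 1e-12)
  expect_equal(fit2$intercept, -0.4, tolerance = 1e-12)

  # duplicate column
  Xd <- cbind(X1 = rnorm(8), X2 = 0)
  Xd[, 2] <- Xd[, 1]
  expect_error(pyrroqsar:::ols_core(Xd, rnorm(8)), "X2",
               class = "singularity_error")
})

test_that("sums of squares, R2 and F match hand arithmetic on the line example", {
  le <- line_example()
  fit <- pyrroqsar:::ols_core(le$x, le$y)
  ss <- sum_of_squares(le$y, fit$fitted)
  expect_equal(ss$rss, 1.2, tolerance = 1e-9)
  expect_equal(ss$tss, 14, tolerance = 1e-9)
  expect_equal(ss$ess, 12.8, tolerance = 1e-9)
  expect_equal(r_squared(ss), 12.8 / 14, tolerance = 1e-9)
  expect_equal(f_statistic(ss, n = 4, p = 2), (12.8 / 1) / (1.2 / 2),
               tolerance = 1e-9)

  # degenerate predictions
  perfect <- sum_of_squares(le$y, le$y)
  expect_equal(perfect$rss, 0)
  expect_equal(perfect$ess, perfect$tss)
  expect_warning(f <- f_statistic(perfect, 4, 2), "perfect fit")
  expect_identical(f, Inf)
  flat <- sum_of_squares(le$y, rep(mean(le$y), 4))
  expect_equal(flat$ess, 0)
  expect_equal(r_squared(flat), 0)
  expect_equal(f_statistic(flat, 4, 2), 0)
  expect_error(f_statistic(ss, n = 2, p = 2),
               class = "degrees_of_freedom_error")
})

test_that("F critical values match the F-distribution quantile", {
  expect_equal(f_critical(p = 2, n = 4), 18.513, tolerance = 1e-3)
  expect_equal(f_critical(p = 4, n = 12), 4.066, tolerance = 1e-3)
  # monotone in alpha
  expect_gt(f_critical(2, 10, 0.01), f_critical(2, 10, 0.05))
})

test_that("PRESS matches an independent lm-based refit loop and the hat closed form", {
  le <- line_example()
  p_pkg <- loo_press(le$x, le$y)
  expect_equal(p_pkg, press_via_lm(le$x, le$y), tolerance = 1e-8)

  set.seed(7)
  X <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("X1", "X2")))
  y <- 1 + X[, 1] - 0.5 * X[, 2] + rnorm(15, 0, 0.4)
  p1 <- loo_press(X, y)
  expect_equal(p1, press_via_lm(X, y), tolerance = 1e-8)
  # hat-matrix closed form
  fit <- pyrroqsar:::ols_core(X, y)
  e <- y - fit$fitted
  expect_equal(p1, sum((e / (1 - fit$leverage))^2), tolerance = 1e-8)
  # leverage inequality
  expect_gte(p1, sum(e^2))

  # exact 3-point line has zero PRESS
  xx <- matrix(c(0, 1, 2, 5, 9), ncol = 1, dimnames = list(NULL, "X1"))
  expect_equal(loo_press(xx, drop(3 * xx) + 1), 0, tolerance = 1e-18)
})

test_that("cross-validated R2 and RMSE follow their definitions", {
  expect_equal(r2_cv(0, 5), 1)
  expect_equal(r2_cv(5, 5), 0)
  le <- line_example()
  expect_equal(r2_cv(loo_press(le$x, le$y), 14),
               1 - press_via_lm(le$x, le$y) / 14, tolerance = 1e-8)

  expect_equal(rmse(c(0, 0, 0, 0), c(0.4, -0.2, -0.8, 0.6)),
               sqrt(1.2 / 4), tolerance = 1e-4)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5, 1:5 + 2), 2)
})

test_that("statistical identities hold on every OLS fit", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:40, 1)
    p1 <- sample(1:3, 1)
    X <- matrix(rnorm(n * p1), n, p1, dimnames = list(NULL, paste0("X", 1:p1)))
    y <- rnorm(n, 5, 2)
    fit <- pyrroqsar:::ols_core(X, y)
    ss <- sum_of_squares(y, fit$fitted)
    expect_equal(ss$tss, ss$ess + ss$rss, tolerance = 1e-9 * ss$tss)
    expect_equal(r_squared(ss), 1 - ss$rss / ss$tss, tolerance = 1e-9)
    # F invariant to affine descriptor rescaling
    X2 <- X
    X2[, 1] <- 3.7 * X2[, 1] - 12
    ss2 <- sum_of_squares(y, pyrroqsar:::ols_core(X2, y)$fitted)
    expect_equal(f_statistic(ss, n, p1 + 1), f_statistic(ss2, n, p1 + 1),
                 tolerance = 1e-8)
  }
})

test_that("OLS recovers planted coefficients within 3 standard errors at n=200", {
  set.seed(42)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("X1", "X2", "X3")))
  beta <- c(2, -1.5, 0.7)
  y <- 4 + drop(X %*% beta) + rnorm(n, 0, 0.3)
  fit <- pyrroqsar:::ols_core(X, y)
  lmfit <- stats::lm(y ~ X)   # independent route for the standard errors
  se <- summary(lmfit)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("Pearson matrix follows the product-moment formula and flags constants", {
  v <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  w <- c(0.3, 1.1, 0.9, 2.0, 1.4)
  M <- cbind(a = v, b = w, c = -v)
  R <- pearson_matrix(M)
  expect_equal(diag(R), rep(1, 3), ignore_attr = TRUE)
  expect_equal(R["a", "c"], -1, tolerance = 1e-12)
  # textbook formula
  r_hand <- sum((v - mean(v)) * (w - mean(w))) /
    sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  expect_equal(R["a", "b"], r_hand, tolerance = 1e-12)
  expect_true(all(R >= -1 & R <= 1))

  expect_warning(Rz <- pearson_matrix(cbind(a = v, z = rep(2, 5))), "z")
  expect_true(is.na(Rz["a", "z"]))
})

test_that("mlr_fit assembles model and diagnostics; predictions match arithmetic", {
  ds <- synthetic_qsar_dataset(seed = 2)
  m <- mlr_fit(ds, "Y1", c("X17", "X19", "X20"))
  expect_s3_class(m, "qsar_mlr")
  expect_equal(m$stats$tss, m$stats$ess + m$stats$rss,
               tolerance = 1e-9 * m$stats$tss)
  expect_lte(m$stats$r2_cv, m$stats$r2)
  expect_gte(m$stats$press, m$stats$rss)
  expect_error(mlr_fit(ds, "Y1", c("X17", "XX9")), class = "alignment_error")

  # reference-equation arithmetic
  eqs <- reference_equations()
  row0 <- matrix(c(0, 0, 0), 1, dimnames = list(NULL, c("X17", "X19", "X20")))
  expect_equal(predict(eqs$Y1, row0), 207.384)
  row1 <- matrix(c(1.5, 1.5, 100), 1,
                 dimnames = list(NULL, c("X17", "X19", "X20")))
  expect_equal(predict(eqs$Y1, row1),
               207.384 - 90.879 * 1.5 - 47.988 * 1.5 + 0.016 * 100,
               tolerance = 1e-12)
  expect_equal(predict(eqs$Y1, row1), 0.6835, tolerance = 1e-4)
  row2 <- matrix(c(1.5, 100, -0.30), 1,
                 dimnames = list(NULL, c("X19", "X20", "X21")))
  expect_equal(predict(eqs$Y2, row2), 4.856, tolerance = 1e-3)
  expect_error(predict(eqs$Y1, row2), "X17", class = "alignment_error")
})
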