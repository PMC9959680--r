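test_that("forward pass composes scaling, tanh hidden layer, linear output", {
  # all-zero weights: output = output bias = 0 on the scaled space
  Xs <- matrix(runif(12, -1, 1), 4, 3)
  fw <- ann_forward_scaled(rep(0, 16), Xs, 3)
  expect_equal(fw$yhat, rep(0, 4))

  # hand-evaluated 1-1-1 network: w_in = 0.8, b_in = -0.1, w_out = 1.5, b_out = 0.2
  w <- c(0.8, -0.1, 1.5, 0.2)
  x <- matrix(c(-0.4, 0.3), 2, 1)
  expect_equal(ann_forward_scaled(w, x, 1)$yhat,
               1.5 * tanh(0.8 * c(-0.4, 0.3) - 0.1) + 0.2, tolerance = 1e-12)

  # continuity under tiny perturbation
  set.seed(1)
  w16 <- runif(16, -0.5, 0.5)
  y1 <- ann_forward_scaled(w16, Xs, 3)$yhat
  y2 <- ann_forward_scaled(w16, Xs + 1e-9, 3)$yhat
  expect_lt(max(abs(y1 - y2)), 1e-6)
})

test_that("analytic Jacobian agrees with central finite differences", {
  for (seed in 1:10) {
    set.seed(seed)
    Xs <- matrix(runif(8 * 3, -1, 1), 8, 3)
    w <- runif(16, -0.8, 0.8)
    J <- ann_jacobian(w, Xs, 3)
    h <- 1e-6
    Jfd <- vapply(seq_along(w), function(k) {
      e <- rep(0, length(w)); e[k] <- h
      (ann_forward_scaled(w + e, Xs, 3)$yhat -
         ann_forward_scaled(w - e, Xs, 3)$yhat) / (2 * h)
    }, numeric(nrow(Xs)))
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
  # zero input row: hidden-weight columns reduce to bias paths
  w <- runif(16, -0.5, 0.5)
  J0 <- ann_jacobian(w, matrix(0, 1, 3), 3)
  # input-weight entries (non-bias) of the hidden layer must be zero
  non_bias <- c(1:3, 5:7, 9:11)
  expect_equal(unname(J0[1, non_bias]), rep(0, 9))
})

test_that("LM step damps to zero at large mu and solves linear problems in one step", {
  set.seed(2)
  X <- cbind(1, matrix(rnorm(30 * 2), 30, 2))
  y <- rnorm(30)
  w0 <- rnorm(3)
  r0 <- drop(X %*% w0) - y
  # mu -> Inf: step -> 0
  w_big <- lm_step(w0, X, r0, mu = 1e12)
  expect_equal(w_big, w0, tolerance = 1e-6)
  # alpha = 0, mu = 0, model linear in weights: one step = OLS optimum
  w1 <- lm_step(w0, X, r0, mu = 0)
  expect_equal(w1, unname(qr.solve(X, y)), tolerance = 1e-8)
})

test_that("evidence updates move hyperparameters in the right direction", {
  H <- diag(16)
  # gamma = N_w and tiny E_W -> large alpha
  up <- bayes_update(alpha = 0, beta = 1, E_W = 1e-6, E_D = 1,
                     n_obs = 20, N_w = 16, hessian = H)
  expect_equal(up$gamma, 16)
  expect_gt(up$alpha, 1e5)
  # larger alpha shrinks gamma
  up2 <- bayes_update(alpha = 10, beta = 1, E_W = 0.5, E_D = 1,
                      n_obs = 20, N_w = 16, hessian = diag(11, 16))
  expect_lt(up2$gamma, 16)
  expect_gte(up2$gamma, 0)
  expect_warning(bayes_update(1, 1, 1, 1, 10, 16, hessian = matrix(0, 16, 16)),
                 "singular")
})

test_that("training represents linear targets to near machine noise", {
  set.seed(10)
  n <- 50
  X <- matrix(runif(n * 3), n, 3,
              dimnames = list(paste0("c", 1:n), c("X1", "X2", "X3")))
  y <- X[, 1] + X[, 2] + X[, 3]
  y <- (y - min(y)) / (max(y) - min(y)) * 8 + 1
  ds <- qsar_dataset(descriptor_table(X), activity_table(rownames(X), y, y, y))
  net <- ann_fit(ds, "Y1", c("X1", "X2", "X3"), ann_config(seed = 3))
  expect_lte(rmse(y, predict(net, ds)), 1e-3)
})

test_that("training is bit-identical under a fixed seed", {
  ds <- synthetic_qsar_dataset(seed = 8)
  cfg <- ann_config(seed = 11, max_epochs = 150)
  n1 <- ann_fit(ds, "Y2", c("X19", "X20", "X21"), cfg)
  n2 <- ann_fit(ds, "Y2", c("X19", "X20", "X21"), cfg)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$objective_history, n2$objective_history)
  expect_identical(n1$gamma, n2$gamma)
})

test_that("accepted steps never increase the fixed-hyperparameter objective", {
  ds <- synthetic_qsar_dataset(seed = 4)
  net <- ann_fit(ds, "Y1", c("X17", "X19", "X20"),
                 ann_config(seed = 2, bayes = FALSE, max_epochs = 300))
  expect_true(all(diff(net$objective_history) <= 1e-10))
})

test_that("Bayesian regularization suppresses overfitting on pure-noise targets", {
  set.seed(33)
  X <- matrix(runif(12 * 3), 12, 3,
              dimnames = list(paste0("c", 1:12), c("X1", "X2", "X3")))
  y <- runif(12, 3, 7)   # no structure
  ds <- qsar_dataset(descriptor_table(X), activity_table(rownames(X), y, y, y))
  reg <- ann_fit(ds, "Y1", c("X1", "X2", "X3"), ann_config(seed = 5))
  un <- ann_fit(ds, "Y1", c("X1", "X2", "X3"),
                ann_config(seed = 5, bayes = FALSE))
  expect_lt(reg$gamma, reg$n_weights / 2)       # few effective parameters
  expect_lt(reg$stats$r2, un$stats$r2 - 0.2)    # overfitting suppressed
})

test_that("training error sits at the noise floor for a smooth nonlinear target", {
  # default nonlinear shape (gain 1): moderately saturating, where the
  # weight prior does not bias the fit appreciably
  sigma <- 0.25
  sp <- synthetic_spec(n_compounds = 100, n_descriptors = 3,
                       planted_subset = c("X1", "X2", "X3"),
                       nonlinear = TRUE, noise_sd = sigma, seed = 21)
  d <- generate_descriptors(sp)
  y <- plant_nonlinear_activity(d, sp)
  ds <- qsar_dataset(d, activity_table(rownames(d), y, y, y))
  net <- ann_fit(ds, "Y1", c("X1", "X2", "X3"), ann_config(seed = 9))
  train_rmse <- rmse(y, predict(net, ds))
  expect_gte(train_rmse, 0.8 * sigma)
  expect_lte(train_rmse, 1.3 * sigma)
  # report route agrees with the noise ceiling 1 - sigma^2 / var(y)
  rep <- ann_report(net, ds)
  ceiling_r2 <- 1 - sigma^2 / stats::var(y) * (length(y) - 1) / length(y)
  expect_equal(rep$train$r2, ceiling_r2, tolerance = 0.08)
})

test_that("network beats the linear model in a strongly nonlinear regime", {
  sp <- synthetic_spec(n_compounds = 100, n_descriptors = 3,
                       planted_subset = c("X1", "X2", "X3"),
                       nonlinear = TRUE, nl_gain = 4, nl_amplitude = 1.5,
                       nl_center = 5, noise_sd = 0.15, seed = 77)
  d <- generate_descriptors(sp)
  y <- plant_nonlinear_activity(d, sp)
  ds <- qsar_dataset(d, activity_table(rownames(d), y, y, y))
  mlr <- mlr_fit(ds, "Y1", c("X1", "X2", "X3"))
  net <- ann_fit(ds, "Y1", c("X1", "X2", "X3"), ann_config(seed = 13))
  expect_gte(net$stats$r2, mlr$stats$r2 + 0.05)
})

test_that("prediction demands the trained descriptor columns", {
  ds <- synthetic_qsar_dataset(seed = 3)
  net <- ann_fit(ds, "Y1", c("X17", "X19", "X20"),
                 ann_config(seed = 1, max_epochs = 50))
  bad <- matrix(1, 2, 2, dimnames = list(NULL, c("X17", "X19")))
  expect_error(predict(net, bad), "X20", class = "alignment_error")
})
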