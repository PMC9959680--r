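#' Training configuration for the Bayesian-regularized MLP
#'
#' Levenberg-Marquardt damping controls and evidence-framework
#' hyperparameter seeds. Defaults follow common fitting-tool practice:
#' initial damping `mu_init = 1e-3`, raised x10 on a rejected step and
#' lowered x0.1 on acceptance, up to `mu_max = 1e10`; up to 1000 epochs;
#' stop when the largest gradient component falls below `gradient_tol`.
#' Regularization starts effectively off (`alpha_init = 0`, `beta_init = 1`)
#' and is adapted from the data after every accepted step.
#'
#' @param max_epochs epoch cap.
#' @param mu_init,mu_increase,mu_decrease,mu_max LM damping controls.
#' @param gradient_tol stopping tolerance on the objective gradient.
#' @param alpha_init,beta_init initial weight-penalty and error-precision
#'   hyperparameters.
#' @param bayes if `FALSE`, hyperparameters stay fixed (plain LM training).
#' @param seed RNG seed for the weight initialization.
#' @return list of class `ann_config`.
#' @export
ann_config <- function(max_epochs = 1000, mu_init = 1e-3, mu_increase = 10,
                       mu_decrease = 0.1, mu_max = 1e10,
                       gradient_tol = 1e-7, alpha_init = 0, beta_init = 1,
                       bayes = TRUE, seed = 1L) {
  stopifnot(mu_init > 0, mu_increase > 1, mu_decrease > 0, mu_decrease < 1,
            mu_max > mu_init, max_epochs >= 1, alpha_init >= 0, beta_init > 0)
  structure(list(max_epochs = as.integer(max_epochs), mu_init = mu_init,
                 mu_increase = mu_increase, mu_decrease = mu_decrease,
                 mu_max = mu_max, gradient_tol = gradient_tol,
                 alpha_init = alpha_init, beta_init = beta_init,
                 bayes = isTRUE(bayes), seed = as.integer(seed)),
            class = "ann_config")
}

# Weight-vector layout for an n_in - n_h - 1 network:
#   first n_h * (n_in + 1) entries: hidden layer, row-major per hidden unit
#   (input weights then bias); last (n_h + 1): output weights then bias.
ann_nweights <- function(n_in, n_h) n_h * (n_in + 1) + (n_h + 1)

ann_unpack <- function(w, n_in, n_h) {
  k <- n_h * (n_in + 1)
  list(W1 = matrix(w[seq_len(k)], nrow = n_h, byrow = TRUE),   # n_h x (n_in+1)
       W2 = w[(k + 1):(k + n_h + 1)])                          # length n_h+1
}

#' Forward pass of the MLP on already-scaled inputs
#'
#' tanh hidden activations, linear output:
#' `yhat = W2 %*% c(tanh(W1 %*% c(x, 1)), 1)`.
#'
#' @param w flat weight vector.
#' @param Xs n x n_in matrix of scaled inputs.
#' @param n_h hidden-unit count.
#' @return list: `yhat` (length n), `H` (n x n_h hidden activations, kept
#'   for the Jacobian).
#' @export
ann_forward_scaled <- function(w, Xs, n_h = 3) {
  Xs <- as.matrix(Xs)
  n_in <- ncol(Xs)
  p <- ann_unpack(w, n_in, n_h)
  A <- cbind(Xs, 1) %*% t(p$W1)          # n x n_h pre-activations
  H <- tanh(A)
  yhat <- drop(cbind(H, 1) %*% p$W2)
  list(yhat = yhat, H = H)
}

#' Jacobian of network outputs with respect to the weights
#'
#' Analytic backpropagated derivatives d(yhat_i)/d(w_k) for every row, on
#' the scaled training space. Since the residual is `yhat - y`, this is also
#' the residual Jacobian.
#'
#' @inheritParams ann_forward_scaled
#' @return n x N_w matrix.
#' @export
ann_jacobian <- function(w, Xs, n_h = 3) {
  Xs <- as.matrix(Xs)
  n <- nrow(Xs); n_in <- ncol(Xs)
  p <- ann_unpack(w, n_in, n_h)
  fw <- ann_forward_scaled(w, Xs, n_h)
  H <- fw$H
  D <- 1 - H^2                               # tanh'
  Xb <- cbind(Xs, 1)                         # n x (n_in+1)
  J <- matrix(0, n, ann_nweights(n_in, n_h))
  # hidden-layer weights: d yhat / d W1[j,k] = W2[j] * (1 - h_j^2) * xb_k
  for (j in seq_len(n_h)) {
    cols <- ((j - 1) * (n_in + 1) + 1):(j * (n_in + 1))
    J[, cols] <- (p$W2[j] * D[, j]) * Xb
  }
  # output-layer weights: d yhat / d W2 = c(h, 1)
  J[, (n_h * (n_in + 1) + 1):ncol(J)] <- cbind(H, 1)
  J
}

#' One Levenberg-Marquardt step on the regularized objective
#'
#' Solves `(beta J'J + (mu + alpha) I) delta = -(beta J'r + alpha w)` and
#' returns the proposed weights `w + delta`. The caller accepts the proposal
#' only if the regularized objective `beta * E_D + alpha * E_W` decreases,
#' raising `mu` otherwise. As `mu -> Inf` the step length goes to 0; with
#' `alpha = 0`, `mu = 0` and a model linear in its weights, one step lands
#' on the least-squares optimum.
#'
#' @param w current weights.
#' @param J residual Jacobian (rows = observations).
#' @param r residuals (`yhat - y`) on the training scale.
#' @param mu damping parameter (>= 0).
#' @param alpha weight-penalty hyperparameter.
#' @param beta error-precision hyperparameter.
#' @return proposed weight vector.
#' @export
lm_step <- function(w, J, r, mu, alpha = 0, beta = 1) {
  A <- beta * crossprod(J) + diag(mu + alpha, length(w))
  g <- beta * drop(crossprod(J, r)) + alpha * w
  w - drop(solve(A, g))
}

#' Evidence-framework hyperparameter update
#'
#' MacKay updates for the Bayesian-regularized objective
#' `F = beta * E_D + alpha * E_W` with `E_D = 0.5 * sum(r^2)` and
#' `E_W = 0.5 * sum(w^2)`:
#' `gamma = N_w - alpha * tr(H^-1)` (effective number of parameters, clamped
#' to `[0, min(N_w, n_obs)]`), then `alpha = gamma / (2 E_W)` and
#' `beta = (n_obs - gamma) / (2 E_D)` with the numerator floored at one
#' residual degree of freedom, so the error precision stays positive even
#' when the network has more weights than there are observations. A
#' singular Hessian is inverted with a small ridge and a warning.
#'
#' @param alpha,beta current hyperparameters.
#' @param E_W,E_D half sums of squared weights / residuals (must be > 0; a
#'   tiny floor is applied internally).
#' @param n_obs training observations.
#' @param N_w weight count.
#' @param hessian Gauss-Newton Hessian `beta J'J + alpha I`.
#' @return list `alpha`, `beta`, `gamma`.
#' @export
bayes_update <- function(alpha, beta, E_W, E_D, n_obs, N_w, hessian) {
  Hinv <- tryCatch(solve(hessian), error = function(e) {
    warning("singular Hessian in evidence update; using ridge-stabilized inverse")
    solve(hessian + diag(1e-8 * max(diag(hessian), 1), nrow(hessian)))
  })
  gamma <- N_w - alpha * sum(diag(Hinv))
  # effective parameters cannot exceed the data count; keep at least one
  # residual degree of freedom so beta never collapses when N_w >= n_obs
  gamma <- min(max(gamma, 0), N_w, n_obs)
  alpha_new <- gamma / (2 * max(E_W, 1e-12))
  beta_new <- max(n_obs - gamma, 1) / (2 * max(E_D, 1e-12))
  list(alpha = alpha_new, beta = beta_new, gamma = gamma)
}

# affine map of each column onto [-1, 1]; returns scaled matrix + record
minmax_scale <- function(M) {
  M <- as.matrix(M)
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  span <- hi - lo
  if (any(span == 0))
    stop_pq("constant column(s) cannot be min-max scaled: %s",
            paste(colnames(M)[span == 0], collapse = ", "),
            class = "degenerate_input_error")
  Z <- sweep(sweep(M, 2, lo), 2, span, "/") * 2 - 1
  list(scaled = Z, lo = lo, hi = hi)
}

minmax_apply <- function(M, rec) {
  sweep(sweep(as.matrix(M), 2, rec$lo), 2, rec$hi - rec$lo, "/") * 2 - 1
}

minmax_invert <- function(Z, rec) {
  (as.matrix(Z) + 1) / 2 * (rec$hi - rec$lo) + rec$lo
}

#' Fit a 3-3-1 neural-network QSAR model
#'
#' Trains a multilayer perceptron (three inputs, one hidden layer of three
#' tanh units, one linear output) on one activity, using Levenberg-Marquardt
#' optimization of the Bayesian-regularized objective
#' `F = beta * E_D + alpha * E_W`. Inputs and target are affinely mapped to
#' \[-1, 1\] before training; the scalings are stored and inverted on
#' prediction. The evidence-framework update of `alpha`, `beta` after every
#' accepted step adapts the effective number of parameters `gamma` to the
#' information in the data, suppressing overfitting on small training sets
#' without a validation split.
#'
#' @param ds a [qsar_dataset()] with at least 6 training compounds.
#' @param response `"Y1"`, `"Y2"` or `"Y3"`.
#' @param descriptors the 3 descriptor ids feeding the network (typically
#'   the subset selected by [ga_select()] for the same activity).
#' @param cfg an [ann_config()].
#' @param n_hidden hidden-layer width (default 3).
#' @return object of class `qsar_ann`: weights, scalings, final `alpha`,
#'   `beta`, `gamma`, objective history, and training stats.
#' @export
ann_fit <- function(ds, response = c("Y1", "Y2", "Y3"), descriptors,
                    cfg = ann_config(), n_hidden = 3) {
  response <- match.arg(response)
  X <- extract_descriptors(ds, descriptors)
  y <- ds$activities[[response]]
  n <- nrow(X)
  if (n < 6)
    stop_pq("need at least 6 training compounds, got %d", n,
            class = "argument_error")
  xs <- minmax_scale(X)
  ys <- minmax_scale(matrix(y, ncol = 1, dimnames = list(NULL, response)))
  Xs <- xs$scaled
  ysc <- drop(ys$scaled)
  n_in <- ncol(Xs)
  N_w <- ann_nweights(n_in, n_hidden)

  with_seed(cfg$seed, {
    w <- stats::runif(N_w, -0.5, 0.5)
    alpha <- cfg$alpha_init; beta <- cfg$beta_init
    gamma <- N_w
    mu <- cfg$mu_init
    objective <- function(w) {
      r <- ann_forward_scaled(w, Xs, n_hidden)$yhat - ysc
      beta * 0.5 * sum(r^2) + alpha * 0.5 * sum(w^2)
    }
    history <- numeric(0)
    epochs <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      epochs <- epoch
      r <- ann_forward_scaled(w, Xs, n_hidden)$yhat - ysc
      J <- ann_jacobian(w, Xs, n_hidden)
      g <- beta * drop(crossprod(J, r)) + alpha * w
      if (!all(is.finite(g)))
        stop_pq("non-finite gradient at epoch %d", epoch,
                class = "training_failure")
      if (max(abs(g)) < cfg$gradient_tol) break
      f_cur <- beta * 0.5 * sum(r^2) + alpha * 0.5 * sum(w^2)
      accepted <- FALSE
      while (mu <= cfg$mu_max) {
        w_try <- lm_step(w, J, r, mu, alpha, beta)
        f_try <- objective(w_try)
        if (is.finite(f_try) && f_try < f_cur) {
          w <- w_try
          mu <- max(mu * cfg$mu_decrease, 1e-20)
          accepted <- TRUE
          break
        }
        mu <- mu * cfg$mu_increase
      }
      history <- c(history, if (accepted) objective(w) else f_cur)
      if (!accepted) break                     # mu exhausted: converged
      if (cfg$bayes) {
        r <- ann_forward_scaled(w, Xs, n_hidden)$yhat - ysc
        J <- ann_jacobian(w, Xs, n_hidden)
        E_D <- 0.5 * sum(r^2); E_W <- 0.5 * sum(w^2)
        H <- beta * crossprod(J) + diag(max(alpha, 1e-8), N_w)
        upd <- bayes_update(alpha, beta, E_W, E_D, n, N_w, H)
        alpha <- upd$alpha; beta <- upd$beta; gamma <- upd$gamma
      }
    }
    yhat <- minmax_invert(
      matrix(ann_forward_scaled(w, Xs, n_hidden)$yhat, ncol = 1), ys)[, 1]
    net <- structure(
      list(architecture = c(n_input = n_in, n_hidden = n_hidden, n_output = 1L),
           weights = w, n_weights = N_w,
           descriptor_ids = colnames(X), response_id = response,
           input_scaling = xs[c("lo", "hi")], output_scaling = ys[c("lo", "hi")],
           alpha = alpha, beta = beta, gamma = gamma,
           epochs_run = epochs, objective_history = history,
           fitted = stats::setNames(yhat, rownames(ds$descriptors)),
           y = y, seed = cfg$seed),
      class = "qsar_ann")
    net$stats <- tryCatch(
      regression_stats(X, y, yhat, loo = FALSE),
      error = function(e) NULL)
    net
  })
}

#' Predict activities from a trained network
#'
#' @param object a `qsar_ann` model.
#' @param newdata tabular input containing the network's descriptor columns.
#' @param ... unused.
#' @return numeric vector of predicted activities (percent/10 scale).
#' @export
predict.qsar_ann <- function(object, newdata, ...) {
  X <- extract_descriptors(newdata, object$descriptor_ids)
  Xs <- minmax_apply(X, object$input_scaling)
  yhat_s <- ann_forward_scaled(object$weights, Xs,
                               object$architecture[["n_hidden"]])$yhat
  drop(minmax_invert(matrix(yhat_s, ncol = 1), object$output_scaling))
}

#' @export
print.qsar_ann <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("Bayesian-regularized MLP %d-%d-%d for %s on {%s}\n",
              a[["n_input"]], a[["n_hidden"]], a[["n_output"]],
              x$response_id, paste(x$descriptor_ids, collapse = ", ")))
  cat(sprintf("  epochs = %d, alpha = %.4g, beta = %.4g, gamma = %.2f of %d weights\n",
              x$epochs_run, x$alpha, x$beta, x$gamma, x$n_weights))
  if (!is.null(x$stats))
    cat(sprintf("  train R2 = %.3f, RMSE = %.3f\n", x$stats$r2, x$stats$rmse))
  invisible(x)
}

#' @export
summary.qsar_ann <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
residuals.qsar_ann <- function(object, ...) object$y - object$fitted

#' Train/test report for a network model
#'
#' Applies the regression-diagnostics formulas (R2, RMSE, sums of squares)
#' to the network's predictions on the training set and, optionally, a test
#' set. Leave-one-out terms are not computed (they are defined for the
#' OLS refit procedure, not network retraining).
#'
#' @param net a `qsar_ann`.
#' @param ds_train training [qsar_dataset()].
#' @param ds_test optional test [qsar_dataset()].
#' @return list with elements `train` and (if given) `test`, each a
#'   [regression_stats()] record.
#' @export
ann_report <- function(net, ds_train, ds_test = NULL) {
  out <- list(train = test_stats(net, ds_train))
  if (!is.null(ds_test)) out$test <- test_stats(net, ds_test)
  out
}
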