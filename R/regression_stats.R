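#' Sums of squares of a fitted regression
#'
#' Residual, total, and explained sums of squares:
#' \deqn{RSS = \sum_i (\hat y_i - y_i)^2, \quad
#'       TSS = \sum_i (y_i - \bar y)^2, \quad
#'       ESS = \sum_i (\hat y_i - \bar y)^2.}
#' For an ordinary-least-squares fit with intercept, `TSS = ESS + RSS`.
#'
#' @param y observed responses.
#' @param yhat fitted values.
#' @return named list `rss`, `tss`, `ess`.
#' @export
sum_of_squares <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop_pq("y and yhat lengths differ (%d vs %d)", length(y), length(yhat),
            class = "argument_error")
  if (length(y) < 2)
    stop_pq("need at least 2 observations", class = "degenerate_input_error")
  ybar <- mean(y)
  list(rss = sum((yhat - y)^2), tss = sum((y - ybar)^2),
       ess = sum((yhat - ybar)^2))
}

#' Coefficient of determination
#'
#' R-squared as the explained fraction of total variance, `ESS / TSS`. For
#' OLS with intercept this equals `1 - RSS/TSS`.
#'
#' @param ss list from [sum_of_squares()].
#' @export
r_squared <- function(ss) {
  if (ss$tss == 0)
    stop_pq("response has zero variance; R2 undefined",
            class = "degenerate_input_error")
  ss$ess / ss$tss
}

#' Significance-of-regression F statistic
#'
#' Ratio of the explained mean square to the residual mean square,
#' `F = (ESS/(p-1)) / (RSS/(n-p))`, where `p` counts parameters including
#' the intercept. A perfect fit (zero residual) is reported as `Inf` with a
#' warning rather than an error.
#'
#' @param ss list from [sum_of_squares()].
#' @param n number of observations.
#' @param p number of model parameters including the intercept.
#' @export
f_statistic <- function(ss, n, p) {
  if (n <= p)
    stop_pq("F statistic needs n > p (n = %d, p = %d)", n, p,
            class = "degrees_of_freedom_error")
  if (ss$rss == 0) {
    warning("perfect fit: zero residual sum of squares, F reported as Inf")
    return(Inf)
  }
  (ss$ess / (p - 1)) / (ss$rss / (n - p))
}

#' Critical F value for the significance-of-regression test
#'
#' Upper-`alpha` quantile of the F distribution with `(p - 1, n - p)`
#' degrees of freedom.
#'
#' @param p parameters including intercept.
#' @param n observations.
#' @param alpha significance level; default 0.05 (95% confidence).
#' @export
f_critical <- function(p, n, alpha = 0.05) {
  if (n <= p || p < 2)
    stop_pq("F critical needs n > p >= 2", class = "degrees_of_freedom_error")
  stats::qf(1 - alpha, df1 = p - 1, df2 = n - p)
}

#' Leave-one-out predicted residual error sum of squares (PRESS)
#'
#' For each observation i the model is refit on the remaining n - 1 points
#' and used to predict y_i; PRESS accumulates the squared prediction errors.
#' For OLS this equals the hat-matrix closed form
#' \eqn{\sum_i (e_i / (1 - h_{ii}))^2}, which serves as an independent check.
#'
#' @param X numeric design matrix, descriptor columns only (no intercept
#'   column; one is added internally).
#' @param y responses.
#' @return PRESS value.
#' @export
loo_press <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X) + 1
  if (n <= p + 1)
    stop_pq("leave-one-out needs n > p + 1 (n = %d, p = %d)", n, p,
            class = "degenerate_input_error")
  press <- 0
  for (i in seq_len(n)) {
    fit <- tryCatch(
      ols_core(X[-i, , drop = FALSE], y[-i]),
      error = function(e)
        stop_pq("leave-one-out fit singular when omitting observation %d", i,
                class = "singularity_error"))
    pred <- fit$intercept + drop(X[i, , drop = FALSE] %*% fit$coefficients)
    press <- press + (y[i] - pred)^2
  }
  press
}

#' Cross-validated R-squared
#'
#' `R2(CV) = 1 - PRESS / TSS`; may be negative for models that predict worse
#' than the response mean.
#'
#' @param press PRESS value from [loo_press()].
#' @param tss total sum of squares.
#' @export
r2_cv <- function(press, tss) {
  if (tss <= 0)
    stop_pq("TSS must be positive", class = "degenerate_input_error")
  1 - press / tss
}

#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))` with divisor equal to the number of
#' observations.
#'
#' @param y observed.
#' @param yhat predicted.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop_pq("y and yhat lengths differ", class = "argument_error")
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation matrix over descriptors and activities
#'
#' Product-moment correlations among all descriptor columns and the three
#' activities, for collinearity screening. Zero-variance columns yield `NA`
#' entries and a warning naming them (never a silent 0).
#'
#' @param ds a [qsar_dataset()], or a plain numeric matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(ds) {
  M <- if (inherits(ds, "qsar_dataset")) {
    cbind(unclass(ds$descriptors),
          Y1 = ds$activities$Y1, Y2 = ds$activities$Y2, Y3 = ds$activities$Y3)
  } else as.matrix(ds)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    warning(sprintf("zero-variance column(s) give undefined correlations: %s",
                    paste(colnames(M)[sds == 0], collapse = ", ")))
  suppressWarnings({
    R <- stats::cor(M)
    diag(R) <- 1
  })
  R
}

# Core OLS solver on a plain design matrix (intercept added here).
# Errors on rank deficiency, naming the aliased columns.
ols_core <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  if (n <= p)
    stop_pq("need n > p (n = %d, p = %d)", n, p, class = "degrees_of_freedom_error")
  qr_ <- qr(Xd)
  if (qr_$rank < p) {
    aliased <- colnames(Xd)[qr_$pivot[(qr_$rank + 1):p]]
    stop_pq("design matrix is rank-deficient; collinear column(s): %s",
            paste(aliased, collapse = ", "), class = "singularity_error")
  }
  beta <- qr.coef(qr_, y)
  fitted <- drop(Xd %*% beta)
  # leverages for the PRESS closed form
  Q <- qr.Q(qr_)
  h <- rowSums(Q^2)
  list(intercept = unname(beta[1]), coefficients = beta[-1],
       fitted = fitted, leverage = h, n = n, p = p)
}

#' Full regression-diagnostics suite for a fitted model
#'
#' Computes the statistics used to judge a QSAR regression: the sums of
#' squares, R2, the significance-of-regression F with its 95% critical
#' value, leave-one-out PRESS and cross-validated R2, and the training RMSE.
#'
#' @param X design columns (no intercept column).
#' @param y responses.
#' @param yhat fitted values.
#' @param alpha significance level for the F test.
#' @param loo if `FALSE`, skip the leave-one-out statistics (e.g. for test
#'   sets, where PRESS is not meaningful).
#' @return object of class `regression_stats`.
#' @export
regression_stats <- function(X, y, yhat, alpha = 0.05, loo = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X) + 1
  ss <- sum_of_squares(y, yhat)
  out <- list(n = n, p = p, rss = ss$rss, tss = ss$tss, ess = ss$ess,
              r2 = r_squared(ss),
              f = f_statistic(ss, n, p),
              f_critical = f_critical(p, n, alpha),
              rmse = rmse(y, yhat))
  if (loo) {
    out$press <- loo_press(X, y)
    out$r2_cv <- r2_cv(out$press, ss$tss)
  } else {
    out$press <- NA_real_
    out$r2_cv <- NA_real_
  }
  structure(out, class = "regression_stats")
}

#' @export
print.regression_stats <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d, p = %d\n", x$n, x$p))
  cat(sprintf("R2 = %.*f   R2(CV) = %s   RMSE = %.*f\n", digits, x$r2,
              if (is.na(x$r2_cv)) "NA" else formatC(x$r2_cv, digits = digits, format = "f"),
              digits, x$rmse))
  cat(sprintf("F = %.*f vs F_cr(%d, %d; 95%%) = %.*f -> %s\n", digits, x$f,
              x$p - 1, x$n - x$p, digits, x$f_critical,
              if (x$f > x$f_critical) "significant" else "not significant"))
  invisible(x)
}
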