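#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of one activity on a chosen descriptor subset,
#' with the full diagnostics suite (R2, significance-of-regression F vs its
#' 95% critical value, leave-one-out PRESS and R2(CV), training RMSE).
#' This is the model form produced by spline-free GFA descriptor selection.
#'
#' @param ds a [qsar_dataset()] (typically the training subset).
#' @param response one of `"Y1"` (.OH), `"Y2"` (O2.-), `"Y3"` (DPPH.).
#' @param descriptors character vector of descriptor ids to use.
#' @param loo compute leave-one-out statistics (default `TRUE`).
#' @return object of class `qsar_mlr`: coefficients, intercept, fitted
#'   values, and a [regression_stats()] record.
#' @export
mlr_fit <- function(ds, response = c("Y1", "Y2", "Y3"), descriptors,
                    loo = TRUE) {
  response <- match.arg(response)
  descriptors <- as.character(descriptors)
  if (anyDuplicated(descriptors))
    stop_pq("duplicate descriptor ids", class = "argument_error")
  miss <- setdiff(descriptors, colnames(ds$descriptors))
  if (length(miss) > 0)
    stop_pq("descriptor column(s) not in data set: %s",
            paste(miss, collapse = ", "), class = "alignment_error")
  X <- unclass(ds$descriptors)[, descriptors, drop = FALSE]
  y <- ds$activities[[response]]
  fit <- ols_core(X, y)
  stats <- regression_stats(X, y, fit$fitted, loo = loo)
  structure(list(descriptor_ids = descriptors,
                 coefficients = stats::setNames(unname(fit$coefficients), descriptors),
                 intercept = fit$intercept,
                 response_id = response,
                 fitted = stats::setNames(fit$fitted, rownames(ds$descriptors)),
                 leverage = fit$leverage,
                 y = y,
                 stats = stats),
            class = "qsar_mlr")
}

#' Build a linear QSAR model from fixed coefficients
#'
#' Wraps a printed coefficient set (e.g. a literature equation) in the same
#' `qsar_mlr` structure produced by [mlr_fit()], without fitting data.
#'
#' @param coefficients named numeric vector (names = descriptor ids).
#' @param intercept intercept value.
#' @param response_id which activity the model predicts.
#' @return object of class `qsar_mlr` (no fitted values or stats).
#' @export
mlr_model <- function(coefficients, intercept, response_id) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(is.finite(coefficients)), is.finite(intercept))
  structure(list(descriptor_ids = names(coefficients),
                 coefficients = coefficients,
                 intercept = unname(intercept),
                 response_id = response_id,
                 fitted = NULL, y = NULL, stats = NULL),
            class = "qsar_mlr")
}

#' @export
coef.qsar_mlr <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.qsar_mlr <- function(x, digits = 3, ...) {
  terms <- paste(sprintf("%+.*f*%s", digits, x$coefficients, x$descriptor_ids),
                 collapse = " ")
  cat(sprintf("%s = %s %+.*f\n", x$response_id, terms, digits, x$intercept))
  if (!is.null(x$stats))
    cat(sprintf("  R2 = %.3f, R2(CV) = %s, RMSE = %.3f\n", x$stats$r2,
                if (is.na(x$stats$r2_cv)) "NA" else sprintf("%.3f", x$stats$r2_cv),
                x$stats$rmse))
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  print(object)
  if (!is.null(object$stats)) print(object$stats)
  invisible(object)
}

#' @export
residuals.qsar_mlr <- function(object, ...) {
  if (is.null(object$fitted))
    stop_pq("model was built from fixed coefficients; no residuals",
            class = "argument_error")
  object$y - object$fitted
}

#' Predict activities from a linear QSAR model
#'
#' @param object a `qsar_mlr` model.
#' @param newdata a [descriptor_table()], `qsar_dataset`, matrix or
#'   data.frame containing the model's descriptor columns.
#' @param ... unused.
#' @return named numeric vector of predicted activities (percent/10 scale,
#'   not clipped).
#' @export
predict.qsar_mlr <- function(object, newdata, ...) {
  X <- extract_descriptors(newdata, object$descriptor_ids)
  drop(object$intercept + X %*% object$coefficients)
}

# Pull named descriptor columns out of any tabular input, erroring with the
# missing names.
extract_descriptors <- function(newdata, ids) {
  M <- if (inherits(newdata, "qsar_dataset")) unclass(newdata$descriptors)
       else if (inherits(newdata, "descriptor_table")) unclass(newdata)
       else as.matrix(as.data.frame(newdata))
  miss <- setdiff(ids, colnames(M))
  if (length(miss) > 0)
    stop_pq("missing descriptor column(s): %s", paste(miss, collapse = ", "),
            class = "alignment_error")
  M <- M[, ids, drop = FALSE]
  storage.mode(M) <- "double"
  M
}

#' Evaluate a fitted model on a test set
#'
#' @param model a `qsar_mlr` or `qsar_ann` model.
#' @param ds a [qsar_dataset()] holding the test compounds.
#' @return a [regression_stats()] record (without leave-one-out terms).
#' @export
test_stats <- function(model, ds) {
  y <- ds$activities[[model$response_id]]
  yhat <- stats::predict(model, ds)
  p_cols <- length(model$descriptor_ids)
  X <- extract_descriptors(ds, model$descriptor_ids)
  if (length(y) <= p_cols + 1) {
    # small external test sets: report descriptive stats only
    ss <- sum_of_squares(y, yhat)
    return(structure(list(n = length(y), p = p_cols + 1, rss = ss$rss,
                          tss = ss$tss, ess = ss$ess,
                          r2 = if (ss$tss > 0) r_squared(ss) else NA_real_,
                          f = NA_real_, f_critical = NA_real_,
                          press = NA_real_, r2_cv = NA_real_,
                          rmse = rmse(y, yhat)),
                     class = "regression_stats"))
  }
  regression_stats(X, y, yhat, loo = FALSE)
}
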