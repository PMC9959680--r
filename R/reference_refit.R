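#' Refit the three reference descriptor subsets on a pyrrole series
#'
#' Given a measured 15-compound pyrrole data set (33 descriptors plus
#' Y1-Y3), refits ordinary least squares on the three reference descriptor
#' subsets — \{X17, X19, X20\} for Y1, \{X19, X20, X21\} for Y2,
#' \{X16, X26, X30\} for Y3 — using the designated training compounds, and
#' reports the full diagnostics plus the Pearson correlation between Y1 and
#' Y2 over the whole series. Optionally trains the three 3-3-1 networks on
#' the same subsets.
#'
#' @param ds a [qsar_dataset()] with descriptor ids X1..X33.
#' @param test_ids compound ids held out as the external test set; default
#'   `Cpd.6`, `Cpd.8`, `Cpd.11`.
#' @param ann if `TRUE`, also train the Bayesian-regularized networks.
#' @param ann_seeds seeds for the network fits (one fit per seed; the best
#'   training R2 per response is reported).
#' @return list: `models` (three fitted `qsar_mlr`), `train_stats`,
#'   `test_stats`, `pearson_y1_y2`, and (with `ann`) `ann_train_r2`.
#' @export
reference_refit <- function(ds, test_ids = c("Cpd.6", "Cpd.8", "Cpd.11"),
                            ann = FALSE, ann_seeds = 1:10) {
  ids <- rownames(ds$descriptors)
  miss <- setdiff(test_ids, ids)
  if (length(miss) > 0)
    stop_pq("test compound(s) not in data set: %s",
            paste(miss, collapse = ", "), class = "alignment_error")
  train <- subset_compounds(ds, setdiff(ids, test_ids))
  test <- subset_compounds(ds, intersect(ids, test_ids))
  subsets <- list(Y1 = c("X17", "X19", "X20"),
                  Y2 = c("X19", "X20", "X21"),
                  Y3 = c("X16", "X26", "X30"))
  models <- lapply(names(subsets), function(resp)
    mlr_fit(train, resp, subsets[[resp]]))
  names(models) <- names(subsets)
  out <- list(models = models,
              train_stats = lapply(models, `[[`, "stats"),
              test_stats = lapply(models, test_stats, ds = test),
              pearson_y1_y2 = stats::cor(ds$activities$Y1, ds$activities$Y2))
  if (ann) {
    out$ann_train_r2 <- vapply(names(subsets), function(resp) {
      max(vapply(ann_seeds, function(s) {
        net <- ann_fit(train, resp, subsets[[resp]], ann_config(seed = s))
        if (is.null(net$stats)) NA_real_ else net$stats$r2
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  out
}
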