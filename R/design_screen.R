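#' Reference GA-MLR equations for the pyrrole antioxidant series
#'
#' The three published linear QSAR equations relating radical-scavenging
#' activities of pyrrole derivatives to quantum-chemical descriptors, with
#' their printed coefficients (activities on the percent/10 scale):
#' \itemize{
#'   \item Y1 (.OH)  = -90.879 X17 - 47.988 X19 + 0.016 X20 + 207.384
#'   \item Y2 (O2.-) = -43.836 X19 + 0.005 X20 - 75.277 X21 + 47.527
#'   \item Y3 (DPPH.) = 61.220 X16 - 1.240 X26 + 0.052 X30 - 102.072
#' }
#' where X16 = bond N1-C13, X17 = bond C2-R(b), X19 = bond C4-C11 (all in
#' Angstrom), X20 = polarizability, X21 = HOMO energy (a.u.), X26 = AlogP,
#' X30 = Connolly surface area (Angstrom^2).
#'
#' @return named list of three [mlr_model()] objects (`Y1`, `Y2`, `Y3`).
#' @export
reference_equations <- function() {
  list(
    Y1 = mlr_model(c(X17 = -90.879, X19 = -47.988, X20 = 0.016),
                   intercept = 207.384, response_id = "Y1"),
    Y2 = mlr_model(c(X19 = -43.836, X20 = 0.005, X21 = -75.277),
                   intercept = 47.527, response_id = "Y2"),
    Y3 = mlr_model(c(X16 = 61.220, X26 = -1.240, X30 = 0.052),
                   intercept = -102.072, response_id = "Y3"))
}

#' Activity thresholds for candidate screening
#'
#' Defaults on the percent/10 scale: a candidate is flagged when its
#' predicted .OH and O2.- scavenging both exceed 80% (8.0) and its DPPH.
#' scavenging exceeds 70% (7.0). Comparisons are strictly greater-than.
#'
#' @param oh_min,o2_min,dpph_min thresholds on the percent/10 scale,
#'   each in \[0, 10\].
#' @param percent if `TRUE`, thresholds are given as raw percentages and
#'   divided by 10.
#' @return list of class `activity_thresholds`.
#' @export
activity_thresholds <- function(oh_min = 8.0, o2_min = 8.0, dpph_min = 7.0,
                                percent = FALSE) {
  v <- c(oh_min = oh_min, o2_min = o2_min, dpph_min = dpph_min)
  if (percent) v <- v / 10
  if (any(v < 0 | v > 10))
    stop_pq("thresholds must lie in [0, 10] on the percent/10 scale",
            class = "argument_error")
  structure(as.list(v), class = "activity_thresholds")
}

#' Screen candidate compounds against activity thresholds
#'
#' Predicts Y1/Y2/Y3 for each candidate with the three linear models and,
#' optionally, the three trained networks, then applies the pass rules:
#' the radical pair rule (`Y1 > oh_min` AND `Y2 > o2_min`) and the DPPH
#' rule (`Y3 > dpph_min`), strictly greater in both cases. `passes_both`
#' requires MLR and ANN agreement (equal to the MLR flags when no networks
#' are supplied).
#'
#' @param candidates a [descriptor_table()] of designed compounds.
#' @param mlr_models named list of `qsar_mlr` models for Y1, Y2, Y3
#'   (default [reference_equations()]).
#' @param ann_models optional named list of `qsar_ann` models for Y1-Y3.
#' @param thresholds an [activity_thresholds()].
#' @return data.frame of class `screen_result`: one row per candidate with
#'   predictions and pass flags.
#' @export
screen_candidates <- function(candidates, mlr_models = reference_equations(),
                              ann_models = NULL,
                              thresholds = activity_thresholds()) {
  for (k in c("Y1", "Y2", "Y3")) {
    if (is.null(mlr_models[[k]]))
      stop_pq("mlr_models is missing a model for %s", k, class = "argument_error")
  }
  n_cand <- nrow(as.data.frame(unclass(candidates)))
  pred_with <- function(models, label) {
    vapply(c("Y1", "Y2", "Y3"), function(k) {
      m <- models[[k]]
      tryCatch(as.numeric(stats::predict(m, candidates)),
               pyrroqsar_error = function(e)
                 stop_pq("%s model %s: %s", label, k, conditionMessage(e),
                         class = "alignment_error"))
    }, numeric(n_cand))
  }
  shape <- function(P) {
    if (is.null(dim(P))) P <- matrix(P, nrow = n_cand,
                                     dimnames = list(NULL, c("Y1", "Y2", "Y3")))
    P
  }
  mlr_p <- shape(pred_with(mlr_models, "MLR"))
  radical_pass <- function(P, thr) P[, "Y1"] > thr$oh_min & P[, "Y2"] > thr$o2_min
  dpph_pass <- function(P, thr) P[, "Y3"] > thr$dpph_min
  cand_ids <- rownames(candidates) %||% (if (n_cand > 0)
    paste0("Cand.", seq_len(n_cand)) else character(0))
  out <- data.frame(compound_id = cand_ids,
                    mlr_y1 = mlr_p[, "Y1"], mlr_y2 = mlr_p[, "Y2"],
                    mlr_y3 = mlr_p[, "Y3"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$passes_mlr_radical <- radical_pass(mlr_p, thresholds)
  out$passes_mlr_dpph <- dpph_pass(mlr_p, thresholds)
  if (!is.null(ann_models)) {
    ann_p <- shape(pred_with(ann_models, "ANN"))
    out$ann_y1 <- ann_p[, "Y1"]; out$ann_y2 <- ann_p[, "Y2"]
    out$ann_y3 <- ann_p[, "Y3"]
    out$passes_ann_radical <- radical_pass(ann_p, thresholds)
    out$passes_ann_dpph <- dpph_pass(ann_p, thresholds)
    out$passes_both_radical <- out$passes_mlr_radical & out$passes_ann_radical
    out$passes_both_dpph <- out$passes_mlr_dpph & out$passes_ann_dpph
  } else {
    out$passes_both_radical <- out$passes_mlr_radical
    out$passes_both_dpph <- out$passes_mlr_dpph
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Summarize a screening run
#'
#' Ranked candidate table (by predicted Y1 descending, then compound id)
#' plus per-activity pass counts for each model route.
#'
#' @param results a `screen_result` from [screen_candidates()].
#' @return list of class `screen_report`: `ranked` (reordered results) and
#'   `counts` (named integer vector).
#' @export
screen_report <- function(results) {
  thr <- attr(results, "thresholds")
  ord <- order(-results$mlr_y1, results$compound_id)
  ranked <- results[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  has_ann <- "ann_y1" %in% names(results)
  counts <- c(
    mlr_oh = sum(results$mlr_y1 > thr$oh_min),
    mlr_o2 = sum(results$mlr_y2 > thr$o2_min),
    mlr_dpph = sum(results$mlr_y3 > thr$dpph_min),
    mlr_radical_pair = sum(results$passes_mlr_radical),
    both_radical_pair = sum(results$passes_both_radical),
    both_dpph = sum(results$passes_both_dpph))
  if (has_ann)
    counts <- c(counts,
                ann_oh = sum(results$ann_y1 > thr$oh_min),
                ann_o2 = sum(results$ann_y2 > thr$o2_min),
                ann_dpph = sum(results$ann_y3 > thr$dpph_min))
  structure(list(ranked = ranked, counts = counts, thresholds = thr),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Screened %d candidates (thresholds: .OH > %g, O2.- > %g, DPPH. > %g, percent/10)\n",
              nrow(x$ranked), x$thresholds$oh_min, x$thresholds$o2_min,
              x$thresholds$dpph_min))
  print(x$counts)
  invisible(x)
}
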