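test_that("reference equations carry the printed coefficient sets", {
  eqs <- reference_equations()
  expect_equal(eqs$Y1$intercept, 207.384)
  expect_equal(eqs$Y1$coefficients,
               c(X17 = -90.879, X19 = -47.988, X20 = 0.016))
  expect_equal(eqs$Y2$coefficients[["X21"]], -75.277)
  expect_equal(eqs$Y2$intercept, 47.527)
  expect_equal(eqs$Y3$coefficients[["X30"]], 0.052)
  expect_equal(eqs$Y3$intercept, -102.072)
  expect_identical(vapply(eqs, function(m) m$response_id, ""),
                   c(Y1 = "Y1", Y2 = "Y2", Y3 = "Y3"))
})

# candidate table whose reference-equation predictions are controlled via
# one free descriptor per activity (others pinned at activity-neutral values)
make_candidates <- function(y1, y2, y3) {
  n <- length(y1)
  # invert each equation for a single descriptor with the others fixed
  X20 <- rep(150, n); X19 <- rep(1.49, n); X21 <- rep(-0.32, n)
  X26 <- rep(2.5, n); X30 <- rep(420, n); X16 <- rep(1.45, n)
  X17 <- (207.384 - 47.988 * X19 + 0.016 * X20 - y1) / 90.879
  X19b <- (47.527 + 0.005 * X20 - 75.277 * X21 - y2) / 43.836
  X16b <- (y3 + 102.072 + 1.240 * X26 - 0.052 * X30) / 61.220
  M <- cbind(X16 = X16b, X17 = X17, X19 = X19, X20 = X20, X21 = X21,
             X26 = X26, X30 = X30)
  # Y2 needs its own X19; rebuild Y1's X17 against that X19
  M[, "X19"] <- X19b
  M[, "X17"] <- (207.384 - 47.988 * X19b + 0.016 * X20 - y1) / 90.879
  rownames(M) <- paste0("Cand.", seq_len(n))
  M
}

test_that("threshold rules are strict and recomputable from predictions", {
  cand <- make_candidates(y1 = c(8.5, 8.0, 2.0),
                          y2 = c(8.2, 8.0, 9.0),
                          y3 = c(7.2, 7.0, 6.0))
  res <- screen_candidates(cand)
  expect_equal(res$mlr_y1, c(8.5, 8.0, 2.0), tolerance = 1e-9)
  expect_equal(res$mlr_y2, c(8.2, 8.0, 9.0), tolerance = 1e-9)
  expect_equal(res$mlr_y3, c(7.2, 7.0, 6.0), tolerance = 1e-9)
  # candidate 1 passes everything; candidate 2 sits exactly on the
  # thresholds and must fail the strictly-greater rule
  expect_identical(res$passes_mlr_radical, c(TRUE, FALSE, FALSE))
  expect_identical(res$passes_mlr_dpph, c(TRUE, FALSE, FALSE))
  # flags recomputable from stored predictions
  thr <- attr(res, "thresholds")
  expect_identical(res$passes_mlr_radical,
                   res$mlr_y1 > thr$oh_min & res$mlr_y2 > thr$o2_min)

  # arithmetic spot check: X17=1.5, X19=1.5, X20=100 under equation 1
  row <- matrix(c(1.5, 1.5, 100, -0.3, 1.45, 2.5, 420), 1,
                dimnames = list("c", c("X17", "X19", "X20", "X21",
                                       "X16", "X26", "X30")))
  r1 <- screen_candidates(row)
  expect_equal(r1$mlr_y1, 0.6835, tolerance = 1e-4)
  expect_false(r1$passes_mlr_radical)
})

test_that("screen report ranks, counts, and stays monotone in the thresholds", {
  # empty candidate list
  empty <- matrix(numeric(0), 0, 7,
                  dimnames = list(NULL, c("X16", "X17", "X19", "X20",
                                          "X21", "X26", "X30")))
  rep0 <- screen_report(screen_candidates(empty))
  expect_equal(nrow(rep0$ranked), 0)
  expect_true(all(rep0$counts == 0))

  # 17-candidate fixture with a planted pass pattern: 9 pass the radical
  # pair, 4 pass DPPH
  y1 <- c(rep(9, 9), rep(5, 8))
  y2 <- c(rep(8.6, 9), rep(6, 8))
  y3 <- c(rep(7.5, 4), rep(5, 13))
  cand <- make_candidates(y1, y2, y3)
  res <- screen_candidates(cand)
  rep1 <- screen_report(res)
  expect_equal(unname(rep1$counts["mlr_radical_pair"]), 9)
  expect_equal(unname(rep1$counts["mlr_dpph"]), 4)
  expect_equal(unname(rep1$counts["mlr_oh"]), 9)
  # ranked by predicted Y1 descending, ties broken by compound id
  expect_true(all(diff(rep1$ranked$mlr_y1) <= 1e-12))

  # raising thresholds never increases counts
  res_hi <- screen_candidates(cand,
    thresholds = activity_thresholds(8.5, 8.5, 7.5))
  rep_hi <- screen_report(res_hi)
  expect_true(all(rep_hi$counts <= rep1$counts))

  # percent-scale thresholds divide by 10
  thr <- activity_thresholds(80, 80, 70, percent = TRUE)
  expect_equal(thr$oh_min, 8)
})

test_that("screening can combine MLR and ANN routes with agreement flags", {
  ds <- synthetic_qsar_dataset(seed = 6)
  tr <- split_subset(ds, ks_split(ds), "train")
  nets <- list(
    Y1 = ann_fit(tr, "Y1", c("X17", "X19", "X20"),
                 ann_config(seed = 1, max_epochs = 100)),
    Y2 = ann_fit(tr, "Y2", c("X19", "X20", "X21"),
                 ann_config(seed = 1, max_epochs = 100)),
    Y3 = ann_fit(tr, "Y3", c("X16", "X26", "X30"),
                 ann_config(seed = 1, max_epochs = 100)))
  res <- screen_candidates(ds$descriptors, ann_models = nets)
  expect_true(all(c("ann_y1", "passes_both_radical") %in% names(res)))
  expect_identical(res$passes_both_radical,
                   res$passes_mlr_radical & res$passes_ann_radical)
  # missing column names the offending model
  bad <- unclass(ds$descriptors)[, setdiff(colnames(ds$descriptors), "X21")]
  expect_error(screen_candidates(bad, ann_models = nets), "X21",
               class = "alignment_error")
})
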