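#' Euclidean pairwise distance matrix
#'
#' @param X numeric matrix (rows = compounds), typically autoscaled.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2)
    stop_pq("need at least 2 rows for pairwise distances",
            class = "degenerate_input_error")
  if (any(!is.finite(X)))
    stop_pq("non-finite values in distance input", class = "validation_error")
  as.matrix(stats::dist(X, method = "euclidean"))
}

#' Kennard-Stone maximin subset selection
#'
#' Deterministic representative-subset selection: seed with the globally most
#' distant pair of points, then repeatedly add the unselected point whose
#' minimum distance to the already-selected set is largest (maximin rule).
#' Ties are broken by lowest row index, making the selection fully
#' deterministic.
#'
#' @param X numeric matrix of (autoscaled) descriptors, or a precomputed
#'   distance matrix via `dist_matrix`.
#' @param k number of points to select, `2 <= k <= nrow(X)`.
#' @param dist_matrix optional precomputed symmetric distance matrix.
#' @return integer vector of length `k`: selected row indices in pick order.
#' @export
kennard_stone <- function(X, k, dist_matrix = NULL) {
  D <- dist_matrix %||% pairwise_distances(X)
  n <- nrow(D)
  if (k < 2 || k > n)
    stop_pq("k must be in [2, %d], got %s", n, format(k),
            class = "argument_error")
  # seed: most distant pair, lexicographically first on ties
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  selected <- best
  mind <- pmin(D[, best[1]], D[, best[2]])  # min distance to selected set
  mind[selected] <- -Inf
  while (length(selected) < k) {
    pick <- unname(which.max(mind))         # which.max takes lowest index on ties
    selected <- c(selected, pick)
    mind <- pmin(mind, D[, pick])
    mind[pick] <- -Inf
  }
  as.integer(selected)
}

#' Split a data set into training and test sets by Kennard-Stone
#'
#' Selects the training set with the Kennard-Stone maximin rule on the
#' autoscaled full descriptor matrix (so large-magnitude descriptors such as
#' surface areas do not dominate bond lengths); the remaining compounds form
#' the test set. Training-set size is `round(fraction * n)` with half-way
#' ties resolved upward.
#'
#' @param ds a [qsar_dataset()].
#' @param fraction training proportion in (0, 1); default 0.8.
#' @return object of class `ks_split`: list with `train_ids`, `test_ids`,
#'   `selection_order` (compound ids in pick order), `distance_metric`.
#' @export
ks_split <- function(ds, fraction = 0.8) {
  if (fraction <= 0 || fraction >= 1)
    stop_pq("fraction must be in (0, 1)", class = "argument_error")
  n <- n_compounds(ds)
  k <- floor(fraction * n + 0.5)   # round half up
  if (k < 2 || k >= n + 1 || n - k < 0 || k > n)
    stop_pq("fraction %g gives training size %d of %d", fraction, k, n,
            class = "split_error")
  if (n - k == 0)
    stop_pq("fraction %g leaves an empty test set", fraction,
            class = "split_error")
  if (n - k == 1)
    warning("test set has a single compound; test statistics will be fragile")
  Z <- autoscale(ds$descriptors)
  sel <- kennard_stone(Z, k)
  ids <- rownames(ds$descriptors)
  structure(list(train_ids = ids[sort(sel)],
                 test_ids = ids[setdiff(seq_len(n), sel)],
                 selection_order = ids[sel],
                 distance_metric = "euclidean on autoscaled descriptors"),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d train / %d test (%s)\n",
              length(x$train_ids), length(x$test_ids), x$distance_metric))
  cat("  test:", paste(x$test_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the training or test portion of a data set
#' @param ds a [qsar_dataset()].
#' @param split a [ks_split()] result.
#' @param set `"train"` or `"test"`.
#' @export
split_subset <- function(ds, split, set = c("train", "test")) {
  set <- match.arg(set)
  subset_compounds(ds, if (set == "train") split$train_ids else split$test_ids)
}
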