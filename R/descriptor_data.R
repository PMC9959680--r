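#' Descriptor metadata registry
#'
#' Builds the default metadata table for the X1--X33 descriptor set used
#' throughout the package: quantum-chemical properties X1--X23 (bond lengths,
#' atomic charges, HOMO energy, polarizability) and cheminformatic properties
#' X24--X33 (AlogP, Connolly surface area, ...). Only seven descriptors have
#' fixed identities; the rest carry placeholder names and can be overridden by
#' a user-supplied metadata table.
#'
#' @param ids character vector of descriptor ids; default `X1`..`X33`.
#' @return data.frame with columns `id`, `name`, `units`, `provenance`
#'   (`"quantum"` for X1--X23, `"cheminformatic"` for X24--X33).
#' @export
descriptor_registry <- function(ids = paste0("X", 1:33)) {
  named <- c(X16 = "bond N1-C13", X17 = "bond C2-R(b)", X19 = "bond C4-C11",
             X20 = "polarizability", X21 = "HOMO energy", X26 = "AlogP",
             X30 = "Connolly surface area")
  units <- c(X16 = "Angstrom", X17 = "Angstrom", X19 = "Angstrom",
             X20 = "a.u.", X21 = "a.u.", X26 = "unitless",
             X30 = "Angstrom^2")
  idx <- suppressWarnings(as.integer(sub("^X", "", ids)))
  data.frame(
    id = ids,
    name = ifelse(ids %in% names(named), named[ids], paste("descriptor", ids)),
    units = ifelse(ids %in% names(units), units[ids], "unknown"),
    provenance = ifelse(!is.na(idx) & idx >= 24, "cheminformatic", "quantum"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Construct a validated descriptor table
#'
#' A descriptor table is an n x m numeric matrix of molecular descriptors
#' (rows = compounds, columns = descriptors) with unique compound ids and
#' per-column metadata. All entries must be finite.
#'
#' @param values numeric matrix (or coercible data.frame) of descriptor values.
#' @param compound_ids character vector of unique compound labels.
#' @param meta optional metadata data.frame as from [descriptor_registry()];
#'   defaults to the registry for the column names of `values`.
#' @return object of class `descriptor_table`: the numeric matrix with
#'   `dimnames` set and a `meta` attribute.
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(compound_ids))
    compound_ids <- paste0("Cpd.", seq_len(nrow(values)))
  compound_ids <- as.character(compound_ids)
  if (nrow(values) < 2)
    stop_pq("descriptor table needs at least 2 compounds, got %d",
            nrow(values), class = "validation_error")
  if (anyDuplicated(compound_ids))
    stop_pq("duplicate compound ids: %s",
            paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
            class = "validation_error")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_pq("non-finite descriptor value at compound '%s', column '%s'",
            compound_ids[bad[1, 1]], colnames(values)[bad[1, 2]],
            class = "validation_error")
  if (is.null(meta)) meta <- descriptor_registry(colnames(values))
  if (nrow(meta) != ncol(values))
    stop_pq("metadata has %d rows but table has %d columns",
            nrow(meta), ncol(values), class = "validation_error")
  rownames(values) <- compound_ids
  structure(values, meta = meta, class = c("descriptor_table", "matrix", "array"))
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d compounds x %d descriptors\n",
              nrow(x), ncol(x)))
  cat("Columns:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Construct a validated activity table
#'
#' Holds the three radical-scavenging activities per compound on the
#' (percent scavenging)/10 scale: `Y1` (hydroxyl radical, .OH), `Y2`
#' (superoxide anion, O2.-), `Y3` (DPPH.). Values must be finite and in
#' \[0, 10\].
#'
#' @param compound_ids unique compound labels.
#' @param y1,y2,y3 numeric activity vectors on the percent/10 scale.
#' @param percent if `TRUE`, inputs are raw percentages and are divided by 10.
#' @return data.frame of class `activity_table` with columns
#'   `compound_id`, `Y1`, `Y2`, `Y3`.
#' @export
activity_table <- function(compound_ids, y1, y2, y3, percent = FALSE) {
  compound_ids <- as.character(compound_ids)
  ys <- list(Y1 = y1, Y2 = y2, Y3 = y3)
  if (percent) ys <- lapply(ys, function(v) v / 10)
  n <- length(compound_ids)
  if (anyDuplicated(compound_ids))
    stop_pq("duplicate compound ids in activity table", class = "validation_error")
  for (nm in names(ys)) {
    v <- ys[[nm]]
    if (length(v) != n)
      stop_pq("%s has length %d, expected %d", nm, length(v), n,
              class = "validation_error")
    if (any(!is.finite(v)))
      stop_pq("non-finite %s value for compound '%s'", nm,
              compound_ids[which(!is.finite(v))[1]], class = "validation_error")
    if (any(v < 0 | v > 10))
      stop_pq("%s outside [0, 10] for compound '%s' (value %g); activities are on the percent/10 scale",
              nm, compound_ids[which(v < 0 | v > 10)[1]],
              v[which(v < 0 | v > 10)[1]], class = "validation_error")
  }
  structure(data.frame(compound_id = compound_ids, Y1 = ys$Y1, Y2 = ys$Y2,
                       Y3 = ys$Y3, stringsAsFactors = FALSE),
            class = c("activity_table", "data.frame"))
}

#' Read a descriptor table from delimited text
#'
#' Expects a header row of descriptor ids and a first column of compound ids.
#' Comma-separated with `.` decimal by default; pass `sep = "\t"` for TSV.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @param meta optional metadata data.frame (id, name, units, provenance).
#' @return a [descriptor_table()].
#' @export
read_descriptor_table <- function(path, sep = ",", meta = NULL) {
  if (!file.exists(path))
    stop_pq("file not found: %s", path, class = "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2)
    stop_pq("no descriptor columns found in %s (missing header?)", path,
            class = "format_error")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_pq("non-numeric cell at row '%s', column '%s' (value '%s')",
            ids[bad[1, 1]], colnames(num)[bad[1, 2]],
            vals[bad[1, 1], bad[1, 2]], class = "validation_error")
  descriptor_table(num, compound_ids = ids, meta = meta)
}

#' Write a descriptor table as canonical CSV
#'
#' @param d a [descriptor_table()].
#' @param path output path.
#' @param sep field delimiter.
#' @param digits significant digits for the text representation.
#' @export
write_descriptor_table <- function(d, path, sep = ",", digits = 12) {
  df <- data.frame(compound_id = rownames(d),
                   signif(unclass(d), digits), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity table from delimited text
#'
#' Expects columns `compound_id`, `Y1`, `Y2`, `Y3` (any order, by name).
#'
#' @inheritParams read_descriptor_table
#' @param percent if `TRUE`, the file stores raw percentages; values are
#'   divided by 10 on read.
#' @return an [activity_table()].
#' @export
read_activity_table <- function(path, sep = ",", percent = FALSE) {
  if (!file.exists(path))
    stop_pq("file not found: %s", path, class = "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("compound_id", "Y1", "Y2", "Y3")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop_pq("activity file missing column(s): %s", paste(miss, collapse = ", "),
            class = "format_error")
  activity_table(df$compound_id, df$Y1, df$Y2, df$Y3, percent = percent)
}

#' Write an activity table as canonical CSV
#' @param a an [activity_table()].
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_activity_table <- function(a, path, sep = ",") {
  utils::write.table(as.data.frame(a), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Join descriptor and activity tables into an aligned data set
#'
#' Verifies the two tables describe the same compounds and reorders both to
#' the descriptor table's compound order.
#'
#' @param descriptors a [descriptor_table()].
#' @param activities an [activity_table()].
#' @return object of class `qsar_dataset` with elements `descriptors` and
#'   `activities`, row-aligned.
#' @export
qsar_dataset <- function(descriptors, activities) {
  d_ids <- rownames(descriptors)
  a_ids <- activities$compound_id
  only_d <- setdiff(d_ids, a_ids)
  only_a <- setdiff(a_ids, d_ids)
  if (length(only_d) > 0 || length(only_a) > 0)
    stop_pq("compound ids do not align; only in descriptors: [%s]; only in activities: [%s]",
            paste(only_d, collapse = ", "), paste(only_a, collapse = ", "),
            class = "alignment_error")
  activities <- activities[match(d_ids, a_ids), , drop = FALSE]
  rownames(activities) <- NULL
  structure(list(descriptors = descriptors, activities = activities),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("QSAR data set: %d compounds, %d descriptors, activities Y1-Y3 (percent/10)\n",
              nrow(x$descriptors), ncol(x$descriptors)))
  invisible(x)
}

#' Number of compounds in a data set
#' @param ds a `qsar_dataset`.
#' @export
n_compounds <- function(ds) nrow(ds$descriptors)

#' Subset a data set by compound
#' @param ds a `qsar_dataset`.
#' @param which compound ids or integer indices to keep.
#' @return a `qsar_dataset` restricted to the selected compounds.
#' @export
subset_compounds <- function(ds, which) {
  if (is.character(which)) which <- match(which, rownames(ds$descriptors))
  d <- descriptor_table(unclass(ds$descriptors)[which, , drop = FALSE],
                        rownames(ds$descriptors)[which],
                        meta = attr(ds$descriptors, "meta"))
  a <- ds$activities[which, , drop = FALSE]
  rownames(a) <- NULL
  qsar_dataset(d, structure(a, class = c("activity_table", "data.frame")))
}

#' Autoscale a descriptor matrix to zero mean and unit variance
#'
#' Centers and scales each descriptor column; constant (zero-variance)
#' columns are dropped with a warning. The returned matrix carries a
#' `scaling` attribute (per-column mean and sd) so [autoscale_invert()] can
#' reconstruct the input exactly.
#'
#' @param d a [descriptor_table()] or numeric matrix.
#' @return scaled matrix with attribute `scaling` (list: `center`, `scale`,
#'   `dropped`).
#' @export
autoscale <- function(d) {
  x <- unclass(as.matrix(d))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (all(const))
    stop_pq("all descriptor columns are constant; nothing to scale",
            class = "degenerate_input_error")
  if (any(const))
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(x)[const], collapse = ", ")))
  keep <- !const
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  attr(z, "scaling") <- list(center = mu[keep], scale = sdv[keep],
                             dropped = colnames(x)[const])
  z
}

#' Invert an autoscaling transform
#' @param z matrix produced by [autoscale()] (must carry its `scaling`
#'   attribute, or pass one via `scaling`).
#' @param scaling optional scaling record.
#' @return matrix on the original descriptor scale.
#' @export
autoscale_invert <- function(z, scaling = attr(z, "scaling")) {
  if (is.null(scaling)) stop_pq("no scaling record found", class = "argument_error")
  out <- sweep(sweep(unclass(z), 2, scaling$scale, "*"), 2, scaling$center, "+")
  attr(out, "scaling") <- NULL
  out
}
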