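#' Construct an abundance table
#'
#' The central data container of the pipeline: a samples x features matrix
#' of non-negative intensities with an explicit missingness mask and a
#' per-feature kind tag (`"protein"` or `"peptide"`). Missing cells are
#' stored as `NA` in the intensity matrix; the mask is `TRUE` exactly
#' where the intensity is undefined.
#'
#' @param intensities numeric matrix, samples in rows and features in
#'   columns; row and column names are used as sample and feature ids.
#'   `NA` cells are treated as missing.
#' @param kind character vector of length `ncol(intensities)` (or a single
#'   value, recycled) with entries `"protein"` or `"peptide"`.
#'
#' @return an object of class `abundance_table` with elements
#'   `intensities`, `missing_mask`, `kind`, `sample_ids`, `feature_ids`.
#' @export
abundance_table <- function(intensities, kind = "protein") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("S%03d", seq_len(nrow(intensities)))
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  }
  if (anyDuplicated(colnames(intensities))) {
    stop("feature ids must be unique")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  kind <- rep_len(as.character(kind), ncol(intensities))
  if (!all(kind %in% c("protein", "peptide"))) {
    stop("`kind` entries must be \"protein\" or \"peptide\"")
  }
  names(kind) <- colnames(intensities)
  structure(
    list(
      intensities  = intensities,
      missing_mask = is.na(intensities),
      kind         = kind,
      sample_ids   = rownames(intensities),
      feature_ids  = colnames(intensities)
    ),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  n_mis <- sum(x$missing_mask)
  cat(sprintf(
    "<abundance_table> %d samples x %d features (%d protein, %d peptide), %.1f%% missing\n",
    length(x$sample_ids), length(x$feature_ids),
    sum(x$kind == "protein"), sum(x$kind == "peptide"),
    100 * n_mis / length(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$intensities)

#' Combine two abundance tables over shared samples
#'
#' Joins the feature sets of two tables (typically a protein table and a
#' peptide table) on the intersection of their samples, preserving the
#' sample order of the first table.
#'
#' @param x,y `abundance_table` objects.
#' @return a combined `abundance_table`.
#' @export
combine_tables <- function(x, y) {
  stopifnot(inherits(x, "abundance_table"), inherits(y, "abundance_table"))
  shared <- intersect(x$sample_ids, y$sample_ids)
  if (length(shared) == 0L) stop("tables share no samples")
  if (length(intersect(x$feature_ids, y$feature_ids)) > 0L) {
    stop("feature ids overlap between tables: ",
         paste(head(intersect(x$feature_ids, y$feature_ids), 3), collapse = ", "))
  }
  m <- cbind(x$intensities[shared, , drop = FALSE],
             y$intensities[shared, , drop = FALSE])
  abundance_table(m, kind = c(x$kind, y$kind))
}

#' Log2-transform an abundance table into a numeric matrix
#'
#' All model fitting downstream (imputation, Gaussian graphical modeling)
#' operates on log2 intensities; raw label-free intensities are strongly
#' right-skewed and multiplicative.
#'
#' @param table an `abundance_table`.
#' @return a numeric samples x features matrix of log2 intensities (`NA`
#'   where missing).
#' @export
log2_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$intensities
  if (any(m == 0, na.rm = TRUE)) {
    stop("zero intensities present; encode missing values as NA before log2")
  }
  log2(m)
}

# replace the intensity matrix, revalidating invariants
set_intensities <- function(table, m) {
  out <- abundance_table(m, kind = table$kind)
  out
}
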