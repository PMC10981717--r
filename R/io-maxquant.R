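#' Read a MaxQuant-dialect abundance table
#'
#' Parses `proteinGroups`-like or `peptides`-like tab-separated files.
#' Intensity columns are located by prefix (`"LFQ intensity "` for the
#' proteinGroups dialect, `"Intensity "` for peptides); zeros in those
#' columns follow the MaxQuant convention for "not quantified" and are
#' recorded as missing. Contaminant and reverse flags use the `"+"`
#' convention.
#'
#' @param path path to a tab-separated file with header.
#' @param dialect `"proteinGroups"` or `"peptides"`.
#' @param intensity_prefix override the dialect's intensity column prefix.
#' @return a list with `table` (an [abundance_table()]) and `meta` (a data
#'   frame of per-feature annotation: accession/gene/flags for proteins;
#'   sequence, precursor and coordinates for peptides).
#' @export
read_maxquant_table <- function(path,
                                dialect = c("proteinGroups", "peptides"),
                                intensity_prefix = NULL) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no rows in ", path)

  prefix <- intensity_prefix %||%
    switch(dialect, proteinGroups = "LFQ intensity ", peptides = "Intensity ")
  int_cols <- grep(paste0("^", prefix), names(df), value = TRUE)
  # the peptides dialect's bare "Intensity" summary column is not a sample
  int_cols <- setdiff(int_cols, trimws(prefix))
  if (length(int_cols) == 0L) {
    stop("zero samples detected: no columns with prefix \"", prefix, "\"")
  }
  sample_ids <- substring(int_cols, nchar(prefix) + 1L)

  need <- switch(dialect,
    proteinGroups = c("Majority protein IDs", "Gene names"),
    peptides = c("Sequence", "Proteins", "Start position", "End position"))
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }

  flag <- function(col) {
    if (!col %in% names(df)) return(rep(FALSE, nrow(df)))
    v <- df[[col]]
    !is.na(v) & v == "+"
  }
  meta <- switch(dialect,
    proteinGroups = data.frame(
      accession = df[["Majority protein IDs"]],
      gene_name = df[["Gene names"]],
      is_contaminant = flag("Potential contaminant"),
      is_reverse = flag("Reverse"),
      stringsAsFactors = FALSE),
    peptides = data.frame(
      sequence = df[["Sequence"]],
      precursor = df[["Proteins"]],
      start = as.integer(df[["Start position"]]),
      end = as.integer(df[["End position"]]),
      is_contaminant = flag("Potential contaminant"),
      is_reverse = flag("Reverse"),
      stringsAsFactors = FALSE))

  feature_ids <- switch(dialect,
    proteinGroups = meta$accession,
    peptides = sprintf("%s_%d_%d", meta$precursor, meta$start, meta$end))
  if (anyDuplicated(feature_ids)) {
    feature_ids <- make.unique(feature_ids, sep = "#")
  }
  meta$feature_id <- feature_ids

  m <- as.matrix(df[int_cols])  # features x samples
  storage.mode(m) <- "numeric"
  m[m == 0] <- NA  # MaxQuant writes 0 for "not quantified"
  m <- t(m)
  dimnames(m) <- list(sample_ids, feature_ids)

  kind <- if (dialect == "proteinGroups") "protein" else "peptide"
  list(table = abundance_table(m, kind = kind), meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_intensity <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "0"
  out
}

#' Write an abundance table in the MaxQuant proteinGroups dialect
#'
#' Missing cells are written as 0, matching the convention
#' [read_maxquant_table()] parses; write/read round-trips are exact.
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @param meta optional data frame with columns `accession`, `gene_name`,
#'   `is_contaminant`, `is_reverse` (defaults derived from feature ids).
#' @export
write_maxquant_proteins <- function(table, path, meta = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  n_feat <- length(table$feature_ids)
  if (is.null(meta)) {
    meta <- data.frame(accession = table$feature_ids,
                       gene_name = table$feature_ids,
                       is_contaminant = rep(FALSE, n_feat),
                       is_reverse = rep(FALSE, n_feat),
                       stringsAsFactors = FALSE)
  }
  out <- data.frame(meta$accession, meta$gene_name,
                    ifelse(meta$is_reverse, "+", ""),
                    ifelse(meta$is_contaminant, "+", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("Majority protein IDs", "Gene names", "Reverse",
                  "Potential contaminant")
  for (s in seq_along(table$sample_ids)) {
    out[[paste0("LFQ intensity ", table$sample_ids[s])]] <-
      fmt_intensity(table$intensities[s, ])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a peptide abundance table in the MaxQuant peptides dialect
#'
#' @param table a peptide [abundance_table()].
#' @param path output path.
#' @param meta data frame with columns `sequence`, `precursor`, `start`,
#'   `end` in the row order of `table` features (as produced by
#'   [simulate_digest()]).
#' @export
write_maxquant_peptides <- function(table, path, meta) {
  stopifnot(inherits(table, "abundance_table"),
            nrow(meta) == length(table$feature_ids))
  out <- data.frame(meta$sequence, meta$precursor, meta$start, meta$end,
                    rep("", nrow(meta)), rep("", nrow(meta)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("Sequence", "Proteins", "Start position", "End position",
                  "Reverse", "Potential contaminant")
  for (s in seq_along(table$sample_ids)) {
    out[[paste0("Intensity ", table$sample_ids[s])]] <-
      fmt_intensity(table$intensities[s, ])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read precursor protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_precursor_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1)
  out
}

#' Write precursor protein sequences to FASTA
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param path output path.
#' @export
write_precursor_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
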