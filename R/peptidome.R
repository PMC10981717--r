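#' Locate a peptide on precursor sequences
#'
#' Exact substring search of a peptide over a set of precursor
#' sequences; used when start/end columns are absent from the input.
#' Coordinates are 1-based inclusive on the full precursor (signal
#' peptide included in the numbering).
#'
#' @param sequence peptide amino-acid string.
#' @param precursors named character vector of precursor sequences (or an
#'   object accepted by `as.character`, e.g. from
#'   [read_precursor_fasta()]).
#' @return a data frame with one row per placement: `precursor`, `start`,
#'   `end`, `sequence`, `ambiguous` (more than one placement overall).
#' @export
map_peptide <- function(sequence, precursors) {
  stopifnot(nchar(sequence) >= 1)
  precursors <- vapply(precursors, as.character, character(1))
  rows <- list()
  for (a in names(precursors)) {
    hits <- gregexpr(sequence, precursors[[a]], fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (s in as.integer(hits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        precursor = a, start = s, end = s + nchar(sequence) - 1L,
        sequence = sequence, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("peptide not found in any precursor: ", sequence)
  out <- do.call(rbind, rows)
  out$ambiguous <- nrow(out) > 1L
  out
}

#' Detect peptide ladders within clusters
#'
#' Peptide ladders are sets of peptides from one precursor with
#' overlapping coordinate ranges, differing by a few terminal residues --
#' the signature of exoproteolytic trimming. Within each
#' (cluster, precursor) group, peptides are nodes of an interval-overlap
#' graph (two peptides overlap iff their ranges share at least one
#' residue); every connected component with at least `min_peptides`
#' members is reported as a ladder. Multiple ladders per group are
#' allowed.
#'
#' @param peptides data frame with columns `cluster`, `precursor`,
#'   `start`, `end` (1-based inclusive).
#' @param min_peptides minimum component size reported.
#' @return a data frame with one row per ladder: `cluster`, `precursor`,
#'   `range_start`, `range_end` (union span), `n_peptides`,
#'   `mean_length` (residues, one decimal).
#' @export
detect_ladders <- function(peptides, min_peptides = 5) {
  stopifnot(all(c("cluster", "precursor", "start", "end") %in%
                  names(peptides)))
  if (any(peptides$end < peptides$start)) stop("end < start in peptide table")
  groups <- split(peptides,
                  interaction(peptides$cluster, peptides$precursor,
                              drop = TRUE))
  rows <- list()
  for (g in groups) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    # connected components of an interval-overlap graph via a sweep:
    # a new component starts when the next interval begins past the
    # running maximum end of the current one
    comp <- integer(nrow(g))
    cur <- 1L; max_end <- g$end[1]; comp[1] <- 1L
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] > max_end) {
        cur <- cur + 1L
        max_end <- g$end[i]
      } else {
        max_end <- max(max_end, g$end[i])
      }
      comp[i] <- cur
    }
    for (cc in split(g, comp)) {
      if (nrow(cc) < min_peptides) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cc$cluster[1], precursor = cc$precursor[1],
        range_start = min(cc$start), range_end = max(cc$end),
        n_peptides = nrow(cc),
        mean_length = round(mean(cc$end - cc$start + 1), 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), precursor = character(),
               range_start = integer(), range_end = integer(),
               n_peptides = integer(), mean_length = numeric(),
               stringsAsFactors = FALSE)
  out[order(out$cluster, out$precursor, out$range_start), , drop = FALSE]
}

#' Single-residue trimming steps between peptides
#'
#' Returns ordered pairs of peptides from one precursor that differ by
#' exactly one residue at exactly one terminus: an N-step (start + 1,
#' same end; aminopeptidase signature) or a C-step (same start, end - 1;
#' carboxypeptidase signature). The pair is oriented longer -> shorter.
#'
#' @param peptides data frame with columns `precursor`, `start`, `end`;
#'   an optional `feature_id` column labels the pair members.
#' @return a data frame with `precursor`, `from`, `to` (labels or
#'   "start-end" strings), `type` (`"N"` or `"C"`).
#' @export
trimming_steps <- function(peptides) {
  stopifnot(all(c("precursor", "start", "end") %in% names(peptides)))
  lab <- peptides$feature_id %||%
    sprintf("%s_%d_%d", peptides$precursor, peptides$start, peptides$end)
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    for (j in seq_len(nrow(peptides))) {
      if (i == j || peptides$precursor[i] != peptides$precursor[j]) next
      n_step <- peptides$start[j] == peptides$start[i] + 1L &&
        peptides$end[j] == peptides$end[i]
      c_step <- peptides$start[j] == peptides$start[i] &&
        peptides$end[j] == peptides$end[i] - 1L
      if (n_step || c_step) {
        rows[[length(rows) + 1L]] <- data.frame(
          precursor = peptides$precursor[i], from = lab[i], to = lab[j],
          type = if (n_step) "N" else "C", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(precursor = character(), from = character(),
               to = character(), type = character(), stringsAsFactors = FALSE)
}

#' Define a protease specificity rule
#'
#' A rule matches a cleavage site when the residue N-terminal of the
#' hydrolyzed bond (P1) is in `allowed_p1` and the residue C-terminal of
#' it (P1') is in `allowed_p1prime`.
#'
#' @param name rule name.
#' @param allowed_p1 P1 residue set (non-empty).
#' @param allowed_p1prime P1' residue set; `NULL` means any residue.
#' @return an object of class `protease_rule`.
#' @export
protease_rule <- function(name, allowed_p1, allowed_p1prime = NULL) {
  stopifnot(nzchar(name), length(allowed_p1) >= 1,
            all(allowed_p1 %in% AA_ALPHABET),
            is.null(allowed_p1prime) || all(allowed_p1prime %in% AA_ALPHABET))
  structure(list(name = name, allowed_p1 = allowed_p1,
                 allowed_p1prime = allowed_p1prime),
            class = "protease_rule")
}

#' Plasmin specificity rule
#'
#' Plasmin hydrolyzes the bond between lysine (K) or arginine (R) at P1
#' and any residue at P1'.
#'
#' @return a [protease_rule()].
#' @export
plasmin_rule <- function() protease_rule("plasmin", c("K", "R"))

#' Protease cleavage-site specificity of a peptide set
#'
#' Every mapped peptide implies up to two endoproteolytic cleavage
#' sites: the bond preceding its first residue (if the peptide does not
#' start at the precursor N-terminus) and the bond following its last
#' residue (if it does not reach the C-terminus). Protein termini are
#' never cleavage sites. Sites are deduplicated by
#' (precursor, bond position) so that the fraction is invariant to
#' duplicate peptide rows, and each unique site is tested against each
#' rule.
#'
#' @param peptides data frame with columns `precursor`, `start`, `end`.
#' @param precursor_sequences named character vector of full precursor
#'   sequences.
#' @param rules a [protease_rule()] or list of rules (default plasmin).
#' @return a list with `sites` (data frame: `precursor`, `bond_position`
#'   -- the bond follows this residue index --, `p1_residue`,
#'   `p1prime_residue`, one logical column per rule) and `fractions`
#'   (named percentages of unique sites matching each rule; `NaN` with
#'   zero sites).
#' @export
cleavage_specificity <- function(peptides, precursor_sequences,
                                 rules = plasmin_rule()) {
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  stopifnot(all(c("precursor", "start", "end") %in% names(peptides)))
  missing_acc <- setdiff(unique(peptides$precursor),
                         names(precursor_sequences))
  if (length(missing_acc)) {
    stop("no sequence for precursor(s): ",
         paste(missing_acc, collapse = ", "))
  }
  lens <- nchar(precursor_sequences)[peptides$precursor]
  if (any(peptides$start < 1 | peptides$end > lens |
            peptides$end < peptides$start)) {
    stop("peptide coordinates outside the precursor sequence")
  }
  site_rows <- list()
  for (i in seq_len(nrow(peptides))) {
    a <- peptides$precursor[i]
    L <- nchar(precursor_sequences[[a]])
    s <- peptides$start[i]; e <- peptides$end[i]
    if (s > 1L) site_rows[[length(site_rows) + 1L]] <-
      data.frame(precursor = a, bond_position = s - 1L,
                 stringsAsFactors = FALSE)
    if (e < L) site_rows[[length(site_rows) + 1L]] <-
      data.frame(precursor = a, bond_position = e,
                 stringsAsFactors = FALSE)
  }
  if (length(site_rows) == 0L) {
    sites <- data.frame(precursor = character(), bond_position = integer(),
                        p1_residue = character(),
                        p1prime_residue = character(),
                        stringsAsFactors = FALSE)
    for (r in rules) sites[[r$name]] <- logical(0)
    return(list(sites = sites,
                fractions = setNames(rep(NaN, length(rules)),
                                     vapply(rules, `[[`, "", "name"))))
  }
  sites <- unique(do.call(rbind, site_rows))
  sites <- sites[order(sites$precursor, sites$bond_position), , drop = FALSE]
  rownames(sites) <- NULL
  sites$p1_residue <- substr(precursor_sequences[sites$precursor],
                             sites$bond_position, sites$bond_position)
  sites$p1prime_residue <- substr(precursor_sequences[sites$precursor],
                                  sites$bond_position + 1L,
                                  sites$bond_position + 1L)
  fractions <- numeric(0)
  for (r in rules) {
    match_r <- sites$p1_residue %in% r$allowed_p1 &
      (is.null(r$allowed_p1prime) |
         sites$p1prime_residue %in% (r$allowed_p1prime %||% AA_ALPHABET))
    sites[[r$name]] <- match_r
    fractions[r$name] <- 100 * mean(match_r)
  }
  list(sites = sites, fractions = fractions)
}

#' Relative precursor contribution to the peptidome
#'
#' Reports, per precursor protein, the percentage of the peptidome it
#' accounts for, both by peptide count and by summed mean intensity.
#'
#' @param meta peptide metadata data frame with a `precursor` column (and
#'   `feature_id` matching `table` when abundances are supplied).
#' @param table optional peptide [abundance_table()] for the
#'   abundance-based percentage.
#' @return a data frame sorted by decreasing count percentage:
#'   `precursor`, `n_peptides`, `count_pct`, `abundance_pct` (`NA`
#'   without a table). Percentage columns each sum to 100.
#' @export
precursor_contribution <- function(meta, table = NULL) {
  stopifnot("precursor" %in% names(meta))
  counts <- table(meta$precursor)
  out <- data.frame(precursor = names(counts),
                    n_peptides = as.integer(counts),
                    count_pct = 100 * as.integer(counts) / nrow(meta),
                    stringsAsFactors = FALSE)
  out$abundance_pct <- NA_real_
  if (!is.null(table)) {
    mean_int <- colMeans(table$intensities, na.rm = TRUE)
    per_prec <- tapply(mean_int[meta$feature_id], meta$precursor, sum)
    out$abundance_pct <-
      100 * as.numeric(per_prec[out$precursor]) / sum(per_prec)
  }
  out <- out[order(-out$count_pct, out$precursor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
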