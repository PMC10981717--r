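AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specify an in-silico digestion of precursor proteins
#'
#' Models the two proteolytic regimes seen in milk: endoproteolysis by
#' trypsin-like proteases (plasmin cleaves after lysine or arginine, the
#' P1 residue) and exoproteolysis by aminopeptidases, which trim single
#' residues off peptide termini and produce peptide ladders. Peptide
#' abundance is coupled to precursor abundance: the formation of a
#' peptide depends on how much of its precursor is present.
#'
#' @param precursor_sequences named character vector of amino-acid
#'   sequences (standard 20-letter alphabet), names are accessions.
#' @param endo_rule residues allowed at P1 of an endoproteolytic cut
#'   (default lysine/arginine, the plasmin specificity).
#' @param cleavage_prob probability that an eligible bond is cut.
#' @param exo_steps maximum number of single-residue trims per terminus.
#' @param length_range retained peptide lengths, inclusive (the
#'   identification window of endogenous milk peptidomics).
#' @param yield global fraction of precursor intensity converted per
#'   peptide.
#' @param exo_decay multiplicative abundance drop per trimming step.
#' @param coupling_sd standard deviation (log2 scale) of the per-cell
#'   log-normal noise on the peptide/precursor coupling.
#' @param seed integer seed.
#' @return an object of class `digest_spec`.
#' @export
digest_spec <- function(precursor_sequences, endo_rule = c("K", "R"),
                        cleavage_prob = 0.5, exo_steps = 2,
                        length_range = c(8, 25), yield = 0.05,
                        exo_decay = 0.5, coupling_sd = 0.3, seed = 1L) {
  if (length(precursor_sequences) == 0L || is.null(names(precursor_sequences)) ||
      any(!nzchar(names(precursor_sequences)))) {
    stop("`precursor_sequences` must be a non-empty named character vector")
  }
  if (any(!nzchar(precursor_sequences))) stop("empty precursor sequence")
  bad <- vapply(strsplit(precursor_sequences, ""),
                function(s) any(!s %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    stop("invalid residue in precursor(s): ",
         paste(names(precursor_sequences)[bad], collapse = ", "))
  }
  stopifnot(all(endo_rule %in% AA_ALPHABET),
            cleavage_prob >= 0, cleavage_prob <= 1,
            exo_steps >= 0, length(length_range) == 2,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            yield > 0, exo_decay > 0, exo_decay <= 1, coupling_sd >= 0)
  structure(
    list(precursor_sequences = precursor_sequences, endo_rule = endo_rule,
         cleavage_prob = cleavage_prob, exo_steps = as.integer(exo_steps),
         length_range = as.integer(length_range), yield = yield,
         exo_decay = exo_decay, coupling_sd = coupling_sd,
         seed = as.integer(seed)),
    class = "digest_spec"
  )
}

#' Digest precursor proteins into a synthetic peptide table
#'
#' Bonds following an `endo_rule` residue are cut independently with
#' probability `cleavage_prob`; the resulting fragments bounded by at
#' least one cut and falling inside `length_range` become base peptides.
#' Each base peptide additionally yields up to `exo_steps` N-terminally
#' and C-terminally trimmed ladder variants with geometrically decreasing
#' abundance. Every peptide's per-sample intensity is
#' `precursor intensity * yield * decay^steps * 2^eps`,
#' `eps ~ N(0, coupling_sd)`.
#'
#' @param spec a [digest_spec()].
#' @param precursor_abundances numeric samples x precursors matrix of raw
#'   intensities; column names must match the accessions in `spec`.
#' @return a list with `table` (peptide [abundance_table()]), `meta`
#'   (data frame: `feature_id`, `precursor`, `sequence`, `start`, `end`,
#'   1-based inclusive coordinates on the full precursor), and `truth`
#'   (list with `true_cleavage_sites`: data frame `accession`,
#'   `bond_position`, `p1_residue` of every endoproteolytic site bounding
#'   an emitted base peptide).
#' @export
simulate_digest <- function(spec, precursor_abundances) {
  stopifnot(inherits(spec, "digest_spec"), is.matrix(precursor_abundances))
  acc <- names(spec$precursor_sequences)
  missing_acc <- setdiff(acc, colnames(precursor_abundances))
  if (length(missing_acc)) {
    stop("no abundance column for precursor(s): ",
         paste(missing_acc, collapse = ", "))
  }

  with_seed(spec$seed, {
    meta_rows <- list()
    site_rows <- list()
    factors <- numeric()

    for (a in acc) {
      seq_a <- spec$precursor_sequences[[a]]
      res <- strsplit(seq_a, "")[[1]]
      L <- length(res)
      eligible <- which(res[-L] %in% spec$endo_rule)  # bond after residue i
      cuts <- eligible[rbinom(length(eligible), 1, spec$cleavage_prob) == 1]
      if (length(cuts) == 0L) next
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, L)

      for (f in seq_along(starts)) {
        s <- starts[f]; e <- ends[f]
        len <- e - s + 1L
        if (len < spec$length_range[1] || len > spec$length_range[2]) next
        # record the endoproteolytic sites this emitted fragment uses
        if (s > 1L) site_rows[[length(site_rows) + 1L]] <-
          data.frame(accession = a, bond_position = s - 1L,
                     p1_residue = res[s - 1L], stringsAsFactors = FALSE)
        if (e < L) site_rows[[length(site_rows) + 1L]] <-
          data.frame(accession = a, bond_position = e,
                     p1_residue = res[e], stringsAsFactors = FALSE)
        # base peptide plus exoproteolytic ladder variants
        variants <- data.frame(start = s, end = e, steps = 0L)
        if (spec$exo_steps > 0) {
          for (k in seq_len(spec$exo_steps)) {
            variants <- rbind(variants,
                              data.frame(start = s + k, end = e, steps = k),
                              data.frame(start = s, end = e - k, steps = k))
          }
        }
        vlen <- variants$end - variants$start + 1L
        keep <- vlen >= spec$length_range[1] & vlen <= spec$length_range[2]
        variants <- variants[keep, , drop = FALSE]
        for (v in seq_len(nrow(variants))) {
          vs <- variants$start[v]; ve <- variants$end[v]
          meta_rows[[length(meta_rows) + 1L]] <- data.frame(
            feature_id = sprintf("%s_%d_%d", a, vs, ve),
            precursor = a,
            sequence = substr(seq_a, vs, ve),
            start = vs, end = ve, stringsAsFactors = FALSE
          )
          factors <- c(factors, spec$yield * spec$exo_decay^variants$steps[v])
        }
      }
    }

    if (length(meta_rows) == 0L) {
      return(list(
        table = abundance_table(
          matrix(numeric(0), nrow(precursor_abundances), 0,
                 dimnames = list(rownames(precursor_abundances), NULL)),
          kind = "peptide"),
        meta = data.frame(feature_id = character(), precursor = character(),
                          sequence = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE),
        truth = list(true_cleavage_sites = data.frame(
          accession = character(), bond_position = integer(),
          p1_residue = character(), stringsAsFactors = FALSE))
      ))
    }

    meta <- do.call(rbind, meta_rows)
    # collapse duplicate coordinates (two cut patterns can coincide)
    dup <- duplicated(meta$feature_id)
    meta <- meta[!dup, , drop = FALSE]
    factors <- factors[!dup]
    rownames(meta) <- NULL

    sites <- unique(do.call(rbind, site_rows))
    rownames(sites) <- NULL

    n <- nrow(precursor_abundances)
    m <- matrix(NA_real_, n, nrow(meta),
                dimnames = list(rownames(precursor_abundances),
                                meta$feature_id))
    for (j in seq_len(nrow(meta))) {
      eps <- rnorm(n, 0, spec$coupling_sd)
      m[, j] <- precursor_abundances[, meta$precursor[j]] *
        factors[j] * 2^eps
    }

    list(table = abundance_table(m, kind = "peptide"), meta = meta,
         truth = list(true_cleavage_sites = sites))
  })
}
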