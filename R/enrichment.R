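#' Read a flat gene-to-GO annotation table
#'
#' Annotations are consumed as a flat, pre-propagated gene-to-term table;
#' no GO-DAG handling is performed.
#'
#' @param gene2term_path two-column TSV (`gene`, `term`), with header.
#' @param term2domain_path two-column TSV (`term`, `domain`), with
#'   header; domains are `BP`, `MF`, or `CC`.
#' @return a data frame with columns `gene`, `term`, `domain`.
#' @export
read_annotations <- function(gene2term_path, term2domain_path) {
  g2t <- read.delim(gene2term_path, stringsAsFactors = FALSE)
  t2d <- read.delim(term2domain_path, stringsAsFactors = FALSE)
  names(g2t)[1:2] <- c("gene", "term")
  names(t2d)[1:2] <- c("term", "domain")
  out <- merge(g2t, t2d, by = "term", all.x = TRUE)
  out$domain[is.na(out$domain)] <- "BP"
  out[, c("gene", "term", "domain")]
}

#' Read a GAF 2.x annotation subset
#'
#' Uses only the object symbol (column 3), GO id (column 5), and aspect
#' (column 9: F/P/C, mapped to MF/BP/CC).
#'
#' @param path GAF file path (lines starting with `!` are skipped).
#' @return a data frame with columns `gene`, `term`, `domain`.
#' @export
read_gaf <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "!",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 9) stop("not a GAF file: fewer than 9 columns")
  data.frame(
    gene = df[[3]], term = df[[5]],
    domain = c(F = "MF", P = "BP", C = "CC")[df[[9]]],
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric overrepresentation of GO terms in a cluster
#'
#' Two-list overrepresentation: for each term annotated to at least one
#' cluster gene, the upper hypergeometric tail
#' \deqn{p = \sum_{k \ge b} \binom{B}{k} \binom{N-B}{n-k} / \binom{N}{n}}
#' with N the background size, B the annotated genes in the background,
#' n the cluster size, and b the annotated genes in the cluster. The
#' background is the set of all identified proteins; only protein members
#' of a cluster should be tested.
#'
#' @param cluster_genes character vector of cluster gene names.
#' @param background_genes character vector; must contain all
#'   `cluster_genes`.
#' @param annotations data frame with columns `gene`, `term`, `domain`
#'   (see [read_annotations()]).
#' @param cluster_id identifier recorded in the output.
#' @return a data frame with one row per tested term: `cluster`, `term`,
#'   `domain`, `b`, `n`, `B`, `N`, `p_value`.
#' @export
hypergeom_overrepresentation <- function(cluster_genes, background_genes,
                                         annotations, cluster_id = 1L) {
  cluster_genes <- unique(cluster_genes)
  background_genes <- unique(background_genes)
  outside <- setdiff(cluster_genes, background_genes)
  if (length(outside)) {
    stop("cluster gene(s) absent from background: ",
         paste(head(outside, 3), collapse = ", "))
  }
  ann <- annotations[annotations$gene %in% background_genes, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term", "domain")])
  n <- length(cluster_genes)
  N <- length(background_genes)
  terms <- unique(ann[ann$gene %in% cluster_genes, c("term", "domain")])
  if (nrow(terms) == 0L) {
    return(data.frame(cluster = integer(), term = character(),
                      domain = character(), b = integer(), n = integer(),
                      B = integer(), N = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- ann$gene[ann$term == terms$term[i] & ann$domain == terms$domain[i]]
    B <- length(tg)
    b <- length(intersect(tg, cluster_genes))
    data.frame(cluster = cluster_id, term = terms$term[i],
               domain = terms$domain[i], b = b, n = n, B = B, N = N,
               p_value = phyper(b - 1, B, N - B, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment of enrichment records
#'
#' Standard step-up adjustment with monotonicity enforcement. The
#' adjustment pool is, by default, all terms tested within one
#' (cluster, GO-domain) pair, mirroring per-domain reporting; `"global"`
#' pools every record.
#'
#' @param records output of [hypergeom_overrepresentation()] (possibly
#'   row-bound over clusters), or a bare numeric vector of p-values.
#' @param pool `"per_cluster_domain"` or `"global"`.
#' @return `records` with an `adjusted_p` column (or the adjusted vector
#'   for numeric input).
#' @export
bh_adjust <- function(records, pool = c("per_cluster_domain", "global")) {
  if (is.numeric(records)) return(p.adjust(records, method = "BH"))
  pool <- match.arg(pool)
  key <- if (pool == "global") rep(1L, nrow(records)) else
    interaction(records$cluster, records$domain, drop = TRUE)
  records$adjusted_p <- ave(records$p_value, key,
                            FUN = function(p) p.adjust(p, method = "BH"))
  records
}

#' Filter enrichment records at an adjusted-p threshold
#'
#' @param records a [bh_adjust()]ed record set.
#' @param alpha significance level; strict inequality
#'   (`adjusted_p < alpha`).
#' @return the significant records.
#' @export
significant_enrichments <- function(records, alpha = 0.05) {
  records[records$adjusted_p < alpha, , drop = FALSE]
}

#' @importFrom stats ave
NULL
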