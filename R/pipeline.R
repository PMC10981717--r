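#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#' Inputs may be given either as file paths (MaxQuant-dialect TSV /
#' FASTA) or as in-memory objects produced by the generator functions.
#'
#' @param proteins protein input: a path to a proteinGroups-dialect TSV,
#'   or a list with elements `table` ([abundance_table()]) and optional
#'   `meta`.
#' @param peptides peptide input: a path to a peptides-dialect TSV, or a
#'   list with `table` and `meta` (as from [simulate_digest()]); may be
#'   `NULL` for a protein-only analysis.
#' @param precursor_fasta optional path to precursor FASTA, or a named
#'   character vector of sequences (enables cleavage-specificity
#'   analysis).
#' @param annotations optional annotation data frame
#'   ([read_annotations()]) enabling GO overrepresentation.
#' @param min_present_fraction prevalence filter threshold (strict).
#' @param outlier_log10_margin magnitude margin for sample outliers.
#' @param impute_iterations Gibbs sweeps of [impute_mnar()].
#' @param lfdr_threshold edge significance cutoff.
#' @param leiden a [leiden_params()].
#' @param min_cluster_size retained-cluster threshold.
#' @param enrichment_alpha adjusted-p cutoff for enrichment.
#' @param ladder_min_peptides ladder detection threshold.
#' @param protease_rules list of [protease_rule()]s.
#' @param seed master integer seed for every stochastic stage.
#' @param out_dir optional directory for artifacts (TSV edge list,
#'   partition, GraphML, JSON report).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, peptides = NULL,
                            precursor_fasta = NULL, annotations = NULL,
                            min_present_fraction = 0.5,
                            outlier_log10_margin = 2.0,
                            impute_iterations = 10,
                            lfdr_threshold = 0.1,
                            leiden = leiden_params(),
                            min_cluster_size = 4,
                            enrichment_alpha = 0.05,
                            ladder_min_peptides = 5,
                            protease_rules = list(plasmin_rule()),
                            seed = 1L, out_dir = NULL) {
  stopifnot(lfdr_threshold > 0, lfdr_threshold <= 1,
            min_cluster_size >= 1, enrichment_alpha > 0,
            ladder_min_peptides >= 2)
  structure(
    list(proteins = proteins, peptides = peptides,
         precursor_fasta = precursor_fasta, annotations = annotations,
         min_present_fraction = min_present_fraction,
         outlier_log10_margin = outlier_log10_margin,
         impute_iterations = impute_iterations,
         lfdr_threshold = lfdr_threshold, leiden = leiden,
         min_cluster_size = min_cluster_size,
         enrichment_alpha = enrichment_alpha,
         ladder_min_peptides = ladder_min_peptides,
         protease_rules = protease_rules, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

load_input <- function(input, dialect) {
  if (is.character(input) && length(input) == 1L) {
    read_maxquant_table(input, dialect = dialect)
  } else if (is.list(input) && inherits(input$table, "abundance_table")) {
    list(table = input$table, meta = input$meta %||% NULL)
  } else {
    stop("input must be a file path or a list(table=, meta=)")
  }
}

#' Run the full proteome-peptidome network pipeline
#'
#' Executes ingest, prevalence filtering, outlier screening, MNAR
#' imputation, combination of the protein and peptide matrices,
#' shrinkage-GGM partial correlations, local-fdr edge calibration,
#' Leiden/CPM clustering, cluster retention, optional GO
#' overrepresentation of protein clusters, and the peptidome analyses
#' (ladders, trimming steps, cleavage specificity, precursor
#' contribution). Deterministic under a fixed config seed.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `run_report`: per-stage counts, the network
#'   summary, the partition and retained-cluster table, enrichment and
#'   peptidome results, the echoed config, and a deterministic
#'   `report_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  prot <- stage("ingest_proteins", load_input(config$proteins, "proteinGroups"))
  pept <- if (!is.null(config$peptides)) {
    stage("ingest_peptides", load_input(config$peptides, "peptides"))
  } else NULL

  counts <- list(
    proteins_in = length(prot$table$feature_ids),
    peptides_in = if (!is.null(pept)) length(pept$table$feature_ids) else 0L
  )

  prot_f <- stage("filter_proteins",
                  filter_features(prot$table, prot$meta,
                                  config$min_present_fraction))
  pept_f <- if (!is.null(pept)) {
    stage("filter_peptides",
          filter_features(pept$table, pept$meta,
                          config$min_present_fraction))
  } else NULL

  outliers <- if (!is.null(pept_f)) {
    stage("outlier_samples",
          flag_outlier_samples(pept_f, config$outlier_log10_margin))
  } else character(0)
  if (length(outliers)) {
    prot_f <- drop_samples(prot_f, outliers)
    pept_f <- drop_samples(pept_f, outliers)
  }

  prot_i <- stage("impute_proteins",
                  impute_mnar(prot_f, seed = config$seed,
                              n_iterations = config$impute_iterations))
  pept_i <- if (!is.null(pept_f)) {
    stage("impute_peptides",
          impute_mnar(pept_f, seed = config$seed + 1L,
                      n_iterations = config$impute_iterations))
  } else NULL

  combined <- if (!is.null(pept_i)) {
    stage("combine", combine_tables(prot_i, pept_i))
  } else prot_i

  counts$proteins_filtered <- sum(combined$kind == "protein")
  counts$peptides_filtered <- sum(combined$kind == "peptide")
  counts$samples_dropped <- length(outliers)
  counts$samples_used <- length(combined$sample_ids)

  ggm <- stage("ggm", partial_correlations(combined))
  edges <- stage("edge_calibration",
                 significant_edges(ggm$pcor, config$lfdr_threshold))
  summ <- network_summary(edges, combined$kind)
  counts$n_edges <- summ$n_edges
  counts$n_nodes <- summ$n_nodes
  counts$n_protein_nodes <- sum(combined$kind[
    unique(c(edges$feature_i[edges$significant],
             edges$feature_j[edges$significant]))] == "protein")
  counts$n_peptide_nodes <- counts$n_nodes - counts$n_protein_nodes

  graph <- stage("graph", edge_graph(edges))
  params <- config$leiden
  params$seed <- config$seed + 2L
  partition <- stage("leiden", leiden_cpm(graph, params))
  clusters <- stage("retain_clusters",
                    retain_clusters(partition, combined$kind,
                                    config$min_cluster_size))
  counts$n_clusters <- nrow(clusters)
  counts$clusters_both <- sum(clusters$composition == "both")
  counts$clusters_protein_only <- sum(clusters$composition == "protein_only")
  counts$clusters_peptide_only <- sum(clusters$composition == "peptide_only")

  enrichment <- NULL
  if (!is.null(config$annotations) && nrow(clusters) > 0) {
    enrichment <- stage("enrichment", {
      background <- prot$meta$gene_name %||% names(
        combined$kind)[combined$kind == "protein"]
      id2gene <- if (!is.null(prot$meta)) {
        setNames(prot$meta$gene_name, prot$meta$feature_id)
      } else NULL
      members <- cluster_members(partition, clusters$cluster)
      recs <- lapply(names(members), function(cl) {
        prot_members <- members[[cl]][combined$kind[members[[cl]]] ==
                                        "protein"]
        genes <- if (!is.null(id2gene)) unname(id2gene[prot_members]) else
          prot_members
        genes <- genes[!is.na(genes) & genes %in% background]
        if (length(genes) == 0L) return(NULL)
        hypergeom_overrepresentation(genes, background,
                                     config$annotations,
                                     cluster_id = as.integer(cl))
      })
      recs <- do.call(rbind, recs)
      if (!is.null(recs) && nrow(recs) > 0) {
        significant_enrichments(bh_adjust(recs), config$enrichment_alpha)
      } else recs
    })
  }

  peptidome <- NULL
  if (!is.null(pept_i) && !is.null(pept$meta)) {
    peptidome <- stage("peptidome", {
      meta <- pept$meta[pept$meta$feature_id %in% combined$feature_ids, ,
                        drop = FALSE]
      meta$cluster <- partition$membership[meta$feature_id]
      mapped <- meta[!is.na(meta$cluster), , drop = FALSE]
      ladders <- detect_ladders(mapped, config$ladder_min_peptides)
      seqs <- if (is.character(config$precursor_fasta) &&
                    length(config$precursor_fasta) == 1L &&
                    file.exists(config$precursor_fasta)) {
        read_precursor_fasta(config$precursor_fasta)
      } else config$precursor_fasta
      spec <- if (!is.null(seqs)) {
        cleavage_specificity(meta, seqs, config$protease_rules)
      } else NULL
      list(ladders = ladders,
           trimming = trimming_steps(meta),
           specificity = spec,
           contribution = precursor_contribution(meta, pept_i))
    })
    counts$n_ladders <- nrow(peptidome$ladders)
  }

  report <- list(
    counts = counts,
    network = summ,
    shrinkage = ggm$fit,
    mixture = list(eta0 = attr(edges, "fit")$eta0,
                   kappa = attr(edges, "fit")$kappa),
    partition = partition,
    clusters = clusters,
    enrichment = enrichment,
    peptidome = peptidome,
    seed = config$seed,
    version = as.character(utils::packageVersion("milknet")),
    config = config[setdiff(names(config), c("proteins", "peptides",
                                             "annotations"))]
  )
  report$report_hash <- rlang::hash(report)
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_edges_tsv(edges, file.path(config$out_dir, "edges.tsv"))
    igraph::write_graph(graph, file.path(config$out_dir, "network.graphml"),
                        format = "graphml")
    part_df <- data.frame(node = names(partition$membership),
                          cluster = unname(partition$membership),
                          kind = unname(combined$kind[
                            names(partition$membership)]),
                          stringsAsFactors = FALSE)
    write.table(part_df, file.path(config$out_dir, "partition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(counts = counts, network = summ, seed = config$seed,
           report_hash = report$report_hash),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (line in summarize_counts(x)$lines) cat(" ", line, "\n")
  invisible(x)
}

#' Render the headline counts of a run report
#'
#' Formats the node breakdown (proteins + peptides), edge count, network
#' density and same-kind edge share (one decimal each), and the cluster
#' composition breakdown.
#'
#' @param report a [run_pipeline()] report, or any list with a compatible
#'   `counts` element (fields `n_protein_nodes`, `n_peptide_nodes`,
#'   `n_edges`, `clusters_both`, `clusters_protein_only`,
#'   `clusters_peptide_only`).
#' @return invisibly, a list with `nodes`, `clusters` (component sums),
#'   `density_pct`, `same_kind_pct`, and the printed `lines`.
#' @export
summarize_counts <- function(report) {
  cn <- report$counts
  nodes <- cn$n_protein_nodes + cn$n_peptide_nodes
  clusters <- cn$clusters_both + cn$clusters_protein_only +
    cn$clusters_peptide_only
  density <- report$network$density_pct %||%
    network_density(cn$n_edges, nodes)
  same <- report$network$same_kind_pct %||% NA_real_
  lines <- c(
    sprintf("%d nodes (%d proteins + %d peptides), %d significant edges",
            nodes, cn$n_protein_nodes, cn$n_peptide_nodes, cn$n_edges),
    sprintf("network density %.1f%%; same-kind edges %.1f%%",
            density, same),
    sprintf("%d retained clusters (%d mixed + %d protein-only + %d peptide-only)",
            clusters, cn$clusters_both, cn$clusters_protein_only,
            cn$clusters_peptide_only)
  )
  invisible(list(nodes = nodes, clusters = clusters, density_pct = density,
                 same_kind_pct = same, lines = lines))
}
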