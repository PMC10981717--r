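#' Parameters for Leiden community detection under the Constant Potts Model
#'
#' Defaults follow the settings used for sparse omics association
#' networks: resolution \eqn{\gamma = 10^{-3}}, refinement randomness
#' \eqn{\beta = 0.01}, and an iteration budget of 1000 (the algorithm
#' stops earlier once the partition is stable).
#'
#' @param resolution CPM resolution \eqn{\gamma > 0}: the internal edge
#'   density a community must exceed to be worth keeping together.
#' @param beta randomness of the Leiden refinement phase.
#' @param iterations outer-iteration budget.
#' @param seed integer seed (Leiden breaks ties randomly).
#' @param use_weights use `|rho|` edge weights if present.
#' @return an object of class `leiden_params`.
#' @export
leiden_params <- function(resolution = 1e-3, beta = 0.01, iterations = 1000,
                          seed = 1L, use_weights = TRUE) {
  stopifnot(resolution > 0, iterations >= 1, beta >= 0)
  structure(list(resolution = resolution, beta = beta,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), use_weights = use_weights),
            class = "leiden_params")
}

#' Build an igraph network from a significant edge list
#'
#' @param edges a [significant_edges()] result (only significant rows are
#'   used).
#' @param nodes optional character vector of node ids to include even
#'   when isolated (e.g. all features of the matrix).
#' @return an undirected [igraph::graph] with edge attribute `weight`
#'   (= `|rho|`) and `rho`.
#' @export
edge_graph <- function(edges, nodes = NULL) {
  sig <- edges[edges$significant, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = sig$feature_i, to = sig$feature_j,
               weight = abs(sig$rho), rho = sig$rho,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = nodes %||% unique(c(sig$feature_i, sig$feature_j))
  )
  g
}

#' Constant Potts Model quality of a partition
#'
#' \deqn{H = \sum_c \left[ W_c - \gamma \, n_c (n_c - 1) / 2 \right]}
#' where \eqn{W_c} is the total intra-community edge weight (edge count
#' when unweighted) and \eqn{n_c} the community size.
#'
#' @param graph an igraph graph.
#' @param membership named community assignment covering every node.
#' @param resolution \eqn{\gamma}.
#' @param use_weights use the graph's `weight` edge attribute if present.
#' @return the CPM value.
#' @export
cpm_quality <- function(graph, membership, resolution,
                        use_weights = TRUE) {
  nodes <- igraph::V(graph)$name
  if (is.null(names(membership)) && length(membership) == length(nodes)) {
    names(membership) <- nodes
  }
  if (!all(nodes %in% names(membership))) {
    stop("node(s) missing from partition: ",
         paste(head(setdiff(nodes, names(membership)), 3), collapse = ", "))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  w <- if (use_weights && "weight" %in% names(el)) el$weight else
    rep(1, nrow(el))
  intra <- membership[el$from] == membership[el$to]
  wc <- sum(w[intra])
  sizes <- table(membership[nodes])
  wc - resolution * sum(sizes * (sizes - 1) / 2)
}

#' Leiden community detection with the Constant Potts Model
#'
#' Runs the Leiden algorithm (local moves, randomized refinement,
#' aggregation) with CPM as the quality function. Communities returned
#' by Leiden are guaranteed connected. Cluster ids are relabelled
#' contiguously from 1 in decreasing size order (ties broken by first
#' node), so labels are deterministic under a fixed seed.
#'
#' @param graph an undirected igraph graph (may be disconnected; isolated
#'   nodes become singleton communities).
#' @param params a [leiden_params()].
#' @return a list of class `partition` with `membership` (named integer),
#'   `quality` (CPM value at the returned partition), and `params`.
#' @export
leiden_cpm <- function(graph, params = leiden_params()) {
  stopifnot(inherits(params, "leiden_params"))
  w <- if (params$use_weights &&
           "weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight
  } else NULL
  res <- with_seed(params$seed, {
    igraph::cluster_leiden(
      graph, objective_function = "CPM", weights = w,
      resolution = params$resolution, beta = params$beta,
      n_iterations = params$iterations
    )
  })
  memb <- igraph::membership(res)
  nodes <- igraph::V(graph)$name
  names(memb) <- nodes
  # contiguous ids, largest community first, ties by earliest node
  first_node <- tapply(seq_along(memb), memb, min)
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(first_node))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  memb <- setNames(as.integer(relabel[as.character(memb)]), nodes)
  structure(
    list(membership = memb,
         quality = cpm_quality(graph, memb, params$resolution,
                               params$use_weights),
         params = params),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities, CPM quality %.4f\n",
              length(x$membership), length(unique(x$membership)), x$quality))
  invisible(x)
}

#' Retain clusters above a minimum size and label their composition
#'
#' Clusters with at least `min_size` members ("more than 3 nodes" at the
#' default) are kept; smaller ones are marked unclustered. Kept clusters
#' are labelled `"both"`, `"protein_only"`, or `"peptide_only"` by
#' membership composition.
#'
#' @param partition a [leiden_cpm()] result.
#' @param kinds named character vector mapping node id to `"protein"` or
#'   `"peptide"`.
#' @param min_size minimum retained cluster size.
#' @return a data frame with one row per retained cluster: `cluster`,
#'   `size`, `n_protein`, `n_peptide`, `composition`. Unretained nodes
#'   are listed in attribute `"unclustered"`.
#' @export
retain_clusters <- function(partition, kinds, min_size = 4) {
  memb <- partition$membership
  sizes <- table(memb)
  kept <- as.integer(names(sizes)[sizes >= min_size])
  rows <- lapply(kept, function(cl) {
    members <- names(memb)[memb == cl]
    np <- sum(kinds[members] == "protein")
    nq <- sum(kinds[members] == "peptide")
    data.frame(
      cluster = cl, size = length(members), n_protein = np, n_peptide = nq,
      composition = if (np > 0 && nq > 0) "both"
                    else if (np > 0) "protein_only" else "peptide_only",
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), size = integer(), n_protein = integer(),
               n_peptide = integer(), composition = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unclustered") <- names(memb)[!(memb %in% kept)]
  out
}

#' Cluster members as a list
#'
#' @param partition a [leiden_cpm()] result.
#' @param clusters optional cluster ids to extract (default all).
#' @return named list of member node-id vectors.
#' @export
cluster_members <- function(partition, clusters = NULL) {
  memb <- partition$membership
  ids <- clusters %||% sort(unique(memb))
  setNames(lapply(ids, function(cl) names(memb)[memb == cl]),
           as.character(ids))
}
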