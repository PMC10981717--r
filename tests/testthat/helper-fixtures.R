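# Shared fixture builders and independent oracles.

# Draw n samples from the Gaussian with precision matrix omega.
rmvnorm_prec <- function(n, omega, seed = 1) {
  sigma <- solve(omega)
  set.seed(seed)
  matrix(rnorm(n * nrow(omega)), n) %*% chol(sigma)
}

# Closed-form partial correlation implied by a precision matrix.
prec_to_pcor <- function(omega) {
  d <- sqrt(diag(omega))
  p <- -omega / outer(d, d)
  diag(p) <- 1
  p
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings); independent oracle for the CPM optimum.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, max_block) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(max_block + 1L)) {
      grow(c(prefix, b), max(max_block, b))
    }
  }
  grow(integer(0), 0L)
  out
}

# Brute-force CPM value from an edge data frame (unweighted).
cpm_brute <- function(edges_df, membership, gamma) {
  intra <- membership[edges_df$from] == membership[edges_df$to]
  sizes <- table(membership)
  sum(intra) - gamma * sum(sizes * (sizes - 1) / 2)
}

# Independent reconstruction of the planted precision matrix: unit
# diagonal, -pcor between members of the same declared block.
build_precision_oracle <- function(spec) {
  p <- spec$n_features
  omega <- diag(p)
  at <- 0
  for (m in spec$block_sizes) {
    idx <- at + seq_len(m)
    omega[idx, idx] <- -spec$within_block_pcor
    diag(omega)[idx] <- 1
    at <- at + m
  }
  omega
}

# Small protein fixture: planted blocks among background features.
toy_blocks_spec <- function(seed = 1, n = 297, p = 100, blocks = rep(4, 12),
                            pcor = 0.3) {
  precision_spec(n_features = p, block_sizes = blocks,
                 within_block_pcor = pcor, n_samples = n, seed = seed)
}

# Planted-edge recovery for one seed: empirical FDR and sensitivity of
# the significant-edge set against the generator truth.
recovery_one <- function(seed, threshold = 0.1) {
  sim <- simulate_abundances(toy_blocks_spec(seed))
  res <- partial_correlations(sim$table)
  edges <- significant_edges(res$pcor, threshold = threshold)
  truth_key <- paste(sim$truth$true_edges$feature_i,
                     sim$truth$true_edges$feature_j)
  sig <- edges[edges$significant, ]
  sig_key <- paste(sig$feature_i, sig$feature_j)
  tp <- sum(sig_key %in% truth_key)
  c(fdr = if (nrow(sig)) (nrow(sig) - tp) / nrow(sig) else 0,
    sensitivity = tp / length(truth_key))
}
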