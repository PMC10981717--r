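#' Specify a planted partial-correlation structure
#'
#' Defines a precision matrix over `n_features` latent Gaussian profiles in
#' which disjoint blocks of features form fully connected clusters with a
#' constant partial correlation, and all other pairs are conditionally
#' independent (precision entry exactly zero).
#'
#' For a complete block of size \eqn{m} with constant partial correlation
#' \eqn{\rho}, positive definiteness requires \eqn{\rho < 1/(m-1)}; the
#' constructor rejects violating blocks by index.
#'
#' @param n_features total number of features.
#' @param block_sizes integer vector of planted cluster sizes (may be
#'   empty; features not covered by a block are independent background).
#' @param within_block_pcor partial correlation shared by all pairs inside
#'   a block, in (-1, 1).
#' @param n_samples number of samples to draw.
#' @param seed integer seed controlling every random element.
#' @return an object of class `precision_spec`.
#' @export
precision_spec <- function(n_features, block_sizes = integer(),
                           within_block_pcor = 0.3, n_samples = 297,
                           seed = 1L) {
  stopifnot(n_features >= 1, n_samples >= 2,
            abs(within_block_pcor) < 1)
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 2)) stop("block sizes must be >= 2")
  if (sum(block_sizes) > n_features) {
    stop("blocks (", sum(block_sizes), " features) exceed n_features (",
         n_features, ")")
  }
  structure(
    list(n_features = as.integer(n_features), block_sizes = block_sizes,
         within_block_pcor = within_block_pcor,
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "precision_spec"
  )
}

# Build the planted precision matrix Omega (unit diagonal). The partial
# correlation implied by a precision matrix is
#   rho_ij = -omega_ij / sqrt(omega_ii * omega_jj),
# so a within-block partial correlation rho requires omega_ij = -rho.
build_precision <- function(spec) {
  p <- spec$n_features
  omega <- diag(p)
  rho <- spec$within_block_pcor
  at <- 0L
  for (b in seq_along(spec$block_sizes)) {
    m <- spec$block_sizes[b]
    idx <- at + seq_len(m)
    block <- matrix(-rho, m, m)
    diag(block) <- 1
    ev <- eigen(block, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("block ", b, " (size ", m, ", pcor ", rho,
           ") gives a non-positive-definite precision matrix; ",
           "constant-pcor blocks require |pcor| < 1/(size - 1)")
    }
    omega[idx, idx] <- block
    at <- at + m
  }
  omega
}

#' Simulate protein abundance profiles with planted network structure
#'
#' Draws `n_samples` observations from the multivariate Gaussian whose
#' precision matrix carries the planted block structure, then maps the
#' latent scores to a label-free intensity scale as
#' \eqn{2^{\mu_f + z}}, with per-feature baselines \eqn{\mu_f} drawn
#' uniformly over log2 intensities 20-30 (a realistic LFQ dynamic range).
#' A log2 transform of the output therefore restores the Gaussian scale
#' assumed by the graphical model.
#'
#' @param spec a [precision_spec()].
#' @return a list with elements `table` (an [abundance_table()] of kind
#'   `"protein"`) and `truth`, a list with `true_edges` (data frame of
#'   feature-id pairs, the non-zero off-diagonal precision entries),
#'   `true_clusters` (named integer; background features get singleton
#'   cluster ids), and `precision` (the planted matrix).
#' @export
simulate_abundances <- function(spec) {
  stopifnot(inherits(spec, "precision_spec"))
  omega <- build_precision(spec)
  p <- spec$n_features
  n <- spec$n_samples
  sigma <- solve(omega)
  ids <- sprintf("PROT%04d", seq_len(p))

  out <- with_seed(spec$seed, {
    z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
    mu <- runif(p, 20, 30)
    sweep(z, 2, mu, `+`)
  })
  m <- 2^out
  dimnames(m) <- list(sprintf("S%03d", seq_len(n)), ids)

  cl <- integer(p)
  at <- 0L
  for (b in seq_along(spec$block_sizes)) {
    cl[at + seq_len(spec$block_sizes[b])] <- b
    at <- at + spec$block_sizes[b]
  }
  nb <- length(spec$block_sizes)
  singleton <- cl == 0L
  cl[singleton] <- nb + seq_len(sum(singleton))
  names(cl) <- ids

  adj <- omega != 0 & upper.tri(omega)
  pair <- which(adj, arr.ind = TRUE)
  true_edges <- data.frame(
    feature_i = ids[pair[, 1]], feature_j = ids[pair[, 2]],
    stringsAsFactors = FALSE
  )

  list(
    table = abundance_table(m, kind = "protein"),
    truth = list(true_edges = true_edges, true_clusters = cl,
                 precision = omega)
  )
}

#' Apply left-censored (MNAR) missingness
#'
#' Emulates the detection-limit missingness of label-free proteomics:
#' within each feature, intensities below that feature's
#' `censor_quantile` quantile are set missing. With `soft = TRUE` the
#' hard threshold is replaced by a logistic dropout probability centred
#' on the threshold, softening the boundary.
#'
#' @param table an [abundance_table()].
#' @param censor_quantile per-feature censoring quantile in \[0, 1).
#' @param seed integer seed (used only by the soft censor).
#' @param soft logical; use stochastic logistic censoring near the
#'   threshold instead of a hard cut.
#' @param soft_scale logistic scale (in log2-intensity units) of the soft
#'   censor.
#' @return the censored `abundance_table`; the per-feature thresholds are
#'   attached as attribute `"censor_thresholds"`.
#' @export
apply_mnar_censoring <- function(table, censor_quantile, seed = 1L,
                                 soft = FALSE, soft_scale = 0.5) {
  stopifnot(inherits(table, "abundance_table"),
            censor_quantile >= 0, censor_quantile < 1)
  m <- table$intensities
  thr <- apply(m, 2, quantile, probs = censor_quantile, na.rm = TRUE)
  if (censor_quantile > 0) {
    if (soft) {
      drop <- with_seed(seed, {
        pr <- stats::plogis(log2(sweep(m, 2, thr, `/`)) / soft_scale,
                            lower.tail = FALSE)
        matrix(runif(length(m)), nrow(m)) < pr
      })
      m[drop] <- NA
    } else {
      m[sweep(m, 2, thr, `<`)] <- NA
    }
  }
  out <- set_intensities(table, m)
  attr(out, "censor_thresholds") <- thr
  out
}
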