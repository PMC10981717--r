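# Null sampling density of a partial correlation with kappa effective
# degrees of freedom:
#   f0(r; kappa) = Gamma(kappa/2) / (sqrt(pi) Gamma((kappa-1)/2))
#                  * (1 - r^2)^((kappa-3)/2)
# Equivalently r^2 ~ Beta(1/2, (kappa-1)/2) with a symmetric sign.
ldnull <- function(r, kappa) {
  lgamma(kappa / 2) - lgamma((kappa - 1) / 2) - 0.5 * log(pi) +
    ((kappa - 3) / 2) * log1p(-pmin(r^2, 1 - 1e-15))
}

#' Null density of a partial correlation
#'
#' @param r values in \[-1, 1\].
#' @param kappa effective degrees of freedom (> 3).
#' @return density values.
#' @export
dnull <- function(r, kappa) exp(ldnull(r, kappa))

#' Sample from the null partial-correlation distribution
#'
#' @param n number of draws.
#' @param kappa effective degrees of freedom (> 3).
#' @return numeric vector in (-1, 1).
#' @export
rnull <- function(n, kappa) {
  sign(runif(n) - 0.5) * sqrt(rbeta(n, 0.5, (kappa - 1) / 2))
}

# Mass of the null within |r| <= c.
pnull_central <- function(c, kappa) pbeta(c^2, 0.5, (kappa - 1) / 2)

# Symmetric kernel density with reflection at +-1; bandwidth by
# Silverman's rule of thumb. The evaluation grid tracks the observed
# range (plus 4 bandwidths) so that strongly shrunk, tightly concentrated
# distributions are still resolved.
kde_reflect <- function(r, n_grid = 2048) {
  bw <- stats::bw.nrd0(r)
  lo <- max(-1, min(r) - 4 * bw)
  hi <- min(1, max(r) + 4 * bw)
  d <- density(c(r, 2 - r, -2 - r), bw = bw, from = lo, to = hi, n = n_grid)
  list(x = d$x, y = 3 * d$y, bw = bw)  # x3: original sample is 1/3 of mass
}

#' Fit the empirical-Bayes two-component mixture over partial correlations
#'
#' Models the observed off-diagonal partial correlations as a mixture
#' \eqn{f(r) = \eta_0 f_0(r; \kappa) + (1 - \eta_0) f_A(r)} of a null
#' component (the sampling law of a zero partial correlation with
#' \eqn{\kappa} effective degrees of freedom) and an alternative carrying
#' the real edges. \eqn{\kappa} is fit by maximum likelihood on the
#' central body of the distribution (|r| below its `central_quantile`
#' quantile, with the truncation accounted for in the likelihood);
#' \eqn{\eta_0} is the ratio of the empirical to the null central mass
#' within one null standard deviation of zero, clipped to \[0, 1\].
#'
#' @param rhos off-diagonal partial correlation values.
#' @param central_quantile quantile of |r| bounding the body used for the
#'   \eqn{\kappa} fit.
#' @return an object of class `null_mixture_fit` with `eta0`, `kappa`,
#'   and `density_grid` (tabulated kernel estimate of the mixture
#'   density).
#' @export
fit_null_mixture <- function(rhos, central_quantile = 0.9) {
  rhos <- rhos[is.finite(rhos)]
  if (length(rhos) < 100) {
    warning("fewer than 100 partial correlations; mixture fit is unstable")
  }
  if (all(abs(rhos) < 1e-12) || sd(rhos) < 1e-12) {
    # degenerate input: everything at zero, pure null by convention
    grid <- seq(-1, 1, length.out = 1024)
    return(structure(
      list(eta0 = 1, kappa = 1e6,
           density_grid = list(x = grid, y = rep(0.5, 1024), bw = NA),
           degenerate = TRUE),
      class = "null_mixture_fit"))
  }
  cutoff <- quantile(abs(rhos), central_quantile)
  body <- rhos[abs(rhos) <= cutoff]
  nll <- function(kappa) {
    -(sum(ldnull(body, kappa)) -
        length(body) * pbeta(cutoff^2, 0.5, (kappa - 1) / 2, log.p = TRUE))
  }
  # search on the log scale; var(r) ~ 1/kappa under the null, so the
  # upper bound adapts to arbitrarily strong shrinkage
  kappa_max <- max(1e6, 100 / var(rhos))
  kappa <- exp(optimize(function(lk) nll(exp(lk)),
                        c(log(3.5), log(kappa_max)))$minimum)
  delta <- 1 / sqrt(kappa)  # one null standard deviation
  eta0 <- min(1, mean(abs(rhos) <= delta) / pnull_central(delta, kappa))
  structure(
    list(eta0 = eta0, kappa = kappa, density_grid = kde_reflect(rhos),
         degenerate = FALSE),
    class = "null_mixture_fit"
  )
}

#' @export
print.null_mixture_fit <- function(x, ...) {
  cat(sprintf("<null_mixture_fit> eta0 = %.3f, kappa = %.1f%s\n",
              x$eta0, x$kappa, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Local false discovery rate of partial correlations
#'
#' \eqn{fdr(r) = \min(1, \eta_0 f_0(r; \kappa) / \hat f(r))}: the
#' posterior probability that an edge with observed partial correlation r
#' belongs to the null component. The "presence probability" of an edge
#' is `1 - local fdr`. Monotone non-increase in |r| is enforced by an
#' isotonic least-squares post-processing step.
#'
#' @param rhos partial correlation values.
#' @param fit a [fit_null_mixture()] result.
#' @return local fdr values in \[0, 1\], aligned with `rhos`.
#' @export
local_fdr <- function(rhos, fit) {
  stopifnot(inherits(fit, "null_mixture_fit"))
  if (isTRUE(fit$degenerate)) return(rep(1, length(rhos)))
  fhat <- approx(fit$density_grid$x, fit$density_grid$y, xout = rhos,
                 rule = 2)$y
  raw <- pmin(1, fit$eta0 * dnull(rhos, fit$kappa) / pmax(fhat, 1e-300))
  o <- order(abs(rhos))
  iso <- isoreg(abs(rhos)[o], -raw[o])  # non-decreasing fit of -fdr
  out <- numeric(length(rhos))
  out[o] <- pmin(1, pmax(0, -iso$yf))
  out
}

#' Call significant edges from a partial-correlation matrix
#'
#' Fits the null mixture over all unordered feature pairs and declares an
#' edge significant when its local fdr is strictly below `threshold`
#' (the default 0.1 corresponds to a presence probability above 0.9).
#'
#' @param pcm a partial-correlation matrix ([partial_correlations()]
#'   output `$pcor` or any symmetric matrix with unit diagonal).
#' @param threshold local-fdr significance cutoff.
#' @param fit optional pre-computed [fit_null_mixture()]; fitted from
#'   `pcm` when `NULL`.
#' @return a data frame (class `edge_list`) with one row per unordered
#'   pair: `feature_i`, `feature_j` (i before j in matrix order), `rho`,
#'   `local_fdr`, `significant`. The mixture fit is attached as attribute
#'   `"fit"`.
#' @export
significant_edges <- function(pcm, threshold = 0.1, fit = NULL) {
  stopifnot(is.matrix(pcm), nrow(pcm) == ncol(pcm))
  ids <- colnames(pcm) %||% sprintf("F%04d", seq_len(ncol(pcm)))
  ut <- which(upper.tri(pcm), arr.ind = TRUE)
  rho <- pcm[upper.tri(pcm)]
  if (is.null(fit)) fit <- fit_null_mixture(rho)
  lf <- local_fdr(rho, fit)
  out <- data.frame(
    feature_i = ids[ut[, 1]], feature_j = ids[ut[, 2]],
    rho = rho, local_fdr = lf, significant = lf < threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  attr(out, "threshold") <- threshold
  class(out) <- c("edge_list", class(out))
  out
}

#' Network density as a percentage
#'
#' `100 * E / (N (N - 1) / 2)`, rounded to one decimal: the share of all
#' possible edges among N nodes that is realised.
#'
#' @param n_edges edge count.
#' @param n_nodes node count.
#' @return density percentage (one decimal).
#' @export
network_density <- function(n_edges, n_nodes) {
  if (n_nodes < 2) return(0)
  round(100 * n_edges / (n_nodes * (n_nodes - 1) / 2), 1)
}

#' Summarize a significant-edge network
#'
#' @param edges an edge list from [significant_edges()] (only rows with
#'   `significant = TRUE` are counted).
#' @param kinds named character vector mapping feature id to `"protein"`
#'   or `"peptide"`.
#' @return a list with `n_edges`, `n_nodes` (nodes incident to at least
#'   one significant edge), `density_pct`, and `same_kind_pct` (share of
#'   edges whose endpoints are the same kind, one decimal; `NA` when
#'   there are no edges).
#' @export
network_summary <- function(edges, kinds) {
  sig <- edges[edges$significant, , drop = FALSE]
  n_edges <- nrow(sig)
  nodes <- unique(c(sig$feature_i, sig$feature_j))
  same <- if (n_edges > 0) {
    round(100 * mean(kinds[sig$feature_i] == kinds[sig$feature_j]), 1)
  } else NA_real_
  list(
    n_edges = n_edges,
    n_nodes = length(nodes),
    density_pct = network_density(n_edges, length(nodes)),
    same_kind_pct = same
  )
}

#' Write an edge list as TSV
#'
#' @param edges a [significant_edges()] result.
#' @param path output path.
#' @param significant_only write only significant edges.
#' @export
write_edges_tsv <- function(edges, path, significant_only = TRUE) {
  out <- if (significant_only) edges[edges$significant, , drop = FALSE] else edges
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
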