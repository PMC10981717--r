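#' Estimate the shrinkage intensity for the correlation matrix
#'
#' Analytic shrinkage of the sample correlation matrix toward the
#' identity target (Schafer-Strimmer estimator): the optimal intensity is
#' \deqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(r_{ij}) /
#'       \sum_{i \ne j} r_{ij}^2,}
#' clipped to \[0, 1\], where \eqn{\widehat{Var}(r_{ij})} is the
#' unbiased-moment estimate of the variance of the empirical correlation
#' computed from the products \eqn{w_{kij} = x_{ki} x_{kj}} of the
#' standardized data. Shrinkage guarantees a positive-definite,
#' invertible correlation matrix even when features outnumber samples.
#'
#' @param x standardized samples x features matrix (zero mean, unit
#'   variance columns).
#' @return an object of class `shrinkage_fit` with elements
#'   `lambda_star`, `n_samples`, `n_features`.
#' @export
estimate_shrinkage_intensity <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 3)
  n <- nrow(x); p <- ncol(x)
  sds <- apply(x, 2, sd)
  bad <- !is.finite(sds) | sds < 1e-12
  if (any(bad)) {
    stop("constant feature(s): ",
         paste(head(colnames(x)[bad] %||% which(bad), 3), collapse = ", "))
  }
  r <- crossprod(x) / (n - 1)
  s1 <- crossprod(x)      # sum_k w_kij
  s2 <- crossprod(x^2)    # sum_k w_kij^2
  v <- n / (n - 1)^3 * (s2 - s1^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom <= 0) 1 else min(1, max(0, sum(v[off]) / denom))
  structure(list(lambda_star = lambda, n_samples = n, n_features = p),
            class = "shrinkage_fit")
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("<shrinkage_fit> lambda* = %.4f (n = %d, p = %d)\n",
              x$lambda_star, x$n_samples, x$n_features))
  invisible(x)
}

#' Shrinkage partial correlations (Gaussian graphical model)
#'
#' Estimates the matrix of partial correlations
#' \eqn{\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}}
#' from the inverse \eqn{\Omega} of the shrunk correlation matrix
#' \eqn{R^* = \lambda^* I + (1 - \lambda^*) R}. \eqn{\rho_{ij}} is the
#' correlation between features i and j after removing the linear effect
#' of all other features, so edges of the resulting graph are direct
#' (conditional) associations.
#'
#' Features are standardized internally; the estimate is therefore
#' invariant to positive rescaling of any raw feature.
#'
#' @param x an [abundance_table()] (complete; log2 is taken internally)
#'   or a numeric samples x features matrix already on the modeling
#'   scale.
#' @param lambda optional shrinkage override (tests and sensitivity
#'   sweeps); `NULL` uses the analytic estimate. With `lambda = 0` and
#'   more features than samples a Moore-Penrose pseudo-inverse is used.
#' @return a list with `pcor` (symmetric partial-correlation matrix with
#'   unit diagonal, class `pcor_matrix`) and `fit` (the
#'   [estimate_shrinkage_intensity()] result).
#' @export
partial_correlations <- function(x, lambda = NULL) {
  if (inherits(x, "abundance_table")) {
    if (any(x$missing_mask)) {
      stop("abundance table contains missing values; run impute_mnar() first")
    }
    x <- log2_matrix(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  raw_sds <- apply(x, 2, sd)
  if (any(!is.finite(raw_sds) | raw_sds < 1e-12)) {
    bad <- !is.finite(raw_sds) | raw_sds < 1e-12
    stop("constant feature(s): ",
         paste(head(colnames(x)[bad] %||% which(bad), 3), collapse = ", "))
  }
  xs <- scale(x)
  fit <- estimate_shrinkage_intensity(xs)
  if (!is.null(lambda)) {
    stopifnot(lambda >= 0, lambda <= 1)
    fit$lambda_star <- lambda
  }
  n <- nrow(xs); p <- ncol(xs)
  r <- crossprod(xs) / (n - 1)
  rs <- (1 - fit$lambda_star) * r
  diag(rs) <- 1
  omega <- if (fit$lambda_star == 0 && p > n) {
    MASS::ginv(rs)
  } else {
    tryCatch(solve(rs), error = function(e) MASS::ginv(rs))
  }
  d <- sqrt(abs(diag(omega)))
  pcor <- -omega / outer(d, d)
  pcor <- (pcor + t(pcor)) / 2
  pcor[pcor > 1] <- 1
  pcor[pcor < -1] <- -1
  diag(pcor) <- 1
  dimnames(pcor) <- list(colnames(x), colnames(x))
  class(pcor) <- c("pcor_matrix", class(pcor))
  list(pcor = pcor, fit = fit)
}
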