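#' Filter features on prevalence and contaminant/reverse flags
#'
#' Retains features observed in strictly more than
#' `min_present_fraction` of the samples (with 300 samples and the
#' default 0.5 this is the ">150 samples" rule), after first dropping
#' features flagged as potential contaminants or reverse (decoy) hits.
#'
#' @param table an [abundance_table()].
#' @param meta optional per-feature data frame with `feature_id` and
#'   logical `is_contaminant` / `is_reverse` columns.
#' @param min_present_fraction prevalence threshold (strict inequality).
#' @return the filtered `abundance_table`.
#' @export
filter_features <- function(table, meta = NULL, min_present_fraction = 0.5) {
  stopifnot(inherits(table, "abundance_table"),
            min_present_fraction >= 0, min_present_fraction < 1)
  keep <- rep(TRUE, length(table$feature_ids))
  if (!is.null(meta)) {
    flagged <- meta$feature_id[meta$is_contaminant | meta$is_reverse]
    keep <- keep & !(table$feature_ids %in% flagged)
  }
  n_present <- colSums(!table$missing_mask)
  keep <- keep & n_present > min_present_fraction * length(table$sample_ids)
  if (!any(keep)) {
    stop("all features removed by the prevalence filter; ",
         "review min_present_fraction = ", min_present_fraction)
  }
  set_intensities(table, table$intensities[, keep, drop = FALSE])
}

#' Flag samples with aberrant total peptide abundance
#'
#' Milk peptidomes of mastitic samples can show total peptide abundance
#' several orders of magnitude above the rest; such samples distort the
#' network and are screened out. A sample is flagged when its log10 total
#' intensity exceeds the median log10 total by at least `log10_margin`.
#'
#' @param table a peptide [abundance_table()].
#' @param log10_margin magnitude margin (log10 units) above the median.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(table, log10_margin = 2.0) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(table$sample_ids) < 3L) stop("need at least 3 samples")
  totals <- rowSums(table$intensities, na.rm = TRUE)
  lt <- log10(totals)
  flagged <- is.finite(lt) & (lt - median(lt)) >= log10_margin
  table$sample_ids[flagged]
}

#' Drop samples from an abundance table
#'
#' @param table an [abundance_table()].
#' @param sample_ids samples to remove.
#' @return the reduced `abundance_table`.
#' @export
drop_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- !(table$sample_ids %in% sample_ids)
  set_intensities(table, table$intensities[keep, , drop = FALSE])
}

# Censored-normal (Tobit) fit for one feature on the log2 scale: observed
# values plus a known count of left-censored cells below `cens`.
fit_censored_normal <- function(obs, n_censored, cens) {
  mu0 <- mean(obs)
  s0 <- max(sd(obs), 1e-3)
  if (n_censored == 0L) return(c(mu = mu0, sigma = s0))
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    -(sum(dnorm(obs, mu, s, log = TRUE)) +
        n_censored * pnorm(cens, mu, s, log.p = TRUE))
  }
  fit <- optim(c(mu0, log(s0)), nll, method = "Nelder-Mead")
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Draw from N(mu, sigma) truncated above at `upper` by inverse CDF.
rtruncnorm_upper <- function(n, mu, sigma, upper) {
  p_hi <- pmax(pnorm(upper, mu, sigma), 1e-12)
  u <- runif(n) * p_hi
  qnorm(pmin(u, 1 - 1e-12), mu, sigma)
}

#' Impute left-censored missing values
#'
#' Gibbs-sampler-style imputation under the assumption that missing
#' values are missing-not-at-random and left censored, operating on the
#' log2 scale. Each feature's missing cells are initialised with draws
#' from a censored-normal fit truncated above at the feature's observed
#' minimum (QRILC-style), then refined by a fixed number of Gibbs sweeps
#' in which every incomplete feature is re-drawn from a ridge regression
#' on its 10 most-correlated features, again truncated above at the
#' observed minimum. Observed cells are never modified.
#'
#' @param table an [abundance_table()] (raw intensity scale, `NA` for
#'   missing).
#' @param seed integer seed.
#' @param n_iterations number of Gibbs sweeps after initialisation.
#' @param n_predictors number of correlated features used as regressors.
#' @param ridge ridge penalty (per observation) on the regression.
#' @return a complete `abundance_table`; imputed cells are `<=` each
#'   feature's minimum observed intensity.
#' @export
impute_mnar <- function(table, seed = 1L, n_iterations = 10,
                        n_predictors = 10, ridge = 0.1) {
  stopifnot(inherits(table, "abundance_table"))
  mask <- table$missing_mask
  if (!any(mask)) return(table)
  zero_obs <- colSums(!mask) == 0
  if (any(zero_obs)) {
    stop("feature(s) with zero observed values: ",
         paste(head(table$feature_ids[zero_obs], 3), collapse = ", "))
  }

  x <- log2(table$intensities)
  n <- nrow(x); p <- ncol(x)
  incomplete <- which(colSums(mask) > 0)
  mins <- vapply(seq_len(p), function(j) min(x[!mask[, j], j]), numeric(1))

  x_imp <- with_seed(seed, {
    # initialisation: per-feature censored-normal draws below the minimum
    for (j in incomplete) {
      obs <- x[!mask[, j], j]
      fit <- fit_censored_normal(obs, sum(mask[, j]), mins[j])
      x[mask[, j], j] <- rtruncnorm_upper(sum(mask[, j]), fit["mu"],
                                          fit["sigma"], mins[j])
    }
    # Gibbs refinement on the completed matrix
    if (p > 1L) {
      for (iter in seq_len(n_iterations)) {
        cm <- cor(x)
        for (j in incomplete) {
          others <- setdiff(order(abs(cm[, j]), decreasing = TRUE), j)
          pred <- others[seq_len(min(n_predictors, length(others)))]
          # condition on the current completed matrix (observed plus
          # current imputations): fitting on observed rows only would
          # regress on the truncated upper tail and bias the intercept
          z <- cbind(1, x[, pred, drop = FALSE])
          pen <- diag(c(0, rep(ridge * n, length(pred))))
          beta <- solve(crossprod(z) + pen, crossprod(z, x[, j]))
          fitted <- drop(z %*% beta)
          s_res <- max(sd(x[, j] - fitted), 1e-3)
          x[mask[, j], j] <- rtruncnorm_upper(sum(mask[, j]),
                                              fitted[mask[, j]], s_res,
                                              mins[j])
        }
      }
    }
    x
  })

  m <- table$intensities
  m[mask] <- 2^x_imp[mask]
  set_intensities(table, m)
}
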