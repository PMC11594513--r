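#' Free-parameter count of a k-component univariate normal mixture
#'
#' `K = 3k - 1`: k means, k standard deviations, and k - 1 free mixing
#' weights (they sum to one). So k = 1, 2, 3 give K = 2, 5, 8.
#'
#' @param k number of mixture components, >= 1.
#' @return integer parameter count.
#' @export
count_params <- function(k) {
  if (any(k < 1)) stop("k must be >= 1")
  as.integer(3 * k - 1)
}

#' Akaike information criterion
#'
#' `AIC = 2K - 2 logL` (natural log).
#'
#' @param log_likelihood maximised log-likelihood in nats.
#' @param K number of free parameters.
#' @return criterion value; lower is better.
#' @export
aic <- function(log_likelihood, K) {
  stopifnot(is.finite(log_likelihood), is.finite(K))
  2 * K - 2 * log_likelihood
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2K(K + 1)/(n - K - 1)`; the correction vanishes as
#' `n -> infinity` and is undefined for `n <= K + 1`.
#'
#' @param log_likelihood maximised log-likelihood in nats.
#' @param K number of free parameters.
#' @param n sample size; must exceed `K + 1`.
#' @return criterion value; lower is better.
#' @export
aicc <- function(log_likelihood, K, n) {
  if (n <= K + 1) {
    stop("AICc undefined for n <= K + 1 (n = ", n, ", K = ", K, ")")
  }
  aic(log_likelihood, K) + 2 * K * (K + 1) / (n - K - 1)
}

#' Bayesian information criterion
#'
#' `BIC = K ln(n) - 2 logL` with the exact natural logarithm.
#'
#' @param log_likelihood maximised log-likelihood in nats.
#' @param K number of free parameters.
#' @param n sample size, >= 1.
#' @return criterion value; lower is better.
#' @export
bic <- function(log_likelihood, K, n) {
  stopifnot(n >= 1)
  K * log(n) - 2 * log_likelihood
}

#' Build a selection table and pick the best k per criterion
#'
#' Given one fitted mixture per candidate k (all on the same data), tabulates
#' K, AIC, AICc and BIC per k and selects the argmin of AICc and of BIC.
#' Ties are broken toward smaller k (parsimony).
#'
#' @param fits list of `gmm_fit` objects covering `k = 1..k_max` with no
#'   gaps, all fitted to the same sample.
#' @return list with `records` (data.frame: `k`, `K`, `n`,
#'   `log_likelihood`, `aic`, `aicc`, `bic`, `best_aicc`, `best_bic`),
#'   `best_k_aicc` and `best_k_bic`.
#' @export
select_model <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fit")
  ks <- unname(vapply(fits, function(f) f$k, integer(1L)))
  fits <- fits[order(ks)]
  ks <- sort(ks)
  if (!identical(ks, seq_len(length(ks)))) {
    stop("fits must cover k = 1..k_max with no gaps; got k = {",
         paste(ks, collapse = ", "), "}")
  }
  ns <- unname(vapply(fits, function(f) f$n, integer(1L)))
  if (length(unique(ns)) != 1L) {
    stop("all fits must be on the same sample (n differs: ",
         paste(ns, collapse = ", "), ")")
  }
  n <- ns[1L]
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1L))
  K <- count_params(ks)
  rec <- data.frame(
    k = ks, K = K, n = n, log_likelihood = ll,
    aic = aic_vec(ll, K),
    aicc = mapply(aicc, ll, K, MoreArgs = list(n = n)),
    bic = mapply(bic, ll, K, MoreArgs = list(n = n))
  )
  # which.min returns the first minimum; rows are ordered by k, so ties
  # already resolve toward the simpler model
  best_aicc <- rec$k[which.min(rec$aicc)]
  best_bic <- rec$k[which.min(rec$bic)]
  rec$best_aicc <- rec$k == best_aicc
  rec$best_bic <- rec$k == best_bic
  list(records = rec, best_k_aicc = best_aicc, best_k_bic = best_bic)
}

aic_vec <- function(ll, K) mapply(aic, ll, K)

#' Complexity-penalty table for the three criteria
#'
#' The penalty (criterion value at `logL = 0`) for each requested parameter
#' count at one sample size: `2K` for AIC, `2K + 2K(K+1)/(n-K-1)` for AICc
#' and `K ln n` for BIC.
#'
#' @param n sample size (default 300).
#' @param K vector of parameter counts (default `c(2, 5, 8)`, the counts of
#'   1-, 2- and 3-component univariate normal mixtures).
#' @return data.frame with columns `K`, `aic_penalty`, `aicc_penalty`,
#'   `bic_penalty`.
#' @export
criteria_demo <- function(n = 300, K = c(2, 5, 8)) {
  data.frame(
    K = K,
    aic_penalty = vapply(K, function(k) aic(0, k), numeric(1L)),
    aicc_penalty = vapply(K, function(k) aicc(0, k, n), numeric(1L)),
    bic_penalty = vapply(K, function(k) bic(0, k, n), numeric(1L))
  )
}
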