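# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::quantile) so they can catch shared
# mistakes.

# type-7 quantile by hand: linear interpolation between order statistics
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
}

oracle_iqr_kept <- function(x, multiplier = 1.5) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  iqr <- q3 - q1
  x[x >= q1 - multiplier * iqr & x <= q3 + multiplier * iqr]
}

# naive direct-summation mixture log-likelihood (no log-sum-exp)
oracle_loglik <- function(x, w, mu, sd) {
  sum(log(vapply(x, function(xi) sum(w * dnorm(xi, mu, sd)), numeric(1))))
}

# seeded draw from a two-component normal mixture
rmix2 <- function(n, p1, mu, sd, seed) {
  set.seed(seed)
  comp <- 1L + (runif(n) >= p1)
  rnorm(n, mu[comp], sd[comp])
}

# small long-format grain data.frame builder
make_records <- function(weights_by_head, cultivar = "GW",
                         seeding_rate = 150, wah = 4L) {
  do.call(rbind, lapply(names(weights_by_head), function(h) {
    data.frame(cultivar = cultivar, seeding_rate = seeding_rate, wah = wah,
               head_id = h, weight = weights_by_head[[h]],
               stringsAsFactors = FALSE)
  }))
}

write_temp_csv <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}
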