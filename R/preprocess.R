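#' Keep the heaviest heads of one treatment group
#'
#' Ranks heads (spikes) by the total weight of their threshed grains and
#' returns every grain belonging to the `n_heads` heads with the largest
#' totals. This mirrors the common field practice of measuring only the
#' heaviest few heads per plot so that distributions are comparable across
#' treatments. Ties in total weight are broken by head identifier so the
#' selection is deterministic and invariant to input row order.
#'
#' @param records data.frame of grain records from a single group.
#' @param n_heads number of heads to keep (default 5).
#' @return the subset of `records` belonging to the selected heads, input
#'   row order preserved.
#' @export
select_heaviest_heads <- function(records, n_heads = 5) {
  totals <- tapply(records$weight, records$head_id, sum)
  if (length(totals) < n_heads) {
    grp <- unique(group_label(records$cultivar, records$seeding_rate,
                              records$wah))
    stop("group ", paste(grp, collapse = ","), " has only ", length(totals),
         " head(s); need at least ", n_heads)
  }
  ord <- order(-unname(totals), names(totals))
  keep <- names(totals)[ord][seq_len(n_heads)]
  records[records$head_id %in% keep, , drop = FALSE]
}

#' Remove outliers by the interquartile-range rule
#'
#' Flags values outside `[Q1 - m*IQR, Q3 + m*IQR]` as outliers, where
#' `IQR = Q3 - Q1` and `m` defaults to the conventional 1.5. Quartiles use
#' linear interpolation between order statistics (`stats::quantile`
#' type 7, the default of mainstream statistics environments); the
#' estimator is configurable because the bounds depend on it.
#'
#' @param weights numeric vector, at least 4 values (quartiles are unstable
#'   below that).
#' @param multiplier IQR multiplier (default 1.5).
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return list with `kept`, `removed` (partitioning the input, order
#'   preserved), and `bounds` (the lower/upper fences).
#' @export
iqr_filter <- function(weights, multiplier = 1.5, type = 7) {
  if (length(weights) < 4L) {
    stop("iqr_filter needs at least 4 values, got ", length(weights))
  }
  q <- stats::quantile(weights, probs = c(0.25, 0.75), names = FALSE,
                       type = type)
  iqr <- q[2L] - q[1L]
  bounds <- c(lower = q[1L] - multiplier * iqr,
              upper = q[2L] + multiplier * iqr)
  inside <- weights >= bounds[1L] & weights <= bounds[2L]
  list(kept = weights[inside], removed = weights[!inside], bounds = bounds)
}

#' Min-max scale a sample to [0, 1]
#'
#' Order-preserving affine map sending the minimum to 0 and the maximum
#' to 1, used to overlay distribution shapes from groups with different
#' locations and spreads.
#'
#' @param weights numeric vector with at least 2 values and `max > min`.
#' @return numeric vector in `[0, 1]`.
#' @export
min_max_scale <- function(weights) {
  if (length(weights) < 2L) {
    stop("min_max_scale needs at least 2 values")
  }
  rng <- range(weights)
  if (rng[1L] == rng[2L]) {
    stop("min_max_scale undefined for constant input (zero range)")
  }
  (weights - rng[1L]) / (rng[2L] - rng[1L])
}

#' Descriptive summary of a weight sample
#'
#' @param weights numeric vector, at least 2 values.
#' @return one-row data.frame with `mean`, `sd` (sample, n-1 denominator),
#'   `max`, `min` and `n`.
#' @export
describe_weights <- function(weights) {
  if (length(weights) < 2L) {
    stop("describe_weights needs at least 2 values")
  }
  data.frame(mean = mean(weights), sd = stats::sd(weights),
             max = max(weights), min = min(weights),
             n = length(weights))
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] returning the pieces the
#' pipeline reports per group. Grain-weight distributions close to harvest
#' are typically left-skewed or bimodal, so small p-values are the norm.
#'
#' @param weights numeric vector with 3 to 5000 values (the supported range
#'   of the W statistic).
#' @return one-row data.frame with `w_statistic`, `p_value` and `n`.
#' @export
check_normality <- function(weights) {
  n <- length(weights)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk test supports 3 <= n <= 5000, got n = ", n)
  }
  sw <- stats::shapiro.test(weights)
  data.frame(w_statistic = unname(sw$statistic),
             p_value = sw$p.value, n = n)
}
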