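# internal helpers shared across modules

#' Run code with a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores whatever `.Random.seed` was in
#' place before, so library calls never perturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive n reproducible child seeds from one parent seed (all < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# log-sum-exp over rows of a matrix, guarding against -Inf rows
row_logsumexp <- function(m) {
  mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric check used by validators
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
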