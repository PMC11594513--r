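#' Parameters of a univariate Gaussian mixture
#'
#' Constructs and validates the parameter set of a k-component univariate
#' normal mixture: mixing weights summing to one, component means (mg) and
#' component standard deviations (mg).
#'
#' @param weights mixing proportions, each in (0, 1], summing to 1.
#' @param means component means.
#' @param sds component standard deviations, all > 0.
#' @return object of class `gmm_params` with elements `k`, `weights`,
#'   `means`, `sds`.
#' @export
gmm_params <- function(weights, means, sds) {
  weights <- as.numeric(weights)
  means <- as.numeric(means)
  sds <- as.numeric(sds)
  k <- length(means)
  if (k < 1L) stop("a mixture needs at least one component")
  if (length(weights) != k || length(sds) != k) {
    stop("weights, means and sds must all have length k = ", k)
  }
  if (any(!is.finite(weights)) || any(!is.finite(means)) ||
      any(!is.finite(sds))) {
    stop("mixture parameters must be finite")
  }
  if (any(weights <= 0) || any(weights > 1)) {
    stop("mixing weights must lie in (0, 1]")
  }
  if (abs(sum(weights) - 1) >= 1e-9) {
    stop("mixing weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  if (any(sds <= 0)) stop("component sds must be > 0")
  structure(list(k = k, weights = weights, means = means, sds = sds),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat("Gaussian mixture, k =", x$k, "\n")
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Normal probability density
#'
#' Density of one mixture component, `exp(-(x-mu)^2/(2 sigma^2)) /
#' (sigma sqrt(2 pi))`, in units of 1/mg when `x` is in mg.
#'
#' @param x evaluation point(s).
#' @param mu mean.
#' @param sigma standard deviation, > 0.
#' @return density value(s), strictly positive.
#' @export
gaussian_pdf <- function(x, mu, sigma) {
  if (!is_number(sigma) || sigma <= 0) stop("sigma must be > 0")
  stats::dnorm(x, mean = mu, sd = sigma)
}

# n x k matrix of log(pi_j) + log N(x_i | mu_j, sd_j)
component_log_density <- function(x, params) {
  n <- length(x)
  k <- params$k
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    out[, j] <- log(params$weights[j]) +
      stats::dnorm(x, params$means[j], params$sds[j], log = TRUE)
  }
  out
}

#' Mixture probability density
#'
#' `p(x) = sum_j pi_j N(x | mu_j, sigma_j)`; strictly positive and
#' integrating to one over the real line.
#'
#' @param x evaluation point(s).
#' @param params a [gmm_params()] object.
#' @return density value(s).
#' @export
mixture_pdf <- function(x, params) {
  stopifnot(inherits(params, "gmm_params"))
  exp(row_logsumexp(component_log_density(x, params)))
}

#' E-step: posterior component responsibilities
#'
#' For each data point, the posterior probability of having been generated
#' by each component (Bayes' rule over the weighted component densities).
#' Computed in log space with log-sum-exp stabilisation so no row can
#' underflow to all zeros.
#'
#' @param x numeric data vector.
#' @param params a [gmm_params()] object.
#' @return `length(x)` x `k` matrix with rows summing to 1.
#' @export
e_step <- function(x, params) {
  stopifnot(inherits(params, "gmm_params"), length(x) >= 1L)
  ld <- component_log_density(x, params)
  lse <- row_logsumexp(ld)
  if (any(!is.finite(lse))) {
    stop("a data point has zero density under every component")
  }
  exp(ld - lse)
}

#' M-step: weight/mean/variance updates from responsibilities
#'
#' Standard maximum-likelihood updates: `pi_j` is the mean responsibility,
#' `mu_j` the responsibility-weighted mean, and `sigma_j^2` the
#' responsibility-weighted variance with the same `sum_i r_ij` denominator
#' (the 1/n-type MLE convention, matching the likelihood EM maximises).
#'
#' @param x numeric data vector.
#' @param responsibilities n x k matrix with rows summing to 1.
#' @param sd_floor lower bound applied to each component sd, guarding
#'   against point-mass collapse (default 0 = no floor).
#' @return a [gmm_params()] object.
#' @export
m_step <- function(x, responsibilities, sd_floor = 0) {
  r <- as.matrix(responsibilities)
  n <- length(x)
  if (nrow(r) != n) stop("responsibility rows must match data length")
  if (any(abs(rowSums(r) - 1) > 1e-6)) {
    stop("responsibility rows must sum to 1")
  }
  nj <- colSums(r)
  if (any(nj <= n * 1e-12)) {
    stop("degenerate component: effective mass ~ 0")
  }
  w <- nj / n
  mu <- colSums(r * x) / nj
  k <- ncol(r)
  sq <- (matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE))^2
  sig <- sqrt(colSums(r * sq) / nj)
  sig <- pmax(sig, sd_floor)
  if (any(sig <= 0)) stop("degenerate component: zero variance")
  gmm_params(w, mu, sig)
}

#' Mixture log-likelihood
#'
#' `sum_i log p(x_i)` in nats, computed via log-sum-exp.
#'
#' @param x numeric data vector.
#' @param params a [gmm_params()] object.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(x, params) {
  stopifnot(inherits(params, "gmm_params"), length(x) >= 1L)
  sum(row_logsumexp(component_log_density(x, params)))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' For `k = 1` the maximum-likelihood fit is closed form (sample mean and
#' 1/n-variance) and no iteration is performed. For `k >= 2` the model is
#' fitted by expectation-maximisation with a deterministic restart scheme:
#' restart 0 seeds component `j` at the `(j - 0.5)/k` sample quantile with
#' the global (MLE) standard deviation and equal weights; restarts
#' `1..n_restarts-1` perturb those means with seeded Gaussian noise scaled
#' by the global sd. The best log-likelihood across non-degenerate restarts
#' wins. Components are always reported sorted by mean ascending, so the
#' returned labelling never depends on initialisation.
#'
#' @param x numeric data vector; needs `length(x) >= 3 * k`.
#' @param k number of components, >= 1.
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-8).
#' @param max_iter iteration cap per restart (default 1000).
#' @param n_restarts number of EM starts for `k >= 2` (default 10).
#' @param seed integer seed controlling the restart perturbations; the fit
#'   is fully deterministic given `seed`.
#' @return object of class `gmm_fit`: `params` (mean-sorted
#'   [gmm_params()]), `log_likelihood`, `responsibilities` (columns in the
#'   sorted component order), `n_iter`, `converged`, `n`, `k`, `seed`,
#'   `restart` (index of the winning start, 0-based) and `ll_trace` (the
#'   per-iteration log-likelihood path of the winning start).
#'
#' @details A component sd is floored at `1e-4` times the data range; a
#'   restart whose floored component also has weight below `1e-3` is
#'   discarded as degenerate. If every restart degenerates the fit errors
#'   out with per-restart diagnostics.
#' @export
fit_em <- function(x, k, tol = 1e-8, max_iter = 1000L, n_restarts = 10L,
                   seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (k < 1L) stop("k must be >= 1")
  if (n < 3L * k) {
    stop("need at least 3*k = ", 3L * k, " observations for k = ", k,
         " components, got ", n)
  }

  if (k == 1L) {
    mu <- mean(x)
    sig <- sqrt(mean((x - mu)^2))
    if (sig <= 0) stop("data has zero variance; cannot fit a density")
    params <- gmm_params(1, mu, sig)
    ll <- log_likelihood(x, params)
    return(structure(list(params = params, log_likelihood = ll,
                          responsibilities = matrix(1, n, 1L),
                          n_iter = 0L, converged = TRUE, n = n, k = 1L,
                          seed = as.integer(seed), restart = 0L,
                          ll_trace = ll),
                     class = "gmm_fit"))
  }

  if (diff(range(x)) <= 0) {
    stop("data has zero range; cannot fit ", k, " components")
  }
  # EM runs on the standardised sample, which makes the whole fit exactly
  # translation/scale equivariant and keeps the floor/tolerances on a
  # scale-free footing; parameters are mapped back afterwards
  m0 <- mean(x)
  s0 <- sqrt(mean((x - m0)^2))
  z <- (x - m0) / s0
  sd_floor <- 1e-4 * diff(range(z))
  q0 <- stats::quantile(z, probs = (seq_len(k) - 0.5) / k, names = FALSE,
                        type = 7)
  restart_seeds <- derive_seeds(seed, n_restarts)

  best <- NULL
  diagnostics <- character(n_restarts)
  for (r in seq_len(n_restarts)) {
    means0 <- if (r == 1L) q0 else {
      q0 + with_seed(restart_seeds[r], stats::rnorm(k, sd = 0.5))
    }
    run <- em_single_run(z, k, means0, 1, tol, max_iter, sd_floor)
    if (!is.null(run$error)) {
      diagnostics[r] <- run$error
      next
    }
    diagnostics[r] <- sprintf("logL = %.6f after %d iter", run$ll, run$n_iter)
    if (is.null(best) || run$ll > best$ll) {
      best <- run
      best$restart <- r - 1L
    }
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " EM restarts degenerated:\n  ",
         paste(sprintf("restart %d: %s", seq_len(n_restarts) - 1L,
                       diagnostics), collapse = "\n  "))
  }

  ord <- order(best$params$means)
  params <- gmm_params(best$params$weights[ord],
                       m0 + s0 * best$params$means[ord],
                       s0 * best$params$sds[ord])
  shift <- n * log(s0)
  structure(list(params = params, log_likelihood = best$ll - shift,
                 responsibilities = best$resp[, ord, drop = FALSE],
                 n_iter = best$n_iter, converged = best$converged,
                 n = n, k = as.integer(k), seed = as.integer(seed),
                 restart = best$restart, ll_trace = best$trace - shift),
            class = "gmm_fit")
}

# one EM run from a fixed initialisation; returns NULL-error list on
# success. Inlined (no per-iteration validation) for speed: the public
# e_step()/m_step() implement the same updates with full checking.
em_single_run <- function(x, k, means0, sd0, tol, max_iter, sd_floor) {
  n <- length(x)
  w <- rep(1 / k, k)
  mu <- as.numeric(means0)
  sig <- rep(max(sd0, sd_floor), k)
  log_dens <- function() {
    vapply(seq_len(k),
           function(j) log(w[j]) + stats::dnorm(x, mu[j], sig[j], log = TRUE),
           numeric(n))
  }
  ld <- log_dens()
  lse <- row_logsumexp(ld)
  ll_prev <- sum(lse)
  trace <- ll_prev
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    resp <- exp(ld - lse)
    nj <- colSums(resp)
    if (any(nj <= n * 1e-12)) {
      return(list(error = sprintf(
        "degenerate component at iteration %d (effective mass ~ 0)", it)))
    }
    w <- nj / n
    mu <- colSums(resp * x) / nj
    sq <- (matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE))^2
    sig <- pmax(sqrt(colSums(resp * sq) / nj), sd_floor)
    if (any(sig <= sd_floor * (1 + 1e-12) & w < 1e-3)) {
      return(list(error = sprintf(
        "component collapsed at iteration %d (sd at floor, weight < 1e-3)",
        it)))
    }
    ld <- log_dens()
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (ll < ll_prev - 1e-8) {
      return(list(error = sprintf(
        "log-likelihood decreased at iteration %d (%.10f -> %.10f)",
        it, ll_prev, ll)))
    }
    if (abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  list(error = NULL, params = gmm_params(w, mu, sig), ll = ll_prev,
       resp = exp(ld - lse), n_iter = it, converged = converged,
       trace = trace)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("GMM fit: k = %d, n = %d, logL = %.3f, %s in %d iteration(s)\n",
              x$k, x$n, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$params)
  invisible(x)
}

#' Evaluate fitted density curves on a grid
#'
#' Produces the table behind a density-overlay figure: the total mixture
#' density plus each component both pi-scaled (so components stack to the
#' total) and unscaled (each integrating to one on its own).
#'
#' @param params a [gmm_params()] object or a `gmm_fit`.
#' @param from,to grid limits; default to the component means +/- 4 sds.
#' @param n number of grid points (default 512).
#' @return data.frame with columns `x`, `density`,
#'   `component<j>_scaled`, `component<j>` for each component `j`.
#' @export
density_curve <- function(params, from = NULL, to = NULL, n = 512) {
  if (inherits(params, "gmm_fit")) params <- params$params
  stopifnot(inherits(params, "gmm_params"))
  from <- from %||% min(params$means - 4 * params$sds)
  to <- to %||% max(params$means + 4 * params$sds)
  grid <- seq(from, to, length.out = n)
  out <- data.frame(x = grid, density = mixture_pdf(grid, params))
  for (j in seq_len(params$k)) {
    comp <- gaussian_pdf(grid, params$means[j], params$sds[j])
    out[[sprintf("component%d_scaled", j)]] <- params$weights[j] * comp
    out[[sprintf("component%d", j)]] <- comp
  }
  out
}
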