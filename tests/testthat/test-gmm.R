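test_that("component and mixture densities evaluate correctly", {
  expect_equal(gaussian_pdf(0, 0, 1), 0.3989423, tolerance = 1e-6)
  # the peak height is 1/(sigma sqrt(2 pi)) regardless of the mean
  expect_equal(gaussian_pdf(57.2, 57.2, 4.1), 1 / (4.1 * sqrt(2 * pi)))
  expect_equal(gaussian_pdf(49, 57.2, 4.1), 0.01317, tolerance = 1e-3)
  expect_error(gaussian_pdf(0, 0, 0), "sigma")
  expect_error(gaussian_pdf(0, 0, -1), "sigma")

  # k = 1 mixture reduces to the single component density
  p1 <- gmm_params(1, 40, 5)
  x <- seq(20, 60, by = 2.5)
  expect_equal(mixture_pdf(x, p1), gaussian_pdf(x, 40, 5))

  # symmetric equal-weight mixture at the midpoint
  psym <- gmm_params(c(0.5, 0.5), c(-1, 1), c(1, 1))
  expect_equal(mixture_pdf(0, psym), dnorm(1), tolerance = 1e-12)

  # two-component parameters typical of a near-harvest distribution,
  # checked against a naive direct-summation oracle
  p <- gmm_params(c(0.5, 0.5), c(41.1, 57.2), c(11.4, 4.1))
  expect_equal(mixture_pdf(49, p), 0.02035, tolerance = 1e-3)
  expect_equal(mixture_pdf(x, p),
               vapply(x, function(xi)
                 sum(p$weights * dnorm(xi, p$means, p$sds)), numeric(1)),
               tolerance = 1e-12)
})

test_that("mixture density integrates to one", {
  p <- gmm_params(c(0.3, 0.6, 0.1), c(15, 40, 55), c(3, 8, 2))
  lo <- min(p$means - 12 * p$sds)
  hi <- max(p$means + 12 * p$sds)
  area <- integrate(function(x) mixture_pdf(x, p), lo, hi,
                    rel.tol = 1e-9)$value
  expect_equal(area, 1, tolerance = 1e-6)
})

test_that("parameter container enforces mixture invariants", {
  expect_error(gmm_params(c(0.5, 0.6), c(1, 2), c(1, 1)), "sum to 1")
  expect_error(gmm_params(c(0.5, 0.5), c(1, 2), c(1, -1)), "sds")
  expect_error(gmm_params(c(0.5, 0.5), c(1, 2), 1), "length")
  expect_error(gmm_params(numeric(0), numeric(0), numeric(0)),
               "at least one")
})

test_that("E-step responsibilities follow Bayes' rule and normalise", {
  psym <- gmm_params(c(0.5, 0.5), c(-2, 2), c(1, 1))
  expect_equal(as.numeric(e_step(0, psym)), c(0.5, 0.5))

  # far-separated components: the near one takes all the mass
  pfar <- gmm_params(c(0.5, 0.5), c(0, 20), c(1, 1))
  expect_gt(e_step(0, pfar)[1, 1], 1 - 1e-10)

  p <- gmm_params(c(0.5, 0.5), c(41.1, 57.2), c(11.4, 4.1))
  expect_equal(as.numeric(e_step(49, p)), c(0.676, 0.324), tolerance = 1e-3)

  set.seed(8)
  r <- e_step(rnorm(200, 45, 12), p)
  expect_equal(rowSums(r), rep(1, 200), tolerance = 1e-9)
})

test_that("M-step recovers weighted means and MLE variances", {
  # hard 0/1 responsibilities reduce to per-cluster moments
  x <- c(1, 2, 3, 10, 12)
  r <- cbind(c(1, 1, 1, 0, 0), c(0, 0, 0, 1, 1))
  p <- m_step(x, r)
  expect_equal(p$means, c(2, 11))
  expect_equal(p$sds, c(sqrt(mean((1:3 - 2)^2)), 1))
  expect_equal(p$weights, c(0.6, 0.4))

  # uniform responsibilities give every component the global moments
  runi <- matrix(0.5, 5, 2)
  puni <- m_step(x, runi)
  expect_equal(puni$means, rep(mean(x), 2))
  expect_equal(puni$sds, rep(sqrt(mean((x - mean(x))^2)), 2))

  # one E-step + M-step on a separable toy keeps the cluster means
  toy <- c(1, 2, 9, 10)
  r1 <- e_step(toy, gmm_params(c(0.5, 0.5), c(1.5, 9.5), c(1, 1)))
  p1 <- m_step(toy, r1)
  expect_equal(p1$means, c(1.5, 9.5), tolerance = 1e-3)

  expect_error(m_step(x, cbind(rep(1, 5), rep(1, 5))), "sum to 1")
})

test_that("log-likelihood matches a direct-summation oracle", {
  p0 <- gmm_params(1, 0, 1)
  expect_equal(log_likelihood(0, p0), log(dnorm(0)))
  expect_equal(log_likelihood(0, p0), -0.9189385, tolerance = 1e-7)

  p <- gmm_params(c(0.5, 0.5), c(41.1, 57.2), c(11.4, 4.1))
  set.seed(21)
  x <- rnorm(10, 48, 10)
  expect_equal(log_likelihood(x, p),
               oracle_loglik(x, p$weights, p$means, p$sds),
               tolerance = 1e-10)

  # additivity: duplicating every point doubles the log-likelihood
  expect_equal(log_likelihood(c(x, x), p), 2 * log_likelihood(x, p),
               tolerance = 1e-12)
})

test_that("k = 1 fits are the closed-form normal MLE", {
  f <- fit_em(c(2, 4, 6), 1)
  expect_equal(f$params$means, 4)
  expect_equal(f$params$sds^2, 8 / 3)
  expect_equal(f$log_likelihood,
               sum(dnorm(c(2, 4, 6), 4, sqrt(8 / 3), log = TRUE)))
  expect_equal(f$n_iter, 0L)
  expect_true(f$converged)
})

test_that("EM separates tight clusters and is deterministic given a seed", {
  x <- c(0, 0.1, 0.2, 100, 100.1, 100.2)
  f <- fit_em(x, 2, seed = 7)
  expect_equal(f$params$means, c(0.1, 100.1), tolerance = 1e-6)
  expect_equal(f$params$weights, c(0.5, 0.5), tolerance = 1e-6)

  g <- fit_em(x, 2, seed = 7)
  expect_identical(f$params, g$params)
  expect_identical(f$log_likelihood, g$log_likelihood)

  expect_error(fit_em(x, 3), "at least 3\\*k")
  expect_error(fit_em(rep(5, 10), 2), "zero range")
})

test_that("EM satisfies its structural invariants", {
  x <- rmix2(400, 0.6, mu = c(30, 55), sd = c(6, 5), seed = 13)
  for (k in 2:3) {
    f <- fit_em(x, k, seed = 2)
    # monotone log-likelihood path
    expect_true(all(diff(f$ll_trace) >= -1e-8))
    # normalisation
    expect_equal(sum(f$params$weights), 1, tolerance = 1e-9)
    expect_equal(rowSums(f$responsibilities), rep(1, length(x)),
                 tolerance = 1e-9)
    # mean-sorted component report
    expect_true(!is.unsorted(f$params$means))
    expect_equal(f$n, length(x))
  }
})

test_that("EM fits are translation/scale equivariant", {
  x <- rmix2(300, 0.5, mu = c(20, 40), sd = c(4, 3), seed = 17)
  a <- 2.5
  b <- 7
  f0 <- fit_em(x, 2, seed = 4)
  f1 <- fit_em(a * x + b, 2, seed = 4)
  expect_equal(f1$params$means, a * f0$params$means + b, tolerance = 1e-6)
  expect_equal(f1$params$sds, a * f0$params$sds, tolerance = 1e-6)
  expect_equal(f1$params$weights, f0$params$weights, tolerance = 1e-6)
  expect_equal(f1$log_likelihood,
               f0$log_likelihood - length(x) * log(a), tolerance = 1e-8)
})

test_that("EM log-likelihood matches an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  x <- rmix2(500, 0.5, mu = c(30, 60), sd = c(5, 5), seed = 23)
  f <- fit_em(x, 2, seed = 1)
  m <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f$log_likelihood, m$loglik, tolerance = 1e-4)
  expect_equal(f$params$means, sort(as.numeric(m$parameters$mean)),
               tolerance = 0.05)
})

test_that("density curves stack pi-scaled components to the total", {
  p <- gmm_params(c(0.4, 0.6), c(30, 50), c(5, 4))
  dc <- density_curve(p, from = 10, to = 70, n = 101)
  expect_equal(nrow(dc), 101)
  expect_equal(dc$density,
               dc$component1_scaled + dc$component2_scaled,
               tolerance = 1e-12)
  expect_equal(dc$component1_scaled, 0.4 * dc$component1, tolerance = 1e-12)
})
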