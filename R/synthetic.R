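#' Define a simulation scenario for one treatment group
#'
#' A scenario specifies the true two-component normal mixture for one
#' (cultivar, seeding rate, weeks-after-heading) cell, plus the sampling
#' design around it: how many heads are sampled, how many grains each head
#' carries, a small lognormal head-level weight multiplier (so "heaviest
#' heads" is a meaningful selection), and a rate of gross outliers.
#'
#' @param cultivar cultivar code (e.g. `"GW"`).
#' @param seeding_rate seeding rate in kg seed/ha.
#' @param wah weeks after heading (integer >= 0).
#' @param p1 mixing weight of the first component, in `[0, 1]`.
#' @param mu1,sd1 mean and sd (mg) of the first component.
#' @param mu2,sd2 mean and sd (mg) of the second component.
#' @param n_heads heads sampled per group (default 60).
#' @param heads_selected heads the downstream analysis keeps (default 5);
#'   recorded in the manifest, not applied here.
#' @param grains_range inclusive range of grains per head
#'   (default `c(47, 82)`).
#' @param outlier_rate fraction of grains replaced by uniform extreme
#'   values (default 0.01).
#' @param head_sd sd of the lognormal head-level multiplier on the log
#'   scale (default 0.05).
#' @return object of class `group_scenario`.
#' @export
group_scenario <- function(cultivar, seeding_rate, wah, p1, mu1, sd1,
                           mu2, sd2, n_heads = 60L, heads_selected = 5L,
                           grains_range = c(47L, 82L), outlier_rate = 0.01,
                           head_sd = 0.05) {
  if (!is_number(p1) || p1 < 0 || p1 > 1) stop("p1 must lie in [0, 1]")
  if (sd1 <= 0 || sd2 <= 0) stop("component sds must be > 0")
  if (mu1 <= 0 || mu2 <= 0) stop("component means must be > 0 mg")
  if (n_heads < 1L) stop("n_heads must be >= 1")
  if (grains_range[1L] < 1L || grains_range[2L] < grains_range[1L]) {
    stop("grains_range must be an increasing range with min >= 1")
  }
  if (outlier_rate < 0 || outlier_rate >= 1) {
    stop("outlier_rate must lie in [0, 1)")
  }
  structure(list(
    cultivar = as.character(cultivar),
    seeding_rate = as.numeric(seeding_rate),
    wah = as.integer(wah),
    p1 = p1, mu1 = mu1, sd1 = sd1, mu2 = mu2, sd2 = sd2,
    n_heads = as.integer(n_heads),
    heads_selected = as.integer(heads_selected),
    grains_range = as.integer(grains_range),
    outlier_rate = outlier_rate, head_sd = head_sd
  ), class = "group_scenario")
}

# closed-form moments of the scenario's two-component mixture
scenario_moments <- function(sc) {
  w <- c(sc$p1, 1 - sc$p1)
  mu <- c(sc$mu1, sc$mu2)
  sd <- c(sc$sd1, sc$sd2)
  m <- sum(w * mu)
  v <- sum(w * (sd^2 + mu^2)) - m^2
  list(mean = m, var = v, sd = sqrt(v))
}

#' Simulate the grains of one treatment group
#'
#' For each head the grain count is drawn uniformly from the configured
#' range; each grain weight is a draw from the two-component normal mixture
#' (non-positive draws are redrawn, not clipped, so no point mass forms at
#' zero), multiplied by the head's lognormal multiplier. A configured
#' fraction of grains is then replaced by uniform extremes 5-8 mixture sds
#' from the mixture mean, emulating gross measurement errors that the IQR
#' filter is meant to catch.
#'
#' @param scenario a [group_scenario()].
#' @param seed integer seed; the output is identical for identical seeds.
#' @return list with `records` (a grain data.frame as returned by
#'   [read_grain_table()]) and `manifest` (every true parameter, the seed,
#'   per-head counts and the injected outlier count).
#' @export
simulate_group <- function(scenario, seed) {
  stopifnot(inherits(scenario, "group_scenario"))
  sc <- scenario
  mom <- scenario_moments(sc)
  with_seed(seed, {
    count_pool <- seq.int(sc$grains_range[1L], sc$grains_range[2L])
    counts <- count_pool[sample.int(length(count_pool), sc$n_heads,
                                    replace = TRUE)]
    mult <- stats::rlnorm(sc$n_heads, meanlog = 0, sdlog = sc$head_sd)
    weights <- numeric(0)
    head_ids <- character(0)
    n_outliers <- 0L
    for (h in seq_len(sc$n_heads)) {
      m <- counts[h]
      comp <- 1L + (stats::runif(m) >= sc$p1)
      mus <- c(sc$mu1, sc$mu2)[comp]
      sds <- c(sc$sd1, sc$sd2)[comp]
      w <- stats::rnorm(m, mus, sds)
      while (any(w <= 0)) {
        bad <- w <= 0
        w[bad] <- stats::rnorm(sum(bad), mus[bad], sds[bad])
      }
      w <- w * mult[h]
      if (sc$outlier_rate > 0) {
        is_out <- stats::runif(m) < sc$outlier_rate
        if (any(is_out)) {
          n_out <- sum(is_out)
          extreme <- mom$mean +
            sample(c(-1, 1), n_out, replace = TRUE) *
              stats::runif(n_out, 5, 8) * mom$sd
          while (any(extreme <= 0)) {
            bad <- extreme <= 0
            extreme[bad] <- mom$mean +
              stats::runif(sum(bad), 5, 8) * mom$sd
          }
          w[is_out] <- extreme
          n_outliers <- n_outliers + n_out
        }
      }
      weights <- c(weights, w)
      head_ids <- c(head_ids, rep(sprintf("h%02d", h), m))
    }
    records <- data.frame(
      cultivar = sc$cultivar,
      seeding_rate = sc$seeding_rate,
      wah = sc$wah,
      head_id = head_ids,
      weight = weights,
      stringsAsFactors = FALSE
    )
    validate_grain_records(records)
    manifest <- c(unclass(sc), list(
      seed = as.integer(seed),
      n_records = nrow(records),
      grains_per_head = as.integer(counts),
      n_outliers_injected = n_outliers,
      mixture_mean = mom$mean,
      mixture_sd = mom$sd
    ))
    list(records = records, manifest = manifest)
  })
}

#' Simulate a full multi-group study and write it to disk
#'
#' Draws every scenario with its own child seed (derived reproducibly from
#' `seed`), concatenates the groups into one long-format CSV readable by
#' [read_grain_table()], and writes a JSON manifest of the true parameters
#' next to it.
#'
#' @param scenarios list of [group_scenario()] objects with unique
#'   (cultivar, seeding_rate, wah) keys.
#' @param path output CSV path.
#' @param seed integer master seed.
#' @param manifest_path path for the JSON manifest (default
#'   `paste0(path, ".manifest.json")`).
#' @return invisibly, a list with `path`, `manifest_path`, `records` and
#'   the per-group `manifests`.
#' @export
simulate_study <- function(scenarios, path, seed,
                           manifest_path = paste0(path, ".manifest.json")) {
  if (length(scenarios) < 1L) stop("need at least one scenario")
  keys <- vapply(scenarios, function(s)
    group_label(s$cultivar, s$seeding_rate, s$wah), character(1L))
  if (anyDuplicated(keys)) {
    stop("duplicate group key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  child <- derive_seeds(seed, length(scenarios))
  sims <- Map(simulate_group, scenarios, child)
  records <- do.call(rbind, lapply(sims, `[[`, "records"))
  rownames(records) <- NULL
  utils::write.table(records, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  manifests <- stats::setNames(lapply(sims, `[[`, "manifest"), keys)
  jsonlite::write_json(
    list(master_seed = as.integer(seed), n_groups = length(scenarios),
         groups = manifests),
    manifest_path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(path = path, manifest_path = manifest_path,
                 records = records, manifests = manifests))
}

#' Default study scenarios: 3 cultivars x 3 seeding rates x 4 sampling times
#'
#' Thirty-six scenarios emulating a triticale grain-filling study. The 4-
#' and 5-weeks-after-heading cells use two-component mixtures with the
#' spread of separations (6.2 to 27.1 mg between component means) typical
#' of near-harvest grain-weight distributions; the 2- and 3-week cells are
#' narrower, mildly bimodal mixtures whose overall mean and sd follow the
#' rightward-drifting, broadening trajectory of grain filling (means rising
#' from roughly 12-17 mg at 2 weeks to 45-52 mg at 5 weeks while the sd
#' grows from about 3-6 mg to 9-13 mg).
#'
#' @param ... overrides passed to every [group_scenario()] (e.g.
#'   `outlier_rate = 0`).
#' @return list of 36 [group_scenario()] objects.
#' @export
default_scenarios <- function(...) {
  # near-harvest cells: explicit two-component parameters
  late <- list(
    # cultivar, wah, rate, p1, mu1, sd1, mu2, sd2
    list("GW", 4L, 150, 0.54, 34.3, 6.6, 49.1, 5.1),
    list("GW", 4L, 225, 0.65, 39.0, 7.7, 52.6, 4.1),
    list("GW", 4L, 300, 0.46, 35.4, 9.1, 49.5, 5.1),
    list("GW", 5L, 150, 0.27, 42.0, 9.9, 55.0, 6.8),
    list("GW", 5L, 225, 0.70, 48.8, 11.4, 60.1, 3.6),
    list("GW", 5L, 300, 0.50, 41.1, 11.4, 57.2, 4.1),
    list("MP", 4L, 150, 0.36, 32.1, 8.1, 47.0, 5.4),
    list("MP", 4L, 225, 0.44, 33.9, 8.4, 49.4, 5.1),
    list("MP", 4L, 300, 0.44, 35.3, 8.0, 46.3, 4.9),
    list("MP", 5L, 150, 0.30, 34.6, 9.0, 53.3, 6.9),
    list("MP", 5L, 225, 0.10, 26.5, 5.5, 53.6, 10.1),
    list("MP", 5L, 300, 0.24, 35.1, 7.1, 53.5, 7.5),
    list("SY", 4L, 150, 0.68, 37.0, 8.9, 43.2, 4.0),
    list("SY", 4L, 225, 0.46, 33.1, 7.7, 42.9, 5.6),
    list("SY", 4L, 300, 0.03, 26.3, 1.4, 40.4, 6.0),
    list("SY", 5L, 150, 0.33, 37.1, 7.9, 53.7, 6.1),
    list("SY", 5L, 225, 0.45, 41.9, 8.6, 54.1, 4.6),
    list("SY", 5L, 300, 0.18, 29.9, 7.0, 48.5, 7.7)
  )
  # early cells: overall (mean, sd) targets; components placed at
  # mean -/+ 0.8 sd with sds 0.6 sd and equal weights, which reproduces
  # the target mean exactly and the target sd to within 1%
  early <- list(
    list("GW", 2L, 150, 15.1, 5.1), list("GW", 2L, 225, 17.2, 4.0),
    list("GW", 2L, 300, 14.0, 6.1), list("GW", 3L, 150, 39.0, 6.0),
    list("GW", 3L, 225, 29.4, 6.7), list("GW", 3L, 300, 35.2, 8.1),
    list("MP", 2L, 150, 15.7, 4.9), list("MP", 2L, 225, 14.3, 4.2),
    list("MP", 2L, 300, 15.6, 4.0), list("MP", 3L, 150, 34.4, 8.5),
    list("MP", 3L, 225, 28.0, 7.0), list("MP", 3L, 300, 30.0, 7.4),
    list("SY", 2L, 150, 12.1, 3.5), list("SY", 2L, 225, 12.1, 3.0),
    list("SY", 2L, 300, 14.9, 4.0), list("SY", 3L, 150, 27.6, 5.4),
    list("SY", 3L, 225, 26.0, 5.4), list("SY", 3L, 300, 28.5, 7.1)
  )
  out <- c(
    lapply(early, function(e) {
      m <- e[[4L]]; s <- e[[5L]]
      group_scenario(e[[1L]], e[[3L]], e[[2L]], p1 = 0.5,
                     mu1 = m - 0.8 * s, sd1 = 0.6 * s,
                     mu2 = m + 0.8 * s, sd2 = 0.6 * s, ...)
    }),
    lapply(late, function(l) {
      group_scenario(l[[1L]], l[[3L]], l[[2L]], p1 = l[[4L]],
                     mu1 = l[[5L]], sd1 = l[[6L]],
                     mu2 = l[[7L]], sd2 = l[[8L]], ...)
    })
  )
  keys <- vapply(out, function(s)
    group_label(s$cultivar, s$seeding_rate, s$wah), character(1L))
  out[order(keys)]
}
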