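#' Configuration for a full grain-weight mixture analysis
#'
#' Collects every knob of the pipeline in one validated object. Defaults
#' follow common practice for this analysis: 5 heaviest heads per group,
#' the 1.5x IQR outlier fence, candidate mixtures up to k = 3, and a
#' 512-point density grid spanning the data range plus 5%.
#'
#' @param input path to the long-format grain CSV/TSV.
#' @param output_dir directory for the result bundle (created if absent).
#' @param column_map optional column remapping for [read_grain_table()].
#' @param n_heads heaviest heads kept per group (default 5).
#' @param iqr_multiplier IQR fence multiplier (default 1.5).
#' @param k_max largest number of mixture components tried (default 3).
#' @param tol,max_iter,n_restarts,seed EM settings, see [fit_em()].
#' @param grid_size points in exported density curves (default 512).
#' @param bins histogram bin count recorded for plotting convenience
#'   (default 30); all statistics are computed on raw weights, never on
#'   binned data.
#' @param digits decimal places in output CSVs (default 3).
#' @param fail_fast stop at the first failing group instead of recording
#'   the error and continuing (default `FALSE`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, column_map = NULL,
                            n_heads = 5L, iqr_multiplier = 1.5,
                            k_max = 3L, tol = 1e-8, max_iter = 1000L,
                            n_restarts = 10L, seed = 1L, grid_size = 512L,
                            bins = 30L, digits = 3L, fail_fast = FALSE) {
  num <- c(n_heads = n_heads, iqr_multiplier = iqr_multiplier,
           k_max = k_max, tol = tol, max_iter = max_iter,
           n_restarts = n_restarts, grid_size = grid_size, bins = bins,
           digits = digits)
  if (any(num <= 0)) {
    stop("non-positive setting(s): ",
         paste(names(num)[num <= 0], collapse = ", "))
  }
  if (k_max < 1L) stop("k_max must be >= 1")
  structure(list(input = input, output_dir = output_dir,
                 column_map = column_map, n_heads = as.integer(n_heads),
                 iqr_multiplier = iqr_multiplier, k_max = as.integer(k_max),
                 tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), grid_size = as.integer(grid_size),
                 bins = as.integer(bins), digits = as.integer(digits),
                 fail_fast = isTRUE(fail_fast)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads the YAML, applies any `...` overrides on top (command-line flags
#' take precedence over the file), and validates via [pipeline_config()].
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @param ... overrides.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

#' Two-component report of a fitted mixture
#'
#' Formats a k = 2 fit the way component tables are usually printed:
#' components sorted by mean ascending, each with mean, sd and proportion,
#' plus the (non-negative) difference between the two component means.
#'
#' @param fit a `gmm_fit` with `k = 2`.
#' @return one-row data.frame: `mean_low`, `sd_low`, `prop_low`,
#'   `mean_high`, `sd_high`, `prop_high`, `mean_diff`.
#' @export
report_k2_components <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (fit$k != 2L) stop("component report requires a k = 2 fit, got k = ",
                        fit$k)
  p <- fit$params
  ord <- order(p$means)  # fits are already sorted; enforce the contract
  data.frame(mean_low = p$means[ord[1L]], sd_low = p$sds[ord[1L]],
             prop_low = p$weights[ord[1L]],
             mean_high = p$means[ord[2L]], sd_high = p$sds[ord[2L]],
             prop_high = p$weights[ord[2L]],
             mean_diff = p$means[ord[2L]] - p$means[ord[1L]])
}

#' Run the full grain-weight mixture analysis
#'
#' Per treatment group: select the heaviest heads, remove IQR outliers,
#' fit mixtures with k = 1..k_max, compute AIC/AICc/BIC, select the best k
#' per criterion, and export descriptive, normality, selection and k = 2
#' component tables plus density curves (raw scale for every k, and a
#' kernel density of the min-max scaled sample for shape comparison).
#' Groups failing a precondition are recorded and skipped unless
#' `fail_fast`. All randomness flows from `config$seed` via per-group
#' child seeds, and outputs carry no timestamps, so reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the bundle: `descriptives`, `normality`, `selection`,
#'   `components_k2` (data.frames), `fits` (per group, per k), `errors`
#'   (named list of failure messages) and `output_dir`.
#'
#' @section Output files:
#' `descriptives.csv`, `normality.csv`, `selection.csv`,
#' `components_k2.csv`, `density/<group>_k<k>.csv`,
#' `density_scaled/<group>.csv`, `run_manifest.json`, `run_log.txt`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$output_dir, "density"), showWarnings = FALSE)
  dir.create(file.path(config$output_dir, "density_scaled"),
             showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  records <- read_grain_table(config$input, column_map = config$column_map)
  groups <- split_groups(records)
  say("input: %s (%d grains, %d groups)", config$input, nrow(records),
      length(groups))
  say("settings: n_heads=%d iqr_multiplier=%g k_max=%d n_restarts=%d seed=%d",
      config$n_heads, config$iqr_multiplier, config$k_max,
      config$n_restarts, config$seed)

  group_seeds <- derive_seeds(config$seed, length(groups))
  desc <- list(); norm <- list(); sel <- list(); comp <- list()
  fits_all <- list(); errors <- list(); group_meta <- list()

  for (i in seq_along(groups)) {
    gname <- names(groups)[i]
    g <- groups[[i]]
    res <- tryCatch(
      analyze_group(g, gname, config, group_seeds[i], say),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      say("group %s: FAILED (%s)", gname, msg)
      errors[[gname]] <- msg
      if (config$fail_fast) {
        stop("group ", gname, " failed: ", msg)
      }
      next
    }
    desc[[gname]] <- res$descriptive
    norm[[gname]] <- res$normality
    sel[[gname]] <- res$selection
    if (!is.null(res$components)) comp[[gname]] <- res$components
    fits_all[[gname]] <- res$fits
    group_meta[[gname]] <- res$meta
  }

  if (!length(desc)) stop("every group failed; nothing to report")

  bundle <- list(
    descriptives = do.call(rbind, c(desc, list(make.row.names = FALSE))),
    normality = do.call(rbind, c(norm, list(make.row.names = FALSE))),
    selection = do.call(rbind, c(sel, list(make.row.names = FALSE))),
    components_k2 = if (length(comp))
      do.call(rbind, c(comp, list(make.row.names = FALSE))) else NULL,
    fits = fits_all, errors = errors, output_dir = config$output_dir
  )
  d <- config$digits
  write_result_table(bundle$descriptives,
                     file.path(config$output_dir, "descriptives.csv"), d)
  write_result_table(bundle$normality,
                     file.path(config$output_dir, "normality.csv"), d)
  write_result_table(bundle$selection,
                     file.path(config$output_dir, "selection.csv"), d)
  if (!is.null(bundle$components_k2)) {
    write_result_table(bundle$components_k2,
                       file.path(config$output_dir, "components_k2.csv"), d)
  } else {
    say("k_max = %d < 2: no k = 2 component report emitted", config$k_max)
  }

  manifest <- list(
    seed = config$seed,
    settings = unclass(config)[c("n_heads", "iqr_multiplier", "k_max",
                                 "tol", "max_iter", "n_restarts",
                                 "grid_size", "bins", "digits")],
    n_grains_input = nrow(records),
    n_groups = length(groups),
    n_groups_failed = length(errors),
    groups = group_meta,
    failed = errors
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(bundle)
}

# one group: select heads -> IQR filter -> fit k = 1..k_max -> criteria
analyze_group <- function(g, gname, config, seed, say) {
  n_raw <- nrow(g)
  picked <- select_heaviest_heads(g, n_heads = config$n_heads)
  filt <- iqr_filter(picked$weight, multiplier = config$iqr_multiplier)
  w <- filt$kept
  say("group %s: %d grains, %d after head selection, %d after IQR filter (%d removed), fit seed %d",
      gname, n_raw, nrow(picked), length(w), length(filt$removed), seed)

  key <- g[1L, c("cultivar", "seeding_rate", "wah")]
  desc <- cbind(key, describe_weights(w), row.names = NULL)
  nrm <- cbind(key, check_normality(w), row.names = NULL)

  fits <- lapply(seq_len(config$k_max), function(k)
    fit_em(w, k, tol = config$tol, max_iter = config$max_iter,
           n_restarts = config$n_restarts, seed = seed))
  names(fits) <- paste0("k", seq_len(config$k_max))
  selection <- select_model(fits)
  sel <- cbind(key, selection$records, row.names = NULL)

  components <- NULL
  if (config$k_max >= 2L) {
    components <- cbind(key, report_k2_components(fits[["k2"]]),
                        row.names = NULL)
  }

  # density exports: raw-scale mixture curves per k, kernel density of the
  # min-max scaled sample for shape comparison across groups
  pad <- 0.05 * diff(range(w))
  for (k in seq_len(config$k_max)) {
    curve <- density_curve(fits[[k]], from = min(w) - pad, to = max(w) + pad,
                           n = config$grid_size)
    write_result_table(curve,
                       file.path(config$output_dir, "density",
                                 sprintf("%s_k%d.csv", gname, k)),
                       digits = 6)
  }
  scaled <- min_max_scale(w)
  kd <- stats::density(scaled, n = config$grid_size)
  write_result_table(data.frame(x = kd$x, density = kd$y),
                     file.path(config$output_dir, "density_scaled",
                               sprintf("%s.csv", gname)),
                     digits = 6)

  meta <- list(
    group = gname, fit_seed = as.integer(seed),
    n_raw = n_raw, n_selected = nrow(picked), n_filtered = length(w),
    n_outliers_removed = length(filt$removed),
    best_k_aicc = selection$best_k_aicc,
    best_k_bic = selection$best_k_bic,
    em = lapply(fits, function(f)
      list(k = f$k, log_likelihood = f$log_likelihood, n_iter = f$n_iter,
           converged = f$converged, restart = f$restart))
  )
  list(descriptive = desc, normality = nrm, selection = sel,
       components = components, fits = fits, meta = meta)
}
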