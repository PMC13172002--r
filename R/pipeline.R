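#' Default pipeline configuration
#'
#' All tunables in one structured list: cohort size and seed, population
#' overrides, the binned reference distribution (shares and bin
#' representatives), the CPT presets run in the sensitivity stage, the RLS
#' methods, and the quantile rule for the aversion summaries. The master
#' seed drives every stage through derived sub-seeds.
#'
#' @param ... Named overrides.
#' @return Configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n = 300,
    seed = 1,
    population = list(),
    respondents_csv = NULL,     # read instead of simulating when set
    distribution_csv = NULL,    # read instead of using `shares` when set
    shares = c(0.06, 0.10, 0.50, 0.34),
    representative_ls = c(2, 5.5, 7.5, 9.5),
    cpt_presets = c("median", "extreme"),
    rls_methods = c("mean_utility", "median_participant"),
    quantile_type = 8,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

# FNV-1a over the deparsed config: a content fingerprint for run logs.
# The output location is not part of the scientific configuration.
.config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256  # xor touches only the low byte since b < 256
    h <- ((h - low + bitwXor(as.integer(low), as.integer(b))) *
            16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end: simulate (or read) the cohort, validate
#' responses, elicit indifference points / aversion measures / utility
#' curves, fit per-participant discrete-choice models, rerun elicitation
#' under each CPT weighting preset, and compute the RLS table. Outputs are
#' deterministic given the configuration; every artifact records the config
#' hash and seed. Stage results are returned in one list and, when
#' `out_dir` is set, also written as CSV/JSON artifacts.
#'
#' @param config List from [pipeline_config()].
#' @return List with elements `config_hash`, `seed`, `respondents`,
#'   `ground_truth`, `validation`, `elicited`, `lambda_summary`, `fits`,
#'   `fit_summary`, `residuals`, `sensitivity` (per preset: elicited points,
#'   lambda summary, RLS table), `distribution`, `rls`, and `log` (retention
#'   counts at each filter).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  hash <- .config_hash(cfg)

  if (!is.null(cfg$respondents_csv)) {
    respondents <- read_respondents(cfg$respondents_csv)
    ground_truth <- NULL
  } else {
    sim <- simulate_cohort(cfg$n, do.call(cohort_population, cfg$population),
                           seed = cfg$seed)
    respondents <- sim$respondents
    ground_truth <- sim$ground_truth
  }
  dist <- if (!is.null(cfg$distribution_csv)) {
    read_distribution(cfg$distribution_csv)
  } else {
    binned_ls_distribution(cfg$shares, cfg$representative_ls)
  }

  n0 <- length(respondents)
  analysed <- Filter(function(r) !r$flags$order_violation, respondents)

  elicited <- elicit_cohort(analysed)
  validation <- validate_cohort(analysed, elicited)
  lambda_summary <- summarize_lambda(elicited$points, analysed,
                                     qtype = cfg$quantile_type)
  fits <- fit_cohort(analysed, curves = elicited$curves)
  ok <- Filter(Negate(is.null), fits)
  fit_summary <- data.frame(
    n_fitted = length(ok),
    prop_r2_gt_0.2 = mean(vapply(ok, function(f) f$mcfadden_r2 > 0.2,
                                 logical(1))),
    median_r2 = stats::median(vapply(ok, function(f) f$mcfadden_r2,
                                     numeric(1))),
    median_pct_correct = stats::median(vapply(ok, function(f) f$pct_correct,
                                              numeric(1))),
    prop_converged = mean(vapply(ok, function(f) f$converged, logical(1))))
  obs_all <- do.call(rbind, lapply(analysed, expand_ladders))
  residuals <- residuals_by_probability(fits, obs_all)

  sensitivity <- lapply(cfg$cpt_presets, function(ps) {
    params <- if (is.character(ps)) cpt_preset(ps) else ps
    wel <- weighted_reanalysis(analysed, params)
    list(params = params,
         lambda_summary = summarize_lambda(wel$points, analysed,
                                           qtype = cfg$quantile_type),
         rls = rls_table(wel, analysed, dist, methods = cfg$rls_methods))
  })
  names(sensitivity) <- vapply(cfg$cpt_presets, function(ps)
    if (is.character(ps)) ps else sprintf("d%g_g%g", ps$delta, ps$gamma),
    character(1))

  rls_tab <- rls_table(elicited, analysed, dist, methods = cfg$rls_methods)

  result <- list(
    config_hash = hash, seed = cfg$seed,
    respondents = respondents, ground_truth = ground_truth,
    validation = validation, elicited = elicited,
    lambda_summary = lambda_summary,
    fits = fits, fit_summary = fit_summary, residuals = residuals,
    sensitivity = sensitivity, distribution = dist, rls = rls_tab,
    log = list(n_input = n0, n_order_violation = n0 - length(analysed),
               n_analysed = length(analysed)))

  if (!is.null(cfg$out_dir)) .write_pipeline_artifacts(result, cfg)
  result
}

.write_pipeline_artifacts <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = result$config_hash, seed = result$seed)
  path <- function(f) file.path(cfg$out_dir, f)
  write_respondents(result$respondents, path("respondents.csv"))
  if (!is.null(result$ground_truth)) {
    utils::write.csv(result$ground_truth, path("ground_truth.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(result$lambda_summary, path("lambda_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$rls, path("rls.csv"), row.names = FALSE)
  utils::write.csv(result$residuals, path("residuals.csv"), row.names = FALSE)
  jsonlite::write_json(c(stamp, result$validation, result$log),
                       path("validation.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  curves_json <- lapply(result$elicited$curves, function(cc) {
    lapply(cc, function(ctx) lapply(ctx, function(cv)
      if (is.null(cv)) NULL else as.list(cv$utilities)))
  })
  jsonlite::write_json(c(stamp, list(curves = curves_json)),
                       path("curves.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  sens <- lapply(result$sensitivity, function(s) {
    list(delta = s$params$delta, gamma = s$params$gamma, rls = s$rls)
  })
  jsonlite::write_json(c(stamp, list(sensitivity = sens)),
                       path("sensitivity.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}
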