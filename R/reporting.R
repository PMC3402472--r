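# Scenario-suite configuration and report generation: validated
# structured-text (JSON) run configs, and a driver that ties generation,
# calibration, evaluation, the expansion pathway and the PSA together,
# emitting delimited result tables with a reproducibility log.

#' Read a run configuration
#'
#' @param path path to a JSON run configuration.
#' @return the parsed configuration list (unvalidated).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

#' Validate a run configuration
#'
#' Checks the whole configuration, aggregating every violation with its
#' JSON path; nothing is partially accepted.
#'
#' @param cfg configuration list from [read_run_config()].
#' @return the validated config (with defaults filled), or an error
#'   listing all violations.
#' @export
validate_run_config <- function(cfg) {
  cc <- check_collect()
  num_in <- function(x, lo, hi) is.numeric(x) && length(x) == 1 &&
    !is.na(x) && x >= lo && x <= hi
  if (is.null(cfg$seed) || !num_in(cfg$seed, -2^31, 2^31))
    cc$fail("$.seed: required integer")
  cfg$survey_n <- cfg$survey_n %||% 300
  if (!num_in(cfg$survey_n, 10, 1e6))
    cc$fail("$.survey_n: must be a number in [10, 1e6]")
  cfg$discount <- cfg$discount %||% 0.03
  if (!num_in(cfg$discount, 0, 1))
    cc$fail("$.discount: must be a non-negative rate in [0,1]")
  cfg$metric <- cfg$metric %||% "DALY"
  if (!cfg$metric %in% c("DALY", "QALY"))
    cc$fail("$.metric: must be 'DALY' or 'QALY'")
  cfg$gp_attendance <- cfg$gp_attendance %||% 0.85
  cfg$assessment_participation <- cfg$assessment_participation %||% 0.70
  if (!num_in(cfg$gp_attendance, 0, 1))
    cc$fail("$.gp_attendance: must be in [0,1]")
  if (!num_in(cfg$assessment_participation, 0, 1))
    cc$fail("$.assessment_participation: must be in [0,1]")
  cfg$statin_price <- cfg$statin_price %||% "australia"
  if (!cfg$statin_price %in% c("australia", "nz"))
    cc$fail("$.statin_price: must be 'australia' or 'nz'")
  cfg$psa <- cfg$psa %||% list(enabled = FALSE)
  if (isTRUE(cfg$psa$enabled)) {
    if (is.null(cfg$seed)) cc$fail("$.seed: required when psa.enabled")
    if (is.null(cfg$psa$n_draws) || !num_in(cfg$psa$n_draws, 2, 1e6))
      cc$fail("$.psa.n_draws: required integer >= 2 when psa.enabled")
  }
  cfg$expansion <- cfg$expansion %||% list(enabled = FALSE)
  if (isTRUE(cfg$expansion$enabled)) {
    cfg$expansion$threshold <- cfg$expansion$threshold %||% 50000
    if (!num_in(cfg$expansion$threshold, 0, Inf))
      cc$fail("$.expansion.threshold: must be a non-negative number")
  }
  lib_names <- names(builtin_intervention_library())
  if (!is.null(cfg$scenarios)) {
    for (i in seq_along(cfg$scenarios)) {
      sc <- cfg$scenarios[[i]]
      if (is.null(sc$label))
        cc$fail(sprintf("$.scenarios[%d].label: required", i))
      for (j in seq_along(sc$components)) {
        ref <- sc$components[[j]]$ref
        if (is.null(ref) || !ref %in% lib_names)
          cc$fail(sprintf("$.scenarios[%d].components[%d].ref: unknown intervention '%s'",
                          i, j, ref %||% "<missing>"))
      }
    }
  }
  cc$raise("invalid run configuration")
  cfg
}

#' Run a configured scenario suite
#'
#' Builds the model context from the configured synthetic world and
#' evaluates each configured scenario against the do-nothing comparator,
#' optionally with a PSA, the expansion pathway and the acceptability
#' frontier. Writes delimited tables and a log to `out_dir`. Two runs with
#' the same configuration are bit-identical.
#'
#' @param cfg validated configuration.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the computed objects.
#' @export
run_scenario_suite <- function(cfg, out_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  demog <- demography_spec(survey_n = cfg$survey_n)
  ctx <- build_model_context(
    demog = demog, discount = cfg$discount, metric = cfg$metric,
    gp_attendance = cfg$gp_attendance,
    assessment_participation = cfg$assessment_participation,
    seed = cfg$seed)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  scenarios <- lapply(cfg$scenarios %||% list(), function(sc)
    cea_scenario(sc$label, sc$components, statin_price = cfg$statin_price))
  names(scenarios) <- vapply(scenarios, function(s) s$label, character(1))
  det <- do.call(rbind, lapply(scenarios, function(s) {
    o <- evaluate_vs_null(s, ctx)
    data.frame(scenario = s$label, health_gain = o$health_gain,
               cost_gov = o$cost_gov, cost_patient = o$cost_patient,
               treatment_costs_averted = o$treatment_costs_averted,
               net_cost = o$net_cost, icer = o$icer,
               classification = o$classification,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(det)) {
    rownames(det) <- NULL
    tsv(det, "scenarios_vs_null.tsv")
  }
  psa <- frontier <- path <- NULL
  if (isTRUE(cfg$psa$enabled) && length(scenarios) > 0) {
    psa <- run_psa(scenarios, ctx, n_draws = cfg$psa$n_draws,
                   seed = cfg$seed)
    tsv(psa$summary, "psa_summary.tsv")
    frontier <- acceptability_frontier(psa)
    tsv(frontier, "acceptability_frontier.tsv")
  }
  if (isTRUE(cfg$expansion$enabled)) {
    path <- expansion_path(default_candidates(ctx$lib), ctx,
                           threshold = cfg$expansion$threshold,
                           statin_price = cfg$statin_price)
    tsv(path$steps, "expansion_path.tsv")
    tsv(path$skipped, "expansion_skipped.tsv")
  }
  log_lines <- c(
    sprintf("cvdcea %s", as.character(utils::packageVersion("cvdcea"))),
    sprintf("seed: %d", as.integer(cfg$seed)),
    sprintf("survey_n: %d", as.integer(cfg$survey_n)),
    sprintf("discount: %g", cfg$discount),
    sprintf("metric: %s", cfg$metric),
    sprintf("statin_price: %s", cfg$statin_price),
    sprintf("reach: %g", ctx$reach),
    sprintf("psa: %s (n_draws: %s)", isTRUE(cfg$psa$enabled),
            cfg$psa$n_draws %||% "-"),
    sprintf("expansion: %s (threshold: %s)", isTRUE(cfg$expansion$enabled),
            cfg$expansion$threshold %||% "-"),
    sprintf("config switches: cf_trend=%s half_cycle=%s unrelated_cost=%g",
            ctx$config$cf_trend, ctx$config$half_cycle,
            ctx$config$unrelated_cost_per_ly))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(ctx = ctx, deterministic = det, psa = psa,
                 frontier = frontier, path = path))
}
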