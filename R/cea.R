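# Generalized cost-effectiveness analysis: every strategy (including
# current practice) is evaluated against a back-calculated 'do nothing'
# counterfactual; interventions are then added greedily in order of
# incremental cost-effectiveness to trace the expansion pathway, with
# Monte Carlo uncertainty propagated to 95% uncertainty intervals and a
# cost-effectiveness acceptability frontier.

#' Assemble the full model context
#'
#' Builds everything a scenario evaluation needs: the calibrated risk
#' engine, risk strata scaled to population counts, the simulation cells
#' (one per age band x sex x risk band), primary-care reach, the current
#' practice scenario, and the back-calculated do-nothing epidemiology.
#'
#' @param survey a `cvd_survey` (or NULL to generate one from `demog`).
#' @param epi observed `cvd_epidemiology`.
#' @param demog a [demography_spec()].
#' @param lib intervention library (default [builtin_intervention_library()]).
#' @param eq risk equation.
#' @param bands risk band specification.
#' @param weights health-state weights.
#' @param dcosts disease treatment cost table.
#' @param discount annual discount rate.
#' @param metric `"DALY"` or `"QALY"`.
#' @param gp_attendance,assessment_participation primary-care reach inputs
#'   (see [primary_care_coverage()]).
#' @param current_practice list of current-practice components (see
#'   [cea_scenario()]); NULL for the built-in default mix.
#' @param config a [model_config()].
#' @param k conversion constants.
#' @param sodium_model sodium-blood pressure slopes.
#' @param seed seed for survey generation when `survey` is NULL.
#' @return a `cvd_model_context` list.
#' @export
build_model_context <- function(survey = NULL, epi = generate_epidemiology(),
                                demog = demography_spec(),
                                lib = builtin_intervention_library(),
                                eq = risk_equation(),
                                bands = risk_band_spec(),
                                weights = health_state_weights(),
                                dcosts = disease_cost_table(),
                                discount = 0.03, metric = "DALY",
                                gp_attendance = 0.85,
                                assessment_participation = 0.70,
                                current_practice = NULL,
                                config = model_config(),
                                k = conversion_constants(),
                                sodium_model = sodium_bp_model(),
                                seed = 1) {
  if (is.null(survey)) survey <- generate_survey(demog, seed = seed)
  cal <- calibrate_risk(survey, eq, epi)
  strata <- stratify(survey, eq, cal, bands)
  eligible <- survey[!survey$prior_cvd, ]
  base_key <- paste(eligible$band, eligible$sex)
  sbp_cell <- tapply(eligible$sbp, base_key, mean)
  cells <- strata[strata$eligible_count > 0, ]
  dem_key <- paste(demog$band, demog$sex)
  cells$population <- demog$population[match(paste(cells$band, cells$sex),
                                             dem_key)] *
    cells$eligible_fraction
  bandsdf <- age_band_frame(35, 85)
  cells$entry_age <- bandsdf$age_mid[match(cells$band, bandsdf$band)]
  cells$baseline_sbp <- sbp_cell[paste(cells$band, cells$sex)]
  cells <- as.data.frame(cells)[, c("band", "sex", "risk_band",
                                    "entry_age", "population",
                                    "mean_relative_risk", "baseline_sbp")]
  names(cells)[names(cells) == "mean_relative_risk"] <- "rel_risk"
  rownames(cells) <- NULL
  reach <- primary_care_coverage(gp_attendance, assessment_participation)
  if (is.null(current_practice)) {
    current_practice <- list(
      list(ref = "voluntary_salt"),
      list(ref = "bp_current", bands = c("5-9", "10-14", "ge15"),
           uptake = 0.35),
      list(ref = "lipid_current", bands = c("5-9", "10-14", "ge15"),
           uptake = 0.25),
      list(ref = "dietary_advice", bands = c("5-9", "10-14", "ge15"),
           uptake = 0.20)
    )
  }
  ctx <- list(survey = survey, epi_observed = epi, demog = demog, lib = lib,
              eq = eq, cal = cal, bands = bands, strata = strata,
              cells = cells, weights = weights, dcosts = dcosts,
              discount = discount, metric = metric, reach = reach,
              config = config, k = k, sodium_model = sodium_model,
              current_practice = current_practice,
              cache = new.env(parent = emptyenv()))
  cp <- cea_scenario("Current practice", current_practice)
  ctx$rr_bar <- average_effective_rr(cp, ctx)
  ctx$null_epi <- backcalculate_null(epi, ctx$rr_bar)
  class(ctx) <- "cvd_model_context"
  ctx
}

#' Define an evaluation scenario
#'
#' A scenario is a set of intervention components, each targeting risk
#' bands, plus economic settings.
#'
#' @param label scenario name.
#' @param components list of components, each `list(ref=, bands=, uptake=)`:
#'   `ref` an intervention library name (or a `cvd_intervention` object),
#'   `bands` the targeted risk bands (defaults to the intervention's own),
#'   `uptake` an optional override of the uptake fraction.
#' @param statin_price `"australia"` or `"nz"` — applies the alternative
#'   price to any component with price scenarios.
#' @param discount,metric,trend optional overrides of the context settings.
#' @return a `cvd_scenario`.
#' @export
cea_scenario <- function(label, components = list(),
                         statin_price = "australia",
                         discount = NULL, metric = NULL, trend = TRUE) {
  comps <- lapply(components, function(cmp) {
    if (inherits(cmp, "cvd_intervention")) cmp <- list(ref = cmp)
    stopifnot(!is.null(cmp$ref))
    if (!is.null(cmp$bands)) cmp$bands <- unlist(cmp$bands)
    cmp
  })
  keys <- vapply(comps, function(cmp) {
    nm <- if (is.character(cmp$ref)) cmp$ref else cmp$ref$name
    paste(nm, paste(cmp$bands %||% "default", collapse = "+"))
  }, character(1))
  if (anyDuplicated(keys))
    stopf("scenario '%s': duplicate intervention/band pair", label)
  structure(list(label = label, components = comps,
                 statin_price = statin_price, discount = discount,
                 metric = metric, trend = trend),
            class = "cvd_scenario")
}

resolve_component <- function(cmp, lib, statin_price = "australia") {
  iv <- if (is.character(cmp$ref)) {
    if (is.null(lib[[cmp$ref]]))
      stopf("intervention '%s' not in library", cmp$ref)
    lib[[cmp$ref]]
  } else cmp$ref
  if (!is.null(iv$price_scenarios) && statin_price %in%
      names(iv$price_scenarios)) {
    iv$cost_year1 <- iv$price_scenarios[[statin_price]]
    iv$cost_subsequent <- iv$price_scenarios[[statin_price]]
  }
  if (!is.null(cmp$uptake)) iv$uptake <- cmp$uptake
  bands <- cmp$bands %||% iv$target_bands
  list(iv = iv, bands = bands)
}

# Relative-risk vector of one intervention for one simulation cell, with
# risk-factor effects converted to RRs and the long-run effect scale
# applied to the risk-factor change (or, for direct RRs, to the log-scale
# effect via 1 - s(1-rr)).
intervention_cell_rr <- function(iv, cell, ctx) {
  eff <- iv$effect
  s <- iv$effect_scale
  parts <- list()
  if (!is.null(eff$rr)) {
    rr <- as_channel_rr(eff$rr)
    parts <- c(parts, list(1 - s * (1 - rr)))
  }
  if (!is.null(eff$sbp_pct))
    parts <- c(parts, list(rr_from_sbp_pct(eff$sbp_pct * s, ctx$k)))
  if (!is.null(eff$tc_pct))
    parts <- c(parts, list(rr_from_tc_pct(eff$tc_pct * s, ctx$k)))
  if (!is.null(eff$sodium)) {
    delta <- eff$sodium[[cell$sex]] * s
    pct <- sbp_pct_from_sodium(delta, cell$band, cell$sex,
                               ctx$sodium_model, cell$baseline_sbp)
    parts <- c(parts, list(rr_from_sbp_pct(pct, ctx$k)))
  }
  if (length(parts) == 0) stopf("intervention '%s' has no effect", iv$name)
  combine_rrs(parts)
}

# Per-cell, per-year effective RR array and cost matrices for a scenario.
scenario_arrays <- function(scenario, ctx, lib = ctx$lib, n_years = NULL) {
  cells <- ctx$cells
  nc <- nrow(cells)
  if (is.null(n_years))
    n_years <- as.integer(ceiling(ctx$config$age_cap -
                                    min(cells$entry_age))) + 1L
  rr_arr <- array(1, dim = c(nc, n_years, 4))
  cost_gov <- matrix(0, nc, n_years)
  cost_pat <- matrix(0, nc, n_years)
  years <- seq_len(n_years)
  for (cmp in scenario$components) {
    rc <- resolve_component(cmp, lib, scenario$statin_price)
    iv <- rc$iv
    popwide <- iv$delivery == "population_wide"
    in_target <- if (popwide || identical(rc$bands, "all")) rep(TRUE, nc)
    else cells$risk_band %in% rc$bands
    if (!any(in_target)) next
    cov <- if (popwide) 1 else ctx$reach * iv$uptake
    af <- adherent_fraction(iv$adherence, years)
    cost_y <- ifelse(years == 1, cov * iv$cost_year1,
                     cov * iv$cost_subsequent * af)
    idx <- which(in_target)
    for (i in idx) {
      rr <- intervention_cell_rr(iv, cells[i, ], ctx)
      for (ch in 1:4) {
        eff_rr <- 1 - cov * af * (1 - rr[ch])
        rr_arr[i, , ch] <- rr_arr[i, , ch] * eff_rr
      }
      cost_gov[i, ] <- cost_gov[i, ] + cost_y * (1 - iv$patient_share)
      cost_pat[i, ] <- cost_pat[i, ] + cost_y * iv$patient_share
    }
  }
  list(rr = rr_arr, cost_gov = cost_gov, cost_pat = cost_pat,
       n_years = n_years)
}

# Deterministic row lookups into the epidemiology and background-weight
# tables for each cell and cycle; depends only on the band layout, so it
# is computed once per context and reused across scenario evaluations.
cells_lookup <- function(cells, epi, bg, ny) {
  nc <- nrow(cells)
  idx <- vapply(seq_len(ny), function(t)
    epi_row_index(epi, cells$entry_age + t - 1, cells$sex), integer(nc))
  bgd <- vapply(seq_len(ny), function(t)
    bg$background_disability[epi_row_index(bg, cells$entry_age + t - 1,
                                           cells$sex)], numeric(nc))
  list(idx = matrix(idx, nc, ny), bgd = matrix(bgd, nc, ny))
}

# Vectorized Markov totals across all simulation cells: one loop over
# cycles, elementwise over cells. Returns discounted per-cell totals.
simulate_cells <- function(cells, epi, arrays, weights, dcosts, discount,
                           config, lookup = NULL) {
  nc <- nrow(cells)
  ny <- arrays$n_years
  ct <- function(dis, col) dcosts[[col]][dcosts$disease == dis]
  c1i <- ct("ihd", "first_year_cost"); c2i <- ct("ihd", "subsequent_year_cost")
  c1s <- ct("stroke", "first_year_cost")
  c2s <- ct("stroke", "subsequent_year_cost")
  cgi <- ct("gi_bleed", "first_year_cost")
  d <- weights$disability; u <- weights$utility
  bg <- weights$background
  W <- cells$population; I <- numeric(nc); S <- numeric(nc)
  out <- list(ly = 0, daly = 0, qaly = 0, cost_gov = 0, cost_pat = 0,
              cost_disease = 0)
  tot <- matrix(0, nc, 6,
                dimnames = list(NULL, c("ly", "daly", "qaly", "cost_gov",
                                        "cost_pat", "cost_disease")))
  epi_cols <- c("ihd_incidence", "stroke_incidence", "ihd_case_fatality",
                "stroke_case_fatality", "background_mortality", "ihd_trend",
                "stroke_trend", "stroke_haem_fraction", "gi_bleed_incidence")
  epi_vecs <- lapply(epi_cols, function(col) epi[[col]])
  names(epi_vecs) <- epi_cols
  lk <- lookup %||% cells_lookup(cells, epi, bg, ny)
  idx_mat <- lk$idx
  bgd_mat <- lk$bgd
  for (t in seq_len(ny)) {
    age <- cells$entry_age + t - 1
    if (all(age > config$age_cap)) break
    alive <- W + I + S
    if (all(alive <= config$extinction_tol * cells$population)) break
    idx <- idx_mat[, t]
    erow <- lapply(epi_vecs, function(v) v[idx])
    pr <- cycle_probs(erow, t - 1, matrix(arrays$rr[, t, ], nc, 4),
                      cells$rel_risk, config)
    ihd_ev <- W * pr$p_ihd
    str_ev <- W * pr$p_str
    gi_ev <- W * pr$gi_event_prob
    bgd <- bgd_mat[, t]
    df <- 1 / (1 + discount)^(t - 1)
    daly_t <- W * (1 - bgd) * (1 - d[["well"]]) +
      I * (1 - bgd) * (1 - d[["ihd"]]) +
      S * (1 - bgd) * (1 - d[["stroke"]]) -
      gi_ev * (1 - bgd) * (d[["gi_bleed"]] - d[["well"]])
    qaly_t <- W * (1 - bgd) * u[["well"]] + I * (1 - bgd) * u[["ihd"]] +
      S * (1 - bgd) * u[["stroke"]] -
      gi_ev * (1 - bgd) * (u[["well"]] - u[["gi_bleed"]])
    dis_t <- ihd_ev * c1i + I * c2i + str_ev * c1s + S * c2s + gi_ev * cgi +
      config$unrelated_cost_per_ly * alive
    tot[, "ly"] <- tot[, "ly"] + df * alive
    tot[, "daly"] <- tot[, "daly"] + df * daly_t
    tot[, "qaly"] <- tot[, "qaly"] + df * qaly_t
    tot[, "cost_gov"] <- tot[, "cost_gov"] + df * alive * arrays$cost_gov[, t]
    tot[, "cost_pat"] <- tot[, "cost_pat"] + df * alive * arrays$cost_pat[, t]
    tot[, "cost_disease"] <- tot[, "cost_disease"] + df * dis_t
    gi_d <- W * pr$p_gif
    well_bg <- W * pr$p_bg
    ihd_dd <- I * pr$p_ihd_dead
    str_dd <- S * pr$p_str_dead
    Wn <- W - ihd_ev - str_ev - gi_d - well_bg
    I <- I - ihd_dd + ihd_ev * (1 - pr$cf_i)
    S <- S - str_dd + str_ev * (1 - pr$cf_s)
    W <- Wn
  }
  colSums(tot)
}

#' Evaluate a scenario's absolute totals (from the do-nothing rates)
#'
#' Simulates all eligible cells under the back-calculated do-nothing
#' epidemiology with the scenario's effective relative risks and costs,
#' returning discounted totals.
#'
#' @param scenario a [cea_scenario()].
#' @param ctx a [build_model_context()].
#' @param lib optional intervention library override (used by the PSA to
#'   inject parameter draws).
#' @return named vector of discounted totals.
#' @export
evaluate_scenario <- function(scenario, ctx, lib = ctx$lib) {
  arrays <- scenario_arrays(scenario, ctx, lib)
  epi <- ctx$null_epi
  if (!isTRUE(scenario$trend)) {
    epi$ihd_trend <- 1
    epi$stroke_trend <- 1
  }
  key <- sprintf("lookup_%d", arrays$n_years)
  if (is.null(ctx$cache[[key]]))
    ctx$cache[[key]] <- cells_lookup(ctx$cells, epi,
                                     ctx$weights$background,
                                     arrays$n_years)
  simulate_cells(ctx$cells, epi, arrays, ctx$weights, ctx$dcosts,
                 scenario$discount %||% ctx$discount, ctx$config,
                 lookup = ctx$cache[[key]])
}

null_totals <- function(ctx, discount, trend = TRUE) {
  key <- sprintf("null_%g_%d", discount, as.integer(trend))
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  scn <- cea_scenario("Do nothing", list(), discount = discount,
                      trend = trend)
  ctx$cache[[key]] <- evaluate_scenario(scn, ctx)
  ctx$cache[[key]]
}

#' Evaluate a scenario against the do-nothing comparator
#'
#' Health gain is the difference in discounted health-adjusted life years
#' (DALY framework by default); costs are split into intervention costs to
#' government and patients and disease treatment costs averted (reported
#' negative). A strategy that saves money while improving health is
#' classified Dominant; positive net cost with non-positive gain is
#' flagged dominated rather than raising an error.
#'
#' @param scenario a [cea_scenario()].
#' @param ctx model context.
#' @param lib optional library override.
#' @return a `cvd_cea_outcome` list with `health_gain`, `cost_gov`,
#'   `cost_patient`, `treatment_costs_averted`, `net_cost`, `icer`,
#'   `classification`.
#' @export
evaluate_vs_null <- function(scenario, ctx, lib = ctx$lib) {
  disc <- scenario$discount %||% ctx$discount
  metric <- tolower(scenario$metric %||% ctx$metric)
  t1 <- evaluate_scenario(scenario, ctx, lib)
  t0 <- null_totals(ctx, disc, isTRUE(scenario$trend))
  outcome_from_totals(t1, t0, metric, label = scenario$label)
}

outcome_from_totals <- function(t1, t0, metric = "daly", label = "") {
  gain <- t1[[metric]] - t0[[metric]]
  averted <- t1[["cost_disease"]] - t0[["cost_disease"]]
  net <- t1[["cost_gov"]] + t1[["cost_pat"]] + averted
  cls <- if (net < 0 && gain > 0) "dominant"
  else if (gain <= 0 && net >= 0) "dominated"
  else "icer"
  structure(list(label = label, health_gain = unname(gain),
                 cost_gov = unname(t1[["cost_gov"]]),
                 cost_patient = unname(t1[["cost_pat"]]),
                 treatment_costs_averted = unname(averted),
                 net_cost = unname(net),
                 icer = if (cls == "icer") unname(net / gain) else NA_real_,
                 classification = cls,
                 life_years_gained = unname(t1[["ly"]] - t0[["ly"]])),
            class = "cvd_cea_outcome")
}

#' Population-average steady-state effective relative risk of a scenario
#'
#' Averages each channel's effective relative risk (at steady-state
#' adherence, simulation year 2+) over the risk-band cells of each age
#' band and sex, weighted by cell population — the quantity needed to
#' back-calculate do-nothing rates from observed rates.
#'
#' @param scenario a [cea_scenario()] (typically current practice).
#' @param ctx model context (or a list with `cells`, `lib`, `reach`, `k`,
#'   `sodium_model`).
#' @return data frame per (band, sex) with one column per channel.
#' @export
average_effective_rr <- function(scenario, ctx) {
  cells <- ctx$cells
  nc <- nrow(cells)
  eff <- matrix(1, nc, 4, dimnames = list(NULL, cvd_channels()))
  for (cmp in scenario$components) {
    rc <- resolve_component(cmp, ctx$lib, scenario$statin_price)
    iv <- rc$iv
    popwide <- iv$delivery == "population_wide"
    in_target <- if (popwide || identical(rc$bands, "all")) rep(TRUE, nc)
    else cells$risk_band %in% rc$bands
    cov <- if (popwide) 1 else ctx$reach * iv$uptake
    af <- adherent_fraction(iv$adherence, 2)
    for (i in which(in_target)) {
      rr <- intervention_cell_rr(iv, cells[i, ], ctx)
      eff[i, ] <- eff[i, ] * (1 - cov * af * (1 - rr))
    }
  }
  agg_key <- paste(cells$band, cells$sex)
  w <- cells$population
  out <- do.call(rbind, lapply(unique(agg_key), function(kk) {
    sel <- agg_key == kk
    avg <- colSums(eff[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
    data.frame(band = cells$band[sel][1], sex = cells$sex[sel][1],
               t(avg), stringsAsFactors = FALSE)
  }))
  names(out)[3:6] <- cvd_channels()
  rownames(out) <- NULL
  out
}

#' Back-calculate do-nothing disease rates
#'
#' Divides observed incidence by the population-average effective relative
#' risk of current practice, per age band, sex and channel, so that
#' re-applying current practice to the do-nothing rates reproduces the
#' observed rates ("the model reproduces the levels of disease currently
#' observed"). Age bands beyond the observed table reuse its oldest band's
#' average (clamped lookup).
#'
#' @param observed observed `cvd_epidemiology`.
#' @param rr_bar output of [average_effective_rr()].
#' @return a do-nothing `cvd_epidemiology`.
#' @export
backcalculate_null <- function(observed, rr_bar) {
  out <- observed
  hf <- observed$stroke_haem_fraction
  idx <- match(paste(observed$band, observed$sex),
               paste(rr_bar$band, rr_bar$sex))
  if (any(is.na(idx))) {
    # bands older than the demography: reuse the oldest calibrated band
    oldest <- rr_bar[rr_bar$band == rr_bar$band[which.max(
      as.numeric(sub("-.*", "", rr_bar$band)))], ]
    for (j in which(is.na(idx)))
      idx[j] <- match(paste(oldest$band[1], observed$sex[j]),
                      paste(rr_bar$band, rr_bar$sex))
  }
  rr_ihd <- rr_bar$ihd[idx]
  rr_str <- (1 - hf) * rr_bar$stroke_isch[idx] + hf * rr_bar$stroke_haem[idx]
  rr_gi <- rr_bar$gi_bleed[idx]
  if (any(rr_ihd <= 0) || any(rr_str <= 0) || any(rr_gi <= 0))
    stopf("back-calculation: population-average relative risk <= 0")
  out$ihd_incidence <- observed$ihd_incidence / rr_ihd
  out$stroke_incidence <- observed$stroke_incidence / rr_str
  out$gi_bleed_incidence <- observed$gi_bleed_incidence / rr_gi
  out
}

#' Re-apply current practice to do-nothing rates
#'
#' The inverse of [backcalculate_null()]: multiplies do-nothing incidence
#' by the population-average effective relative risks. Used to verify the
#' round-trip reproduces observed rates.
#'
#' @param null_epi do-nothing `cvd_epidemiology`.
#' @param rr_bar output of [average_effective_rr()].
#' @return a `cvd_epidemiology`.
#' @export
apply_average_rr <- function(null_epi, rr_bar) {
  out <- null_epi
  hf <- null_epi$stroke_haem_fraction
  idx <- match(paste(null_epi$band, null_epi$sex),
               paste(rr_bar$band, rr_bar$sex))
  if (any(is.na(idx))) {
    oldest <- rr_bar[rr_bar$band == rr_bar$band[which.max(
      as.numeric(sub("-.*", "", rr_bar$band)))], ]
    for (j in which(is.na(idx)))
      idx[j] <- match(paste(oldest$band[1], null_epi$sex[j]),
                      paste(rr_bar$band, rr_bar$sex))
  }
  out$ihd_incidence <- null_epi$ihd_incidence * rr_bar$ihd[idx]
  out$stroke_incidence <- null_epi$stroke_incidence *
    ((1 - hf) * rr_bar$stroke_isch[idx] + hf * rr_bar$stroke_haem[idx])
  out$gi_bleed_incidence <- null_epi$gi_bleed_incidence * rr_bar$gi_bleed[idx]
  out
}

#' Default mutual-exclusivity groups for the expansion path
#'
#' Each group lists intervention names of which at most `capacity` may
#' enter the package per risk band; further members are skipped and
#' labelled "more cost-effective alternative available". Defaults: at most
#' three of the four blood pressure-lowering drug classes (no fourth BP
#' add-on, so beta-blockers are displaced by diuretic/CCB/ACE inhibitor);
#' one of dietary advice vs the lifestyle program; aspirin evaluated
#' standalone only (capacity 0) because of its bleed harms.
#'
#' @return list of groups.
#' @export
default_exclusivity_groups <- function() {
  list(
    list(name = "bp_drugs", capacity = 3,
         members = c("thiazide", "ccb", "ace_inhibitor", "beta_blocker")),
    list(name = "behaviour", capacity = 1,
         members = c("dietary_advice", "lifestyle_program")),
    list(name = "aspirin", capacity = 0, members = "aspirin")
  )
}

candidate_label <- function(name, bands, lib) {
  iv <- lib[[name]]
  band_lab <- if (identical(bands, "all")) "all risk levels"
  else paste0(paste(bands, collapse = "+"), "% risk")
  sprintf("%s (%s)", iv$name, band_lab)
}

#' Default candidate set for the expansion pathway
#'
#' Every prevention intervention of the built-in library crossed with its
#' target risk bands (population-wide interventions target everyone;
#' primary-care interventions are offered band by band).
#'
#' @param lib intervention library.
#' @return list of `list(name=, bands=)` candidates.
#' @export
default_candidates <- function(lib = builtin_intervention_library()) {
  prevention <- setdiff(names(lib),
                        c("voluntary_salt", "lipid_current", "bp_current"))
  out <- list()
  for (nm in prevention) {
    iv <- lib[[nm]]
    if (iv$delivery == "population_wide") {
      out[[length(out) + 1]] <- list(name = nm, bands = "all")
    } else {
      for (b in c("ge15", "10-14", "5-9"))
        out[[length(out) + 1]] <- list(name = nm, bands = b)
    }
  }
  out
}

#' Greedy expansion pathway (efficiency frontier)
#'
#' Starting from an empty package, repeatedly evaluates every remaining
#' candidate incrementally to the current package (effects combine
#' multiplicatively, so overlapping target populations shrink each
#' addition's residual gain), and adds the candidate with the lowest
#' incremental cost-effectiveness ratio — cost-saving (Dominant)
#' candidates first, ordered by health gain. Candidates whose exclusivity
#' group is at capacity are skipped and labelled. The pathway is cut where
#' the incremental ICER first exceeds the threshold.
#'
#' @param candidates list of `list(name=, bands=)` (see
#'   [default_candidates()]).
#' @param ctx model context.
#' @param exclusivity list of exclusivity groups.
#' @param threshold cost-effectiveness threshold (AUD per unit health).
#' @param statin_price price scenario passed to every evaluation.
#' @param lib optional library override.
#' @return a `cvd_expansion_path` list with `steps` (data frame),
#'   `skipped`, and `threshold_cut`.
#' @export
expansion_path <- function(candidates, ctx,
                           exclusivity = default_exclusivity_groups(),
                           threshold = 50000, statin_price = "australia",
                           lib = ctx$lib) {
  if (length(candidates) == 0) stopf("expansion_path: no candidates")
  metric <- tolower(ctx$metric)
  disc <- ctx$discount
  t0 <- null_totals(ctx, disc)
  selected <- list()
  sel_names_by_band <- list()
  remaining <- candidates
  skipped <- data.frame(label = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  pkg_scn <- function(comps, label = "package")
    cea_scenario(label, comps, statin_price = statin_price)
  pkg_totals <- t0
  cum_gain <- 0; cum_net <- 0
  steps <- list()
  comps_now <- list()
  repeat {
    # drop candidates blocked by exclusivity
    keep <- logical(length(remaining))
    for (j in seq_along(remaining)) {
      cand <- remaining[[j]]
      blocked <- FALSE
      for (g in exclusivity) {
        if (!(cand$name %in% g$members)) next
        n_sel <- sum(vapply(sel_names_by_band[[paste(cand$bands,
                                                     collapse = "+")]] %||%
                              character(0),
                            function(x) x %in% g$members, logical(1)))
        if (g$capacity == 0 || n_sel >= g$capacity) blocked <- TRUE
      }
      if (blocked) {
        skipped <- rbind(skipped, data.frame(
          label = candidate_label(cand$name, cand$bands, lib),
          reason = "more cost-effective alternative available",
          stringsAsFactors = FALSE))
      }
      keep[j] <- !blocked
    }
    remaining <- remaining[keep]
    if (length(remaining) == 0) break
    evals <- lapply(remaining, function(cand) {
      comps <- c(comps_now, list(list(ref = cand$name, bands = cand$bands)))
      t1 <- evaluate_scenario(pkg_scn(comps), ctx, lib)
      outcome_from_totals(t1, pkg_totals, metric)
    })
    gain <- vapply(evals, function(e) e$health_gain, numeric(1))
    net <- vapply(evals, function(e) e$net_cost, numeric(1))
    dominant <- net < 0 & gain > 0
    icer <- ifelse(gain > 0, net / gain, Inf)
    labels <- vapply(remaining, function(cand)
      candidate_label(cand$name, cand$bands, lib), character(1))
    ord <- order(!dominant, ifelse(dominant, -gain, icer), -gain, labels)
    best <- ord[1]
    cand <- remaining[[best]]
    comps_now <- c(comps_now, list(list(ref = cand$name,
                                        bands = cand$bands)))
    pkg_totals_new <- evaluate_scenario(pkg_scn(comps_now), ctx, lib)
    cum_gain <- pkg_totals_new[[metric]] - t0[[metric]]
    cum_net <- (pkg_totals_new[["cost_gov"]] + pkg_totals_new[["cost_pat"]] +
                  pkg_totals_new[["cost_disease"]]) -
      (t0[["cost_gov"]] + t0[["cost_pat"]] + t0[["cost_disease"]])
    pkg_totals <- pkg_totals_new
    steps[[length(steps) + 1]] <- data.frame(
      step = length(steps) + 1L,
      label = labels[best], name = cand$name,
      bands = paste(cand$bands, collapse = "+"),
      inc_health_gain = gain[best], inc_net_cost = net[best],
      inc_icer = ifelse(dominant[best], NA_real_, icer[best]),
      dominant = dominant[best],
      cum_health_gain = cum_gain, cum_net_cost = cum_net,
      stringsAsFactors = FALSE)
    bkey <- paste(cand$bands, collapse = "+")
    sel_names_by_band[[bkey]] <- c(sel_names_by_band[[bkey]], cand$name)
    remaining <- remaining[-best]
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(0), label = character(0),
               dominant = logical(0), inc_icer = numeric(0))
  ok <- steps$dominant | (!is.na(steps$inc_icer) &
                            steps$inc_icer <= threshold)
  threshold_cut <- if (length(ok) == 0) 0L
  else if (all(ok)) nrow(steps) else which(!ok)[1] - 1L
  structure(list(steps = steps, skipped = skipped,
                 threshold_cut = threshold_cut, threshold = threshold,
                 components = comps_now[seq_len(min(length(comps_now),
                                                    nrow(steps)))]),
            class = "cvd_expansion_path")
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of intervention parameter uncertainty: each
#' iteration draws one realisation of the intervention library (shared
#' parameters drawn once) and re-evaluates every scenario against the
#' do-nothing comparator with common random numbers across scenarios.
#'
#' @param scenarios named list of [cea_scenario()].
#' @param ctx model context.
#' @param n_draws number of Monte Carlo iterations (>= 2).
#' @param seed integer seed.
#' @param threshold cost-effectiveness threshold for the probability of
#'   being cost-effective.
#' @return a `cvd_psa` list: `draws` (per-scenario data frames),
#'   `summary` (one row per scenario and quantity with mean, median and
#'   95% uncertainty interval), `point` (deterministic outcomes),
#'   `prob_cost_effective`.
#' @export
run_psa <- function(scenarios, ctx, n_draws = 1000, seed = 1,
                    threshold = 50000) {
  if (n_draws < 2) stopf("run_psa: n_draws must be >= 2")
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$label, character(1))
  point <- lapply(scenarios, evaluate_vs_null, ctx = ctx)
  draws <- with_seed(seed, {
    res <- lapply(scenarios, function(s)
      matrix(NA_real_, n_draws, 5,
             dimnames = list(NULL, c("health_gain", "cost_gov", "cost_pat",
                                     "averted", "net_cost"))))
    for (it in seq_len(n_draws)) {
      lib_d <- sample_library(ctx$lib)
      names(lib_d) <- names(ctx$lib)
      for (nm in names(scenarios)) {
        s_d <- scenarios[[nm]]
        # components given as objects (not library names) are drawn here
        s_d$components <- lapply(s_d$components, function(cmp) {
          if (inherits(cmp$ref, "cvd_intervention"))
            cmp$ref <- sample_draw(cmp$ref)
          cmp
        })
        o <- evaluate_vs_null(s_d, ctx, lib = lib_d)
        res[[nm]][it, ] <- c(o$health_gain, o$cost_gov, o$cost_patient,
                             o$treatment_costs_averted, o$net_cost)
      }
    }
    res
  })
  qs <- function(x) c(mean = mean(x), median = stats::median(x),
                      lo95 = unname(stats::quantile(x, 0.025)),
                      hi95 = unname(stats::quantile(x, 0.975)))
  summary <- do.call(rbind, lapply(names(draws), function(nm) {
    m <- draws[[nm]]
    icer_draws <- ifelse(m[, "health_gain"] > 0,
                         m[, "net_cost"] / m[, "health_gain"],
                         Inf)
    rows <- rbind(
      data.frame(scenario = nm, quantity = colnames(m),
                 t(apply(m, 2, qs)), stringsAsFactors = FALSE),
      data.frame(scenario = nm, quantity = "icer",
                 t(qs(icer_draws)), stringsAsFactors = FALSE))
    rows
  }))
  rownames(summary) <- NULL
  prob_ce <- vapply(draws, function(m)
    mean(threshold * m[, "health_gain"] - m[, "net_cost"] >= 0), numeric(1))
  structure(list(draws = draws, summary = summary, point = point,
                 prob_cost_effective = prob_ce, threshold = threshold,
                 n_draws = n_draws, seed = seed),
            class = "cvd_psa")
}

#' Cost-effectiveness acceptability frontier
#'
#' For each willingness-to-pay threshold, computes per Monte Carlo draw
#' which package maximises net monetary benefit (threshold x health gain
#' minus net cost), the probability each package is optimal, and the
#' frontier: the probability that the package that is optimal at the point
#' estimates is optimal across draws.
#'
#' @param psa a [run_psa()] result (draws aligned across packages by
#'   common random numbers).
#' @param thresholds grid of thresholds (AUD per unit health gain).
#' @return data frame `(threshold, package, prob_optimal, is_frontier)`.
#' @export
acceptability_frontier <- function(psa,
                                   thresholds = seq(0, 150000, by = 1000)) {
  draws <- psa$draws
  nd <- unique(vapply(draws, nrow, integer(1)))
  if (length(nd) != 1) stopf("acceptability_frontier: misaligned draw counts")
  pkgs <- names(draws)
  gain <- sapply(draws, function(m) m[, "health_gain"])
  net <- sapply(draws, function(m) m[, "net_cost"])
  pt_gain <- vapply(psa$point, function(o) o$health_gain, numeric(1))
  pt_net <- vapply(psa$point, function(o) o$net_cost, numeric(1))
  out <- lapply(thresholds, function(l) {
    nmb <- l * gain - net
    win <- max.col(nmb, ties.method = "first")
    prob <- vapply(seq_along(pkgs), function(j) mean(win == j), numeric(1))
    opt <- which.max(l * pt_gain - pt_net)
    data.frame(threshold = l, package = pkgs,
               prob_optimal = prob,
               is_frontier = seq_along(pkgs) == opt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Lifetime cost and health-gain ledger for a package
#'
#' Summary of a package versus the do-nothing comparator: lifetime health
#' gain, intervention cost to government and to patients, disease
#' treatment costs averted (negative) and net lifetime cost (the sum of
#' the three cost components), with 95% uncertainty intervals when a PSA
#' is supplied.
#'
#' @param scenario a [cea_scenario()].
#' @param ctx model context.
#' @param psa optional [run_psa()] result containing this scenario.
#' @return data frame of ledger rows.
#' @export
package_ledger <- function(scenario, ctx, psa = NULL) {
  o <- evaluate_vs_null(scenario, ctx)
  rows <- data.frame(
    quantity = c("health_gain", "cost_gov", "cost_patient",
                 "treatment_costs_averted", "net_cost"),
    value = c(o$health_gain, o$cost_gov, o$cost_patient,
              o$treatment_costs_averted, o$net_cost),
    stringsAsFactors = FALSE)
  if (!is.null(psa) && scenario$label %in% names(psa$draws)) {
    m <- psa$draws[[scenario$label]]
    net_draws <- m[, "cost_gov"] + m[, "cost_pat"] + m[, "averted"]
    stopifnot(max(abs(net_draws - m[, "net_cost"])) < 1e-6)
    qlo <- function(x) unname(stats::quantile(x, 0.025))
    qhi <- function(x) unname(stats::quantile(x, 0.975))
    cols <- c("health_gain", "cost_gov", "cost_pat", "averted", "net_cost")
    rows$lo95 <- vapply(cols, function(cc) qlo(m[, cc]), numeric(1))
    rows$hi95 <- vapply(cols, function(cc) qhi(m[, cc]), numeric(1))
  }
  rows
}
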