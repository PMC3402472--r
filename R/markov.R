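# Four-state discrete-time Markov cohort model (well, IHD, stroke, dead;
# dead absorbing) with one-year cycles, run until cohort extinction.
# Event channels: first IHD events, first strokes (ischaemic or
# haemorrhagic), and GI bleeds as acute side-effect events. Rates are
# converted to probabilities with the exponential competing-risk formula,
# allocating the combined exit probability proportionally to hazards.

cvd_states <- function() c("well", "ihd", "stroke", "dead")

#' Markov model configuration
#'
#' @param ihd_excess_mortality,stroke_excess_mortality additional annual
#'   death hazard (beyond background mortality) while living with the
#'   disease.
#' @param gi_case_fatality probability a GI bleed event is fatal.
#' @param age_cap simulation stops when a cohort reaches this age.
#' @param extinction_tol simulation stops when the alive fraction of the
#'   cohort falls below this.
#' @param cf_trend apply the secular trend multiplier to case fatality as
#'   well as incidence.
#' @param unrelated_cost_per_ly optional non-CVD health care cost per life
#'   year lived (the "other costs in added years of life" sensitivity
#'   scenario); default off.
#' @param half_cycle apply a half-cycle correction to life-year and cost
#'   accrual (default off: plain discrete-time accounting).
#' @return a `cvd_model_config` list.
#' @export
model_config <- function(ihd_excess_mortality = 0.03,
                         stroke_excess_mortality = 0.06,
                         gi_case_fatality = 0.05,
                         age_cap = 110, extinction_tol = 1e-9,
                         cf_trend = TRUE, unrelated_cost_per_ly = 0,
                         half_cycle = FALSE) {
  structure(list(ihd_excess_mortality = ihd_excess_mortality,
                 stroke_excess_mortality = stroke_excess_mortality,
                 gi_case_fatality = gi_case_fatality,
                 age_cap = age_cap, extinction_tol = extinction_tol,
                 cf_trend = cf_trend,
                 unrelated_cost_per_ly = unrelated_cost_per_ly,
                 half_cycle = half_cycle),
            class = "cvd_model_config")
}

# row indices of the epidemiology (or background-weights) table by age and
# sex; ages beyond the last band clamp to it
epi_row_index <- function(tab, age, sex) {
  bands <- unique(tab[, c("band", "age_lo", "age_hi")])
  bands <- bands[order(bands$age_lo), ]
  bidx <- clamp(findInterval(age, bands$age_lo), 1L, nrow(bands))
  match(paste(bands$band[bidx], sex), paste(tab$band, tab$sex))
}

# Vectorized per-cycle transition probabilities. `erow` is a list of
# epidemiology column vectors aligned to the cells; `rr` a cells x 4
# channel matrix; returns probability components for the cycle.
cycle_probs <- function(erow, year_offset, rr, rel_risk, cfg) {
  ti <- erow$ihd_trend^year_offset
  ts <- erow$stroke_trend^year_offset
  h_ihd <- erow$ihd_incidence * rel_risk * rr[, 1] * ti
  str_mult <- (1 - erow$stroke_haem_fraction) * rr[, 2] +
    erow$stroke_haem_fraction * rr[, 3]
  h_str <- erow$stroke_incidence * rel_risk * str_mult * ts
  h_gi <- erow$gi_bleed_incidence * rr[, 4]
  tmod_i <- if (cfg$cf_trend) ti else 1
  tmod_s <- if (cfg$cf_trend) ts else 1
  cf_i <- clamp(erow$ihd_case_fatality * tmod_i, 0, 1)
  cf_s <- clamp(erow$stroke_case_fatality * tmod_s, 0, 1)
  m <- erow$background_mortality
  h_gif <- h_gi * cfg$gi_case_fatality
  htot <- h_ihd + h_str + h_gif + m
  p_exit <- 1 - exp(-htot)
  frac <- ifelse(htot > 0, p_exit / htot, 0)
  list(p_ihd = h_ihd * frac, p_str = h_str * frac,
       p_gif = h_gif * frac, p_bg = m * frac,
       cf_i = cf_i, cf_s = cf_s,
       gi_event_prob = 1 - exp(-h_gi),
       p_ihd_dead = 1 - exp(-(m + cfg$ihd_excess_mortality)),
       p_str_dead = 1 - exp(-(m + cfg$stroke_excess_mortality)))
}

#' One-cycle transition matrix
#'
#' Assembles the four-state stochastic matrix for a given age, sex and
#' calendar year: incidence scaled by channel relative risks and the
#' secular trend, case fatality splitting events into fatal and non-fatal,
#' background (plus disease-excess) mortality applying from all alive
#' states. Rows sum to 1 by construction.
#'
#' @param age current age (years).
#' @param sex `"male"` or `"female"`.
#' @param calendar_year calendar year of the cycle.
#' @param epi a `cvd_epidemiology`.
#' @param rr_mods channel relative-risk vector (see [cvd_channels()]).
#' @param rel_risk cohort risk relative to the age/sex mean (risk-band
#'   stratification multiplier on CVD incidence).
#' @param config a [model_config()].
#' @return 4x4 matrix with dimnames over `c("well","ihd","stroke","dead")`.
#' @export
transition_matrix <- function(age, sex, calendar_year, epi, rr_mods = 1,
                              rel_risk = 1, config = model_config()) {
  rr <- matrix(as_channel_rr(if (length(rr_mods) == 1 && rr_mods == 1)
    c(ihd = 1, stroke = 1) else rr_mods), nrow = 1)
  ref <- attr(epi, "reference_year") %||% calendar_year
  i <- epi_row_index(epi, age, sex)
  erow <- lapply(epi[i, , drop = FALSE], identity)
  pr <- cycle_probs(erow, calendar_year - ref, rr, rel_risk, config)
  s <- cvd_states()
  M <- matrix(0, 4, 4, dimnames = list(s, s))
  M["well", "ihd"] <- pr$p_ihd * (1 - pr$cf_i)
  M["well", "stroke"] <- pr$p_str * (1 - pr$cf_s)
  M["well", "dead"] <- pr$p_ihd * pr$cf_i + pr$p_str * pr$cf_s +
    pr$p_gif + pr$p_bg
  M["well", "well"] <- 1 - sum(M["well", -1])
  M["ihd", "dead"] <- pr$p_ihd_dead
  M["ihd", "ihd"] <- 1 - pr$p_ihd_dead
  M["stroke", "dead"] <- pr$p_str_dead
  M["stroke", "stroke"] <- 1 - pr$p_str_dead
  M["dead", "dead"] <- 1
  if (any(M < -1e-15 | M > 1 + 1e-15))
    stopf("transition_matrix: probability outside [0,1] at age %s (%s), year %s",
          age, sex, calendar_year)
  M
}

#' Simulate one age/sex cohort until extinction
#'
#' Runs the cohort through the Markov model from its entry age until the
#' alive occupancy falls below `extinction_tol` of the cohort or the age
#' cap is reached. Occupancy is recorded at cycle start (person-years at
#' risk are the alive occupancy at the start of each one-year cycle; no
#' half-cycle correction by default). Health-adjusted years and cost
#' streams are appended via [health_adjusted_years()] and
#' [disease_costs()].
#'
#' @param n cohort size at entry.
#' @param entry_age age at entry (years).
#' @param sex `"male"` or `"female"`.
#' @param epi a `cvd_epidemiology` (must cover all ages reached).
#' @param rr channel relative-risk vector, or a function of the simulation
#'   year (1-based) returning one — effective RRs already blended for
#'   coverage and adherence.
#' @param intervention_cost function of simulation year returning
#'   `c(government, patient)` intervention cost per alive person, or NULL.
#' @param weights a [health_state_weights()].
#' @param dcosts a [disease_cost_table()].
#' @param rel_risk cohort CVD risk relative to the age/sex mean.
#' @param config a [model_config()].
#' @return a `cvd_cohort_trace` data frame, one row per cycle.
#' @export
simulate_cohort <- function(n, entry_age, sex, epi, rr = 1,
                            intervention_cost = NULL,
                            weights = health_state_weights(),
                            dcosts = disease_cost_table(),
                            rel_risk = 1, config = model_config()) {
  rr_fun <- if (is.function(rr)) rr else function(year) rr
  cost_fun <- intervention_cost %||% function(year) c(0, 0)
  ref <- attr(epi, "reference_year") %||% 2008
  max_cycles <- max(1L, as.integer(ceiling(config$age_cap - entry_age)) + 1L)
  occ <- c(well = n, ihd = 0, stroke = 0, dead = 0)
  rows <- vector("list", max_cycles)
  for (t in seq_len(max_cycles)) {
    age <- entry_age + t - 1
    if (age > config$age_cap) break
    alive <- occ[1] + occ[2] + occ[3]
    i <- epi_row_index(epi, age, sex)
    erow <- lapply(epi[i, , drop = FALSE], identity)
    rrv <- matrix(as_channel_rr(rr_fun(t)), nrow = 1)
    pr <- cycle_probs(erow, t - 1, rrv, rel_risk, config)
    ihd_ev <- occ[1] * pr$p_ihd
    str_ev <- occ[1] * pr$p_str
    gi_ev <- occ[1] * pr$gi_event_prob
    ihd_deaths <- ihd_ev * pr$cf_i
    str_deaths <- str_ev * pr$cf_s
    gi_deaths <- occ[1] * pr$p_gif
    well_bg <- occ[1] * pr$p_bg
    ihd_dd <- occ[2] * pr$p_ihd_dead
    str_dd <- occ[3] * pr$p_str_dead
    ic <- cost_fun(t)
    rows[[t]] <- c(cycle = t, year = ref + t - 1, age = age, occ,
                   ihd_events = unname(ihd_ev),
                   ihd_deaths = unname(ihd_deaths),
                   stroke_events = unname(str_ev),
                   stroke_deaths = unname(str_deaths),
                   gi_events = unname(gi_ev), gi_deaths = unname(gi_deaths),
                   other_deaths = unname(well_bg + ihd_dd + str_dd),
                   life_years = unname(alive),
                   cost_int_gov = unname(alive * ic[1]),
                   cost_int_pat = unname(alive * ic[2]))
    occ <- c(
      well = unname(occ[1] - ihd_ev - str_ev - gi_deaths - well_bg),
      ihd = unname(occ[2] - ihd_dd + ihd_ev - ihd_deaths),
      stroke = unname(occ[3] - str_dd + str_ev - str_deaths),
      dead = unname(occ[4] + ihd_deaths + str_deaths + gi_deaths +
                      well_bg + ihd_dd + str_dd))
    if (occ[1] + occ[2] + occ[3] <= config$extinction_tol * n) break
  }
  trace <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null,
                                                     logical(1))]))
  attr(trace, "sex") <- sex
  attr(trace, "entry_age") <- entry_age
  attr(trace, "cohort_size") <- n
  attr(trace, "reference_year") <- ref
  class(trace) <- c("cvd_cohort_trace", "data.frame")
  trace$haly_daly <- health_adjusted_years(trace, weights, "DALY")
  trace$haly_qaly <- health_adjusted_years(trace, weights, "QALY")
  trace$cost_disease <- disease_costs(trace, dcosts)
  if (config$unrelated_cost_per_ly > 0)
    trace$cost_disease <- trace$cost_disease +
      config$unrelated_cost_per_ly * trace$life_years
  trace
}

#' Health-adjusted life-year stream of a cohort trace
#'
#' DALY metric: occupancy weighted by `(1 - background disability) x
#' (1 - state disability)`; QALY metric: occupancy weighted by background
#' utility (complement of background disability) times state utility.
#' GI bleeds downgrade the event year's well-state weight to the bleed
#' weight for those experiencing the event. With matched weights
#' (`utility = 1 - disability`) the two streams coincide.
#'
#' @param trace a `cvd_cohort_trace`.
#' @param weights a [health_state_weights()].
#' @param metric `"DALY"` or `"QALY"`.
#' @return per-cycle healthy-equivalent life years.
#' @export
health_adjusted_years <- function(trace, weights, metric = c("DALY", "QALY")) {
  metric <- match.arg(metric)
  sex <- attr(trace, "sex")
  bg <- weights$background
  idx <- epi_row_index(bg, trace$age, rep(sex, nrow(trace)))
  bgd <- bg$background_disability[idx]
  d <- weights$disability
  u <- weights$utility
  if (any(d < 0 | d > 1) || any(u < 0 | u > 1) || any(bgd < 0 | bgd > 1))
    stopf("health_adjusted_years: weights must be in [0,1]")
  if (metric == "DALY") {
    sw <- function(st) (1 - bgd) * (1 - d[[st]])
    gi_adj <- trace$gi_events * (1 - bgd) * (d[["gi_bleed"]] - d[["well"]])
  } else {
    sw <- function(st) (1 - bgd) * u[[st]]
    gi_adj <- trace$gi_events * (1 - bgd) * (u[["well"]] - u[["gi_bleed"]])
  }
  trace$well * sw("well") + trace$ihd * sw("ihd") +
    trace$stroke * sw("stroke") - gi_adj
}

#' Disease treatment cost stream of a cohort trace
#'
#' Incident IHD and stroke events are charged the first-year treatment
#' cost; occupants of a disease state at cycle start (at least one year
#' post-event) are charged the subsequent-year cost; GI bleeds are charged
#' per event.
#'
#' @param trace a `cvd_cohort_trace`.
#' @param cost_table a [disease_cost_table()].
#' @return per-cycle treatment costs (AUD).
#' @export
disease_costs <- function(trace, cost_table) {
  ct <- function(dis, col) {
    v <- cost_table[[col]][cost_table$disease == dis]
    if (length(v) != 1) stopf("disease cost table missing '%s'", dis)
    v
  }
  trace$ihd_events * ct("ihd", "first_year_cost") +
    trace$ihd * ct("ihd", "subsequent_year_cost") +
    trace$stroke_events * ct("stroke", "first_year_cost") +
    trace$stroke * ct("stroke", "subsequent_year_cost") +
    trace$gi_events * ct("gi_bleed", "first_year_cost")
}

#' Discounted sum of a per-cycle stream
#'
#' `sum(value_t / (1 + rate)^t)` with `t = 0` at the first cycle (the
#' reference year); a zero rate gives the plain sum.
#'
#' @param stream per-cycle values.
#' @param rate annual discount rate (default 0.03).
#' @return scalar present value.
#' @export
discounted_sum <- function(stream, rate = 0.03) {
  if (length(stream) == 0) return(0)
  sum(stream / (1 + rate)^(seq_along(stream) - 1))
}

#' Export a cohort trace as delimited text
#'
#' One row per cycle with a metadata header embedding the scenario
#' descriptor.
#'
#' @param trace a `cvd_cohort_trace`.
#' @param path file path.
#' @param scenario_label free-text descriptor for the header.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path, scenario_label = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scenario: %s | sex: %s | entry_age: %s | n: %s",
                     scenario_label, attr(trace, "sex"),
                     attr(trace, "entry_age"), attr(trace, "cohort_size")),
             con)
  utils::write.table(as.data.frame(trace), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
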