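# Intervention effect algebra: encode interventions, convert risk-factor
# changes (systolic blood pressure, total cholesterol, dietary sodium) to
# relative risks of IHD and stroke, combine effects multiplicatively, and
# apply coverage, adherence and cost schedules at the cohort level.

#' Construct an intervention
#'
#' @param name display name.
#' @param delivery `"population_wide"` (reaches everyone; effects sustained
#'   with ongoing delivery, no discontinuation) or `"primary_care"`
#'   (reaches GP attenders assessed for risk; subject to discontinuation).
#' @param target_bands risk bands targeted (`"all"` for population-wide
#'   interventions, otherwise a subset of `c("5-9","10-14","ge15")`).
#' @param effect an effect specification: list with any of
#'   `rr` (named means over channels, `rr_se` standard errors),
#'   `sbp_pct`/`sbp_pct_se` (percent systolic BP reduction),
#'   `tc_pct`/`tc_pct_se` (percent total-cholesterol reduction; negative =
#'   harm), `sodium` / `sodium_se` (named by sex, mmol/day reduction).
#' @param cost_year1,cost_subsequent annual cost per covered person (2008
#'   AUD); `cost_subsequent` defaults to `cost_year1`.
#' @param cost_year1_se,cost_subsequent_se standard errors (0 = fixed).
#' @param patient_share fraction of cost borne by the patient.
#' @param adherence an [adherence_model()]; population-wide interventions
#'   default to no discontinuation.
#' @param uptake fraction of the reached population initiating.
#' @param effect_scale long-run retention of the trial effect size
#'   (1 = fully sustained; behaviour-change interventions use a small
#'   value, see the methods vignette).
#' @param price_scenarios optional named list of alternative
#'   `cost_year1`/`cost_subsequent` values (e.g. statin NZ pricing).
#' @param share_group optional label; interventions in the same group share
#'   one relative-risk draw per Monte Carlo iteration.
#' @return a `cvd_intervention` list.
#' @export
intervention <- function(name, delivery = c("primary_care", "population_wide"),
                         target_bands = NULL, effect,
                         cost_year1, cost_subsequent = cost_year1,
                         cost_year1_se = 0, cost_subsequent_se = 0,
                         patient_share = if (delivery[1] == "population_wide") 0 else 0.2,
                         adherence = NULL, uptake = 1, effect_scale = 1,
                         price_scenarios = NULL, share_group = NULL) {
  delivery <- match.arg(delivery)
  if (delivery == "population_wide") {
    target_bands <- "all"
    if (is.null(adherence)) adherence <- adherence_model(0, 1)
  } else {
    if (is.null(target_bands)) target_bands <- c("5-9", "10-14", "ge15")
    if (is.null(adherence)) adherence <- adherence_model()
  }
  cc <- check_collect()
  cc$check(cost_year1 >= 0 && cost_subsequent >= 0, "costs must be >= 0")
  cc$check(cost_year1_se >= 0 && cost_subsequent_se >= 0,
           "cost standard errors must be >= 0")
  cc$check(patient_share >= 0 && patient_share <= 1,
           "patient_share must be in [0,1]")
  cc$check(uptake >= 0 && uptake <= 1, "uptake must be in [0,1]")
  cc$check(effect_scale >= 0 && effect_scale <= 1,
           "effect_scale must be in [0,1]")
  if (!is.null(effect$rr)) {
    cc$check(all(effect$rr > 0), "effect$rr must be > 0")
    cc$check(all((effect$rr_se %||% 0) >= 0), "effect$rr_se must be >= 0")
  }
  for (f in c("sbp_pct", "tc_pct")) {
    if (!is.null(effect[[f]]))
      cc$check(abs(effect[[f]]) < 100,
               sprintf("effect$%s must be in (-100, 100)", f))
  }
  cc$raise(sprintf("invalid intervention '%s'", name))
  structure(list(name = name, delivery = delivery,
                 target_bands = target_bands, effect = effect,
                 cost_year1 = cost_year1, cost_subsequent = cost_subsequent,
                 cost_year1_se = cost_year1_se,
                 cost_subsequent_se = cost_subsequent_se,
                 patient_share = patient_share, adherence = adherence,
                 uptake = uptake, effect_scale = effect_scale,
                 price_scenarios = price_scenarios,
                 share_group = share_group),
            class = "cvd_intervention")
}

#' Adherence model
#'
#' Of patients initiating a primary-care intervention, a fraction is no
#' longer adherent after 12 months (default 40%); retention thereafter is
#' `post_year1_retention` per year. Discontinuers incur no further drug
#' costs and receive no effect from year 2; year-1 costs are charged to all
#' initiators.
#'
#' @param year1_discontinuation fraction discontinuing after the first year.
#' @param post_year1_retention annual retention among continuers.
#' @return a `cvd_adherence` list.
#' @export
adherence_model <- function(year1_discontinuation = 0.40,
                            post_year1_retention = 1.0) {
  if (year1_discontinuation < 0 || year1_discontinuation > 1 ||
      post_year1_retention < 0 || post_year1_retention > 1)
    stopf("adherence fractions must be in [0,1]")
  structure(list(year1_discontinuation = year1_discontinuation,
                 post_year1_retention = post_year1_retention),
            class = "cvd_adherence")
}

#' Adherent fraction of initiators by simulation year
#'
#' @param adh an [adherence_model()].
#' @param year simulation year (1-based; year 1 is the initiation year).
#' @return fraction of initiators still adherent.
#' @export
adherent_fraction <- function(adh, year) {
  ifelse(year <= 1, 1,
         (1 - adh$year1_discontinuation) *
           adh$post_year1_retention^(pmax(year, 2) - 2))
}

#' Conversion constants from risk-factor change to relative risk
#'
#' Percent reduction in relative risk per 1% reduction in the risk factor:
#' a 1% systolic blood pressure reduction gives a 3.4% reduction in IHD
#' risk and 6.3% in stroke risk; a 1% total-cholesterol reduction gives
#' 1.8% (IHD) and 0.80% (stroke).
#'
#' @param sbp_to_ihd,sbp_to_stroke,tc_to_ihd,tc_to_stroke percent per
#'   percent.
#' @return a `cvd_conversion` list.
#' @export
conversion_constants <- function(sbp_to_ihd = 3.4, sbp_to_stroke = 6.3,
                                 tc_to_ihd = 1.8, tc_to_stroke = 0.80) {
  vals <- c(sbp_to_ihd, sbp_to_stroke, tc_to_ihd, tc_to_stroke)
  if (any(vals <= 0 | vals >= 100))
    stopf("conversion constants must be in (0, 100)")
  structure(list(sbp_to_ihd = sbp_to_ihd, sbp_to_stroke = sbp_to_stroke,
                 tc_to_ihd = tc_to_ihd, tc_to_stroke = tc_to_stroke),
            class = "cvd_conversion")
}

check_delta_pct <- function(delta_pct) {
  if (any(abs(delta_pct) >= 100))
    stopf("percent reduction must be in (-100, 100)")
}

#' Relative risks from a percent reduction in systolic blood pressure
#'
#' Linear scaling of the per-1% constants; a configurable floor prevents
#' non-positive relative risks for very large reductions.
#'
#' @param delta_pct percent SBP reduction (negative = increase).
#' @param k a [conversion_constants()].
#' @param floor minimum relative risk.
#' @return named vector `c(ihd=, stroke=)`.
#' @export
rr_from_sbp_pct <- function(delta_pct, k = conversion_constants(),
                            floor = 0.01) {
  check_delta_pct(delta_pct)
  c(ihd = max(floor, 1 - k$sbp_to_ihd / 100 * delta_pct),
    stroke = max(floor, 1 - k$sbp_to_stroke / 100 * delta_pct))
}

#' Relative risks from a percent reduction in total cholesterol
#'
#' @inheritParams rr_from_sbp_pct
#' @param delta_pct percent total-cholesterol reduction; negative values
#'   (an increase) yield relative risks above 1.
#' @return named vector `c(ihd=, stroke=)`.
#' @export
rr_from_tc_pct <- function(delta_pct, k = conversion_constants(),
                           floor = 0.01) {
  check_delta_pct(delta_pct)
  c(ihd = max(floor, 1 - k$tc_to_ihd / 100 * delta_pct),
    stroke = max(floor, 1 - k$tc_to_stroke / 100 * delta_pct))
}

#' Sodium to systolic blood pressure model
#'
#' mmHg systolic blood pressure change per mmol/day change in dietary
#' sodium, by age band and sex. The response strengthens with age (the
#' default rises linearly from 0.025 mmHg per mmol/day at age 35).
#'
#' @param slope_at35 slope at age 35 (mmHg per mmol/day).
#' @param slope_age_gain additional slope per year of age.
#' @return a `cvd_sodium_model` data frame over bands 35-109 and sex.
#' @export
sodium_bp_model <- function(slope_at35 = 0.025, slope_age_gain = 0.0012) {
  bands <- age_band_frame(35, 110)
  out <- merge(bands, data.frame(sex = c("male", "female")))
  out <- out[order(out$age_lo, out$sex), ]
  out$slope <- slope_at35 + slope_age_gain * (out$age_mid - 35)
  if (any(out$slope < 0)) stopf("sodium slopes must be >= 0")
  rownames(out) <- NULL
  class(out) <- c("cvd_sodium_model", "data.frame")
  out
}

#' Percent SBP reduction from a sodium reduction
#'
#' A change in blood pressure is first derived by age and sex from the
#' sodium-blood pressure slopes, then expressed as a percentage of the
#' baseline systolic blood pressure so it can enter [rr_from_sbp_pct()].
#'
#' @param delta_na sodium reduction per day, in `units`.
#' @param band age band label (e.g. `"60-64"`).
#' @param sex `"male"` or `"female"`.
#' @param m a [sodium_bp_model()].
#' @param baseline_sbp baseline systolic blood pressure (mmHg).
#' @param units `"mmol"` (default; the slopes' native unit) or `"mg"`
#'   (reinterpreted via 23 mg sodium per mmol).
#' @return percent SBP reduction.
#' @export
sbp_pct_from_sodium <- function(delta_na, band, sex, m = sodium_bp_model(),
                                baseline_sbp, units = c("mmol", "mg")) {
  units <- match.arg(units)
  if (units == "mg") delta_na <- delta_na / 23
  if (any(baseline_sbp <= 0)) stopf("baseline_sbp must be > 0")
  idx <- match(paste(band, sex), paste(m$band, m$sex))
  if (any(is.na(idx)))
    stopf("sodium model has no entry for cell (%s, %s)",
          band[which(is.na(idx))[1]], sex[which(is.na(idx))[1]])
  100 * m$slope[idx] * delta_na / baseline_sbp
}

#' Combine relative risks multiplicatively
#'
#' Componentwise product over the four event channels; risk-factor
#' mediated effects must already have been converted to relative risks.
#' Order-independent; combining with 1 is a no-op.
#'
#' @param effects list of relative-risk vectors (named channel vectors, or
#'   length-2 `(ihd, stroke)`).
#' @return named four-channel relative-risk vector.
#' @export
combine_rrs <- function(effects) {
  if (length(effects) == 0) stopf("combine_rrs: empty effect list")
  Reduce(`*`, lapply(effects, as_channel_rr))
}

#' Cohort-level effective relative risk
#'
#' Blends treated and untreated: with coverage `c` and adherent fraction
#' `a(y)`, the effective relative risk is `1 - c a(y) (1 - rr)` per
#' channel. Harms (`rr > 1`) dilute the same way.
#'
#' @param rr channel relative-risk vector for full adherence.
#' @param coverage fraction of the cohort treated at initiation.
#' @param adh an [adherence_model()].
#' @param sim_year simulation year (1-based).
#' @return effective channel relative-risk vector.
#' @export
population_effective_rr <- function(rr, coverage, adh = adherence_model(),
                                    sim_year = 1) {
  if (coverage < 0 || coverage > 1) stopf("coverage must be in [0,1]")
  rr <- as_channel_rr(rr)
  1 - coverage * adherent_fraction(adh, sim_year) * (1 - rr)
}

#' Annual intervention cost per person in the target population
#'
#' Year 1 charges the year-1 cost to all initiators (including those who
#' later discontinue); later years charge the subsequent-year cost scaled
#' by the adherent fraction.
#'
#' @param iv a [intervention()].
#' @param sim_year simulation year (1-based).
#' @param coverage fraction of the target population initiating.
#' @param adh adherence model (defaults to the intervention's own).
#' @param perspective `"both"`, `"government"` or `"patient"`.
#' @return AUD per person per year.
#' @export
annual_cost <- function(iv, sim_year, coverage,
                        adh = iv$adherence,
                        perspective = c("both", "government", "patient")) {
  perspective <- match.arg(perspective)
  if (coverage < 0 || coverage > 1) stopf("coverage must be in [0,1]")
  base <- if (sim_year <= 1) iv$cost_year1 else
    iv$cost_subsequent * adherent_fraction(adh, sim_year)
  total <- coverage * base
  switch(perspective,
         both = total,
         government = total * (1 - iv$patient_share),
         patient = total * iv$patient_share)
}

# lognormal parameters matching a target mean and standard error
lnorm_match <- function(mean, se) {
  s2 <- log(1 + (se / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

draw_lnorm <- function(mean, se) {
  if (se <= 0) return(mean)
  p <- lnorm_match(mean, se)
  stats::rlnorm(1, p$meanlog, p$sdlog)
}

draw_norm_trunc <- function(mean, se, lo = -99.9, hi = 99.9) {
  if (se <= 0) return(mean)
  clamp(stats::rnorm(1, mean, se), lo, hi)
}

draw_gamma <- function(mean, se) {
  if (se <= 0) return(mean)
  if (mean <= 0) return(max(0, stats::rnorm(1, mean, se)))
  shape <- (mean / se)^2
  stats::rgamma(1, shape = shape, rate = shape / mean)
}

#' Draw one Monte Carlo realisation of an intervention's parameters
#'
#' Relative risks are drawn lognormal (moment-matched to mean and standard
#' error), percent risk-factor effects normal, sodium effects normal
#' truncated at 0, and costs gamma. A zero standard error leaves the
#' parameter at its mean. Consumes the current RNG stream, so draws are
#' deterministic given the seed set by the caller.
#'
#' @param iv a [intervention()].
#' @return the intervention with parameters resampled.
#' @export
sample_draw <- function(iv) {
  eff <- iv$effect
  if (!is.null(eff$rr)) {
    se <- eff$rr_se %||% rep(0, length(eff$rr))
    if (!is.null(names(se))) {
      se <- se[names(eff$rr)]
      se[is.na(se)] <- 0
    }
    if (any(se < 0)) stopf("sample_draw: negative rr_se in '%s'", iv$name)
    eff$rr <- stats::setNames(
      vapply(seq_along(eff$rr),
             function(i) draw_lnorm(eff$rr[[i]], se[[i]]), numeric(1)),
      names(eff$rr))
  }
  if (!is.null(eff$sbp_pct))
    eff$sbp_pct <- draw_norm_trunc(eff$sbp_pct, eff$sbp_pct_se %||% 0)
  if (!is.null(eff$tc_pct))
    eff$tc_pct <- draw_norm_trunc(eff$tc_pct, eff$tc_pct_se %||% 0)
  if (!is.null(eff$sodium)) {
    se <- eff$sodium_se %||% stats::setNames(rep(0, length(eff$sodium)),
                                             names(eff$sodium))
    eff$sodium <- stats::setNames(
      vapply(seq_along(eff$sodium), function(i)
        max(0, draw_norm_trunc(eff$sodium[[i]], se[[i]], -Inf, Inf)),
        numeric(1)),
      names(eff$sodium))
  }
  iv$effect <- eff
  iv$cost_year1 <- draw_gamma(iv$cost_year1, iv$cost_year1_se)
  iv$cost_subsequent <- if (iv$cost_subsequent_se > 0)
    draw_gamma(iv$cost_subsequent, iv$cost_subsequent_se)
  else if (identical(iv$cost_subsequent, iv$cost_year1) &&
           iv$cost_year1_se > 0) iv$cost_year1
  else iv$cost_subsequent
  iv
}

#' Draw a full intervention library, sharing grouped parameters
#'
#' Interventions with the same `share_group` receive the same relative-risk
#' draw (e.g. the statin trial effect reused by current-practice
#' lipid-lowering), drawn once per iteration.
#'
#' @param lib list of interventions.
#' @return list of resampled interventions.
#' @export
sample_library <- function(lib) {
  drawn <- list()
  lapply(lib, function(iv) {
    g <- iv$share_group
    if (!is.null(g)) {
      if (is.null(drawn[[g]])) drawn[[g]] <<- sample_draw(iv)$effect$rr
      s <- sample_draw(iv)       # advance cost draws independently
      s$effect$rr <- drawn[[g]]
      s
    } else {
      sample_draw(iv)
    }
  })
}

#' Serialize / restore an intervention library as JSON
#'
#' Structured-text round-trip mirroring the effect-measure, mean, standard
#' error and cost-schedule columns of the intervention table.
#'
#' @param lib list of interventions.
#' @param path file path.
#' @return `read_intervention_library` returns the list of interventions.
#' @export
write_intervention_library <- function(lib, path) {
  payload <- lapply(lib, function(iv) {
    x <- unclass(iv)
    x$adherence <- unclass(x$adherence)
    # keep names of effect vectors: serialize them as JSON objects
    x$effect <- lapply(x$effect, function(v)
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
    x
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_intervention_library
#' @export
read_intervention_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(x) {
    eff <- lapply(x$effect, function(v) if (is.list(v)) unlist(v) else v)
    intervention(
      name = x$name, delivery = x$delivery,
      target_bands = unlist(x$target_bands), effect = eff,
      cost_year1 = x$cost_year1, cost_subsequent = x$cost_subsequent,
      cost_year1_se = x$cost_year1_se,
      cost_subsequent_se = x$cost_subsequent_se,
      patient_share = x$patient_share,
      adherence = adherence_model(x$adherence$year1_discontinuation,
                                  x$adherence$post_year1_retention),
      uptake = x$uptake, effect_scale = x$effect_scale,
      price_scenarios = x$price_scenarios,
      share_group = x$share_group
    )
  })
}
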