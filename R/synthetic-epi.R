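# Synthetic epidemiology: every model input (risk-factor survey, event
# rates, health-state weights, disease costs) can be generated with the
# statistical structure the analysis assumes, so the full pipeline is
# testable without any external data. Defaults are order-of-magnitude
# plausible for a Western population in 2008 but deliberately NOT
# calibrated to any country's actual rates.

age_band_frame <- function(age_min, age_max, width = 5) {
  lo <- seq(age_min, age_max - width, by = width)
  data.frame(
    band = sprintf("%d-%d", lo, lo + width - 1),
    age_lo = lo, age_hi = lo + width,
    age_mid = lo + width / 2,
    stringsAsFactors = FALSE
  )
}

band_of_age <- function(age, bands) {
  idx <- findInterval(age, c(bands$age_lo, max(bands$age_hi)),
                      rightmost.closed = TRUE)
  clamp(idx, 1L, nrow(bands))
}

#' Demography specification
#'
#' Five-year age/sex cohorts spanning ages 35 to 84 in the reference year
#' (2008). `population` is the number of persons each band represents;
#' `survey_n` is the number of synthetic survey respondents drawn per band
#' to characterise the risk-factor distribution.
#'
#' @param population named numeric vector of persons per age band and sex,
#'   or a single number recycled to every band/sex cell. The default is a
#'   plausible 2008 population of about 11 million 35-84 year olds.
#' @param survey_n synthetic survey respondents per age/sex band.
#' @param reference_year calendar year the cohorts enter the model.
#' @return a `cvd_demography` data frame with one row per age band and sex.
#' @export
demography_spec <- function(population = NULL, survey_n = 500,
                            reference_year = 2008) {
  bands <- age_band_frame(35, 85)
  if (is.null(population)) {
    # thousands of persons per 5-year band (both sexes combined)
    per_band <- c(1550, 1500, 1450, 1350, 1250, 1050, 800, 650, 550, 400) * 1e3
  } else if (length(population) == 1) {
    per_band <- rep(population * 2, nrow(bands))
  } else {
    if (length(population) != nrow(bands))
      stopf("demography: population must have length 1 or %d", nrow(bands))
    per_band <- population
  }
  out <- merge(bands, data.frame(sex = c("male", "female")))
  out <- out[order(out$age_lo, out$sex), ]
  out$population <- rep(per_band / 2, each = 2)
  out$survey_n <- as.integer(survey_n)
  if (any(out$population <= 0)) stopf("demography: all cohort sizes must be > 0")
  if (any(out$survey_n <= 0)) stopf("demography: survey_n must be > 0")
  rownames(out) <- NULL
  attr(out, "reference_year") <- reference_year
  class(out) <- c("cvd_demography", "data.frame")
  out
}

#' Risk-factor distribution specification
#'
#' Parameters of the synthetic individual-level survey. Continuous factors
#' are normal within age/sex strata with a linear drift in age (centred at
#' age 50); binary factors are Bernoulli with age-linear prevalence.
#' Factors are generated independently within strata apart from the
#' age drifts; real survey correlations are not emulated.
#'
#' @param sbp_mean,sbp_age_slope,sbp_sd systolic blood pressure (mmHg);
#'   means named by sex.
#' @param tc_mean,tc_age_slope,tc_sd total cholesterol (mmol/L).
#' @param hdl_mean,hdl_sd HDL cholesterol (mmol/L), named by sex.
#' @param smoking_prev,smoking_age_slope smoking prevalence by sex and its
#'   change per year of age.
#' @param diabetes_prev,diabetes_age_slope diabetes prevalence at age 50
#'   and change per year of age.
#' @param prior_cvd_at50,prior_cvd_log_slope prevalence of prior CVD at age
#'   50 and its exponential age gradient (prior-CVD records are excluded
#'   from all downstream eligibility).
#' @return a `cvd_riskfactor_spec` list.
#' @export
riskfactor_spec <- function(sbp_mean = c(male = 129, female = 125),
                            sbp_age_slope = 0.5, sbp_sd = 15,
                            tc_mean = c(male = 5.5, female = 5.4),
                            tc_age_slope = 0.012, tc_sd = 1.0,
                            hdl_mean = c(male = 1.25, female = 1.5),
                            hdl_sd = 0.32,
                            smoking_prev = c(male = 0.27, female = 0.21),
                            smoking_age_slope = -0.002,
                            diabetes_prev = 0.05,
                            diabetes_age_slope = 0.003,
                            prior_cvd_at50 = 0.02,
                            prior_cvd_log_slope = 0.08) {
  spec <- list(
    sbp_mean = sbp_mean, sbp_age_slope = sbp_age_slope, sbp_sd = sbp_sd,
    tc_mean = tc_mean, tc_age_slope = tc_age_slope, tc_sd = tc_sd,
    hdl_mean = hdl_mean, hdl_sd = hdl_sd,
    smoking_prev = smoking_prev, smoking_age_slope = smoking_age_slope,
    diabetes_prev = diabetes_prev, diabetes_age_slope = diabetes_age_slope,
    prior_cvd_at50 = prior_cvd_at50,
    prior_cvd_log_slope = prior_cvd_log_slope
  )
  cc <- check_collect()
  cc$check(spec$sbp_sd > 0, "sbp_sd must be > 0")
  cc$check(spec$tc_sd > 0, "tc_sd must be > 0")
  cc$check(spec$hdl_sd > 0, "hdl_sd must be > 0")
  cc$check(spec$smoking_prev >= 0 & spec$smoking_prev <= 1,
           "smoking_prev must be in [0,1]")
  cc$check(spec$diabetes_prev >= 0 & spec$diabetes_prev <= 1,
           "diabetes_prev must be in [0,1]")
  cc$check(spec$prior_cvd_at50 >= 0 & spec$prior_cvd_at50 <= 1,
           "prior_cvd_at50 must be in [0,1]")
  cc$raise("invalid riskfactor_spec")
  class(spec) <- "cvd_riskfactor_spec"
  spec
}

#' Generate a synthetic risk-factor survey
#'
#' Draws individual records (age, sex, smoking, total and HDL cholesterol,
#' diabetes, systolic blood pressure, prior-CVD flag) for every age/sex
#' band of the demography. Deterministic given `seed`.
#'
#' @param demog a [demography_spec()].
#' @param rf a [riskfactor_spec()].
#' @param seed integer seed.
#' @return a `cvd_survey` data frame, one row per respondent.
#' @export
generate_survey <- function(demog, rf = riskfactor_spec(), seed = 1) {
  stopifnot(inherits(demog, "cvd_demography"))
  if (!inherits(rf, "cvd_riskfactor_spec")) {
    rf <- do.call(riskfactor_spec, rf)  # re-validate plain lists
  }
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(demog)), function(i) {
      row <- demog[i, ]
      n <- row$survey_n
      sex <- row$sex
      age <- stats::runif(n, row$age_lo, row$age_hi)
      d50 <- age - 50
      sbp <- stats::rnorm(n, rf$sbp_mean[[sex]] + rf$sbp_age_slope * d50,
                          rf$sbp_sd)
      sbp <- clamp(sbp, 70.5, 259.5)
      tc <- stats::rnorm(n, rf$tc_mean[[sex]] + rf$tc_age_slope * d50,
                         rf$tc_sd)
      tc <- pmax(tc, 2.0)
      hdl <- clamp(stats::rnorm(n, rf$hdl_mean[[sex]], rf$hdl_sd), 0.4, 3.5)
      hdl <- pmin(hdl, tc - 0.1)
      smoker <- stats::runif(n) <
        clamp(rf$smoking_prev[[sex]] + rf$smoking_age_slope * d50, 0, 1)
      diabetes <- stats::runif(n) <
        clamp(rf$diabetes_prev + rf$diabetes_age_slope * d50, 0, 1)
      prior <- stats::runif(n) <
        clamp(rf$prior_cvd_at50 * exp(rf$prior_cvd_log_slope * d50), 0, 1)
      data.frame(band = row$band, sex = sex, age = age, smoker = smoker,
                 total_chol = tc, hdl_chol = hdl, diabetes = diabetes,
                 sbp = sbp, prior_cvd = prior, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    out$id <- seq_len(nrow(out))
    out <- out[, c("id", "band", "sex", "age", "smoker", "total_chol",
                   "hdl_chol", "diabetes", "sbp", "prior_cvd")]
    class(out) <- c("cvd_survey", "data.frame")
    out
  })
}

#' Epidemiology rate-curve specification
#'
#' Exponential age gradients for first-event incidence and background
#' mortality, linear age gradients for case fatality, plus secular trend
#' multipliers. Rates are per person-year; `*_at50` anchors the curve at
#' age 50 and `*_slope` is the log-linear (incidence, mortality) or linear
#' (case fatality) change per year of age.
#'
#' @param ... named overrides of the default curve parameters.
#' @return a `cvd_epi_spec` list.
#' @export
epi_spec <- function(...) {
  spec <- list(
    ihd_at50 = c(male = 0.0025, female = 0.00125),
    ihd_slope = 0.08,
    stroke_at50 = c(male = 0.001, female = 0.0009),
    stroke_slope = 0.095,
    ihd_cf_at50 = 0.25, ihd_cf_slope = 0.004,
    stroke_cf_at50 = 0.18, stroke_cf_slope = 0.004,
    bg_mort_at50 = c(male = 0.0025, female = 0.0018),
    bg_mort_slope = c(male = 0.085, female = 0.09),
    ihd_trend = 0.98, stroke_trend = 0.985,
    stroke_haem_fraction = 0.20,
    gi_bleed_at50 = 0.001, gi_bleed_slope = 0.05,
    noise_sd = 0
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stopf("epi_spec: unknown field(s) %s",
                         paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  cc <- check_collect()
  for (f in c("ihd_at50", "stroke_at50", "bg_mort_at50", "gi_bleed_at50"))
    cc$check(spec[[f]] >= 0, sprintf("%s must be >= 0", f))
  for (f in c("ihd_cf_at50", "stroke_cf_at50"))
    cc$check(spec[[f]] >= 0 & spec[[f]] <= 1,
             sprintf("%s must be in [0,1]", f))
  for (f in c("ihd_trend", "stroke_trend"))
    cc$check(spec[[f]] > 0.8 & spec[[f]] < 1.2,
             sprintf("%s must be in (0.8, 1.2)", f))
  cc$check(spec$stroke_haem_fraction >= 0 & spec$stroke_haem_fraction <= 1,
           "stroke_haem_fraction must be in [0,1]")
  cc$check(spec$noise_sd >= 0, "noise_sd must be >= 0")
  cc$raise("invalid epi_spec")
  class(spec) <- "cvd_epi_spec"
  spec
}

#' Generate an age/sex epidemiology table
#'
#' Evaluates the rate curves of an [epi_spec()] at five-year band midpoints
#' from age 35 up to 110 (bands above 84 are needed as cohorts age through
#' the Markov model). With `noise_sd > 0`, multiplicative lognormal noise
#' is added per cell (deterministic given `seed`).
#'
#' @param spec an [epi_spec()].
#' @param seed integer seed (only consumed when `noise_sd > 0`).
#' @param reference_year calendar year the table describes.
#' @return a `cvd_epidemiology` data frame, one row per band and sex.
#' @export
generate_epidemiology <- function(spec = epi_spec(), seed = 1,
                                  reference_year = 2008) {
  stopifnot(inherits(spec, "cvd_epi_spec"))
  bands <- age_band_frame(35, 110)
  out <- merge(bands, data.frame(sex = c("male", "female")))
  out <- out[order(out$age_lo, out$sex), ]
  rownames(out) <- NULL
  a <- out$age_mid - 50
  sx <- out$sex
  pick <- function(v) if (length(v) == 1) rep(v, nrow(out)) else unname(v[sx])
  out$ihd_incidence <- pick(spec$ihd_at50) * exp(spec$ihd_slope * a)
  out$stroke_incidence <- pick(spec$stroke_at50) * exp(spec$stroke_slope * a)
  out$ihd_case_fatality <- clamp(spec$ihd_cf_at50 + spec$ihd_cf_slope * a, 0, 1)
  out$stroke_case_fatality <-
    clamp(spec$stroke_cf_at50 + spec$stroke_cf_slope * a, 0, 1)
  out$background_mortality <-
    pick(spec$bg_mort_at50) * exp(pick(spec$bg_mort_slope) * a)
  out$ihd_trend <- spec$ihd_trend
  out$stroke_trend <- spec$stroke_trend
  out$stroke_haem_fraction <- spec$stroke_haem_fraction
  out$gi_bleed_incidence <- spec$gi_bleed_at50 * exp(spec$gi_bleed_slope * a)
  if (spec$noise_sd > 0) {
    out <- with_seed(seed, {
      for (col in c("ihd_incidence", "stroke_incidence",
                    "background_mortality", "gi_bleed_incidence")) {
        out[[col]] <- out[[col]] *
          exp(stats::rnorm(nrow(out), 0, spec$noise_sd))
      }
      out
    })
  }
  attr(out, "reference_year") <- reference_year
  class(out) <- c("cvd_epidemiology", "data.frame")
  validate_epidemiology(out)
  out
}

#' Validate an epidemiology table
#'
#' @param epi a `cvd_epidemiology` data frame.
#' @return the table, invisibly; errors on invariant violations.
#' @export
validate_epidemiology <- function(epi) {
  cc <- check_collect()
  rates <- c("ihd_incidence", "stroke_incidence", "background_mortality",
             "gi_bleed_incidence")
  for (col in rates) cc$check(epi[[col]] >= 0,
                              sprintf("%s must be >= 0", col))
  for (col in c("ihd_case_fatality", "stroke_case_fatality",
                "stroke_haem_fraction"))
    cc$check(epi[[col]] >= 0 & epi[[col]] <= 1,
             sprintf("%s must be in [0,1]", col))
  for (col in c("ihd_trend", "stroke_trend"))
    cc$check(epi[[col]] > 0.8 & epi[[col]] < 1.2,
             sprintf("%s must be in (0.8, 1.2)", col))
  cc$raise("invalid epidemiology table")
  invisible(epi)
}

#' Health-state disability and utility weights
#'
#' Per-state weights used to health-adjust life years: `disability` is the
#' state-specific disability weight of the burden-of-disease framework,
#' `utility` the corresponding utility decrement complement used for
#' QALYs (default `1 - disability`, which makes the DALY- and QALY-metric
#' streams coincide). Background (non-CVD) disability rises linearly with
#' age. GI bleed weights apply for the single event year.
#'
#' @param disability named vector of state disability weights.
#' @param utility named vector of state utility weights (default matched).
#' @param background_at35,background_slope background disability at age 35
#'   and increase per year of age (capped at 0.4).
#' @return a `cvd_weights` list with a band/sex background table.
#' @export
health_state_weights <- function(disability = c(well = 0, ihd = 0.15,
                                                stroke = 0.30,
                                                gi_bleed = 0.10),
                                 utility = NULL,
                                 background_at35 = 0.05,
                                 background_slope = 0.002) {
  if (is.null(utility)) utility <- 1 - disability
  if (any(disability < 0 | disability > 1) || any(utility < 0 | utility > 1))
    stopf("health_state_weights: weights must be in [0,1]")
  if (disability[["well"]] > min(disability))
    stopf("health_state_weights: well-state disability must be the smallest")
  bands <- age_band_frame(35, 110)
  bg <- merge(bands, data.frame(sex = c("male", "female")))
  bg <- bg[order(bg$age_lo, bg$sex), ]
  bg$background_disability <-
    clamp(background_at35 + background_slope * (bg$age_mid - 35), 0, 0.4)
  rownames(bg) <- NULL
  structure(list(disability = disability, utility = utility,
                 background = bg),
            class = "cvd_weights")
}

#' Disease treatment cost table
#'
#' Annual treatment costs (2008 AUD per person) in the first year of
#' illness and in subsequent years, for IHD, stroke and GI bleed. GI bleeds
#' are acute events costed once.
#'
#' @param ihd,stroke,gi_bleed length-2 numeric `(first_year, subsequent)`.
#' @return a `cvd_disease_costs` data frame.
#' @export
disease_cost_table <- function(ihd = c(11000, 2200),
                               stroke = c(16000, 5200),
                               gi_bleed = c(4500, 0)) {
  out <- data.frame(
    disease = c("ihd", "stroke", "gi_bleed"),
    first_year_cost = c(ihd[1], stroke[1], gi_bleed[1]),
    subsequent_year_cost = c(ihd[2], stroke[2], gi_bleed[2]),
    stringsAsFactors = FALSE
  )
  if (any(out$first_year_cost < 0) || any(out$subsequent_year_cost < 0))
    stopf("disease_cost_table: costs must be >= 0")
  class(out) <- c("cvd_disease_costs", "data.frame")
  out
}

#' Export / import a survey as CSV
#'
#' Plain-delimited round-trip of the synthetic survey with a documented
#' header (`id, band, sex, age, smoker, total_chol, hdl_chol, diabetes,
#' sbp, prior_cvd`).
#'
#' @param survey a `cvd_survey`.
#' @param path file path.
#' @return `read_survey_csv` returns a `cvd_survey` data frame.
#' @export
write_survey_csv <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "band", "sex", "age", "smoker", "total_chol", "hdl_chol",
            "diabetes", "sbp", "prior_cvd")
  missing <- setdiff(need, names(out))
  if (length(missing)) stopf("survey file missing column(s): %s",
                             paste(missing, collapse = ", "))
  class(out) <- c("cvd_survey", "data.frame")
  out
}
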