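# Absolute-risk engine: predict five-year first-event CVD risk per
# individual, calibrate predicted risk to observed age/sex event rates
# (scaling the prediction rather than refitting the equation), and
# stratify the population into absolute-risk bands.

#' Five-year CVD risk equation
#'
#' A logistic-form risk equation on the classic risk factors (Framingham
#' style). Published cohort-equation coefficients are not reproduced:
#' predictions are
#' always scaled to observed age/sex event rates by [calibrate_risk()],
#' which makes downstream results insensitive to the precise coefficients.
#' Default placeholder coefficients give realistic risk gradients.
#'
#' @param coefficients named vector of log-odds weights on `age` (years),
#'   `male` (indicator), `smoker`, `total_chol` (mmol/L), `hdl_chol`
#'   (mmol/L; negative weight), `diabetes`, `sbp` (mmHg).
#' @param intercept log-odds at the centring point.
#' @param centre named vector of centring values subtracted from the
#'   continuous factors.
#' @return a `cvd_risk_equation`.
#' @export
risk_equation <- function(coefficients = c(age = 0.07, male = 0.45,
                                           smoker = 0.55, total_chol = 0.28,
                                           hdl_chol = -0.65, diabetes = 0.65,
                                           sbp = 0.016),
                          intercept = -3.2,
                          centre = c(age = 55, total_chol = 5.5,
                                     hdl_chol = 1.35, sbp = 130)) {
  need <- c("age", "male", "smoker", "total_chol", "hdl_chol", "diabetes",
            "sbp")
  missing <- setdiff(need, names(coefficients))
  if (length(missing)) stopf("risk_equation: missing coefficient(s) %s",
                             paste(missing, collapse = ", "))
  structure(list(coefficients = coefficients, intercept = intercept,
                 centre = centre, horizon = 5),
            class = "cvd_risk_equation")
}

#' Predict five-year CVD risk
#'
#' @param records a `cvd_survey` data frame (all rows must have
#'   `prior_cvd = FALSE`: the analysis covers primary prevention only).
#' @param eq a [risk_equation()].
#' @param cal optional `cvd_calibration` (per age-band/sex multiplicative
#'   scale, applied on the probability scale and capped at 1).
#' @return vector of five-year first-event probabilities.
#' @export
predict_5yr_risk <- function(records, eq = risk_equation(), cal = NULL) {
  if (any(records$prior_cvd))
    stopf("predict_5yr_risk: records with prior CVD are not eligible")
  co <- eq$coefficients
  ce <- eq$centre
  lp <- eq$intercept +
    co[["age"]] * (records$age - ce[["age"]]) +
    co[["male"]] * (records$sex == "male") +
    co[["smoker"]] * records$smoker +
    co[["total_chol"]] * (records$total_chol - ce[["total_chol"]]) +
    co[["hdl_chol"]] * (records$hdl_chol - ce[["hdl_chol"]]) +
    co[["diabetes"]] * records$diabetes +
    co[["sbp"]] * (records$sbp - ce[["sbp"]])
  p <- stats::plogis(lp)
  if (!is.null(cal)) {
    idx <- match(paste(records$band, records$sex),
                 paste(cal$band, cal$sex))
    if (any(is.na(idx)))
      stopf("calibration missing cell for band %s",
            records$band[which(is.na(idx))[1]])
    p <- pmin(1, cal$scale[idx] * p)
  }
  p
}

#' Observed five-year first-event probability from an epidemiology table
#'
#' Converts annual first-event incidence to a five-year probability net of
#' competing background mortality, exact under constant hazards:
#' `P = lambda/(lambda+m) * (1 - exp(-5 (lambda+m)))` with `lambda` the
#' combined IHD and stroke first-event rate and `m` background mortality.
#'
#' @param epi a `cvd_epidemiology`.
#' @return data frame of band, sex and `p5` observed probability.
#' @export
observed_5yr_probability <- function(epi) {
  lam <- epi$ihd_incidence + epi$stroke_incidence
  m <- epi$background_mortality
  tot <- lam + m
  p5 <- ifelse(tot > 0, lam / tot * (1 - exp(-5 * tot)), 0)
  data.frame(band = epi$band, sex = epi$sex, p5 = p5,
             stringsAsFactors = FALSE)
}

# solve mean(pmin(1, s * p)) = target for s >= 0 (monotone, so bisection);
# closed form when the cap never binds
solve_cell_scale <- function(p, target, tol = 1e-12) {
  if (target <= 0) return(0)
  s0 <- target / mean(p)
  if (max(s0 * p) <= 1) return(s0)
  f <- function(s) mean(pmin(1, s * p)) - target
  lo <- 0; hi <- max(s0, 1)
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e12) stopf("calibration: target probability unreachable")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

#' Calibrate predicted risk to observed event rates
#'
#' For every age-band/sex cell, finds the multiplicative scale on predicted
#' five-year risk (capped at probability 1) such that the mean calibrated
#' prediction among eligible (non-prior-CVD) respondents equals the
#' observed five-year first-event probability. When the cap binds the
#' scale is found by bisection.
#'
#' @param survey a `cvd_survey`.
#' @param eq a [risk_equation()].
#' @param epi observed `cvd_epidemiology`.
#' @return a `cvd_calibration` data frame (band, sex, scale).
#' @export
calibrate_risk <- function(survey, eq, epi) {
  eligible <- survey[!survey$prior_cvd, ]
  obs <- observed_5yr_probability(epi)
  cells <- unique(survey[, c("band", "sex")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    b <- cells$band[i]; s <- cells$sex[i]
    rec <- eligible[eligible$band == b & eligible$sex == s, ]
    if (nrow(rec) == 0)
      stopf("calibration: no eligible records in cell (%s, %s)", b, s)
    target <- obs$p5[obs$band == b & obs$sex == s]
    if (length(target) != 1)
      stopf("calibration: epidemiology missing cell (%s, %s)", b, s)
    p <- predict_5yr_risk(rec, eq)
    data.frame(band = b, sex = s, scale = solve_cell_scale(p, target),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cvd_calibration", "data.frame")
  out
}

#' Absolute-risk band specification
#'
#' Three treatment-eligibility levels of five-year CVD risk — at least
#' 15%, 10 to 14%, and 5 to 9% — plus the residual below-5% stratum.
#'
#' @param thresholds increasing band lower bounds on the probability scale.
#' @param labels band labels, lowest first (residual band first).
#' @return a `cvd_risk_bands` list.
#' @export
risk_band_spec <- function(thresholds = c(0.05, 0.10, 0.15),
                           labels = c("lt5", "5-9", "10-14", "ge15")) {
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0 | thresholds >= 1))
    stopf("risk bands: thresholds must be strictly increasing in (0,1)")
  if (length(labels) != length(thresholds) + 1)
    stopf("risk bands: need one more label than thresholds")
  structure(list(thresholds = thresholds, labels = labels),
            class = "cvd_risk_bands")
}

#' Assign risks to bands
#'
#' @param p vector of five-year risks.
#' @param bands a [risk_band_spec()].
#' @return factor of band labels (ordered, lowest first).
#' @export
assign_band <- function(p, bands = risk_band_spec()) {
  idx <- findInterval(p, bands$thresholds) + 1L
  factor(bands$labels[idx], levels = bands$labels, ordered = TRUE)
}

#' Stratify the survey into risk bands
#'
#' Partitions eligible (non-prior-CVD) respondents into risk bands within
#' each age-band/sex cell, recording counts, mean calibrated risk, and the
#' band's mean risk relative to the cell mean ("initial CVD risk relative
#' to the mean risk in the population, by age and sex").
#'
#' @param survey a `cvd_survey`.
#' @param eq a [risk_equation()].
#' @param cal a `cvd_calibration` from [calibrate_risk()].
#' @param bands a [risk_band_spec()].
#' @return a `cvd_strata` data frame, one row per (band, age band, sex)
#'   with columns `eligible_count`, `mean_risk`, `mean_relative_risk`,
#'   `eligible_fraction` (of the cell's respondents, prior-CVD included)
#'   and cell means as attributes.
#' @export
stratify <- function(survey, eq, cal, bands = risk_band_spec()) {
  eligible <- survey[!survey$prior_cvd, ]
  p <- predict_5yr_risk(eligible, eq, cal)
  rb <- assign_band(p, bands)
  key <- interaction(eligible$band, eligible$sex, drop = FALSE)
  cell_mean <- tapply(p, key, mean)
  cells <- unique(survey[, c("band", "sex")])
  n_cell_all <- table(interaction(survey$band, survey$sex, drop = FALSE))
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    b <- cells$band[i]; s <- cells$sex[i]
    sel <- eligible$band == b & eligible$sex == s
    cm <- mean(p[sel])
    for (rband in bands$labels) {
      in_band <- sel & rb == rband
      cnt <- sum(in_band)
      mr <- if (cnt > 0) mean(p[in_band]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        band = b, sex = s, risk_band = rband,
        eligible_count = cnt,
        mean_risk = mr,
        mean_relative_risk = if (cnt > 0) mr / cm else NA_real_,
        eligible_fraction = cnt / n_cell_all[[paste(b, s, sep = ".")]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$risk_band <- factor(out$risk_band, levels = bands$labels,
                          ordered = TRUE)
  attr(out, "cell_mean_risk") <- cell_mean
  attr(out, "n_eligible") <- nrow(eligible)
  attr(out, "bands") <- bands
  class(out) <- c("cvd_strata", "data.frame")
  out
}

#' Primary-care reach of risk assessment
#'
#' The fraction of the target population reachable through primary care:
#' the product of the annual GP attendance fraction and GP participation
#' in CVD risk assessment. Population-wide interventions bypass this
#' (coverage 1 by construction).
#'
#' @param gp_attendance fraction of 35-84 year olds visiting a GP per year.
#' @param assessment_participation GP participation in risk assessment.
#' @return reachable fraction.
#' @export
primary_care_coverage <- function(gp_attendance, assessment_participation) {
  if (gp_attendance < 0 || gp_attendance > 1 ||
      assessment_participation < 0 || assessment_participation > 1)
    stopf("coverage fractions must be in [0,1]")
  gp_attendance * assessment_participation
}

#' Serialize / restore a risk equation and calibration as JSON
#'
#' @param eq a [risk_equation()].
#' @param cal a `cvd_calibration`.
#' @param path file path.
#' @return `read_risk_model` returns `list(equation, calibration)`.
#' @export
write_risk_model <- function(eq, cal, path) {
  jsonlite::write_json(
    list(equation = list(coefficients = as.list(eq$coefficients),
                         intercept = eq$intercept,
                         centre = as.list(eq$centre)),
         calibration = cal),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  eq <- risk_equation(coefficients = unlist(raw$equation$coefficients),
                      intercept = raw$equation$intercept,
                      centre = unlist(raw$equation$centre))
  cal <- raw$calibration
  class(cal) <- c("cvd_calibration", "data.frame")
  list(equation = eq, calibration = cal)
}
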