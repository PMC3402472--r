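# Built-in library of primary-prevention interventions: two population-wide
# strategies (community heart health program, mandatory salt limits in
# bread/margarine/cereal manufacture), six drug classes delivered in
# primary care by absolute-risk band, three behaviour-change strategies,
# and the current-practice components (voluntary salt reduction, dietary
# advice, blood pressure- and lipid-lowering as currently prescribed).
# Costs are 2008 Australian dollars per person per year; values carry their
# published means and standard errors.

#' Built-in intervention library
#'
#' Returns the full set of modelled interventions with mean effect sizes,
#' standard errors and annual costs. Behaviour-change interventions carry a
#' long-run `effect_scale` of 0.01 reflecting near-complete decay of the
#' trial effect at the population level (see the methods vignette); drug
#' and salt interventions are fully sustained in adherers.
#'
#' @param statin_price `"australia"` ($687/year) or `"nz"` ($19/year,
#'   New Zealand pricing scenario).
#' @return named list of [intervention()] objects.
#' @export
builtin_intervention_library <- function(statin_price = c("australia", "nz")) {
  statin_price <- match.arg(statin_price)
  statin_cost <- if (statin_price == "nz") 19 else 687
  lib <- list(
    thiazide = intervention(
      "Thiazide diuretic", "primary_care",
      effect = list(rr = c(ihd = 0.86, stroke = 0.62),
                    rr_se = c(ihd = 0.06, stroke = 0.05)),
      cost_year1 = 71),
    beta_blocker = intervention(
      "Beta-blocker", "primary_care",
      effect = list(rr = c(ihd = 0.89, stroke = 0.83),
                    rr_se = c(ihd = 0.06, stroke = 0.07)),
      cost_year1 = 106),
    ccb = intervention(
      "Calcium channel blocker", "primary_care",
      effect = list(rr = c(ihd = 0.85, stroke = 0.66),
                    rr_se = c(ihd = 0.04, stroke = 0.04)),
      cost_year1 = 218),
    ace_inhibitor = intervention(
      "ACE inhibitor", "primary_care",
      effect = list(rr = c(ihd = 0.83, stroke = 0.78),
                    rr_se = c(ihd = 0.03, stroke = 0.07)),
      cost_year1 = 212),
    aspirin = intervention(
      "Aspirin", "primary_care",
      effect = list(rr = c(ihd = 0.82, stroke_isch = 0.86,
                           stroke_haem = 1.32, gi_bleed = 1.54),
                    rr_se = c(ihd = 0.04, stroke_isch = 0.07,
                              stroke_haem = 0.19, gi_bleed = 0.13)),
      cost_year1 = 40),
    statin = intervention(
      "Statin", "primary_care",
      effect = list(rr = c(ihd = 0.70, stroke = 0.81),
                    rr_se = c(ihd = 0.05, stroke = 0.06)),
      cost_year1 = statin_cost,
      price_scenarios = list(australia = 687, nz = 19),
      share_group = "statin_rr"),
    phytosterol = intervention(
      "Phytosterol margarine", "primary_care",
      effect = list(tc_pct = 7.5, tc_pct_se = 1.9),
      cost_year1 = 258, cost_year1_se = 38, cost_subsequent_se = 38,
      effect_scale = 0.01),
    dietary_advice = intervention(
      "Dietary advice", "primary_care",
      effect = list(sbp_pct = 1.6, sbp_pct_se = 0.4,
                    tc_pct = 3.1, tc_pct_se = 1.2),
      cost_year1 = 132, cost_subsequent = 86,
      cost_year1_se = 213, cost_subsequent_se = 39,
      effect_scale = 0.01),
    lifestyle_program = intervention(
      "Lifestyle program", "primary_care",
      effect = list(sbp_pct = 2.6, sbp_pct_se = 0.5,
                    tc_pct = 3.3, tc_pct_se = 0.6),
      cost_year1 = 257, cost_subsequent = 172,
      cost_year1_se = 152, cost_subsequent_se = 58,
      effect_scale = 0.01),
    community_program = intervention(
      "Community heart health program", "population_wide",
      effect = list(sbp_pct = 2.5, sbp_pct_se = 0.7,
                    tc_pct = -0.51, tc_pct_se = 0.6),
      cost_year1 = 2.37, cost_subsequent = 1.60,
      cost_year1_se = 0.47, cost_subsequent_se = 0.32,
      effect_scale = 0.01),
    mandatory_salt = intervention(
      "Mandatory salt limits", "population_wide",
      effect = list(sodium = c(male = 10.6, female = 7.3),
                    sodium_se = c(male = 0.74, female = 0.53)),
      cost_year1 = 0.81, cost_year1_se = 0.08, cost_subsequent_se = 0.08),
    voluntary_salt = intervention(
      "Voluntary salt limits (current practice)", "population_wide",
      effect = list(sodium = c(male = 0.50, female = 0.34),
                    sodium_se = c(male = 0.03, female = 0.02)),
      cost_year1 = 0.49, cost_year1_se = 0.05, cost_subsequent_se = 0.05),
    lipid_current = intervention(
      "Lipid-lowering (current practice)", "primary_care",
      effect = list(rr = c(ihd = 0.70, stroke = 0.81),
                    rr_se = c(ihd = 0.05, stroke = 0.06)),
      cost_year1 = 683, share_group = "statin_rr"),
    bp_current = intervention(
      "BP-lowering (current practice)", "primary_care",
      effect = list(rr = c(ihd = 0.85, stroke = 0.70),
                    rr_se = c(ihd = 0.04, stroke = 0.05)),
      cost_year1 = 170)
  )
  lib
}
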