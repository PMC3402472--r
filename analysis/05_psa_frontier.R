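#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis of the main strategy choices and the
# cost-effectiveness acceptability frontier over thresholds up to
# $150,000/DALY.

suppressPackageStartupMessages(library(cvdcea))

seed <- 2008
n_draws <- 300
dir.create("results", showWarnings = FALSE)

ctx <- build_model_context(demog = demography_spec(survey_n = 500),
                           seed = seed)

all_bands <- c("5-9", "10-14", "ge15")
scenarios <- list(
  "Do nothing +salt" = cea_scenario("Do nothing +salt", list(
    list(ref = "mandatory_salt"))),
  "Current practice" = cea_scenario("Current practice",
                                    ctx$current_practice),
  "Salt + BP drugs" = cea_scenario("Salt + BP drugs", list(
    list(ref = "mandatory_salt"),
    list(ref = "thiazide", bands = all_bands),
    list(ref = "ccb", bands = all_bands),
    list(ref = "ace_inhibitor", bands = all_bands))),
  "Salt + BP drugs + statin" = cea_scenario("Salt + BP drugs + statin", list(
    list(ref = "mandatory_salt"),
    list(ref = "thiazide", bands = all_bands),
    list(ref = "ccb", bands = all_bands),
    list(ref = "ace_inhibitor", bands = all_bands),
    list(ref = "statin", bands = all_bands))))

psa <- run_psa(scenarios, ctx, n_draws = n_draws, seed = seed)
write.table(psa$summary, "results/psa_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

frontier <- acceptability_frontier(psa)
write.table(frontier, "results/acceptability_frontier.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("PSA with %d draws over %d packages\n", n_draws,
            length(scenarios)))
for (nm in names(scenarios))
  cat(sprintf("  P(%s cost-effective at $50k/DALY) = %.2f\n", nm,
              psa$prob_cost_effective[[nm]]))
fr50 <- frontier[frontier$threshold == 50000 & frontier$is_frontier, ]
cat(sprintf("at $50,000/DALY the optimal package is '%s' (P = %.2f)\n",
            fr50$package, fr50$prob_optimal))
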