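#!/usr/bin/env Rscript
# Generate the synthetic model inputs: an individual-level risk-factor
# survey (national health-survey structure), age/sex epidemiology tables, and the
# intervention library, exported as plain text under results/inputs/.

suppressPackageStartupMessages(library(cvdcea))

seed <- 2008
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

demog <- demography_spec(survey_n = 500)
survey <- generate_survey(demog, seed = seed)
epi <- generate_epidemiology(seed = seed)
lib <- builtin_intervention_library()

write_survey_csv(survey, file.path(out, "survey.csv"))
write.table(as.data.frame(epi), file.path(out, "epidemiology.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write_intervention_library(lib, file.path(out, "interventions.json"))

eligible <- survey[!survey$prior_cvd, ]
cat(sprintf("survey: %d respondents (%d eligible, %.1f%% with prior CVD)\n",
            nrow(survey), nrow(eligible),
            100 * mean(survey$prior_cvd)))
cat(sprintf("smoking prevalence: %.1f%% (men) / %.1f%% (women)\n",
            100 * mean(survey$smoker[survey$sex == "male"]),
            100 * mean(survey$smoker[survey$sex == "female"])))
cat(sprintf("IHD incidence spans %.2g to %.2g per person-year across bands\n",
            min(epi$ihd_incidence), max(epi$ihd_incidence)))
cat(sprintf("%d interventions in the library\n", length(lib)))
cat("inputs written to", out, "\n")
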