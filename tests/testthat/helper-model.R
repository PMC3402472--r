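# Shared fixtures, built in code and memoised so each is constructed once
# per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# mid-sized synthetic world shared across CEA tests
test_ctx <- function() {
  memo("ctx", build_model_context(demog = demography_spec(survey_n = 200),
                                  seed = 42))
}

# single-cell toy context: one male 60-64 high-risk cohort, used where an
# analytic oracle needs a fast, transparent model
toy_ctx <- function() {
  memo("toy_ctx", {
    ctx <- build_model_context(demog = demography_spec(survey_n = 120),
                               seed = 11)
    cell <- ctx$cells[ctx$cells$band == "60-64" & ctx$cells$sex == "male" &
                        ctx$cells$risk_band == "ge15", ]
    if (nrow(cell) == 0)
      cell <- ctx$cells[ctx$cells$sex == "male" &
                          ctx$cells$risk_band == "ge15", ][1, ]
    ctx$cells <- cell
    rownames(ctx$cells) <- NULL
    ctx$cache <- new.env(parent = emptyenv())
    ctx
  })
}

# epidemiology with a constant, age-flat background hazard and no disease
flat_mortality_epi <- function(m = 0.4) {
  generate_epidemiology(epi_spec(
    ihd_at50 = c(male = 0, female = 0), stroke_at50 = c(male = 0, female = 0),
    gi_bleed_at50 = 0,
    bg_mort_at50 = c(male = m, female = m),
    bg_mort_slope = c(male = 0, female = 0)))
}

# exhaustive path enumeration over the four-state chain: occupancy after
# each cycle as a sum over all state sequences, independent of the cohort
# simulation loop
enumerate_occupancy <- function(n, matrices) {
  states <- c("well", "ihd", "stroke", "dead")
  occ <- list()
  paths <- list(list(seq = "well", prob = 1))
  for (t in seq_along(matrices)) {
    M <- matrices[[t]]
    new_paths <- list()
    for (p in paths) {
      from <- p$seq[length(p$seq)]
      for (to in states) {
        pr <- M[from, to]
        if (pr > 0)
          new_paths[[length(new_paths) + 1]] <-
            list(seq = c(p$seq, to), prob = p$prob * pr)
      }
    }
    paths <- new_paths
    o <- stats::setNames(numeric(4), states)
    for (p in paths) {
      end <- p$seq[length(p$seq)]
      o[end] <- o[end] + p$prob
    }
    occ[[t]] <- n * o
  }
  occ
}

# intervention with fully fixed parameters (no uncertainty)
fixed_intervention <- function(name = "fixed drug", rr_ihd = 0.8,
                               rr_stroke = 0.7, cost = 100,
                               bands = c("5-9", "10-14", "ge15")) {
  intervention(name, "primary_care", target_bands = bands,
               effect = list(rr = c(ihd = rr_ihd, stroke = rr_stroke)),
               cost_year1 = cost)
}
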