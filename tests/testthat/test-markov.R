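# Markov cohort model: transition assembly, simulation, weighting,
# discounting, cost bookkeeping

test_that("transition matrix degenerates and scales as expected", {
  e0 <- generate_epidemiology(epi_spec(
    ihd_at50 = c(male = 0, female = 0), stroke_at50 = c(male = 0, female = 0),
    bg_mort_at50 = c(male = 0, female = 0), gi_bleed_at50 = 0))
  M <- transition_matrix(60, "male", 2008, e0,
                         config = model_config(ihd_excess_mortality = 0,
                                               stroke_excess_mortality = 0))
  expect_equal(unname(M), diag(4), tolerance = 1e-15)

  epi <- generate_epidemiology()
  M1 <- transition_matrix(60, "male", 2008, epi, rr_mods = 1)
  Mnull <- transition_matrix(60, "male", 2008, epi,
                             rr_mods = c(ihd = 1, stroke = 1, gi_bleed = 1))
  expect_identical(M1, Mnull)
  # rows always sum to one
  for (age in c(37, 52, 71, 95)) {
    M <- transition_matrix(age, "female", 2015, epi,
                           rr_mods = c(ihd = 0.7, stroke = 0.8))
    expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("secular trend compounds exactly as trend^years", {
  epi <- generate_epidemiology(epi_spec(ihd_trend = 0.98))
  # extract the well->event hazard through the matrix at two dates
  cfg <- model_config(gi_case_fatality = 0, cf_trend = FALSE)
  p_at <- function(year) {
    M <- transition_matrix(60, "male", year, epi, config = cfg)
    M["well", "ihd"] + 0  # non-fatal IHD flow
  }
  # under pure trend scaling of the hazard, recover the hazard ratio
  hz <- function(year) {
    M <- transition_matrix(60, "male", year, epi, config = cfg)
    p_exit <- 1 - M["well", "well"]
    # invert the competing-risk allocation: hazard proportional to flows
    -log(1 - p_exit) * (M["well", "ihd"] / (1 - M["well", "well"]))
  }
  cf <- epi$ihd_case_fatality[epi$band == "60-64" & epi$sex == "male"]
  h0 <- hz(2008) / (1 - cf)
  h10 <- hz(2018) / (1 - cf)
  brute <- prod(rep(0.98, 10))
  expect_equal(h10 / h0, brute, tolerance = 1e-10)
  expect_equal(brute, 0.98^10, tolerance = 1e-12)
})

test_that("cohort simulation conserves people and ends in extinction", {
  epi <- generate_epidemiology()
  tr <- simulate_cohort(1000, 62.5, "female", epi,
                        rr = c(ihd = 0.8, stroke = 0.75))
  occ <- tr$well + tr$ihd + tr$stroke + tr$dead
  expect_equal(occ, rep(1000, nrow(tr)), tolerance = 1e-9)
  expect_true(all(diff(tr$dead) >= 0))
  expect_true(all(tr[, c("well", "ihd", "stroke", "dead")] >= 0))
  # by the age cap (110) essentially everyone has died
  alive_end <- 1000 - tr$dead[nrow(tr)]
  expect_lt(alive_end, 0.01 * 1000)

  # cohort of zero: an all-zero trace
  tr0 <- simulate_cohort(0, 62.5, "female", epi)
  expect_true(all(tr0$well == 0) && all(tr0$dead == 0))
  expect_equal(sum(tr0$cost_disease), 0)
})

test_that("two-state toy matches hand-computed occupancy", {
  # no disease, constant mortality 0.4/yr: survival is (e^-0.4)^t
  epi <- flat_mortality_epi(0.4)
  tr <- simulate_cohort(100, 50, "male", epi,
                        config = model_config(ihd_excess_mortality = 0,
                                              stroke_excess_mortality = 0))
  s <- exp(-0.4)
  expect_equal(tr$well[1:4], 100 * s^(0:3), tolerance = 1e-12)
  expect_equal(tr$dead[1:4], 100 * (1 - s^(0:3)), tolerance = 1e-12)
})

test_that("matrix simulation equals exhaustive path enumeration", {
  epi <- generate_epidemiology()
  cfg <- model_config()
  n <- 1000
  rr <- c(ihd = 0.8, stroke = 0.7, gi_bleed = 1.5)
  tr <- simulate_cohort(n, 72.5, "male", epi, rr = rr, config = cfg)
  mats <- lapply(1:3, function(t)
    transition_matrix(72.5 + t - 1, "male", 2008 + t - 1, epi,
                      rr_mods = rr, config = cfg))
  oracle <- enumerate_occupancy(n, mats)
  for (t in 1:3) {
    # trace row t+1 records occupancy after t cycles
    got <- as.numeric(tr[t + 1, c("well", "ihd", "stroke", "dead")])
    expect_equal(got, unname(oracle[[t]]), tolerance = 1e-12)
  }
})

test_that("discounted life expectancy matches the geometric closed form", {
  m <- 0.4
  epi <- flat_mortality_epi(m)
  cfg <- model_config(ihd_excess_mortality = 0, stroke_excess_mortality = 0,
                      age_cap = 2000, extinction_tol = 1e-15)
  r <- 0.03
  tr <- simulate_cohort(1, 50, "male", epi, config = cfg)
  le <- discounted_sum(tr$life_years, r)
  p <- 1 - exp(-m)
  closed <- (1 + r) / (r + p)   # sum_{t>=0} ((1-p)/(1+r))^t
  expect_equal(le, closed, tolerance = 1e-9)
  # undiscounted case too
  expect_equal(discounted_sum(tr$life_years, 0), 1 / p, tolerance = 1e-9)
})

test_that("discounted_sum matches the annuity closed form", {
  expect_equal(discounted_sum(c(1, 1, 1), 0), 3)
  v <- 1 / 1.03
  expect_equal(discounted_sum(rep(1, 10), 0.03), (1 - v^10) / (1 - v),
               tolerance = 1e-12)
  expect_equal(discounted_sum(numeric(0), 0.03), 0)
  # higher rates never increase a non-negative stream's present value
  set.seed(1)
  for (i in 1:20) {
    stream <- runif(30, 0, 10)
    expect_lte(discounted_sum(stream, 0.05), discounted_sum(stream, 0.03))
    expect_lte(discounted_sum(stream, 0.03), discounted_sum(stream, 0))
  }
})

test_that("health-adjusted years weight occupancy as documented", {
  epi <- generate_epidemiology()
  tr <- simulate_cohort(1000, 62.5, "male", epi,
                        rr = c(ihd = 1, stroke = 1))
  # all-zero disability: the stream is plain life years
  w0 <- health_state_weights(disability = c(well = 0, ihd = 0, stroke = 0,
                                            gi_bleed = 0),
                             background_at35 = 0, background_slope = 0)
  expect_equal(health_adjusted_years(tr, w0, "DALY"), tr$life_years,
               tolerance = 1e-12)
  # matched weights: DALY and QALY streams coincide
  w <- health_state_weights()
  expect_equal(health_adjusted_years(tr, w, "DALY"),
               health_adjusted_years(tr, w, "QALY"), tolerance = 1e-12)
  # occupancy fully in the stroke state with disability 0.3 -> 0.7x
  toy <- tr[5, ]
  toy$well <- 0; toy$ihd <- 0; toy$stroke <- 400; toy$gi_events <- 0
  attr(toy, "sex") <- "male"
  w3 <- health_state_weights(disability = c(well = 0, ihd = 0.15,
                                            stroke = 0.3, gi_bleed = 0.1),
                             background_at35 = 0, background_slope = 0)
  expect_equal(health_adjusted_years(toy, w3, "DALY"), 0.7 * 400,
               tolerance = 1e-12)
})

test_that("disease cost bookkeeping charges incidence then prevalence", {
  ct <- disease_cost_table(ihd = c(0, 0), stroke = c(5000, 1200),
                           gi_bleed = c(0, 0))
  trace <- data.frame(cycle = 1:2, age = c(60, 61),
                      well = c(100, 88), ihd = c(0, 0),
                      stroke = c(0, 8), dead = c(0, 4),
                      ihd_events = c(0, 0), stroke_events = c(10, 0),
                      gi_events = c(0, 0), life_years = c(100, 96))
  attr(trace, "sex") <- "male"
  stream <- disease_costs(trace, ct)
  expect_equal(stream, c(10 * 5000, 8 * 1200))
  # linearity: doubling the cohort doubles every entry
  trace2 <- trace
  for (col in c("well", "ihd", "stroke", "dead", "ihd_events",
                "stroke_events", "gi_events")) trace2[[col]] <- 2 * trace[[col]]
  expect_equal(disease_costs(trace2, ct), 2 * stream)
  expect_error(disease_costs(trace, disease_cost_table()[1:2, ]),
               "gi_bleed")
})

test_that("lowering any channel's RR never reduces health-adjusted years", {
  epi <- generate_epidemiology()
  w <- health_state_weights()
  total <- function(rr) {
    tr <- simulate_cohort(1000, 57.5, "female", epi, rr = rr, weights = w)
    discounted_sum(tr$haly_daly, 0.03)
  }
  base <- c(ihd = 0.9, stroke_isch = 0.9, stroke_haem = 0.9, gi_bleed = 1)
  t0 <- total(base)
  for (ch in c("ihd", "stroke_isch", "stroke_haem", "gi_bleed")) {
    low <- base
    low[ch] <- low[ch] * 0.7
    expect_gte(total(low), t0)
  }
  # and a harm (gi_bleed above 1) reduces them
  harm <- base
  harm["gi_bleed"] <- 1.8
  expect_lt(total(harm), t0)
})

test_that("null scenario reproduces the do-nothing trace exactly", {
  epi <- generate_epidemiology()
  tr_null <- simulate_cohort(500, 67.5, "male", epi)
  tr_rr1 <- simulate_cohort(500, 67.5, "male", epi,
                            rr = c(ihd = 1, stroke = 1, gi_bleed = 1),
                            intervention_cost = function(y) c(0, 0))
  expect_equal(as.data.frame(tr_rr1), as.data.frame(tr_null),
               tolerance = 1e-15)
})

test_that("trace export writes a readable delimited file", {
  epi <- generate_epidemiology()
  tr <- simulate_cohort(10, 62.5, "male", epi)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path, "demo")
  lines <- readLines(path, n = 2)
  expect_match(lines[1], "scenario: demo")
  back <- utils::read.delim(path, skip = 1)
  expect_equal(nrow(back), nrow(tr))
})
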