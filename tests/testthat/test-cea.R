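# Generalized CEA: do-nothing back-calculation, scenario evaluation,
# expansion pathway, PSA and acceptability frontier

test_that("back-calculation inverts current practice exactly", {
  ctx <- test_ctx()
  # identity: zero-coverage current practice leaves rates unchanged
  cp0 <- cea_scenario("no practice", list(
    list(ref = "bp_current", bands = c("ge15"), uptake = 0)))
  rr_bar0 <- average_effective_rr(cp0, ctx)
  null0 <- backcalculate_null(ctx$epi_observed, rr_bar0)
  expect_equal(null0$ihd_incidence, ctx$epi_observed$ihd_incidence,
               tolerance = 1e-15)
  # uniform RR 0.9: a scalar division
  rr_bar9 <- rr_bar0
  rr_bar9[, c("ihd", "stroke_isch", "stroke_haem", "gi_bleed")] <- 0.9
  null9 <- backcalculate_null(ctx$epi_observed, rr_bar9)
  expect_equal(null9$ihd_incidence, ctx$epi_observed$ihd_incidence / 0.9,
               tolerance = 1e-12)
  expect_equal(null9$stroke_incidence,
               ctx$epi_observed$stroke_incidence / 0.9, tolerance = 1e-12)
  # round trip through the real current practice
  recovered <- apply_average_rr(ctx$null_epi, ctx$rr_bar)
  expect_equal(recovered$ihd_incidence, ctx$epi_observed$ihd_incidence,
               tolerance = 1e-9)
  expect_equal(recovered$stroke_incidence,
               ctx$epi_observed$stroke_incidence, tolerance = 1e-9)
  expect_equal(recovered$gi_bleed_incidence,
               ctx$epi_observed$gi_bleed_incidence, tolerance = 1e-9)
  # degenerate average RR is refused
  rr_bad <- rr_bar0
  rr_bad$ihd <- 0
  expect_error(backcalculate_null(ctx$epi_observed, rr_bad), "<= 0")
})

test_that("evaluating the do-nothing scenario gives exactly nothing", {
  ctx <- test_ctx()
  o <- evaluate_vs_null(cea_scenario("nothing", list()), ctx)
  expect_equal(o$health_gain, 0)
  expect_equal(o$net_cost, 0)
  expect_equal(o$cost_gov, 0)
})

test_that("outcome arithmetic and dominance classification", {
  t0 <- c(daly = 1000, qaly = 1000, ly = 1100, cost_gov = 0, cost_pat = 0,
          cost_disease = 5e6)
  t1 <- c(daly = 1010, qaly = 1010, ly = 1110, cost_gov = 2e5,
          cost_pat = 5e4, cost_disease = 4.9e6)
  o <- cvdcea:::outcome_from_totals(t1, t0, "daly")
  expect_equal(o$health_gain, 10)
  expect_equal(o$treatment_costs_averted, -1e5)
  expect_equal(o$net_cost, 2e5 + 5e4 - 1e5)
  expect_equal(o$icer, 1.5e5 / 10)
  expect_equal(o$classification, "icer")
  # cost saving with positive gain: Dominant
  t2 <- t1; t2[["cost_gov"]] <- 1e4
  expect_equal(cvdcea:::outcome_from_totals(t2, t0, "daly")$classification,
               "dominant")
  # positive cost with no gain: dominated, not an error
  t3 <- t1; t3[["daly"]] <- 999
  expect_equal(cvdcea:::outcome_from_totals(t3, t0, "daly")$classification,
               "dominated")
})

test_that("vectorized cell engine agrees with the cohort trace engine", {
  ctx <- toy_ctx()
  scn <- cea_scenario("one drug", list(list(ref = "thiazide",
                                            bands = "ge15")))
  totals <- evaluate_scenario(scn, ctx)
  # rebuild the same cohort with the single-cohort trace engine
  arrays <- cvdcea:::scenario_arrays(scn, ctx)
  cell <- ctx$cells[1, ]
  rr_fun <- function(y) arrays$rr[1, min(y, arrays$n_years), ]
  cost_fun <- function(y) c(arrays$cost_gov[1, min(y, arrays$n_years)],
                            arrays$cost_pat[1, min(y, arrays$n_years)])
  tr <- simulate_cohort(cell$population, cell$entry_age, cell$sex,
                        ctx$null_epi, rr = rr_fun,
                        intervention_cost = cost_fun,
                        weights = ctx$weights, dcosts = ctx$dcosts,
                        rel_risk = cell$rel_risk, config = ctx$config)
  expect_equal(totals[["daly"]], discounted_sum(tr$haly_daly, ctx$discount),
               tolerance = 1e-6)
  expect_equal(totals[["cost_disease"]],
               discounted_sum(tr$cost_disease, ctx$discount),
               tolerance = 1e-6)
  expect_equal(totals[["cost_gov"]],
               discounted_sum(tr$cost_int_gov, ctx$discount),
               tolerance = 1e-6)
})

test_that("expansion path: single candidate equals its vs-null evaluation", {
  ctx <- test_ctx()
  cand <- list(list(name = "thiazide", bands = "ge15"))
  path <- expansion_path(cand, ctx)
  o <- evaluate_vs_null(cea_scenario("solo", list(
    list(ref = "thiazide", bands = "ge15"))), ctx)
  expect_equal(nrow(path$steps), 1)
  expect_equal(path$steps$inc_health_gain, o$health_gain, tolerance = 1e-9)
  expect_equal(path$steps$inc_net_cost, o$net_cost, tolerance = 1e-9)
})

test_that("overlapping candidates shrink each other's incremental gain", {
  ctx <- test_ctx()
  lib <- ctx$lib
  lib$drug_a <- fixed_intervention("Drug A", bands = "ge15")
  lib$drug_b <- fixed_intervention("Drug B", bands = "ge15")
  ctx2 <- ctx
  ctx2$lib <- lib
  ctx2$cache <- new.env(parent = emptyenv())
  path <- expansion_path(list(list(name = "drug_a", bands = "ge15"),
                              list(name = "drug_b", bands = "ge15")),
                         ctx2)
  standalone_b <- evaluate_vs_null(
    cea_scenario("b", list(list(ref = "drug_b", bands = "ge15"))), ctx2)
  expect_equal(nrow(path$steps), 2)
  expect_lt(path$steps$inc_health_gain[2], standalone_b$health_gain)
})

test_that("threshold cut and exclusivity bookkeeping", {
  ctx <- test_ctx()
  path <- memo("default_path",
               expansion_path(default_candidates(ctx$lib), ctx))
  st <- path$steps
  # recompute the cut independently from the step table
  ok <- st$dominant | (!is.na(st$inc_icer) & st$inc_icer <= 50000)
  expected_cut <- if (all(ok)) nrow(st) else which(!ok)[1] - 1L
  expect_equal(path$threshold_cut, expected_cut)
  expect_gt(path$threshold_cut, 0)
  # dominant steps come first; ICERs are non-decreasing thereafter
  expect_true(all(diff(st$dominant) <= 0))
  expect_false(is.unsorted(st$inc_icer[!st$dominant]))
  # cumulative health gain is non-decreasing along the path
  expect_true(all(diff(st$cum_health_gain) > -1e-9))
  # skipped alternatives are labelled
  expect_true(all(grepl("alternative available", path$skipped$reason)))
  expect_true(any(grepl("Aspirin", path$skipped$label)))
  expect_true(any(grepl("Beta-blocker", path$skipped$label)))
})

test_that("candidate order never changes the selected path", {
  ctx <- test_ctx()
  cands <- list(list(name = "mandatory_salt", bands = "all"),
                list(name = "thiazide", bands = "ge15"),
                list(name = "ccb", bands = "ge15"),
                list(name = "statin", bands = "ge15"),
                list(name = "community_program", bands = "all"))
  p1 <- expansion_path(cands, ctx)
  p2 <- expansion_path(rev(cands), ctx)
  expect_identical(p1$steps$label, p2$steps$label)
  expect_equal(p1$steps$inc_icer, p2$steps$inc_icer, tolerance = 1e-9)
})

test_that("PSA is reproducible and degenerates with zero uncertainty", {
  ctx <- toy_ctx()
  scn <- list(drug = cea_scenario("drug", list(
    list(ref = fixed_intervention(), bands = "ge15"))))
  psa <- run_psa(scn, ctx, n_draws = 25, seed = 3)
  # no parameter uncertainty: every draw identical, zero-width interval
  s <- psa$summary
  hg <- s[s$quantity == "health_gain", ]
  expect_equal(hg$lo95, hg$hi95)
  expect_equal(hg$median, psa$point$drug$health_gain, tolerance = 1e-9)
  # same seed, same summaries; different seed may differ
  scn2 <- list(drug = cea_scenario("drug", list(
    list(ref = "thiazide", bands = "ge15"))))
  a <- run_psa(scn2, ctx, n_draws = 30, seed = 5)
  b <- run_psa(scn2, ctx, n_draws = 30, seed = 5)
  expect_identical(a$summary, b$summary)
  c3 <- run_psa(scn2, ctx, n_draws = 30, seed = 6)
  expect_false(identical(a$summary, c3$summary))
  expect_error(run_psa(scn2, ctx, n_draws = 1, seed = 1), ">= 2")
})

test_that("acceptability frontier behaves at its limiting cases", {
  ctx <- toy_ctx()
  scn <- list(drug = cea_scenario("drug", list(
    list(ref = "thiazide", bands = "ge15"))))
  psa <- run_psa(scn, ctx, n_draws = 40, seed = 2)
  fr <- acceptability_frontier(psa, thresholds = c(0, 50000, 150000))
  # single package: probability one everywhere
  expect_true(all(fr$prob_optimal == 1))
  # two packages: probabilities sum to one per threshold; lambda = 0
  # rewards the lower net cost in every draw
  scn2 <- list(cheap = cea_scenario("cheap", list(
    list(ref = "mandatory_salt"))),
    dear = cea_scenario("dear", list(
      list(ref = "statin", bands = "ge15"))))
  psa2 <- run_psa(scn2, ctx, n_draws = 60, seed = 4)
  fr2 <- acceptability_frontier(psa2, thresholds = seq(0, 100000, 20000))
  sums <- tapply(fr2$prob_optimal, fr2$threshold, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  at0 <- fr2[fr2$threshold == 0, ]
  cheaper <- mean(psa2$draws$cheap[, "net_cost"] <
                    psa2$draws$dear[, "net_cost"])
  expect_equal(at0$prob_optimal[at0$package == "cheap"], cheaper)
})

test_that("frontier crossing matches the closed-form NMB solution", {
  # synthetic two-package PSA with one normal parameter: package B beats A
  # when lambda * 100 > 2e6 + eps, eps ~ N(0, 5e5); the frontier therefore
  # crosses 50% at lambda = 20,000
  set.seed(8)
  nd <- 20000
  eps <- rnorm(nd, 0, 5e5)
  mk <- function(gain, net) {
    m <- cbind(health_gain = gain, cost_gov = net, cost_pat = 0,
               averted = 0, net_cost = net)
    m
  }
  psa <- list(draws = list(A = mk(rep(100, nd), rep(1e6, nd)),
                           B = mk(rep(200, nd), 3e6 + eps)),
              point = list(A = list(health_gain = 100, net_cost = 1e6),
                           B = list(health_gain = 200, net_cost = 3e6)))
  class(psa) <- "cvd_psa"
  fr <- acceptability_frontier(psa, thresholds = seq(10000, 30000, 500))
  pb <- fr$prob_optimal[fr$package == "B"]
  lam <- fr$threshold[fr$package == "B"]
  analytic <- pnorm((100 * lam - 2e6) / 5e5)
  expect_lt(max(abs(pb - analytic)), 3 / sqrt(nd) + 0.01)
  # crossing threshold within Monte Carlo error of 20,000
  crossing <- lam[which.min(abs(pb - 0.5))]
  expect_lt(abs(crossing - 20000), 1000)
})

test_that("package ledger satisfies the accounting identity", {
  ctx <- test_ctx()
  pkg <- cea_scenario("package", list(
    list(ref = "mandatory_salt"),
    list(ref = "thiazide", bands = c("5-9", "10-14", "ge15")),
    list(ref = "statin", bands = "ge15")))
  led <- package_ledger(pkg, ctx)
  v <- setNames(led$value, led$quantity)
  expect_equal(v[["net_cost"]],
               v[["cost_gov"]] + v[["cost_patient"]] +
                 v[["treatment_costs_averted"]], tolerance = 1e-9)
  # treatment costs averted are negative for an effective package
  expect_lt(v[["treatment_costs_averted"]], 0)
  # NZ statin pricing lowers government cost without touching health gain
  pkg_nz <- cea_scenario("package nz", pkg$components, statin_price = "nz")
  led_nz <- package_ledger(pkg_nz, ctx)
  v_nz <- setNames(led_nz$value, led_nz$quantity)
  expect_lt(v_nz[["cost_gov"]], v[["cost_gov"]])
  expect_equal(v_nz[["health_gain"]], v[["health_gain"]], tolerance = 1e-9)
})

test_that("ledger uncertainty intervals come from the PSA draws", {
  ctx <- toy_ctx()
  pkg <- cea_scenario("pkg", list(list(ref = "thiazide", bands = "ge15")))
  psa <- run_psa(list(pkg = pkg), ctx, n_draws = 50, seed = 9)
  led <- package_ledger(pkg, ctx, psa = psa)
  expect_true(all(c("lo95", "hi95") %in% names(led)))
  expect_true(all(led$lo95 <= led$hi95))
})
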