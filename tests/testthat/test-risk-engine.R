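# Risk prediction, calibration to observed rates, and stratification

make_records <- function(n = 4, band = "60-64", sex = "male", age = 62) {
  data.frame(id = seq_len(n), band = band, sex = sex, age = age,
             smoker = FALSE, total_chol = 5.5, hdl_chol = 1.35,
             diabetes = FALSE, sbp = 130, prior_cvd = FALSE,
             stringsAsFactors = FALSE)
}

test_that("risk prediction follows the equation and its monotonicities", {
  # all coefficients zero: the intercept sets a flat baseline risk
  eq0 <- risk_equation(coefficients = c(age = 0, male = 0, smoker = 0,
                                        total_chol = 0, hdl_chol = 0,
                                        diabetes = 0, sbp = 0),
                       intercept = qlogis(0.1))
  rec <- make_records(3)
  expect_equal(predict_5yr_risk(rec, eq0), rep(0.1, 3), tolerance = 1e-12)

  # calibration with scale 1 is the identity
  cal1 <- data.frame(band = "60-64", sex = "male", scale = 1)
  class(cal1) <- c("cvd_calibration", "data.frame")
  eq <- risk_equation()
  expect_equal(predict_5yr_risk(rec, eq, cal1), predict_5yr_risk(rec, eq))

  # smoking strictly raises risk; so do sbp, cholesterol, diabetes, age;
  # HDL lowers it
  base <- make_records(1)
  risk <- function(mod) {
    r <- base
    r[names(mod)] <- mod
    predict_5yr_risk(r, eq)
  }
  p0 <- predict_5yr_risk(base, eq)
  expect_gt(risk(list(smoker = TRUE)), p0)
  expect_gt(risk(list(sbp = 150)), p0)
  expect_gt(risk(list(total_chol = 6.5)), p0)
  expect_gt(risk(list(diabetes = TRUE)), p0)
  expect_gt(risk(list(age = 70)), p0)
  expect_lt(risk(list(hdl_chol = 1.8)), p0)

  # prior-CVD records are not eligible
  bad <- base; bad$prior_cvd <- TRUE
  expect_error(predict_5yr_risk(bad, eq), "prior CVD")
})

test_that("calibration matches cell means to observed probabilities", {
  ctx <- test_ctx()
  obs <- observed_5yr_probability(ctx$epi_observed)
  eligible <- ctx$survey[!ctx$survey$prior_cvd, ]
  p <- predict_5yr_risk(eligible, ctx$eq, ctx$cal)
  key <- paste(eligible$band, eligible$sex)
  for (cell in unique(key)) {
    target <- obs$p5[paste(obs$band, obs$sex) == cell]
    expect_equal(mean(p[key == cell]), target, tolerance = 1e-9,
                 label = sprintf("calibrated mean in cell %s", cell))
  }
  # idempotence: recalibrating predictions that already match gives 1
  p_unc <- predict_5yr_risk(eligible, ctx$eq)
  for (cell in unique(key)[1:4]) {
    sc <- ctx$cal$scale[paste(ctx$cal$band, ctx$cal$sex) == cell]
    stopifnot(max(sc * p_unc[key == cell]) < 1)  # cap inactive here
    target <- obs$p5[paste(obs$band, obs$sex) == cell]
    # linearity: halving the target halves the scale when the cap is slack
    half <- cvdcea:::solve_cell_scale(p_unc[key == cell], target / 2)
    expect_equal(half, sc / 2, tolerance = 1e-9)
  }
})

test_that("capped calibration matches a brute-force grid scan", {
  # risks where the cap at probability 1 binds before the mean hits target
  p <- c(0.5, 0.4, 0.05, 0.02)
  target <- 0.6
  s_bis <- cvdcea:::solve_cell_scale(p, target)
  expect_gt(max(s_bis * p), 1)  # capping is active
  grid <- seq(0.01, 40, by = 1e-4)
  obj <- vapply(grid, function(s) abs(mean(pmin(1, s * p)) - target),
                numeric(1))
  s_grid <- grid[which.min(obj)]
  expect_equal(s_bis, s_grid, tolerance = 1e-3)
  expect_equal(mean(pmin(1, s_bis * p)), target, tolerance = 1e-6)
  # degenerate: zero target gives zero scale; empty cell errors
  expect_equal(cvdcea:::solve_cell_scale(p, 0), 0)
  bad <- test_ctx()$survey
  bad$prior_cvd <- TRUE
  expect_error(calibrate_risk(bad, risk_equation(),
                              test_ctx()$epi_observed), "no eligible")
})

test_that("stratification partitions the eligible survey", {
  ctx <- test_ctx()
  st <- ctx$strata
  expect_equal(sum(st$eligible_count), attr(st, "n_eligible"))

  # 4-record toy survey with risks straddling every threshold
  eq0 <- risk_equation(coefficients = c(age = 0, male = 0, smoker = 0,
                                        total_chol = 0, hdl_chol = 0,
                                        diabetes = 0, sbp = 1),
                       intercept = 0, centre = c(age = 55, total_chol = 5.5,
                                                 hdl_chol = 1.35, sbp = 130))
  toy <- make_records(4)
  toy$sbp <- 130 + qlogis(c(0.04, 0.06, 0.12, 0.20))
  cal1 <- data.frame(band = "60-64", sex = "male", scale = 1)
  class(cal1) <- c("cvd_calibration", "data.frame")
  st_toy <- stratify(toy, eq0, cal1)
  counts <- tapply(st_toy$eligible_count, st_toy$risk_band, sum)
  expect_equal(as.numeric(counts[c("lt5", "5-9", "10-14", "ge15")]),
               c(1, 1, 1, 1))

  # weighted-mean identity per cell: sum(count x band mean) = n x cell mean
  p <- predict_5yr_risk(ctx$survey[!ctx$survey$prior_cvd, ], ctx$eq, ctx$cal)
  key <- paste(ctx$survey$band[!ctx$survey$prior_cvd],
               ctx$survey$sex[!ctx$survey$prior_cvd])
  for (cell in unique(key)[1:6]) {
    rows <- st[paste(st$band, st$sex) == cell & st$eligible_count > 0, ]
    lhs <- sum(rows$eligible_count * rows$mean_risk)
    rhs <- sum(key == cell) * mean(p[key == cell])
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }

  # mean relative risk rises with band severity within each cell
  for (cell in unique(paste(st$band, st$sex))) {
    rows <- st[paste(st$band, st$sex) == cell & st$eligible_count > 0, ]
    rows <- rows[order(rows$risk_band), ]
    if (nrow(rows) > 1)
      expect_true(!is.unsorted(rows$mean_relative_risk),
                  label = sprintf("relative risk ordering in %s", cell))
  }
})

test_that("raising a risk factor never lowers an individual's band", {
  eq <- risk_equation()
  bands <- risk_band_spec()
  base <- make_records(1)
  for (seed in 1:20) {
    set.seed(seed)
    r <- base
    r$age <- runif(1, 35, 84); r$sbp <- runif(1, 100, 200)
    r$total_chol <- runif(1, 3.5, 8); r$hdl_chol <- runif(1, 0.7, 2)
    r$smoker <- runif(1) < 0.5; r$diabetes <- runif(1) < 0.2
    b0 <- as.integer(assign_band(predict_5yr_risk(r, eq), bands))
    r2 <- r
    r2$sbp <- r$sbp + runif(1, 0, 40)
    expect_gte(as.integer(assign_band(predict_5yr_risk(r2, eq), bands)), b0)
  }
})

test_that("primary-care coverage is the product of its two fractions", {
  expect_equal(primary_care_coverage(1, 1), 1)
  expect_equal(primary_care_coverage(0.8, 0.5), 0.4)
  expect_error(primary_care_coverage(1.2, 0.5), "\\[0,1\\]")
})

test_that("risk model serializes and restores", {
  ctx <- test_ctx()
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(ctx$eq, ctx$cal, path)
  rm2 <- read_risk_model(path)
  expect_equal(rm2$equation$coefficients, ctx$eq$coefficients)
  expect_equal(rm2$calibration$scale, ctx$cal$scale, tolerance = 1e-12)
})
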