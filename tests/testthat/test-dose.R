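# Ventilation prediction and inhaled-dose integration.

test_that("ventilation predictions evaluate the published equations", {
  m2 <- ventilation_model("model2")
  # 4.0 * (-4.247 + 0.0595*100 + 0.226*20) = 24.892
  expect_equal(predict_ve(100, 20, fvc = 4.0, model = m2), 24.892,
               tolerance = 1e-12)
  # fvc = 1 returns VE/FVC itself
  expect_equal(predict_ve(100, 20, fvc = 1, model = m2),
               -4.247 + 5.95 + 4.52, tolerance = 1e-12)
  # very low heart rate extrapolates negative and is floored at zero
  m1 <- ventilation_model("model1")
  expect_equal(predict_ve(38, fvc = 4.0, model = m1), 0)
  expect_gt(predict_ve(39, fvc = 4.0, model = m1), 0)
  expect_error(predict_ve(100, fb = NULL, fvc = 4, model = m2),
               "requires a breathing-rate")
  expect_error(ventilation_model("custom", intercept = 1), "nonzero")
})

make_constant_scenario <- function(minutes = 30, hr = 120, fb = 25,
                                   conc = 10) {
  n <- minutes * 60
  list(
    physio = data.frame(t = 0:(n - 1), hr = hr, fb = fb, act = 0.3),
    conc = data.frame(t = 0:(minutes - 1), conc = conc),
    subject = data.frame(subject_id = "S001", age = 17, sex = 0, height = 175,
                         weight = 63, race = "caucasian", fvc_measured = 4.0)
  )
}

test_that("constant inputs give the closed-form rectangle dose", {
  sc <- make_constant_scenario(minutes = 30, hr = 120, fb = 25, conc = 10)
  model <- ventilation_model("model2")
  v <- predict_ve(120, 25, 4.0, model)
  res <- compute_dose(sc$physio, sc$conc, sc$subject, model)
  expect_equal(res$totals$dose_ug, 10 * v * 30 / 1000, tolerance = 1e-9)
  expect_equal(res$totals$volume_m3, v * 30 / 1000, tolerance = 1e-9)
  expect_equal(res$totals$exposure, 10 * 30, tolerance = 1e-9)
  expect_equal(res$totals$dose_ug_per_kg, res$totals$dose_ug / 63,
               tolerance = 1e-12)
  expect_equal(max(abs(res$series$ve - v)), 0)
  # cumulative dose reconciles with the increments
  expect_equal(res$series$cumulative_dose[nrow(res$series)],
               sum(res$series$dose), tolerance = 1e-9)
  expect_true(all(diff(res$series$cumulative_dose) >= 0))
})

test_that("zero pollutant means zero dose but nonzero breathing", {
  sc <- make_constant_scenario(conc = 0)
  res <- compute_dose(sc$physio, sc$conc, sc$subject, ventilation_model())
  expect_equal(res$totals$dose_ug, 0)
  expect_equal(res$totals$exposure, 0)
  expect_gt(res$totals$volume_m3, 0)
})

test_that("randomized scenarios match a per-second integration oracle", {
  set.seed(14)
  minutes <- 30
  n <- minutes * 60
  physio <- data.frame(t = 0:(n - 1),
                       hr = 80 + 60 * abs(sin((0:(n - 1)) / 300)) +
                         rnorm(n, 0, 3),
                       fb = 20 + rnorm(n, 0, 2), act = 0.3)
  conc <- data.frame(t = 0:(minutes - 1), conc = rexp(minutes, 1 / 8))
  subject <- data.frame(subject_id = "X", weight = 60, fvc_measured = 4.4)
  model <- ventilation_model("model2")
  res <- compute_dose(physio, conc, subject, model)
  # brute force: accumulate second by second
  ve_sec <- predict_ve(physio$hr, physio$fb, 4.4, model)
  conc_sec <- conc$conc[floor(physio$t / 60) + 1]
  dose_oracle <- sum(conc_sec * ve_sec / 60 / 1000)
  vol_oracle <- sum(ve_sec / 60 / 1000)
  expect_lt(abs(res$totals$dose_ug - dose_oracle) / dose_oracle, 0.001)
  expect_lt(abs(res$totals$volume_m3 - vol_oracle) / vol_oracle, 0.001)
})

test_that("dose is bilinear in concentration and lung size", {
  sc <- make_constant_scenario()
  model <- ventilation_model("model2")
  base <- compute_dose(sc$physio, sc$conc, sc$subject, model)
  sc2 <- sc; sc2$conc$conc <- 3 * sc$conc$conc
  expect_equal(compute_dose(sc2$physio, sc2$conc, sc$subject, model)$totals$dose_ug,
               3 * base$totals$dose_ug, tolerance = 1e-9)
  scf <- sc; scf$subject$fvc_measured <- 2 * sc$subject$fvc_measured
  expect_equal(compute_dose(sc$physio, sc$conc, scf$subject, model)$totals$dose_ug,
               2 * base$totals$dose_ug, tolerance = 1e-9)
})

test_that("exposure equals mean concentration times duration", {
  set.seed(15)
  sc <- make_constant_scenario(minutes = 45)
  sc$conc$conc <- runif(45, 0, 12)
  res <- compute_dose(sc$physio, sc$conc, sc$subject, ventilation_model())
  expect_equal(res$totals$exposure, mean(sc$conc$conc) * 45, tolerance = 1e-9)
})

test_that("partial minutes are weighted by coverage", {
  sc <- make_constant_scenario(minutes = 10)
  physio <- sc$physio[sc$physio$t >= 30 & sc$physio$t < 570, ]  # 9 min span
  res <- compute_dose(physio, sc$conc, sc$subject, ventilation_model())
  expect_equal(res$series$dt_min[1], 0.5)
  expect_equal(res$series$dt_min[nrow(res$series)], 0.5)
  expect_equal(sum(res$series$dt_min), 9)
})

test_that("coverage gaps and bad concentrations are rejected", {
  sc <- make_constant_scenario(minutes = 10)
  short <- sc$conc[1:5, ]
  expect_error(compute_dose(sc$physio, short, sc$subject,
                            ventilation_model()), "does not cover")
  gap <- sc$conc[-4, ]
  expect_error(compute_dose(sc$physio, gap, sc$subject, ventilation_model()),
               "1-minute grid")
  neg <- sc$conc; neg$conc[2] <- -1
  expect_error(compute_dose(sc$physio, neg, sc$subject, ventilation_model()),
               "negative")
})

test_that("NHANES-predicted FVC can replace measured FVC", {
  sc <- make_constant_scenario()
  m_meas <- ventilation_model("model2", fvc_source = "measured")
  m_pred <- ventilation_model("model2", fvc_source = "nhanes_predicted")
  d_meas <- compute_dose(sc$physio, sc$conc, sc$subject, m_meas)
  d_pred <- compute_dose(sc$physio, sc$conc, sc$subject, m_pred)
  fvc_pred <- predict_lung_function(17, 175, 0, "caucasian")$fvc_pred
  expect_equal(d_pred$totals$dose_ug / d_meas$totals$dose_ug, fvc_pred / 4.0,
               tolerance = 1e-9)
})

test_that("rest counterfactual scales linearly and matches constant-c logic", {
  sc <- make_constant_scenario(minutes = 20, conc = 5)
  res <- compute_dose(sc$physio, sc$conc, sc$subject, ventilation_model())
  # constant concentration: counterfactual at the session's actual mean VE
  # reproduces the actual dose
  cf <- rest_counterfactual(sc$conc, res$totals$mean_ve)
  expect_equal(cf, res$totals$dose_ug, tolerance = 1e-9)
  expect_equal(rest_counterfactual(sc$conc, res$totals$mean_ve / 2), cf / 2,
               tolerance = 1e-12)
  expect_error(rest_counterfactual(sc$conc, 0), "positive")
})

test_that("activity multiplies dose relative to a rest baseline", {
  truth <- truth_params(seed = 71)
  cohort <- generate_cohort(1, truth)
  ses <- simulate_field_session(cohort[1, ], truth, duration = 60,
                                mean_conc = 3.9)
  res <- compute_dose(ses$physio, ses$conc, cohort[1, ], ventilation_model())
  # a baseline of a third of the session mean: the activity dose should be
  # about three times the counterfactual (up to conc-activity covariance)
  cf <- rest_counterfactual(ses$conc, res$totals$mean_ve / 3)
  expect_lt(abs(res$totals$dose_ug / cf - 3) / 3, 0.15)
})

test_that("the recommended one- and two-predictor models agree on dose", {
  truth <- truth_params(seed = 72)
  cohort <- generate_cohort(1, truth)
  ses <- simulate_field_session(cohort[1, ], truth, duration = 90,
                                mean_conc = 5)
  d1 <- compute_dose(ses$physio, ses$conc, cohort[1, ],
                     ventilation_model("model1"))
  d2 <- compute_dose(ses$physio, ses$conc, cohort[1, ],
                     ventilation_model("model2"))
  # soft regression guard, not a sharp bound: the one-predictor model leans
  # on the breathing-rate link, whose scatter decouples the two predictions
  expect_lt(abs(d1$totals$dose_ug - d2$totals$dose_ug) /
              d2$totals$dose_ug, 0.15)
})
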