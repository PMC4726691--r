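# Random-intercept REML fitter: oracle agreement, inference, invariances.

test_that("fitter matches the dense-grid + closed-form GLS oracle", {
  d <- tiny_lmm_data()
  oracle <- lmm_gls_oracle(d, "x", "y")
  fit <- fit_lmm(d, "x", response = "y")
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-5)
  expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-4)
  expect_equal(fit$reml_loglik, oracle$reml_loglik, tolerance = 1e-6)
})

test_that("fitter agrees with an independent mixed-model implementation", {
  st <- noisy_study()
  fit <- fit_lmm(st$dataset, c("hr", "fb"))
  m <- lme4::lmer(ve_norm ~ hr + fb + (1 | subject_id), data = st$dataset,
                  REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 1e-5)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(m)),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(c(fit$tau2, fit$sigma2), vc$vcov, tolerance = 1e-4)
})

test_that("with no between-subject variance the fit reduces to OLS", {
  # pure-noise grouping: responses share one regression line across subjects
  set.seed(42)
  d <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 10),
                  x = rep(seq(0, 9), 4))
  d$y <- 1 + 0.5 * d$x + rnorm(40, 0, 0.3)
  fit <- fit_lmm(d, "x", response = "y")
  ols <- lm(y ~ x, data = d)
  if (fit$tau2 == 0) {
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  } else {
    # a small positive tau2 can be estimated from finite noise; the fixed
    # effects must still be within Monte Carlo distance of OLS
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-2)
  }
  # noise-free synthetic study: exact OLS equality and exact truth
  st <- clean_study("ib")
  f0 <- fit_lmm(st$dataset, c("hr", "fb"))
  ols0 <- lm(ve_norm ~ hr + fb, data = st$dataset)
  expect_equal(unname(f0$beta), unname(coef(ols0)), tolerance = 1e-6)
  expect_equal(f0$tau2, 0)
})

test_that("AIC follows the covariance-parameter REML convention", {
  d <- tiny_lmm_data()
  fit <- fit_lmm(d, "x", response = "y")
  oracle <- lmm_gls_oracle(d, "x", "y")
  # hand evaluation: -2 * restricted log-likelihood + 2 covariance parameters
  expect_equal(fit$aic, -2 * oracle$reml_loglik + 2 * 2, tolerance = 1e-6)
  expect_identical(fit$aic, aic_of(fit))
  # determinism across refits
  expect_identical(fit$aic, fit_lmm(d, "x", response = "y")$aic)
  # the count-all-parameters convention adds 2 * (p fixed effects)
  fit_all <- fit_lmm(d, "x", response = "y", aic_convention = "all")
  expect_equal(fit_all$aic - fit$aic, 2 * 2)
})

test_that("a pure-noise predictor never looks informative", {
  set.seed(33)
  st <- noisy_study()
  d <- st$dataset
  base <- fit_lmm(d, c("hr", "fb"))
  m_base <- lme4::lmer(ve_norm ~ hr + fb + (1 | subject_id), d, REML = TRUE)
  stats <- replicate(25, {
    d$junk <- rnorm(nrow(d))
    fit <- fit_lmm(d, c("hr", "fb", "junk"))
    m <- lme4::lmer(ve_norm ~ hr + fb + junk + (1 | subject_id), d,
                    REML = TRUE)
    c(delta = fit$aic - base$aic,
      delta_ref = -2 * (as.numeric(stats::logLik(m)) -
                          as.numeric(stats::logLik(m_base))),
      p = fit$coef$p[4])
  })
  # the AIC change agrees exactly with an independent REML implementation
  # (under the covariance-parameter convention the change is the difference
  # of -2 restricted log-likelihoods)
  expect_equal(unname(stats["delta", ]), unname(stats["delta_ref", ]),
               tolerance = 1e-6)
  # noise never buys a material AIC improvement, and is rarely significant
  expect_true(all(stats["delta", ] > -4))
  expect_gte(mean(stats["p", ] > 0.05), 0.8)
})

test_that("t-based inference brackets estimates and flags null effects", {
  st <- noisy_study()
  fit <- fit_lmm(st$dataset, c("hr", "fb"))
  w <- wald_inference(fit, alpha = 0.05)
  expect_true(all(w$ci_lo < w$estimate & w$estimate < w$ci_hi))
  expect_equal(fit$df, fit$n_obs - 3 - (fit$n_subjects - 1))
  # narrower level, wider interval
  w10 <- wald_inference(fit, alpha = 0.10)
  expect_true(all(w10$ci_hi - w10$ci_lo < w$ci_hi - w$ci_lo))
  # a coefficient exactly zero has p = 1
  fit0 <- fit
  fit0$beta[2] <- 0
  expect_equal(wald_inference(fit0)$p[2], 1)
})

test_that("true-effect p-values shrink as residual noise shrinks", {
  pvals <- sapply(c(2, 0.8, 0.2), function(sg) {
    truth <- truth_params(sigma = sg, tau = 0.2, seed = 77)
    coh <- generate_cohort(8, truth)
    ses <- lapply(seq_len(8), function(i)
      simulate_treadmill_session(coh[i, ], truth))
    names(ses) <- coh$subject_id
    d <- suppressMessages(build_analysis_dataset(ses, coh, "30"))
    max(fit_lmm(d, c("hr", "fb"))$coef$p[-1])
  })
  expect_true(all(diff(pvals) <= 0))
})

test_that("REML optimum beats random lambda probes", {
  set.seed(9)
  st <- noisy_study()
  for (preds in list("hr", c("hr", "fb"), c("hr", "fb", "act"))) {
    fit <- fit_lmm(st$dataset, preds)
    probes <- 10^runif(64, -10, 6)
    m2ll <- ventdose:::reml_m2ll_profile(st$dataset, preds, "ve_norm",
                                         c(fit$lambda, probes))
    expect_true(all(m2ll[1] <= m2ll[-1] + 1e-8))
  }
})

test_that("estimates are invariant to relabeling, row order and scaling", {
  st <- noisy_study()
  d <- st$dataset
  fit <- fit_lmm(d, c("hr", "fb"))

  shuffled <- d[sample(nrow(d)), ]
  expect_equal(fit_lmm(shuffled, c("hr", "fb"))$beta, fit$beta,
               tolerance = 1e-6)

  relab <- d
  relab$subject_id <- paste0("Z", relab$subject_id)
  expect_equal(fit_lmm(relab, c("hr", "fb"))$beta, fit$beta, tolerance = 1e-9)

  doubled <- d
  doubled$ve_norm <- 2 * d$ve_norm
  fit2 <- fit_lmm(doubled, c("hr", "fb"))
  expect_equal(fit2$beta, 2 * fit$beta, tolerance = 1e-6)
  expect_equal(fit2$sigma2, 4 * fit$sigma2, tolerance = 1e-5)
})

test_that("degenerate designs are rejected with named causes", {
  st <- noisy_study()
  d <- st$dataset
  d$hr2 <- 2 * d$hr
  expect_error(fit_lmm(d, c("hr", "hr2")), "rank deficient.*hr2")
  one <- d[d$subject_id == d$subject_id[1], ]
  expect_error(fit_lmm(one, "hr"), "2 subjects")
  expect_error(fit_lmm(d, "nope"), "not in data")
  few <- d[c(which(d$subject_id == d$subject_id[1]),
             which(d$subject_id == "S002")[1]), ]
  expect_error(fit_lmm(few, "hr"), ">= 2 observations")
})

test_that("fitted models serialize to JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  fit <- fit_lmm(tiny_lmm_data(), "x", response = "y")
  write_fit_json(fit, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$aic, fit$aic, tolerance = 1e-9)
  expect_equal(rep$n_subjects, 3L)
})
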