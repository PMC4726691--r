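# Synthetic study generator: cohorts, treadmill sessions, field sessions.
#
# The generative truth for ventilation is the linear model
#   VE/FVC = beta0 + beta_hr * HR + beta_fb * fB + b_i + e,
# with b_i ~ N(0, tau^2) a subject random intercept and e ~ N(0, sigma^2) an
# independent per-breath-window residual (resid_phi > 0 optionally makes the
# residual AR(1)-correlated from breath to breath for sensitivity studies;
# real breath data is autocorrelated, but the default generator matches the
# independence assumption of the variance-components analysis model).

#' Ground-truth parameters for the synthetic ventilation model
#'
#' @param beta0 Intercept of the generative VE/FVC model (min^-1).
#' @param beta_hr Coefficient per beat/min of heart rate.
#' @param beta_fb Coefficient per breath/min of breathing rate.
#' @param tau Between-subject SD of the random intercept (min^-1).
#' @param sigma Marginal residual SD of per-breath-window VE/FVC (min^-1).
#' @param resid_phi Breath-to-breath AR(1) correlation of the residual
#'   (default 0: independent residuals, matching the analysis model's
#'   assumption; positive values available for sensitivity studies).
#' @param fb_link `c(intercept, slope)` mapping HR (beats/min) to mean
#'   breathing rate (breaths/min).
#' @param vt_cap_frac Maximum tidal volume as a fraction of the subject's FVC;
#'   excess ventilation demand is realized by raising breathing rate.
#' @param seed Integer seed for all randomness derived from these parameters.
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(beta0 = -4.247, beta_hr = 0.0595, beta_fb = 0.226,
                         tau = 0.4, sigma = 1.4, resid_phi = 0,
                         fb_link = c(-7.7, 0.31), vt_cap_frac = 0.6,
                         seed = 1L) {
  stopifnot(tau >= 0, sigma >= 0, vt_cap_frac > 0, vt_cap_frac <= 1,
            length(fb_link) == 2, resid_phi >= 0, resid_phi < 1)
  structure(list(beta0 = beta0, beta_hr = beta_hr, beta_fb = beta_fb,
                 tau = tau, sigma = sigma, resid_phi = resid_phi,
                 fb_link = fb_link, vt_cap_frac = vt_cap_frac,
                 seed = as.integer(seed)),
            class = "truth_params")
}

#' Generate a synthetic cohort of adolescent subjects
#'
#' Draws subject demographics and spirometry to mirror a panel of healthy
#' adolescent athletes: age ~ N(17.3, 1.3) truncated to \[15, 18\], height ~
#' N(175, 10) cm, 40% female, BMI ~ N(20.6, 2.9), race drawn from the three
#' NHANES III categories. Measured FVC is the NHANES III predicted FVC times
#' a N(0.92, 0.10) percent-predicted factor (truncated positive), and
#' FEV1/FVC ~ N(0.88, 0.051) truncated to (0.5, 1\]. Each subject also gets a
#' latent random intercept `b ~ N(0, tau^2)` used by the session simulators.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param truth A [truth_params()] object (supplies `tau` and the seed).
#' @param seed Optional integer seed overriding `truth$seed`.
#' @return data.frame of subject records plus columns `fvc_pred`, `fev1_pred`,
#'   and the latent `b`.
#' @export
generate_cohort <- function(n_subjects, truth = truth_params(), seed = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  seed <- seed %||% truth$seed
  with_seed(substream_seed(seed, "cohort"), {
    age <- rtrunc_norm(n_subjects, 17.3, 1.3, 15, 18)
    height <- rtrunc_norm(n_subjects, 175, 10, 145, 205)
    sex <- stats::rbinom(n_subjects, 1, 0.4)
    bmi <- rtrunc_norm(n_subjects, 20.6, 2.9, 15, 35)
    race <- sample(nhanes3_races(), n_subjects, replace = TRUE,
                   prob = c(0.80, 0.07, 0.13))
    pred <- predict_lung_function(age, height, sex, race)
    pp <- rtrunc_norm(n_subjects, 0.92, 0.10, 0.5, Inf)
    fvc <- pred$fvc_pred * pp
    ratio <- rtrunc_norm(n_subjects, 0.88, 0.051, 0.5, 1)
    b <- stats::rnorm(n_subjects, 0, truth$tau)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      age = age, sex = sex, height = height,
      weight = bmi * (height / 100)^2, bmi = bmi, race = race,
      fvc_measured = fvc, fev1_measured = fvc * ratio, fev1_fvc = ratio,
      fvc_pred = pred$fvc_pred, fev1_pred = pred$fev1_pred, b = b,
      stringsAsFactors = FALSE
    )
  })
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- pmin(pmax(x[bad], lo), hi); break }
  }
  x
}

# Piecewise treadmill HR profile: rest, walk, ramp, cool-down. Durations in
# seconds; returns the noise-free mean HR at 1-second resolution.
treadmill_hr_profile <- function(baseline, peak, rest_s = 60, walk_s = 60,
                                 ramp_s = 270, cool_s = 210) {
  walk <- 100
  segs <- c(
    rep(baseline, rest_s),
    baseline + (walk - baseline) * seq_len(walk_s) / walk_s,
    walk + (peak - walk) * seq_len(ramp_s) / ramp_s,
    peak + (baseline + 20 - peak) * seq_len(cool_s) / cool_s
  )
  segs
}

#' Simulate a treadmill session for one subject
#'
#' Produces the two raw data streams of a laboratory session: 1-second
#' physiologic records (heart rate, breathing rate, activity) and
#' breath-by-breath tidal-volume events, generated so that per-breath-window
#' VE/FVC follows the ground-truth linear model. The protocol is about a
#' minute at rest, a minute of walking, a ramp of 4-5 minutes to a peak heart
#' rate drawn uniformly from 160-180 beats/min, then a 3-4 minute cool-down.
#' Tidal volume is capped at `vt_cap_frac * FVC`; when the cap binds, the
#' demanded ventilation is realized by raising the breathing rate instead,
#' mimicking the tidal-volume plateau of vigorous exercise.
#'
#' @param subject One row of a [generate_cohort()] data.frame (needs
#'   `fvc_measured` and the latent `b`; `b` defaults to 0 if absent).
#' @param truth A [truth_params()] object.
#' @param seed Optional integer seed overriding the derived substream.
#' @return list with data.frames `physio` (`t, hr, fb, act`; 1-second spacing)
#'   and `breaths` (`t_start, vt`).
#' @export
simulate_treadmill_session <- function(subject, truth = truth_params(),
                                       seed = NULL) {
  fvc <- subject$fvc_measured
  if (is.null(fvc) || !is.finite(fvc) || fvc <= 0)
    stop("subject must have a positive measured FVC")
  b_i <- subject$b %||% 0
  idx <- suppressWarnings(as.integer(sub("^S", "", subject$subject_id %||% "0")))
  if (is.na(idx)) idx <- 0L
  seed <- seed %||% substream_seed(truth$seed, "treadmill", idx)

  with_seed(seed, {
    baseline <- stats::rnorm(1, 70, 8)
    peak <- stats::runif(1, 160, 180)
    ramp_s <- round(stats::runif(1, 240, 300))
    cool_s <- round(stats::runif(1, 180, 240))
    hr_mean <- treadmill_hr_profile(baseline, peak, ramp_s = ramp_s,
                                    cool_s = cool_s)
    n <- length(hr_mean)
    hr <- pmax(40, hr_mean + ar1_series(n, 0, 2, 0.9))

    # Peak ventilation demand must be positive under the supplied truth.
    fb_at <- function(h) pmax(8, truth$fb_link[1] + truth$fb_link[2] * h)
    ve_peak <- truth$beta0 + truth$beta_hr * peak +
      truth$beta_fb * fb_at(peak) + b_i
    if (ve_peak <= 0)
      stop("truth parameters imply nonpositive VE/FVC at peak heart rate; ",
           "increase beta_hr/beta_fb or raise beta0")

    # Breaths are generated sequentially; the physio breathing-rate series is
    # derived from realized breath spacing so the two streams agree.
    fb_noise <- ar1_series(n, 0, 2, 0.95)
    resid <- ar1_series(n + 100L, 0, truth$sigma, truth$resid_phi)
    t_breath <- numeric(0); vt <- numeric(0); fb_real <- numeric(0)
    cap <- truth$vt_cap_frac * fvc
    tcur <- stats::runif(1, 0, 3)
    tprev <- 0
    # rate governing the interval that ends at the upcoming breath
    fb_prev <- max(8, truth$fb_link[1] + truth$fb_link[2] * hr[1] +
                     fb_noise[1])
    k <- 0L
    while (tcur < n - 1) {
      k <- k + 1L
      sec <- max(1L, min(n, floor(tcur) + 1L))
      # the breath "owns" the seconds since the previous breath; the truth is
      # stated on that window (window-mean HR, the realized breathing rate
      # that paced it) so that generation and analysis average alike
      win <- max(1L, min(sec, floor(tprev) + 2L)):sec
      hr_win <- mean(hr[win])
      ve_norm <- truth$beta0 + truth$beta_hr * hr_win +
        truth$beta_fb * fb_prev + b_i + resid[min(k, length(resid))]
      ve_norm <- max(0.2, ve_norm)              # ventilation cannot stop
      ve <- ve_norm * fvc                       # L/min
      vt_k <- ve / fb_prev                      # L/breath
      vt_k <- min(vt_k, cap)                    # tidal-volume plateau
      t_breath[k] <- tcur
      vt[k] <- vt_k
      # pace the next interval; demand exceeding the cap raises the rate
      fb_next <- max(8, truth$fb_link[1] + truth$fb_link[2] * hr[sec] +
                       fb_noise[sec])
      ve_next <- max(0.2, truth$beta0 + truth$beta_hr * hr[sec] +
                       truth$beta_fb * fb_next + b_i) * fvc
      fb_prev <- max(fb_next, ve_next / cap)
      fb_real[k] <- fb_prev       # the rate in force from this breath on
      tprev <- tcur
      tcur <- tcur + 60 / fb_prev
    }

    # 1-second fb series: rate implied by the breath interval covering each
    # second (constant between breath events).
    fb_sec <- stats::approx(t_breath, fb_real, xout = seq_len(n) - 1,
                            method = "constant", rule = 2)$y
    act <- act_profile(hr_mean, baseline, peak)
    structure(
      list(
        physio = data.frame(t = seq_len(n) - 1, hr = hr, fb = fb_sec,
                            act = act),
        breaths = data.frame(t_start = t_breath, vt = vt)
      ),
      protocol = list(baseline = baseline, peak = peak, ramp_s = ramp_s,
                      cool_s = cool_s)
    )
  })
}

act_profile <- function(hr_mean, baseline, peak) {
  n <- length(hr_mean)
  frac <- pmin(1, pmax(0, (hr_mean - 100) / (peak - 100)))
  level <- ifelse(hr_mean <= baseline + 5, 0.02,
           ifelse(hr_mean <= 100, 0.2, 0.4 + 0.4 * frac))
  pmax(0, level + stats::rnorm(n, 0, 0.02))
}

#' Simulate a field exposure session
#'
#' Generates a physiologic series of alternating rest and activity bouts plus
#' a 1-minute-resolution pollutant concentration series. The concentration is
#' a stationary AR(1) process with the requested mean, marginal SD equal to
#' a quarter of the mean, lag-1 correlation 0.8, floored at zero.
#'
#' @param subject One row of a cohort data.frame.
#' @param truth A [truth_params()] object.
#' @param duration Session duration in minutes (>= 2).
#' @param mean_conc Mean pollutant concentration, ug/m^3 (>= 0).
#' @param seed Optional integer seed.
#' @param bout_min Length of each rest/activity bout in minutes.
#' @return list with data.frames `physio` (`t, hr, fb, act`; seconds) and
#'   `conc` (`t` minutes from start of each 1-minute interval, `conc` ug/m^3).
#' @export
simulate_field_session <- function(subject, truth = truth_params(),
                                   duration = 90, mean_conc = 3.9,
                                   seed = NULL, bout_min = 5) {
  if (duration < 2) stop("duration must be at least 2 minutes")
  if (mean_conc < 0) stop("mean_conc must be nonnegative")
  idx <- suppressWarnings(as.integer(sub("^S", "", subject$subject_id %||% "0")))
  if (is.na(idx)) idx <- 0L
  seed <- seed %||% substream_seed(truth$seed, "field", idx)
  with_seed(seed, {
    n_min <- as.integer(duration)
    conc <- pmax(0, ar1_series(n_min, mean_conc, 0.25 * mean_conc, 0.8))
    n <- n_min * 60L
    minute <- (seq_len(n) - 1) %/% 60
    active <- (minute %/% bout_min) %% 2 == 1
    hr_mean <- ifelse(active, 150, 75)
    # smooth 30-s transitions between bouts
    hr_mean <- rolling_mean(hr_mean, 31)
    hr <- pmax(40, hr_mean + ar1_series(n, 0, 3, 0.95))
    fb <- pmax(8, truth$fb_link[1] + truth$fb_link[2] * hr +
                 ar1_series(n, 0, 2, 0.95))
    act <- pmax(0, ifelse(active, 0.5, 0.03) + stats::rnorm(n, 0, 0.02))
    list(
      physio = data.frame(t = seq_len(n) - 1, hr = hr, fb = fb, act = act),
      conc = data.frame(t = seq_len(n_min) - 1, conc = conc)
    )
  })
}

#' Write a complete synthetic study to a directory
#'
#' Emits the subject roster CSV plus per-subject physio and breath-event CSVs
#' for treadmill sessions, in the package's CSV dialects.
#'
#' @param dir Output directory (created if needed).
#' @param cohort A [generate_cohort()] data.frame.
#' @param truth A [truth_params()] object.
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(dir, cohort, truth = truth_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  roster <- data.frame(
    subject_id = cohort$subject_id, age = cohort$age, sex = cohort$sex,
    height_cm = cohort$height, weight_kg = cohort$weight, race = cohort$race,
    fvc_L = cohort$fvc_measured, fev1_L = cohort$fev1_measured
  )
  f <- file.path(dir, "subjects.csv")
  utils::write.csv(roster, f, row.names = FALSE)
  files <- c(files, f)
  for (i in seq_len(nrow(cohort))) {
    ses <- simulate_treadmill_session(cohort[i, ], truth)
    pf <- file.path(dir, sprintf("%s_physio.csv", cohort$subject_id[i]))
    bf <- file.path(dir, sprintf("%s_breaths.csv", cohort$subject_id[i]))
    utils::write.csv(
      stats::setNames(ses$physio, c("t_s", "hr_bpm", "fb_brpm", "act_g")),
      pf, row.names = FALSE)
    utils::write.csv(stats::setNames(ses$breaths, c("t_start_s", "vt_L")),
                     bf, row.names = FALSE)
    files <- c(files, pf, bf)
  }
  invisible(files)
}
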