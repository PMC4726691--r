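# Field ventilation prediction and time-resolved inhaled-dose integration.

#' Ventilation model specification
#'
#' The two recommended forms are available as presets: `"model1"`
#' (`VE/FVC = -3.859 + 0.101 HR`, heart rate only) and `"model2"`
#' (`VE/FVC = -4.247 + 0.0595 HR + 0.226 fB`). Custom coefficients may be
#' supplied instead.
#'
#' @param preset `"model1"`, `"model2"` or `"custom"`.
#' @param intercept,coef_hr,coef_fb Coefficients for `preset = "custom"`
#'   (`coef_fb = 0` means breathing rate is not used).
#' @param fvc_source `"measured"` or `"nhanes_predicted"`: where the FVC
#'   normalizer comes from when predicting for a subject.
#' @return List of class `ventilation_model`.
#' @export
ventilation_model <- function(preset = c("model2", "model1", "custom"),
                              intercept = NULL, coef_hr = NULL, coef_fb = NULL,
                              fvc_source = c("measured", "nhanes_predicted")) {
  preset <- match.arg(preset)
  fvc_source <- match.arg(fvc_source)
  cf <- switch(preset,
    model1 = c(-3.859, 0.101, 0),
    model2 = c(-4.247, 0.0595, 0.226),
    custom = c(intercept %||% stop("custom model needs intercept"),
               coef_hr %||% 0, coef_fb %||% 0))
  if (cf[2] == 0 && cf[3] == 0)
    stop("at least one of coef_hr, coef_fb must be nonzero")
  structure(list(intercept = cf[1], coef_hr = cf[2], coef_fb = cf[3],
                 fvc_source = fvc_source, preset = preset),
            class = "ventilation_model")
}

#' Predict minute ventilation from heart rate (and breathing rate)
#'
#' `VE = FVC * (intercept + coef_hr * HR + coef_fb * fB)`, floored at zero
#' (a negative extrapolation at very low heart rate is unphysical).
#'
#' @param hr Heart rate, beats/min (vectorized).
#' @param fb Breathing rate, breaths/min; required iff the model uses it.
#' @param fvc Forced vital capacity, liters (> 0).
#' @param model A [ventilation_model()].
#' @return Minute ventilation, L/min.
#' @export
predict_ve <- function(hr, fb = NULL, fvc, model = ventilation_model()) {
  if (!is.finite(fvc) || fvc <= 0) stop("fvc must be positive")
  if (model$coef_fb != 0 && is.null(fb))
    stop("this ventilation model requires a breathing-rate series (fb)")
  if (model$coef_fb == 0) fb <- 0
  raw <- fvc * (model$intercept + model$coef_hr * hr + model$coef_fb * fb)
  pmax(0, raw)
}

#' Time-resolved inhaled dose of a pollutant
#'
#' Aligns 1-second physiologic records to the 1-minute concentration grid
#' (each second belongs to the minute containing it; partial leading/trailing
#' minutes are weighted by their coverage fraction) and integrates by the
#' rectangle rule: per interval, ventilation is the mean of per-second
#' predictions, `volume = VE * dt / 1000` (m^3),
#' `exposure = conc * dt` (ug min m^-3), `dose = conc * volume` (ug).
#'
#' @param physio data.frame `t` (seconds), `hr`, `fb`, `act`.
#' @param conc data.frame `t` (minutes, start of each 1-minute interval),
#'   `conc` (ug/m^3).
#' @param subject One-row subject data.frame (for FVC, NHANES inputs and
#'   body weight).
#' @param model A [ventilation_model()].
#' @return List of class `dose_series`: per-interval data.frame `series`
#'   (`t_min, dt_min, conc, ve, volume_m3, exposure, dose, cumulative_dose`)
#'   and `totals` (`volume_m3, exposure, dose_ug, dose_ug_per_kg,
#'   mean_ve`).
#' @export
compute_dose <- function(physio, conc, subject, model = ventilation_model()) {
  if (any(conc$conc < 0)) stop("negative pollutant concentrations supplied")
  if (nrow(conc) > 1 && any(abs(diff(conc$t) - 1) > 1e-9))
    stop("concentration series must be on a contiguous 1-minute grid; gap ",
         "after t = ", conc$t[which(abs(diff(conc$t) - 1) > 1e-9)[1]], " min")
  fvc <- subject_fvc(subject, model$fvc_source)
  minute <- floor(physio$t / 60)
  lo <- conc$t[1]; hi <- conc$t[nrow(conc)] + 1
  if (min(minute) < lo || max(minute) >= hi)
    stop("concentration series does not cover the physio time span: physio ",
         "minutes [", min(minute), ", ", max(minute), "] vs concentration [",
         lo, ", ", hi - 1, "]")
  ve_sec <- predict_ve(physio$hr,
                       fb = if (model$coef_fb != 0) physio$fb else NULL,
                       fvc = fvc, model = model)
  agg_ve <- tapply(ve_sec, minute, mean)
  agg_n <- tapply(ve_sec, minute, length)
  mins <- as.numeric(names(agg_ve))
  dt <- as.numeric(agg_n) / 60          # coverage fraction of each minute
  ci <- conc$conc[match(mins, conc$t)]
  ve <- as.numeric(agg_ve)
  volume <- ve * dt / 1000
  exposure <- ci * dt
  dose <- ci * volume
  series <- data.frame(
    t_min = mins, dt_min = dt, conc = ci, ve = ve, volume_m3 = volume,
    exposure = exposure, dose = dose, cumulative_dose = cumsum(dose)
  )
  weight <- subject$weight %||% NA_real_
  totals <- list(
    volume_m3 = sum(volume), exposure = sum(exposure), dose_ug = sum(dose),
    dose_ug_per_kg = sum(dose) / weight,
    mean_ve = sum(ve * dt) / sum(dt)
  )
  structure(list(series = series, totals = totals, model = model),
            class = "dose_series")
}

subject_fvc <- function(subject, fvc_source) {
  if (fvc_source == "measured") {
    fvc <- subject$fvc_measured
    if (is.null(fvc)) stop("subject has no measured FVC")
    fvc
  } else {
    predict_lung_function(subject$age, subject$height, subject$sex,
                          subject$race)$fvc_pred
  }
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf(paste0("Inhaled-dose series over %.1f min: volume %.3f m^3, ",
                     "exposure %.1f ug min m^-3, dose %.2f ug\n"),
              sum(x$series$dt_min), x$totals$volume_m3, x$totals$exposure,
              x$totals$dose_ug))
  invisible(x)
}

#' Dose under a rest-baseline counterfactual
#'
#' Inhaled dose had the subject breathed at a constant baseline minute
#' ventilation over the same concentration series.
#'
#' @param conc Concentration data.frame (`t` minutes, `conc` ug/m^3).
#' @param baseline_ve Constant minute ventilation, L/min (> 0).
#' @return Dose in ug.
#' @export
rest_counterfactual <- function(conc, baseline_ve) {
  if (!is.finite(baseline_ve) || baseline_ve <= 0)
    stop("baseline_ve must be positive")
  if (any(conc$conc < 0)) stop("negative pollutant concentrations supplied")
  sum(conc$conc * baseline_ve / 1000)
}
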