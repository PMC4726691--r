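# Fusion of breath events with 1-second physiologic records and construction
# of the time-averaged analysis datasets.

#' Merge breath events into the 1-second physiologic table
#'
#' Each breath's tidal volume is attached to the 1-second row containing the
#' time its exhalation began (floor of `t_start`). Rows without a breath carry
#' `NA`. Two breaths flooring to the same second have their volumes summed on
#' that row, so total attached volume always equals total input volume.
#'
#' @param physio data.frame with columns `t` (seconds, 1-second spacing),
#'   `hr`, `fb`, `act`.
#' @param breaths data.frame with columns `t_start` (seconds), `vt` (liters),
#'   or `NULL`/empty for a session with no breath data.
#' @return `physio` with additional columns `vt` (liters, `NA` where no
#'   breath) and `n_breaths`.
#' @export
merge_breaths <- function(physio, breaths) {
  stopifnot(all(c("t", "hr", "fb", "act") %in% names(physio)))
  dt <- diff(physio$t)
  if (length(dt) && (any(dt <= 0) || any(abs(dt - 1) > 1e-6)))
    stop("physio records must be at strictly increasing 1-second spacing")
  out <- physio
  out$vt <- NA_real_
  out$n_breaths <- 0L
  if (is.null(breaths) || nrow(breaths) == 0) {
    warning("no breath events supplied; all tidal volumes are missing")
    return(out)
  }
  stopifnot(all(c("t_start", "vt") %in% names(breaths)))
  t0 <- physio$t[1]
  span_hi <- physio$t[nrow(physio)] + 1
  outside <- breaths$t_start < t0 | breaths$t_start >= span_hi
  if (any(outside))
    stop("breath event at t=", breaths$t_start[which(outside)[1]],
         " s lies outside the physio time span [", t0, ", ", span_hi, ")")
  row <- floor(breaths$t_start - t0) + 1L
  vt_sum <- tapply(breaths$vt, row, sum)
  n_sum <- tapply(rep(1L, nrow(breaths)), row, sum)
  idx <- as.integer(names(vt_sum))
  out$vt[idx] <- as.numeric(vt_sum)
  out$n_breaths[idx] <- as.integer(n_sum)
  stopifnot(abs(sum(out$vt, na.rm = TRUE) - sum(breaths$vt)) < 1e-9)
  out
}

#' Warm-up / cool-down indicator from a heart-rate series
#'
#' Smooths the 1-second heart-rate series with a centered rolling mean
#' (default 15 s) and splits the session at the smoothed global maximum:
#' `warm = 0` at and before the peak (heart rate rising: warm-up), `1` after
#' (cool-down). A constant series is all 0.
#'
#' @param hr Numeric heart-rate series at 1-second spacing.
#' @param smooth_s Rolling-mean window, seconds.
#' @return Integer vector of 0/1, same length as `hr`.
#' @export
compute_warm <- function(hr, smooth_s = 15) {
  if (length(hr) < smooth_s)
    stop("heart-rate series shorter than the ", smooth_s, "-s smoothing window")
  sm <- rolling_mean(hr, smooth_s)
  # last index attaining the max, so flat or monotone series are all 0
  peak <- max(which(sm == max(sm)))
  as.integer(seq_along(hr) > peak)
}

.timebases <- c("60" = 60, "30" = 30, "15" = 15)

#' Build a time-averaged analysis dataset
#'
#' Reduces a merged 1-second table to one of the four analysis time bases:
#' fixed 60-, 30- or 15-second windows aligned to session start, or the
#' individual-breath time base with one record per breath averaging all
#' 1-second values since the previous breath. Heart rate, breathing rate and
#' activity are within-window means; tidal volume is the mean volume of the
#' breaths in the window; minute ventilation is computed as
#' `ve = vt * fb` (mean volumetric flow during the window), and both `ve` and
#' `vt` are normalized by the subject's FVC. Fixed windows containing no
#' breath are dropped (with a message), since ventilation is undefined there.
#'
#' @param merged Output of [merge_breaths()].
#' @param fvc Subject forced vital capacity, liters (> 0).
#' @param timebase One of `"60"`, `"30"`, `"15"` (seconds) or `"ib"`
#'   (individual breath). Numeric 60/30/15 also accepted.
#' @param subject_id Identifier copied into every record.
#' @param ve_mode `"mean_vt_times_fb"` (default; the mean tidal volume times
#'   the mean breathing rate) or `"volume_per_time"` (total exhaled volume
#'   divided by window duration), available for sensitivity checks.
#' @return data.frame of averaged records: `subject_id, window_start,
#'   window_dur, hr, fb, act, vt, ve, ve_norm, vt_norm, warm`.
#' @export
build_averaged_dataset <- function(merged, fvc, timebase = "30",
                                   subject_id = "S001",
                                   ve_mode = c("mean_vt_times_fb",
                                               "volume_per_time")) {
  ve_mode <- match.arg(ve_mode)
  if (!is.finite(fvc) || fvc <= 0) stop("fvc must be positive")
  if (nrow(merged) == 0) stop("merged table is empty")
  tb <- as.character(timebase)
  if (!tb %in% c(names(.timebases), "ib"))
    stop("timebase must be one of 60, 30, 15 or \"ib\"")
  warm <- compute_warm(merged$hr)
  t0 <- merged$t[1]
  if (tb == "ib") {
    groups <- breath_groups(merged)
  } else {
    w <- .timebases[[tb]]
    groups <- split(seq_len(nrow(merged)), floor((merged$t - t0) / w))
  }
  recs <- lapply(groups, function(ix) {
    nb <- sum(merged$n_breaths[ix])
    if (nb == 0) return(NULL)
    vt_bar <- sum(merged$vt[ix], na.rm = TRUE) / nb
    dur <- length(ix)
    fb_bar <- mean(merged$fb[ix])
    ve <- if (ve_mode == "mean_vt_times_fb") vt_bar * fb_bar
          else sum(merged$vt[ix], na.rm = TRUE) / (dur / 60)
    data.frame(
      subject_id = subject_id,
      window_start = merged$t[ix[1]],
      window_dur = dur,
      hr = mean(merged$hr[ix]), fb = fb_bar, act = mean(merged$act[ix]),
      vt = vt_bar, ve = ve, ve_norm = ve / fvc, vt_norm = vt_bar / fvc,
      warm = as.integer(round(mean(warm[ix]) > 0.5)),
      stringsAsFactors = FALSE
    )
  })
  dropped <- sum(vapply(recs, is.null, logical(1)))
  if (dropped > 0 && tb != "ib")
    message(dropped, " window(s) with no breath dropped")
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

# Individual-breath grouping: one group per breath-carrying second, covering
# all seconds since the previous breath. Seconds before the first breath are
# discarded (no previous breath to average from).
breath_groups <- function(merged) {
  bsec <- which(merged$n_breaths > 0)
  if (length(bsec) < 2) return(list())
  groups <- vector("list", length(bsec) - 1L)
  for (j in 2:length(bsec)) {
    groups[[j - 1L]] <- (bsec[j - 1L] + 1L):bsec[j]
  }
  groups
}

#' Read physio / breath / concentration CSVs
#'
#' Readers for the package's CSV dialects. `read_physio` expects header
#' `t_s, hr_bpm, fb_brpm, act_g`; `read_breaths` expects `t_start_s, vt_L`;
#' `read_concentration` expects `t_min, conc_ugm3`.
#'
#' @param path CSV file path.
#' @return data.frame in the internal column naming (`t, hr, fb, act`;
#'   `t_start, vt`; `t, conc`).
#' @export
read_physio <- function(path) {
  raw <- utils::read.csv(path)
  stopifnot(all(c("t_s", "hr_bpm", "fb_brpm", "act_g") %in% names(raw)))
  data.frame(t = raw$t_s, hr = raw$hr_bpm, fb = raw$fb_brpm, act = raw$act_g)
}

#' @rdname read_physio
#' @export
read_breaths <- function(path) {
  raw <- utils::read.csv(path)
  stopifnot(all(c("t_start_s", "vt_L") %in% names(raw)))
  data.frame(t_start = raw$t_start_s, vt = raw$vt_L)
}

#' @rdname read_physio
#' @export
read_concentration <- function(path) {
  raw <- utils::read.csv(path)
  stopifnot(all(c("t_min", "conc_ugm3") %in% names(raw)))
  data.frame(t = raw$t_min, conc = raw$conc_ugm3)
}

#' Build the pooled analysis dataset for a cohort of sessions
#'
#' Convenience wrapper: merges and averages each subject's session and joins
#' the subject covariates needed by the candidate models (age, sex, BMI,
#' FEV1/FVC, height).
#'
#' @param sessions Named list (by subject_id) of lists with elements `physio`
#'   and `breaths`.
#' @param cohort Subject data.frame (one row per subject).
#' @param timebase Passed to [build_averaged_dataset()].
#' @param response `"ve_norm"` (VE/FVC) or `"ve_over_fev1"` (VE/FEV1);
#'   controls which normalizer fills the `ve_norm` response column.
#' @param fvc_source `"measured"` or `"nhanes_predicted"`: which FVC value
#'   normalizes ventilation.
#' @return data.frame: averaged records joined to subject covariates.
#' @export
build_analysis_dataset <- function(sessions, cohort, timebase = "30",
                                   response = c("ve_norm", "ve_over_fev1"),
                                   fvc_source = c("measured",
                                                  "nhanes_predicted")) {
  response <- match.arg(response)
  fvc_source <- match.arg(fvc_source)
  parts <- lapply(names(sessions), function(id) {
    row <- cohort[cohort$subject_id == id, , drop = FALSE]
    if (nrow(row) != 1) stop("subject ", id, " not found (once) in cohort")
    norm <- switch(fvc_source,
      measured = switch(response, ve_norm = row$fvc_measured,
                        ve_over_fev1 = row$fev1_measured),
      nhanes_predicted = {
        pred <- predict_lung_function(row$age, row$height, row$sex, row$race)
        switch(response, ve_norm = pred$fvc_pred, ve_over_fev1 = pred$fev1_pred)
      })
    merged <- merge_breaths(sessions[[id]]$physio, sessions[[id]]$breaths)
    avg <- build_averaged_dataset(merged, norm, timebase, subject_id = id)
    avg$age <- row$age; avg$sex <- row$sex; avg$bmi <- row$bmi
    avg$fev1_fvc <- row$fev1_fvc; avg$height <- row$height
    avg
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
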