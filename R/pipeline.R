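# End-to-end pipeline with configuration, logging and a provenance manifest.

#' Pipeline run configuration
#'
#' Validates and normalizes the configuration for [run_pipeline()]. All
#' randomness in a run flows from `seed` through deterministic per-stage
#' substreams.
#'
#' @param seed Integer master seed.
#' @param n_subjects Cohort size for the synthetic study.
#' @param timebase `"60"`, `"30"`, `"15"` or `"ib"`.
#' @param response `"ve_norm"` or `"ve_over_fev1"`.
#' @param predictor_pool Candidate predictors (default all nine).
#' @param k_folds Cross-validation folds (>= 2).
#' @param dose_model `"model1"`, `"model2"` or `"fitted"` (use the best
#'   two-predictor model selected in this run).
#' @param fvc_source `"measured"` or `"nhanes_predicted"`.
#' @param field_duration,field_mean_conc Field-session scenario (minutes,
#'   ug/m^3).
#' @param max_subset_size Evaluate subsets up to this size (default: all).
#' @param truth A [truth_params()] object for the generator.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 15L, timebase = "30",
                       response = "ve_norm",
                       predictor_pool = candidate_predictors(),
                       k_folds = 5L, dose_model = "model2",
                       fvc_source = "measured",
                       field_duration = 90, field_mean_conc = 3.9,
                       max_subset_size = NULL, truth = NULL) {
  problems <- character(0)
  if (!is.numeric(seed) || length(seed) != 1) problems <- c(problems, "seed must be a single integer")
  if (!as.character(timebase) %in% c("60", "30", "15", "ib"))
    problems <- c(problems, "timebase must be one of 60, 30, 15, ib")
  if (!response %in% c("ve_norm", "ve_over_fev1"))
    problems <- c(problems, "response must be ve_norm or ve_over_fev1")
  if (!is.numeric(k_folds) || k_folds < 2)
    problems <- c(problems, "k_folds must be >= 2")
  if (!is.numeric(n_subjects) || n_subjects < max(2, k_folds))
    problems <- c(problems, "n_subjects must be >= max(2, k_folds)")
  if (length(predictor_pool) < 1)
    problems <- c(problems, "predictor_pool must not be empty")
  if (!dose_model %in% c("model1", "model2", "fitted"))
    problems <- c(problems, "dose_model must be model1, model2 or fitted")
  if (!fvc_source %in% c("measured", "nhanes_predicted"))
    problems <- c(problems, "fvc_source must be measured or nhanes_predicted")
  if (length(problems))
    stop("invalid run configuration:\n  - ", paste(problems, collapse = "\n  - "))
  truth <- truth %||% truth_params(seed = substream_seed(seed, "truth"))
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 timebase = as.character(timebase), response = response,
                 predictor_pool = predictor_pool, k_folds = as.integer(k_folds),
                 dose_model = dose_model, fvc_source = fvc_source,
                 field_duration = field_duration,
                 field_mean_conc = field_mean_conc,
                 max_subset_size = max_subset_size, truth = truth),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

#' Run the full pipeline on a synthetic study
#'
#' Simulates a cohort and its treadmill sessions, builds the time-averaged
#' analysis dataset, evaluates predictor subsets (fit + AIC + grouped CV),
#' selects per-size winners, simulates a field session for the first subject
#' and computes its inhaled-dose series, writing every artifact plus a
#' manifest (seed, configuration hash, per-stage row counts, per-file MD5
#' content hashes) into `out_dir`.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logit <- function(stage, msg, n = NA) {
    log_lines <<- c(log_lines, sprintf("[%s] %s%s", stage, msg,
                                       if (is.na(n)) "" else paste0(" n=", n)))
  }

  truth <- config$truth
  cohort <- generate_cohort(config$n_subjects, truth)
  logit("simulate", "cohort generated", nrow(cohort))
  sessions <- lapply(seq_len(nrow(cohort)), function(i)
    simulate_treadmill_session(cohort[i, ], truth))
  names(sessions) <- cohort$subject_id
  dataset <- build_analysis_dataset(sessions, cohort, config$timebase,
                                    response = config$response,
                                    fvc_source = config$fvc_source)
  logit("preprocess", paste0("averaged dataset, timebase ", config$timebase),
        nrow(dataset))

  subsets <- enumerate_subsets(config$predictor_pool)
  if (!is.null(config$max_subset_size))
    subsets <- Filter(function(s) length(s) <= config$max_subset_size, subsets)
  tab <- selection_table(dataset, config$predictor_pool, k = config$k_folds,
                         seed = substream_seed(config$seed, "cv"),
                         response = config$response, subsets = subsets)
  logit("select", "subsets evaluated", nrow(tab))
  sizes <- sort(unique(tab$size))
  winners <- lapply(sizes, function(s) {
    ch <- select_best(tab, s)
    list(size = s, predictors = ch$row$predictors, criterion = ch$criterion,
         aic = ch$row$aic, mean_pe = ch$row$mean_pe, sd_pe = ch$row$sd_pe)
  })

  best2 <- select_best(tab, min(2, max(sizes)))
  best_preds <- strsplit(best2$row$predictors, "/")[[1]]
  best_fit <- fit_lmm(dataset, best_preds, response = config$response)
  cv_best <- cv_percent_error(dataset, best_preds, k = config$k_folds,
                              seed = substream_seed(config$seed, "cv"),
                              response = config$response)

  dose_model <- switch(config$dose_model,
    model1 = ventilation_model("model1", fvc_source = config$fvc_source),
    model2 = ventilation_model("model2", fvc_source = config$fvc_source),
    fitted = ventilation_model("custom",
      intercept = unname(best_fit$beta[1]),
      coef_hr = unname(best_fit$beta["hr"] %|na|% 0),
      coef_fb = unname(best_fit$beta["fb"] %|na|% 0),
      fvc_source = config$fvc_source))
  field <- simulate_field_session(cohort[1, ], truth,
                                  duration = config$field_duration,
                                  mean_conc = config$field_mean_conc)
  dose <- compute_dose(field$physio, field$conc, cohort[1, ], dose_model)
  logit("dose", "field session dosed", nrow(dose$series))

  # ---- write artifacts -------------------------------------------------
  paths <- list(
    roster = file.path(out_dir, "subjects.csv"),
    dataset = file.path(out_dir, "analysis_dataset.csv"),
    selection = file.path(out_dir, "selection_table.csv"),
    winners = file.path(out_dir, "winners.json"),
    fit = file.path(out_dir, "best_model.json"),
    cv = file.path(out_dir, "cv_result.json"),
    dose_series = file.path(out_dir, "dose_series.csv"),
    dose_totals = file.path(out_dir, "dose_totals.json"),
    log = file.path(out_dir, "run.log")
  )
  utils::write.csv(cohort[, setdiff(names(cohort), "b")], paths$roster,
                   row.names = FALSE)
  utils::write.csv(dataset, paths$dataset, row.names = FALSE)
  utils::write.csv(as.data.frame(tab), paths$selection, row.names = FALSE)
  jsonlite::write_json(winners, paths$winners, auto_unbox = TRUE, digits = NA)
  write_fit_json(best_fit, paths$fit)
  jsonlite::write_json(list(predictors = cv_best$predictors,
                            seed = cv_best$seed, mean_pe = cv_best$mean_pe,
                            sd_pe = cv_best$sd_pe,
                            n = length(cv_best$percent_errors)),
                       paths$cv, auto_unbox = TRUE, digits = NA)
  utils::write.csv(dose$series, paths$dose_series, row.names = FALSE)
  jsonlite::write_json(dose$totals, paths$dose_totals, auto_unbox = TRUE,
                       digits = NA)
  writeLines(log_lines, paths$log)

  cfg_for_hash <- config; cfg_for_hash$truth <- unclass(truth)
  manifest <- list(
    seed = config$seed,
    config_hash = hash_object(cfg_for_hash),
    counts = list(subjects = nrow(cohort), dataset_rows = nrow(dataset),
                  subsets_evaluated = nrow(tab),
                  dose_intervals = nrow(dose$series)),
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Stable hash of an R object via its deparsed representation.
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}
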