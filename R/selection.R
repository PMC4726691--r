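# Brute-force all-subsets model selection with subject-grouped k-fold
# cross-validation and percent-error scoring.

#' Candidate predictor pool
#'
#' The nine candidate predictors of normalized minute ventilation.
#' @return Character vector.
#' @export
candidate_predictors <- function() {
  c("hr", "fb", "act", "warm", "age", "sex", "bmi", "fev1_fvc", "height")
}

#' Enumerate all non-empty predictor subsets
#'
#' @param predictor_names Character vector of candidate names (1 to 20).
#' @return List of character vectors, all `2^p - 1` non-empty subsets in
#'   size-then-lexicographic order.
#' @export
enumerate_subsets <- function(predictor_names) {
  p <- length(predictor_names)
  if (p < 1) stop("predictor list must not be empty")
  if (p > 20) stop("more than 20 predictors would enumerate over a million subsets")
  if (anyDuplicated(predictor_names)) stop("predictor names must be unique")
  subsets <- list()
  for (size in seq_len(p)) {
    combos <- utils::combn(sort(predictor_names), size, simplify = FALSE)
    ord <- order(vapply(combos, paste, character(1), collapse = "\r"))
    subsets <- c(subsets, combos[ord])
  }
  subsets
}

#' Partition subjects into k folds
#'
#' Randomly assigns subjects to `k` folds as equal in size as possible
#' (sizes differ by at most one), deterministically for a given seed.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param k Number of folds (>= 2, <= number of subjects).
#' @param seed Integer seed for the shuffle.
#' @return Named integer vector: fold index (1..k) per subject.
#' @export
grouped_kfold <- function(subject_ids, k, seed) {
  # sorted so the assignment depends only on the id set and the seed,
  # never on row order of the data the ids came from
  subject_ids <- sort(unique(as.character(subject_ids)))
  n <- length(subject_ids)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  with_seed(substream_seed(seed, "kfold"), {
    shuffled <- sample(subject_ids)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold <- rep(seq_len(k), times = sizes)
    stats::setNames(fold, shuffled)[subject_ids]
  })
}

#' Subject-grouped cross-validated percent error
#'
#' For each fold, the model is fit on the training subjects only and
#' validation observations are predicted with fixed effects alone (held-out
#' subjects' random intercepts are zero: nothing about a validation subject
#' ever reaches training). Percent errors
#' `100 * (prediction - observation) / observation` are pooled over all
#' validation observations of all folds.
#'
#' @param data Analysis data.frame (must contain `subject_id`, the response
#'   and the predictors).
#' @param predictors Character vector of predictor names.
#' @param k Number of folds.
#' @param seed Fold-assignment seed (required; logged in the result).
#' @param response Response column name.
#' @return Object of class `cv_result`: `percent_errors`, `mean_pe`, `sd_pe`,
#'   `fold_map`, `seed`, `predictors`.
#' @export
cv_percent_error <- function(data, predictors, k = 5, seed = 1L,
                             response = "ve_norm") {
  fold_map <- grouped_kfold(unique(data$subject_id), k, seed)
  fold_of <- fold_map[as.character(data$subject_id)]
  pe <- numeric(0)
  for (f in sort(unique(fold_map))) {
    train <- data[fold_of != f, , drop = FALSE]
    valid <- data[fold_of == f, , drop = FALSE]
    # leakage guard: training and validation subject sets must be disjoint
    stopifnot(length(intersect(unique(train$subject_id),
                               unique(valid$subject_id))) == 0)
    if (length(unique(train$subject_id)) < 2)
      stop("fold ", f, ": training set has fewer than 2 subjects")
    fit <- fit_lmm(train, predictors, response = response)
    obs <- valid[[response]]
    if (any(obs <= 0))
      stop("validation observations with nonpositive response; ",
           "percent error is undefined")
    pred <- predict(fit, valid)
    pe <- c(pe, 100 * (pred - obs) / obs)
  }
  structure(list(predictors = predictors, fold_map = fold_map,
                 seed = as.integer(seed), percent_errors = pe,
                 mean_pe = mean(pe), sd_pe = stats::sd(pe), k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold subject-grouped CV for {%s}: percent error %.2f (SD %.1f)%%, n = %d\n",
              x$k, paste(x$predictors, collapse = ", "), x$mean_pe, x$sd_pe,
              length(x$percent_errors)))
  invisible(x)
}

#' Evaluate predictor subsets: fits, AIC and cross-validated percent error
#'
#' Runs the brute-force evaluation: for each subset, a full-data REML fit
#' (estimates, p-values, AIC) and a subject-grouped k-fold cross-validation
#' (mean and SD of percent error). One fold split, fixed by `seed`, is reused
#' across all subsets so that their scores are comparable.
#'
#' @param data Analysis data.frame.
#' @param predictor_names Candidate pool (default [candidate_predictors()]).
#' @param k Folds.
#' @param seed Fold seed.
#' @param response Response column.
#' @param subsets Optional list of subsets to evaluate (default: all
#'   `2^p - 1`).
#' @return data.frame of class `selection_table`: one row per subset with
#'   `predictors` (slash-separated), `size`, `aic`, `mean_pe`, `sd_pe`,
#'   `all_significant`, `max_p`; fits attached as attribute `"fits"`.
#' @export
selection_table <- function(data, predictor_names = candidate_predictors(),
                            k = 5, seed = 1L, response = "ve_norm",
                            subsets = NULL) {
  subsets <- subsets %||% enumerate_subsets(predictor_names)
  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    fit <- fit_lmm(data, s, response = response)
    cv <- cv_percent_error(data, s, k = k, seed = seed, response = response)
    pv <- fit$coef$p[-1]          # slope p-values; intercept not gated
    rows[[i]] <- data.frame(
      predictors = paste(s, collapse = "/"), size = length(s),
      aic = fit$aic, mean_pe = cv$mean_pe, sd_pe = cv$sd_pe,
      all_significant = all(pv < 0.05), max_p = max(pv),
      stringsAsFactors = FALSE
    )
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("selection_table", class(out))
  out
}

#' Choose the best model of a given size
#'
#' Applies the three-criteria rule among subsets of the requested size. If
#' one subset minimizes both the absolute mean percent error and the AIC it
#' wins outright. When the two criteria disagree, the decision is arbitrated
#' between those two front-runners by the confidence in their coefficient
#' estimates: if exactly one has every coefficient significant at 0.05 it is
#' chosen; otherwise the one whose largest p-value is smaller (the stronger
#' cumulative evidence) wins, with any remaining tie broken by the smaller
#' absolute mean percent error. The returned report states which criterion
#' decided.
#'
#' @param table A [selection_table()] data.frame.
#' @param n_predictors Requested model size.
#' @return List: `row` (the chosen row), `criterion` (one of
#'   `"pe_and_aic_agree"`, `"significance"`, `"confidence"`,
#'   `"percent_error"`, `"only_candidate"`), `candidates` (the front-runner
#'   rows the decision was made between).
#' @export
select_best <- function(table, n_predictors) {
  cand <- table[table$size == n_predictors, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no evaluated models with ", n_predictors, " predictor(s)")
  if (nrow(cand) == 1)
    return(list(row = cand, criterion = "only_candidate", candidates = cand))
  i_pe <- which.min(abs(cand$mean_pe))
  i_aic <- which.min(cand$aic)
  if (i_pe == i_aic) {
    return(list(row = cand[i_pe, , drop = FALSE],
                criterion = "pe_and_aic_agree",
                candidates = cand[i_pe, , drop = FALSE]))
  }
  pair <- cand[c(i_pe, i_aic), , drop = FALSE]
  if (sum(pair$all_significant) == 1) {
    return(list(row = pair[pair$all_significant, , drop = FALSE],
                criterion = "significance", candidates = pair))
  }
  if (pair$max_p[1] != pair$max_p[2]) {
    return(list(row = pair[which.min(pair$max_p), , drop = FALSE],
                criterion = "confidence", candidates = pair))
  }
  list(row = pair[which.min(abs(pair$mean_pe)), , drop = FALSE],
       criterion = "percent_error", candidates = pair)
}
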