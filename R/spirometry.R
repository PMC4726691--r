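# Spirometry reference equations and maneuver handling.
#
# Reference-value coefficients are from Hankinson, Odencrantz & Fedan (1999),
# "Spirometric reference values from a sample of the general U.S. population",
# Am J Respir Crit Care Med 159:179-187 (NHANES III). Predicted value:
#   V = b0 + b1*age + b2*age^2 + b3*height^2     [age yr, height cm, V liters]
# with separate coefficient rows for adolescents and adults (males switch
# equations at age 20, females at 18). The lower limit of normal (LLN) uses
# the same b0..b2 with the LLN height^2 coefficient.

.nhanes3_age_split <- c(male = 20, female = 18)

# columns: b0, age, age2, ht2, ht2_lln
.nhanes3 <- list(
  caucasian = list(
    male = list(
      fvc_young  = c(-0.2584, -0.20415, 0.010133, 0.00018642, 0.00015695),
      fvc_old    = c(-0.1933,  0.00064, -0.000269, 0.00018642, 0.00015695),
      fev1_young = c(-0.7453, -0.04106, 0.004477, 0.00014098, 0.00011607),
      fev1_old   = c( 0.5536, -0.01303, -0.000172, 0.00014098, 0.00011607)
    ),
    female = list(
      fvc_young  = c(-1.2082, 0.05916, 0.000000, 0.00014815, 0.00012198),
      fvc_old    = c(-0.3560, 0.01870, -0.000382, 0.00014815, 0.00012198),
      fev1_young = c(-0.8710, 0.06537, 0.000000, 0.00011496, 0.00009283),
      fev1_old   = c( 0.4333, -0.00361, -0.000194, 0.00011496, 0.00009283)
    )
  ),
  african_american = list(
    male = list(
      fvc_young  = c(-0.4971, -0.15497, 0.007701, 0.00016643, 0.00013670),
      fvc_old    = c(-0.1517, -0.01821, 0.000000, 0.00016643, 0.00013670),
      fev1_young = c(-0.7048, -0.05711, 0.004316, 0.00013194, 0.00010561),
      fev1_old   = c( 0.3411, -0.02309, 0.000000, 0.00013194, 0.00010561)
    ),
    female = list(
      fvc_young  = c(-0.6370, -0.04243, 0.003508, 0.00013497, 0.00010916),
      fvc_old    = c(-0.3039,  0.00536, -0.000265, 0.00013497, 0.00010916),
      fev1_young = c(-0.9630, 0.05799, 0.000000, 0.00010846, 0.00008546),
      fev1_old   = c( 0.3433, -0.01283, -0.000097, 0.00010846, 0.00008546)
    )
  ),
  mexican_american = list(
    male = list(
      fvc_young  = c(-0.7571, -0.09520, 0.006619, 0.00017823, 0.00014947),
      fvc_old    = c( 0.2376, -0.00891, -0.000182, 0.00017823, 0.00014947),
      fev1_young = c(-0.8218, -0.04248, 0.004291, 0.00015104, 0.00012670),
      fev1_old   = c( 0.6306, -0.02928, 0.000000, 0.00015104, 0.00012670)
    ),
    female = list(
      fvc_young  = c(-1.2507, 0.07501, 0.000000, 0.00014246, 0.00011570),
      fvc_old    = c( 0.1210, 0.00307, -0.000237, 0.00014246, 0.00011570),
      fev1_young = c(-0.9282, 0.06149, 0.000000, 0.00012154, 0.00010017),
      fev1_old   = c( 0.4529, -0.01178, -0.000113, 0.00012154, 0.00010017)
    )
  )
)

#' Supported spirometry reference race categories
#'
#' @return Character vector of the three NHANES III race/ethnicity categories.
#' @export
nhanes3_races <- function() names(.nhanes3)

.eval_nhanes3 <- function(cf, age, height) {
  pred <- cf[1] + cf[2] * age + cf[3] * age^2 + cf[4] * height^2
  lln  <- cf[1] + cf[2] * age + cf[3] * age^2 + cf[5] * height^2
  c(pred = unname(pred), lln = unname(lln))
}

#' Predict lung function from NHANES III reference equations
#'
#' Computes predicted forced vital capacity (FVC) and forced expiratory volume
#' in one second (FEV1), with lower limits of normal, for a healthy subject of
#' given age, height, sex and race. Adolescent and adult coefficient rows are
#' switched at age 20 (males) or 18 (females). Age is taken as supplied in
#' decimal years; no rounding to birthdays is applied.
#'
#' @param age Age in years, in \[8, 80\]. Vectorized.
#' @param height Standing height in cm, in \[100, 220\]. Vectorized.
#' @param sex `0`/`"M"`/`"male"` for male, `1`/`"F"`/`"female"` for female.
#' @param race One of `nhanes3_races()`, or a category translated through
#'   `race_map`.
#' @param race_map Optional named character vector mapping non-NHANES
#'   categories to one of the three supported ones, e.g.
#'   `c(hispanic = "mexican_american")`. By default no mapping is assumed and
#'   unsupported categories are an error.
#' @return A data.frame with columns `fvc_pred`, `fvc_lln`, `fev1_pred`,
#'   `fev1_lln` (liters).
#' @examples
#' predict_lung_function(17.3, 175, sex = 0, race = "caucasian")
#' @export
predict_lung_function <- function(age, height, sex, race, race_map = NULL) {
  n <- max(length(age), length(height), length(sex), length(race))
  age <- rep_len(age, n); height <- rep_len(height, n)
  sex <- rep_len(sex, n); race <- rep_len(race, n)
  if (any(!is.finite(age)) || any(age < 8) || any(age > 80))
    stop("age must lie in [8, 80] years; got ", paste(age[age < 8 | age > 80 | !is.finite(age)][1]))
  if (any(!is.finite(height)) || any(height < 100) || any(height > 220))
    stop("height must lie in [100, 220] cm; got ",
         paste(height[height < 100 | height > 220 | !is.finite(height)][1]))
  sexn <- normalize_sex(sex)
  race <- as.character(race)
  if (!is.null(race_map)) {
    hit <- race %in% names(race_map)
    race[hit] <- unname(race_map[race[hit]])
  }
  bad <- setdiff(unique(race), nhanes3_races())
  if (length(bad))
    stop("unsupported race category ", paste(sQuote(bad), collapse = ", "),
         "; supported categories are ",
         paste(sQuote(nhanes3_races()), collapse = ", "),
         " (supply race_map= to translate others)")
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("fvc_pred", "fvc_lln", "fev1_pred", "fev1_lln")))
  for (i in seq_len(n)) {
    sx <- if (sexn[i] == 0) "male" else "female"
    era <- if (age[i] < .nhanes3_age_split[[sx]]) "young" else "old"
    tab <- .nhanes3[[race[i]]][[sx]]
    fvc  <- .eval_nhanes3(tab[[paste0("fvc_", era)]], age[i], height[i])
    fev1 <- .eval_nhanes3(tab[[paste0("fev1_", era)]], age[i], height[i])
    out[i, ] <- c(fvc["pred"], fvc["lln"], fev1["pred"], fev1["lln"])
  }
  as.data.frame(out)
}

# Accepts 0/1, "0"/"1", "M"/"F", "male"/"female" (any case); returns 0/1.
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- ifelse(s %in% c("0", "m", "male"), 0L,
         ifelse(s %in% c("1", "f", "female"), 1L, NA_integer_))
  if (anyNA(out))
    stop("sex must be coded 0/M/male or 1/F/female; got ",
         sQuote(s[is.na(out)][1]))
  out
}

#' Select the best spirometry maneuver
#'
#' Returns the acceptable maneuver with the highest FVC, the rule used to
#' reduce repeated pre-test maneuvers to the analysis values.
#'
#' @param maneuvers data.frame with columns `fvc`, `fev1` (liters) and logical
#'   `acceptable` (flow-volume loop acceptability flag).
#' @return One-row data.frame: the chosen maneuver.
#' @export
select_best_maneuver <- function(maneuvers) {
  if (is.null(maneuvers) || nrow(maneuvers) == 0)
    stop("at least one spirometry maneuver is required")
  stopifnot(all(c("fvc", "fev1", "acceptable") %in% names(maneuvers)))
  if (any(maneuvers$fev1 > maneuvers$fvc + 1e-12) || any(maneuvers$fvc <= 0))
    stop("maneuvers must satisfy 0 < fev1 <= fvc")
  ok <- maneuvers[isTRUE_vec(maneuvers$acceptable), , drop = FALSE]
  if (nrow(ok) == 0) stop("no acceptable maneuver among the ", nrow(maneuvers), " supplied")
  ok[which.max(ok$fvc), , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Percent of predicted lung function
#'
#' @param measured Measured value (liters).
#' @param predicted Reference-equation predicted value (liters); must be > 0.
#' @return `100 * measured / predicted`.
#' @export
percent_predicted <- function(measured, predicted) {
  if (any(predicted <= 0)) stop("predicted lung function must be positive")
  100 * measured / predicted
}

#' Read a subject roster CSV
#'
#' Expected header: `subject_id, age, sex, height_cm, weight_kg, race, fvc_L,
#' fev1_L`. Sex is accepted as 0/1 or M/F and normalized to 0 (male) /
#' 1 (female). BMI and the FEV1/FVC ratio are derived.
#'
#' @param path CSV file path.
#' @return data.frame of subject records with columns `subject_id, age, sex,
#'   height, weight, bmi, race, fvc_measured, fev1_measured, fev1_fvc`.
#' @export
read_subjects <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "height_cm", "weight_kg", "race",
            "fvc_L", "fev1_L")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("subject roster is missing columns: ",
                         paste(miss, collapse = ", "))
  subjects <- data.frame(
    subject_id = as.character(raw$subject_id),
    age = raw$age,
    sex = normalize_sex(raw$sex),
    height = raw$height_cm,
    weight = raw$weight_kg,
    bmi = raw$weight_kg / (raw$height_cm / 100)^2,
    race = as.character(raw$race),
    fvc_measured = raw$fvc_L,
    fev1_measured = raw$fev1_L,
    fev1_fvc = raw$fev1_L / raw$fvc_L,
    stringsAsFactors = FALSE
  )
  validate_subjects(subjects)
  subjects
}

validate_subjects <- function(subjects) {
  with(subjects, {
    stopifnot(all(height > 0), all(weight > 0),
              all(fvc_measured > 0), all(fev1_measured > 0),
              all(fev1_measured <= fvc_measured + 1e-9),
              all(fev1_fvc > 0), all(fev1_fvc <= 1 + 1e-9))
    if (any(abs(bmi - weight / (height / 100)^2) > 1e-6))
      stop("bmi inconsistent with weight/height")
  })
  invisible(subjects)
}
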