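# Random-intercept linear mixed model fit by REML.
#
# Model: y = X beta + Z b + e, b_i ~ N(0, tau2) one intercept per subject,
# e ~ N(0, sigma2 I). Writing lambda = tau2/sigma2, the marginal covariance
# is sigma2 * Sigma(lambda) with Sigma block-diagonal, block I + lambda J.
# For fixed lambda, GLS gives beta and the REML-profiled sigma2 in closed
# form, so estimation reduces to a 1-D search over lambda:
#   Sigma_i^{-1} = I - (lambda / (1 + lambda n_i)) J
#   -2 l_R(lambda) = (n-p)(log sigma2_hat + 1 + log 2pi)
#                    + sum_i log(1 + lambda n_i) + log |X' Sigma^{-1} X|
# All per-subject quantities enter through cross-products, so each lambda
# evaluation is O(p^2 * n_subjects) after a single pass over the data.

# Per-subject sufficient statistics for the profiled REML criterion.
.lmm_suff <- function(X, y, group) {
  idx <- split(seq_along(y), group)
  list(
    XtX = lapply(idx, function(i) crossprod(X[i, , drop = FALSE])),
    Xty = lapply(idx, function(i) crossprod(X[i, , drop = FALSE], y[i])),
    yty = vapply(idx, function(i) sum(y[i]^2), numeric(1)),
    sx  = lapply(idx, function(i) colSums(X[i, , drop = FALSE])),
    sy  = vapply(idx, function(i) sum(y[i]), numeric(1)),
    ni  = lengths(idx),
    n = length(y), p = ncol(X)
  )
}

# Returns beta, rss (in Sigma metric), XtSX and the -2 REML log-likelihood
# at a given lambda.
.lmm_at_lambda <- function(suff, lambda) {
  p <- suff$p; n <- suff$n
  A <- matrix(0, p, p); v <- numeric(p); q <- 0
  for (i in seq_along(suff$ni)) {
    ci <- lambda / (1 + lambda * suff$ni[i])
    A <- A + suff$XtX[[i]] - ci * tcrossprod(suff$sx[[i]])
    v <- v + suff$Xty[[i]] - ci * suff$sx[[i]] * suff$sy[i]
    q <- q + suff$yty[i] - ci * suff$sy[i]^2
  }
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), v))
  rss <- max(q - sum(v * beta), 1e-300)
  sigma2 <- rss / (n - p)
  logdetA <- 2 * sum(log(diag(ch)))
  m2ll <- (n - p) * (log(sigma2) + 1 + log(2 * pi)) +
    sum(log(1 + lambda * suff$ni)) + logdetA
  list(beta = beta, sigma2 = sigma2, lambda = lambda, m2ll = m2ll,
       XtSX = A, rss = rss)
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Fits `response ~ 1 + predictors` with a random intercept per subject
#' (variance-components covariance structure). The variance ratio
#' `lambda = tau2/sigma2` is profiled out with a log-scale grid search
#' followed by bounded scalar refinement; fixed effects are generalized least
#' squares at the optimum. A boundary estimate `tau2 = 0` is reported as such.
#'
#' @param data data.frame containing the response, the predictors and
#'   `subject_id`.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only model). Canonical candidate names:
#'   `hr, fb, act, warm, age, sex, bmi, fev1_fvc, height`.
#' @param response Response column name (default `"ve_norm"`).
#' @param alpha Level for the two-sided confidence intervals.
#' @param aic_convention `"covariance"` (default): `AIC = -2 l_R + 2 q` with
#'   `q` the number of covariance parameters (2 here), matching software that
#'   counts only covariance parameters under REML; `"all"` additionally
#'   counts the fixed effects.
#' @return Object of class `lmm_fit`: coefficient table, `tau2`, `sigma2`,
#'   `reml_loglik`, `aic`, `n_obs`, `n_subjects`.
#' @export
fit_lmm <- function(data, predictors, response = "ve_norm", alpha = 0.05,
                    aic_convention = c("covariance", "all")) {
  aic_convention <- match.arg(aic_convention)
  stopifnot("subject_id" %in% names(data), response %in% names(data))
  miss <- setdiff(predictors, names(data))
  if (length(miss)) stop("predictors not in data: ", paste(miss, collapse = ", "))
  y <- data[[response]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  group <- as.character(data$subject_id)
  n_subj <- length(unique(group))
  if (n_subj < 2)
    stop("at least 2 subjects are required to identify the random intercept")
  tab <- table(group)
  if (any(tab < 2))
    stop("every subject needs >= 2 observations; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  suff <- .lmm_suff(X, y, group)

  crit <- function(loglam) .lmm_at_lambda(suff, 10^loglam)$m2ll
  grid <- seq(-10, 6, by = 0.25)
  vals <- vapply(grid, crit, numeric(1))
  j <- which.min(vals)
  lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
  opt <- stats::optimize(crit, c(lo, hi), tol = 1e-10)
  lambda <- 10^opt$minimum
  # boundary check: tau2 = 0 competes with the interior optimum
  at0 <- .lmm_at_lambda(suff, 0)
  fit <- .lmm_at_lambda(suff, lambda)
  if (at0$m2ll <= fit$m2ll + 1e-10) { fit <- at0; lambda <- 0 }

  p <- ncol(X); n <- length(y)
  vcov_beta <- fit$sigma2 * chol2inv(chol(fit$XtSX))
  se <- sqrt(diag(vcov_beta))
  df <- n - p - (n_subj - 1)
  tstat <- fit$beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  tcrit <- stats::qt(1 - alpha / 2, df)
  coef_tab <- data.frame(
    term = colnames(X), estimate = as.numeric(fit$beta), se = se,
    ci_lo = as.numeric(fit$beta) - tcrit * se,
    ci_hi = as.numeric(fit$beta) + tcrit * se,
    t = as.numeric(tstat), df = df, p = as.numeric(pval),
    stringsAsFactors = FALSE
  )
  reml_ll <- -fit$m2ll / 2
  q_cov <- 2L
  aic <- -2 * reml_ll + 2 * switch(aic_convention,
                                   covariance = q_cov,
                                   all = q_cov + p)
  structure(list(
    predictors = predictors, response = response, coef = coef_tab,
    beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
    vcov = vcov_beta, tau2 = lambda * fit$sigma2, sigma2 = fit$sigma2,
    lambda = lambda, reml_loglik = reml_ll, aic = aic,
    aic_convention = aic_convention, n_obs = n, n_subjects = n_subj,
    df = df, alpha = alpha
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat("  response:", x$response, "  n_obs:", x$n_obs,
      "  n_subjects:", x$n_subjects, "\n")
  cat(sprintf("  tau2 = %.5g   sigma2 = %.5g   REML logLik = %.4f   AIC = %.2f\n",
              x$tau2, x$sigma2, x$reml_loglik, x$aic))
  print(format(x$coef, digits = 4), row.names = FALSE)
  invisible(x)
}

#' REML-based AIC of a fitted model
#'
#' `AIC = -2 l_R + 2 q`, with `q` the covariance-parameter count under the
#' default convention (see [fit_lmm()]).
#'
#' @param fit An `lmm_fit` object.
#' @return Scalar AIC.
#' @export
aic_of <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$aic
}

#' Wald (t-based) inference table for a fitted model
#'
#' Recomputes per-coefficient confidence intervals and two-sided p-values at
#' a chosen level using residual (containment-style) degrees of freedom
#' `n_obs - rank(X) - (n_subjects - 1)`.
#'
#' @param fit An `lmm_fit` object.
#' @param alpha Two-sided level (default 0.05).
#' @return data.frame with `term, estimate, se, ci_lo, ci_hi, p`.
#' @export
wald_inference <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  se <- sqrt(diag(fit$vcov))
  tcrit <- stats::qt(1 - alpha / 2, fit$df)
  est <- fit$beta
  tstat <- ifelse(se > 0, est / se, 0)
  data.frame(
    term = names(est), estimate = as.numeric(est), se = se,
    ci_lo = as.numeric(est) - tcrit * se, ci_hi = as.numeric(est) + tcrit * se,
    p = 2 * stats::pt(abs(tstat), fit$df, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Predict fixed-effects response for new observations
#'
#' Fixed-effects-only prediction (random intercepts of unseen subjects are
#' taken as zero), the rule used for held-out subjects in cross-validation.
#'
#' @param object An `lmm_fit` object.
#' @param newdata data.frame containing the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lmm_fit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$predictors, drop = FALSE]))
  as.numeric(X %*% object$beta)
}

# -2 REML log-likelihood profile, exposed for optimality checks and oracles.
reml_m2ll_profile <- function(data, predictors, response, lambdas) {
  y <- data[[response]]
  X <- cbind(1, as.matrix(data[, predictors, drop = FALSE]))
  suff <- .lmm_suff(X, y, as.character(data$subject_id))
  vapply(lambdas, function(l) .lmm_at_lambda(suff, l)$m2ll, numeric(1))
}

#' Serialize a fitted model to a JSON report
#'
#' @param fit An `lmm_fit` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  rep <- list(
    response = fit$response, predictors = fit$predictors,
    coefficients = fit$coef, tau2 = fit$tau2, sigma2 = fit$sigma2,
    reml_loglik = fit$reml_loglik, aic = fit$aic,
    n_obs = fit$n_obs, n_subjects = fit$n_subjects
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
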