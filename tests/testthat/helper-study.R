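# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A full synthetic study at the default (study-condition) noise level.
noisy_study <- function() {
  memo("noisy", function() {
    truth <- truth_params(seed = 104)
    cohort <- generate_cohort(15, truth)
    sessions <- lapply(seq_len(nrow(cohort)), function(i)
      simulate_treadmill_session(cohort[i, ], truth))
    names(sessions) <- cohort$subject_id
    dataset <- suppressMessages(build_analysis_dataset(sessions, cohort, "30"))
    list(truth = truth, cohort = cohort, sessions = sessions,
         dataset = dataset)
  })
}

# The same study design with all noise removed (tau = sigma = 0).
clean_study <- function(timebase = "ib") {
  memo(paste0("clean_", timebase), function() {
    truth <- truth_params(tau = 0, sigma = 0, seed = 104)
    cohort <- generate_cohort(15, truth)
    sessions <- lapply(seq_len(nrow(cohort)), function(i)
      simulate_treadmill_session(cohort[i, ], truth))
    names(sessions) <- cohort$subject_id
    dataset <- suppressMessages(
      build_analysis_dataset(sessions, cohort, timebase))
    list(truth = truth, cohort = cohort, sessions = sessions,
         dataset = dataset)
  })
}

# Small deterministic repeated-measures table for mixed-model oracle tests:
# 3 subjects x 4 observations, clear subject offsets.
tiny_lmm_data <- function() {
  data.frame(
    subject_id = rep(c("A", "B", "C"), each = 4),
    x = c(1.0, 2.0, 3.0, 4.0,  1.5, 2.5, 3.5, 4.5,  0.5, 1.5, 2.5, 3.5),
    y = c(2.1, 3.9, 6.2, 8.1,  4.6, 6.4, 8.3, 10.6,  0.9, 2.8, 5.2, 6.9)
  )
}

# Independent REML oracle: dense lambda grid (coarse pass over 16 decades,
# then a fine local grid around the coarse optimum), closed-form GLS and
# explicit determinants at every node. Shares no code with the fitter.
lmm_gls_oracle <- function(data, predictors, response = "y") {
  y <- data[[response]]
  X <- cbind(1, as.matrix(data[, predictors, drop = FALSE]))
  g <- as.character(data$subject_id)
  n <- length(y); p <- ncol(X)
  eval_lambda <- function(lam) {
    Sigma <- matrix(0, n, n)
    for (id in unique(g)) {
      i <- which(g == id)
      Sigma[i, i] <- lam
      Sigma[cbind(i, i)] <- 1 + lam
    }
    Si <- solve(Sigma)
    XtSiX <- t(X) %*% Si %*% X
    beta <- solve(XtSiX, t(X) %*% Si %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Si %*% r)
    sigma2 <- rss / (n - p)
    m2ll <- (n - p) * (log(sigma2) + 1 + log(2 * pi)) +
      as.numeric(determinant(Sigma)$modulus) +
      as.numeric(determinant(XtSiX)$modulus)
    list(lambda = lam, beta = drop(beta), sigma2 = sigma2,
         tau2 = lam * sigma2, m2ll = m2ll, reml_loglik = -m2ll / 2)
  }
  scan <- function(lambdas) {
    best <- NULL
    for (lam in lambdas) {
      cand <- eval_lambda(lam)
      if (is.null(best) || cand$m2ll < best$m2ll) best <- cand
    }
    best
  }
  coarse <- scan(10^seq(-10, 6, length.out = 2000))
  scan(coarse$lambda * 10^seq(-0.02, 0.02, length.out = 2001))
}

# Constant-signal physio/breath pair: hr, fb constant, one breath of volume
# vt every `every` seconds.
constant_session <- function(n_sec = 180, hr = 100, fb = 20, vt = 1,
                             every = 3) {
  physio <- data.frame(t = 0:(n_sec - 1), hr = hr, fb = fb, act = 0)
  t_start <- seq(every, n_sec - 1, by = every)
  list(physio = physio, breaths = data.frame(t_start = t_start, vt = vt))
}
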