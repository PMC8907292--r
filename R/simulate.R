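#' Simulate an expression cohort with survival times
#'
#' Generates a features-x-samples expression matrix with i.i.d.
#' log-normal marginals (count-like positivity and right skew) and
#' survival times driven linearly by a sparse subset of `k` features:
#' `time = softplus(baseline + sum_j w_j * standardized(x_j) + noise)`,
#' where standardization uses the theoretical log-normal moments and the
#' softplus link guarantees positive times. With the defaults the times
#' span roughly 0.05-8 years around a 2-year baseline, emulating a
#' bladder-carcinoma-sized cohort. Cells are independently flagged
#' missing (not detected) at `missing_rate`. The returned truth record
#' carries the driver features, their weights, and a generative (oracle)
#' R-squared — the squared correlation between noiseless and noisy
#' survival times estimated on a fresh held-out draw — which upper-bounds
#' what any estimator can reach in cross-validation.
#'
#' @param n samples; `p` features; `k` survival-driver features.
#' @param p,k see above.
#' @param weights effect weights, length `k` (recycled from a scalar).
#' @param baseline latent baseline survival level (years, pre-softplus).
#' @param noise_sd additive Gaussian noise sd (latent scale, years).
#' @param meanlog,sdlog log-normal expression parameters.
#' @param missing_rate per-cell missingness probability.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list: `expression` ([expr_matrix()]), `cohort` (tibble
#'   `sample_id`, `time_years`, `is_followup`), `truth` (list with
#'   `true_features`, `weights`, `baseline`, `noise_sd`, `oracle_r2`).
#' @export
simulate_survival_cohort <- function(n = 106L, p = 485L, k = 10L,
                                     weights = 0.5, baseline = 2,
                                     noise_sd = 0.6, meanlog = 3,
                                     sdlog = 0.6, missing_rate = 0.02,
                                     seed = 1L) {
  if (k > p) abort("k must not exceed p.")
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  weights <- rep_len(weights, k)
  withr::with_seed(as.integer(seed), {
    feature_ids <- sprintf("miR-%04d", seq_len(p))
    sample_ids <- sprintf("S%03d", seq_len(n))
    true_idx <- sort(sample.int(p, k))

    draw <- function(n_draw) {
      z <- matrix(rnorm(p * n_draw), nrow = p)
      x <- exp(meanlog + sdlog * z)
      mu <- exp(meanlog + sdlog^2 / 2)
      sigma <- mu * sqrt(exp(sdlog^2) - 1)
      std <- (x[true_idx, , drop = FALSE] - mu) / sigma
      signal <- drop(crossprod(std, weights))
      list(x = x, latent = baseline + signal)
    }

    d <- draw(n)
    times <- softplus(d$latent + rnorm(n, 0, noise_sd))

    # oracle R^2 on a fresh held-out draw
    h <- draw(2000L)
    clean <- softplus(h$latent)
    noisy <- softplus(h$latent + rnorm(2000L, 0, noise_sd))
    oracle_r2 <- if (sd(clean) == 0 || sd(noisy) == 0) 0 else cor(clean, noisy)^2

    x <- d$x
    if (missing_rate > 0) {
      x[runif(length(x)) < missing_rate] <- NA_real_
    }
    dimnames(x) <- list(feature_ids, sample_ids)

    list(
      expression = expr_matrix(x),
      cohort = tibble(sample_id = sample_ids, time_years = times,
                      is_followup = FALSE),
      truth = list(true_features = feature_ids[true_idx], weights = weights,
                   baseline = baseline, noise_sd = noise_sd,
                   oracle_r2 = oracle_r2)
    )
  })
}

softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)

#' Simulate a tumor/normal diagnostic cohort
#'
#' Log-normal expression in both groups; for the designated differential
#' features the tumor group's latent normal score is shifted by
#' `shift` within-group standard deviations, so the theoretical
#' per-feature AUC is `pnorm(shift / sqrt(2))`. All other features are
#' exchangeable between groups.
#'
#' @param n_tumor,n_normal group sizes (>= 2 each).
#' @param p number of features; `k_diff` differential features.
#' @param k_diff,shift number and latent-scale effect size of
#'   differential features.
#' @param meanlog,sdlog log-normal parameters.
#' @param seed integer seed.
#' @return A list: `expression`, `labels` (tibble `sample_id`, `label`
#'   with levels normal/tumor), `truth` (differential feature ids and
#'   shift).
#' @export
simulate_diagnostic_cohort <- function(n_tumor = 418L, n_normal = 18L,
                                       p = 485L, k_diff = 8L, shift = 1.5,
                                       meanlog = 3, sdlog = 0.6, seed = 1L) {
  if (n_tumor < 2L || n_normal < 2L) abort("each group needs >= 2 samples.")
  if (k_diff > p) abort("k_diff must not exceed p.")
  withr::with_seed(as.integer(seed), {
    n <- n_tumor + n_normal
    feature_ids <- sprintf("miR-%04d", seq_len(p))
    sample_ids <- c(sprintf("T%03d", seq_len(n_tumor)),
                    sprintf("N%03d", seq_len(n_normal)))
    is_tumor <- rep(c(TRUE, FALSE), c(n_tumor, n_normal))
    diff_idx <- sort(sample.int(p, k_diff))
    z <- matrix(rnorm(p * n), nrow = p)
    z[diff_idx, is_tumor] <- z[diff_idx, is_tumor] + shift
    x <- exp(meanlog + sdlog * z)
    dimnames(x) <- list(feature_ids, sample_ids)
    list(
      expression = expr_matrix(x),
      labels = tibble(sample_id = sample_ids,
                      label = factor(ifelse(is_tumor, "tumor", "normal"),
                                     levels = c("normal", "tumor"))),
      truth = list(diff_features = feature_ids[diff_idx], shift = shift)
    )
  })
}

#' Simulate a right-censored follow-up cohort
#'
#' Draws follow-up times inside `(0, window]` from a scaled beta
#' distribution with the requested mean, emulating an independent test
#' cohort still in follow-up (all observations right-censored). The
#' defaults mirror a one-year window with a mean follow-up of 5.54
#' months.
#'
#' @param n patients.
#' @param window follow-up window in years (default 1).
#' @param mean_followup target mean follow-up (years), inside
#'   `(0, window)`.
#' @param shape1 beta first shape parameter (the second is solved from
#'   the mean).
#' @param seed integer seed.
#' @return A tibble `sample_id`, `time_years`, `is_followup = TRUE`.
#' @export
simulate_followup_cohort <- function(n = 123L, window = 1,
                                     mean_followup = 5.54 / 12,
                                     shape1 = 2, seed = 1L) {
  if (mean_followup <= 0 || mean_followup >= window) {
    abort("mean_followup must lie strictly inside (0, window).")
  }
  withr::with_seed(as.integer(seed), {
    shape2 <- shape1 * (window / mean_followup - 1)
    t <- window * rbeta(n, shape1, shape2)
    t[t <= 0] <- window * .Machine$double.eps
    tibble(sample_id = sprintf("F%03d", seq_len(n)),
           time_years = t, is_followup = TRUE)
  })
}
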