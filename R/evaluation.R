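#' Penalised-regression baselines
#'
#' Fits ridge, lasso or elastic-net regression of survival time on the
#' full filtered feature set (via glmnet). The penalty weight lambda is
#' the minimizer of the mean cross-validation error averaged over
#' `n_rep` seeded repetitions of `n_folds`-fold CV on a common lambda
#' path; performance is then measured from pooled out-of-fold predictions
#' at that weight (same convention as the SVR fitness, so comparisons are
#' like-for-like), and the number of nonzero coefficients of the
#' full-data fit is reported — ridge keeps all `p` features by
#' construction.
#'
#' @param x an [expr_matrix()] or samples x features matrix.
#' @param y survival times in years.
#' @param method `"ridge"`, `"lasso"` or `"elastic_net"`.
#' @param alpha elastic-net mixing weight (only for `"elastic_net"`;
#'   `1` reduces to lasso, `0` to ridge).
#' @param n_folds CV folds (default 10).
#' @param n_rep number of repeated CV draws for choosing lambda
#'   (default 100).
#' @param seed base seed; repetition `i` uses `seed + i`.
#' @return A `baseline_result` tibble row: `method`, `lambda`,
#'   `r_squared`, `mae_years`, `n_nonzero`.
#' @export
fit_baseline <- function(x, y, method = c("ridge", "lasso", "elastic_net"),
                         alpha = 0.5, n_folds = 10L, n_rep = 100L,
                         seed = 1L) {
  method <- match.arg(method)
  xs <- as_sample_matrix(x)
  n <- nrow(xs)
  if (length(y) != n) abort("sample count mismatch between x and y.")
  if (sd(y) == 0) abort("degenerate (constant) response.")
  a <- switch(method, ridge = 0, lasso = 1, elastic_net = alpha)

  # common lambda path from the full-data fit
  path_fit <- glmnet::glmnet(xs, y, alpha = a, nlambda = 100)
  lambda <- path_fit$lambda

  cvm <- matrix(0, nrow = length(lambda), ncol = n_rep)
  for (i in seq_len(n_rep)) {
    foldid <- make_folds(n, cv_config(n_folds, seed = seed + i))
    cv <- glmnet::cv.glmnet(xs, y, alpha = a, lambda = lambda,
                            foldid = foldid)
    cvm[, i] <- cv$cvm[match(lambda, cv$lambda)]
  }
  mean_cvm <- rowMeans(cvm, na.rm = TRUE)
  lambda_min <- lambda[which.min(mean_cvm)]

  # pooled out-of-fold predictions at lambda_min
  foldid <- make_folds(n, cv_config(n_folds, seed = seed))
  z <- numeric(n)
  for (k in seq_len(n_folds)) {
    hold <- foldid == k
    fit_k <- glmnet::glmnet(xs[!hold, , drop = FALSE], y[!hold], alpha = a,
                            lambda = lambda)
    z[hold] <- as.numeric(
      predict(fit_k, xs[hold, , drop = FALSE], s = lambda_min))
  }
  nz <- sum(as.numeric(coef(path_fit, s = lambda_min))[-1L] != 0)
  if (method == "ridge") nz <- ncol(xs)

  out <- tibble(
    method = method,
    lambda = lambda_min,
    r_squared = suppressWarnings(r_squared(y, z)),
    mae_years = mean_abs_error(y, z),
    n_nonzero = as.integer(nz)
  )
  attr(out, "predictions") <- tibble(sample = seq_len(n), fold = foldid,
                                     actual = y, predicted = z)
  attr(out, "nonzero_features") <- {
    beta <- as.numeric(coef(path_fit, s = lambda_min))[-1L]
    cn <- colnames(xs)
    if (is.null(cn)) cn <- paste0("f", seq_len(ncol(xs)))
    cn[beta != 0]
  }
  class(out) <- c("baseline_result", class(out))
  out
}

#' Rank-based ROC analysis
#'
#' AUC as the Mann-Whitney rank statistic: the probability that a
#' positive-class score exceeds a negative-class score, counting ties as
#' one half. No direction is forced — an anti-discriminating score yields
#' AUC below 0.5 and is reported as-is. Operating points (sensitivity,
#' specificity) are returned for every distinct threshold.
#'
#' @param scores numeric scores, higher = more "positive".
#' @param labels binary labels; `positive` names the positive class.
#' @param positive the positive class value (default: the larger factor
#'   level, or `TRUE`/`1`).
#' @return A `roc_result` with `auc`, `n_pos`, `n_neg`, `points` tibble
#'   (`threshold`, `sensitivity`, `specificity`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) abort("length mismatch.")
  lab <- as.factor(labels)
  if (nlevels(lab) != 2L) abort("need exactly two classes present.")
  if (is.null(positive)) positive <- levels(lab)[2L]
  pos <- lab == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present.")
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)

  thresholds <- sort(unique(scores), decreasing = TRUE)
  points <- tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(scores[pos] >= t),
                         numeric(1)),
    specificity = vapply(thresholds, function(t) mean(scores[!pos] < t),
                         numeric(1))
  )
  structure(list(auc = unname(auc), n_pos = n1, n_neg = n0, points = points),
            class = "roc_result")
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Differential-expression test between two groups
#'
#' Two-sided Wilcoxon rank-sum test by default (nonparametric, robust to
#' the right skew of expression data); `method = "t"` switches to
#' Welch's t-test. When every value is tied across both groups the
#' p-value is defined as 1.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param method `"wilcox"` or `"t"`.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
diff_expression_test <- function(values_a, values_b,
                                 method = c("wilcox", "t")) {
  method <- match.arg(method)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("each group needs at least two values.")
  }
  if (length(unique(c(values_a, values_b))) == 1L) return(1)
  p <- if (method == "wilcox") {
    suppressWarnings(
      wilcox.test(values_a, values_b, alternative = "two.sided",
                  exact = FALSE, correct = TRUE)$p.value)
  } else {
    stats::t.test(values_a, values_b)$p.value
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Cross-validated random-forest diagnosis from a signature
#'
#' Combines a feature subset (e.g. the top-ranked signature miRNAs) into
#' a random-forest tumor/normal classifier evaluated by repeated
#' stratified `n_folds`-fold CV. Per repetition, out-of-fold class-vote
#' fractions are pooled; accuracy, sensitivity and specificity are taken
#' at the 0.5 vote threshold (tumor = positive class) and AUC from the
#' pooled votes. Mean, standard deviation and maximum over repetitions
#' are reported.
#'
#' @param x an [expr_matrix()] restricted to the signature, or samples x
#'   features matrix.
#' @param labels two-class factor; `positive` names the positive (tumor)
#'   class.
#' @param positive positive class (default: second factor level).
#' @param n_folds stratified CV folds (default 10).
#' @param n_rep repetitions (default 100).
#' @param ntree random-forest trees per fit.
#' @param seed base seed.
#' @return A `classifier_cv` with `summary` tibble (metric,
#'   mean, sd, max) and `per_rep` tibble.
#' @export
combined_classifier_cv <- function(x, labels, positive = NULL,
                                   n_folds = 10L, n_rep = 100L,
                                   ntree = 200L, seed = 1L) {
  xs <- as_sample_matrix(x)
  lab <- as.factor(labels)
  if (nlevels(lab) != 2L) abort("need exactly two classes.")
  if (is.null(positive)) positive <- levels(lab)[2L]
  pos <- lab == positive
  n <- nrow(xs)
  if (min(sum(pos), sum(!pos)) < n_folds) {
    n_folds <- max(2L, min(sum(pos), sum(!pos)))
  }

  rep_metrics <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    votes <- withr::with_seed(seed + i, {
      # stratified folds: assign within each class so every training
      # fold keeps both classes
      foldid <- integer(n)
      for (cl in c(TRUE, FALSE)) {
        idx <- which(pos == cl)
        foldid[idx[sample.int(length(idx))]] <-
          rep(seq_len(n_folds), length.out = length(idx))
      }
      v <- numeric(n)
      for (k in seq_len(n_folds)) {
        hold <- foldid == k
        rf <- randomForest::randomForest(
          xs[!hold, , drop = FALSE], lab[!hold], ntree = ntree)
        v[hold] <- predict(rf, xs[hold, , drop = FALSE],
                           type = "prob")[, positive]
      }
      v
    })
    pred_pos <- votes >= 0.5
    tp <- sum(pred_pos & pos); tn <- sum(!pred_pos & !pos)
    fp <- sum(pred_pos & !pos); fn <- sum(!pred_pos & pos)
    rep_metrics[[i]] <- tibble(
      rep = i,
      accuracy = (tp + tn) / n,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      auc = roc_auc(votes, pos, positive = TRUE)$auc
    )
  }
  per_rep <- dplyr::bind_rows(rep_metrics)
  summary <- per_rep |>
    tidyr::pivot_longer(-"rep", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (n_rep > 1L) sd(.data$value) else NA_real_,
                     max = max(.data$value), .groups = "drop")
  structure(list(summary = summary, per_rep = per_rep,
                 positive = positive, n_folds = n_folds),
            class = "classifier_cv")
}

#' @exportS3Method base::print
print.classifier_cv <- function(x, ...) {
  cat(sprintf("<classifier_cv> %d-fold stratified CV, %d repetition(s)\n",
              x$n_folds, nrow(x$per_rep)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.classifier_cv <- function(x, ...) x$per_rep

#' @export
glance.classifier_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd", "max"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via the survival package) returned as a tidy
#' step table.
#'
#' @param times positive event/censoring times (years).
#' @param events 1/TRUE = event observed, 0/FALSE = censored.
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) abort("empty group.")
  if (any(times <= 0)) abort("times must be > 0.")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank test between two survival groups
#'
#' @param times_a,times_b positive times per group.
#' @param events_a,events_b event indicators per group (default: all
#'   events).
#' @return A list with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(times_a, times_b,
                         events_a = rep(1L, length(times_a)),
                         events_b = rep(1L, length(times_b))) {
  if (length(times_a) == 0L || length(times_b) == 0L) abort("empty group.")
  time <- c(times_a, times_b)
  event <- c(as.integer(events_a), as.integer(events_b))
  if (all(event == 0L)) return(list(statistic = 0, p_value = 1))
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd_fit$chisq),
       p_value = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE))
}

#' Coverage accuracy on a right-censored follow-up cohort
#'
#' For patients still in follow-up, an estimate is not contradicted by
#' the data exactly when the predicted survival time is at least the
#' observed follow-up time; the coverage accuracy is the fraction of
#' patients for which that holds.
#'
#' @param predicted predicted survival times (> 0).
#' @param followup observed follow-up times (> 0), same length.
#' @return Fraction in `[0, 1]`.
#' @examples
#' coverage_accuracy(c(2, 0.4), c(0.5, 0.5)) # 0.5
#' @export
coverage_accuracy <- function(predicted, followup) {
  if (length(predicted) != length(followup)) abort("length mismatch.")
  if (length(predicted) == 0L) abort("need at least one patient.")
  if (any(predicted <= 0) || any(followup <= 0)) abort("times must be > 0.")
  mean(predicted >= followup)
}
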