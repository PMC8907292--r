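#' Full signature-selection workflow
#'
#' Runs the complete pipeline: presence filtering, missing-value
#' imputation, alignment with the survival cohort, `n_runs` independent
#' seeded GA runs, appearance-score selection of the robust signature,
#' and (optionally) main-effect-difference ranking of its features with
#' the winning run's hyperparameters and fold partition. Per-run seeds
#' are `master_seed + run index`, so the whole workflow is a pure
#' function of its arguments and any run can be replayed from the
#' manifest alone.
#'
#' @param expression an [expr_matrix()].
#' @param cohort survival tibble (`sample_id`, `time_years`).
#' @param n_runs number of independent GA runs (50 at production scale).
#' @param config an [ibcga_config()].
#' @param master_seed integer master seed.
#' @param presence_threshold presence fraction for [filter_present()].
#' @param med_ranking also compute the MED table of the robust signature.
#' @param verbose print one line per finished run.
#' @return A `sig_workflow` object: `runs` (list of `ibcga_run`), `asc`
#'   (`asc_report`), `med` (`med_table` or `NULL`), `model` (nu-SVR
#'   refit of the robust signature on all training samples), `manifest`.
#' @export
run_signature_workflow <- function(expression, cohort, n_runs = 50L,
                                   config = ibcga_config(),
                                   master_seed = 1L,
                                   presence_threshold = 0.7,
                                   med_ranking = TRUE, verbose = FALSE) {
  x <- filter_present(expression, presence_threshold)
  x <- impute_missing(x)
  al <- align_cohort(x, cohort)
  x <- al$expression
  y <- al$cohort$time_years
  run_seeds <- as.integer(master_seed) + seq_len(n_runs)

  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    runs[[i]] <- run_ibcga(x, y, cfg = config, seed = run_seeds[i])
    if (verbose) {
      message(sprintf("run %d/%d: %d features, CV R^2 = %.3f", i, n_runs,
                      length(runs[[i]]$selected_features), runs[[i]]$fitness))
    }
  }

  asc <- select_robust_signature(runs)
  winner <- runs[[asc$selected_run]]
  med <- NULL
  if (med_ranking && length(asc$signature) >= 2L) {
    med <- med_rank(x, y, asc$signature, params = winner$hyperparams,
                    cv = winner$folds, standardize = config$standardize)
  }
  model <- train_nusvr(x, y, features = asc$signature,
                       params = winner$hyperparams,
                       standardize = config$standardize)

  manifest <- list(
    package = "survsig",
    version = as.character(utils::packageVersion("survsig")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = as.integer(master_seed),
    run_seeds = run_seeds,
    n_runs = as.integer(n_runs),
    presence_threshold = presence_threshold,
    config = unclass(config),
    n_samples = length(y),
    n_features = nrow(x)
  )

  structure(list(runs = runs, asc = asc, med = med, model = model,
                 expression = x, survival_years = y, manifest = manifest),
            class = "sig_workflow")
}

#' @exportS3Method base::print
print.sig_workflow <- function(x, ...) {
  w <- x$runs[[x$asc$selected_run]]
  cat(sprintf(
    "<sig_workflow> %d runs; robust signature: %d features, CV R^2 = %.3f, MAE = %.3f yr\n",
    length(x$runs), length(x$asc$signature), w$fitness, w$mae))
  cat(sprintf("appearance score mean %.2f +/- %.2f, max %.2f\n",
              x$asc$mean_score, x$asc$sd_score, x$asc$max_score))
  invisible(x)
}

#' @export
glance.sig_workflow <- function(x, ...) {
  w <- x$runs[[x$asc$selected_run]]
  tibble(
    n_runs = length(x$runs),
    signature_size = length(x$asc$signature),
    cv_r_squared = w$fitness,
    cv_mae_years = w$mae,
    asc_mean = x$asc$mean_score,
    asc_sd = x$asc$sd_score,
    asc_max = x$asc$max_score
  )
}

#' @export
tidy.sig_workflow <- function(x, ...) {
  dplyr::bind_rows(lapply(x$runs, glance))
}

#' Write workflow outputs to a directory
#'
#' Emits the manifest and appearance report as JSON, per-run summaries
#' as TSV and full per-run results (seed, stages, selected features,
#' hyperparameters) as JSON, the frequency table, the robust signature
#' (one feature per line) and, when present, the MED ranking as TSV.
#'
#' @param x a `sig_workflow`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_workflow <- function(x, dir) {
  stopifnot(inherits(x, "sig_workflow"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(mean_score = x$asc$mean_score, sd_score = x$asc$sd_score,
         max_score = x$asc$max_score, selected_run = x$asc$selected_run,
         signature = x$asc$signature),
    file.path(dir, "asc_report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(tidy(x), file.path(dir, "runs.tsv"))
  jsonlite::write_json(
    lapply(x$runs, function(run) {
      list(seed = run$seed, fitness = run$fitness, mae = run$mae,
           r = run$r, hyperparams = run$hyperparams,
           selected_features = run$selected_features,
           stages = run$stages, n_evals = run$n_evals)
    }),
    file.path(dir, "runs.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(x$asc$frequencies, file.path(dir, "frequencies.tsv"))
  writeLines(x$asc$signature, file.path(dir, "signature.txt"))
  if (!is.null(x$med)) readr::write_tsv(x$med, file.path(dir, "med_rank.tsv"))
  invisible(dir)
}

#' Compare the GA signature against penalised baselines
#'
#' Builds a comparison table in the conventional layout: one row each for
#' ridge, lasso and elastic net on the full feature pool, then the
#' workflow's robust-signature model (ASC), its best single run, and the
#' across-run mean with standard deviations.
#'
#' @param workflow a `sig_workflow`.
#' @param n_rep repeated-CV draws for baseline lambda selection.
#' @param seed baseline CV seed.
#' @return A tibble: `method`, `r_squared`, `mae_years`, `n_features`,
#'   plus `r_squared_sd`, `mae_years_sd`, `n_features_sd` (non-`NA` only
#'   for the mean row).
#' @export
compare_methods <- function(workflow, n_rep = 100L, seed = 1L) {
  stopifnot(inherits(workflow, "sig_workflow"))
  x <- workflow$expression
  y <- workflow$survival_years
  baselines <- dplyr::bind_rows(lapply(
    c("ridge", "lasso", "elastic_net"),
    function(m) fit_baseline(x, y, method = m, n_rep = n_rep, seed = seed)))

  per_run <- tidy(workflow)
  asc_run <- workflow$runs[[workflow$asc$selected_run]]
  best_run <- per_run[order(-per_run$cv_r_squared), ][1L, ]

  tibble(
    method = c(baselines$method, "svr_asc", "svr_best", "svr_mean"),
    r_squared = c(baselines$r_squared, asc_run$fitness,
                  best_run$cv_r_squared, mean(per_run$cv_r_squared)),
    mae_years = c(baselines$mae_years, asc_run$mae, best_run$cv_mae_years,
                  mean(per_run$cv_mae_years)),
    n_features = c(as.numeric(baselines$n_nonzero),
                   length(asc_run$selected_features),
                   best_run$n_features, mean(per_run$n_features)),
    r_squared_sd = c(rep(NA_real_, 5L), sd(per_run$cv_r_squared)),
    mae_years_sd = c(rep(NA_real_, 5L), sd(per_run$cv_mae_years)),
    n_features_sd = c(rep(NA_real_, 5L), sd(per_run$n_features))
  )
}

#' Per-feature diagnostic table
#'
#' For each requested feature, the rank-based AUC separating the two
#' label classes and the two-sided differential-expression p-value.
#'
#' @param expression an [expr_matrix()].
#' @param labels tibble (`sample_id`, `label`) as from [read_labels()].
#' @param features feature ids (default: all).
#' @param positive positive class (default: second factor level).
#' @return A tibble `feature_id`, `auc`, `p_value`, sorted by descending
#'   AUC.
#' @export
diagnose_features <- function(expression, labels, features = NULL,
                              positive = NULL) {
  al <- align_cohort(expression, labels)
  x <- unclass(al$expression)
  lab <- as.factor(al$cohort$label)
  if (is.null(positive)) positive <- levels(lab)[2L]
  if (is.null(features)) features <- rownames(x)
  missing <- setdiff(features, rownames(x))
  if (length(missing)) {
    abort(paste0("unknown feature id(s): ", paste(missing, collapse = ", ")))
  }
  pos <- lab == positive
  out <- purrr::map_dfr(features, function(f) {
    v <- x[f, ]
    tibble(feature_id = f,
           auc = roc_auc(v, lab, positive = positive)$auc,
           p_value = diff_expression_test(v[pos], v[!pos]))
  })
  dplyr::arrange(out, dplyr::desc(.data$auc))
}

#' Per-feature prognostic table
#'
#' Splits samples at a per-feature expression quantile (default: the
#' median) into high and low groups and tests their survival curves with
#' the log-rank test.
#'
#' @param expression an [expr_matrix()].
#' @param cohort survival tibble (`sample_id`, `time_years`,
#'   `is_followup`); follow-up rows count as censored.
#' @param features feature ids (default: all).
#' @param split_quantile group-split quantile in (0, 1).
#' @return A tibble `feature_id`, `statistic`, `p_value`, `n_high`,
#'   `n_low`, sorted by ascending p-value.
#' @export
prognose_features <- function(expression, cohort, features = NULL,
                              split_quantile = 0.5) {
  al <- align_cohort(expression, cohort)
  x <- unclass(al$expression)
  times <- al$cohort$time_years
  events <- if ("is_followup" %in% names(al$cohort)) {
    as.integer(!al$cohort$is_followup)
  } else rep(1L, length(times))
  if (is.null(features)) features <- rownames(x)
  out <- purrr::map_dfr(features, function(f) {
    v <- x[f, ]
    cut <- quantile(v, split_quantile, na.rm = TRUE)
    high <- v > cut
    if (!any(high) || all(high)) {
      return(tibble(feature_id = f, statistic = 0, p_value = 1,
                    n_high = sum(high), n_low = sum(!high)))
    }
    lr <- logrank_test(times[high], times[!high],
                       events[high], events[!high])
    tibble(feature_id = f, statistic = lr$statistic, p_value = lr$p_value,
           n_high = sum(high), n_low = sum(!high))
  })
  dplyr::arrange(out, .data$p_value)
}

#' Validate a model on a right-censored follow-up cohort
#'
#' Predicts survival times for follow-up patients and reports the
#' coverage accuracy — the fraction whose prediction is at least the
#' observed follow-up time — with per-patient verdicts.
#'
#' @param model a fitted `nusvr_model` (or any object with a `predict`
#'   method over the expression features).
#' @param expression an [expr_matrix()] holding the follow-up patients.
#' @param followup tibble (`sample_id`, `time_years`) of follow-up times.
#' @return A list: `accuracy` (fraction), `mean_predicted_years`,
#'   `verdicts` tibble (`sample_id`, `followup_years`, `predicted_years`,
#'   `covered`).
#' @export
validate_followup <- function(model, expression, followup) {
  al <- align_cohort(expression, followup)
  pred <- as.numeric(predict(model, al$expression))
  pred <- pmax(pred, .Machine$double.eps)
  fup <- al$cohort$time_years
  tibble_out <- tibble(
    sample_id = al$cohort$sample_id,
    followup_years = fup,
    predicted_years = pred,
    covered = pred >= fup
  )
  list(accuracy = mean(tibble_out$covered),
       mean_predicted_years = mean(pred),
       verdicts = tibble_out)
}
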