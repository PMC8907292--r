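#' Appearance frequencies across independent runs
#'
#' For a collection of per-run signatures (feature-id sets), counts for
#' each feature the number of run signatures containing it.
#'
#' @param signatures list of character vectors (one per run), or a list of
#'   `ibcga_run` objects.
#' @return A tibble with columns `feature_id`, `frequency`, sorted by
#'   decreasing frequency then feature id.
#' @examples
#' appearance_frequencies(list(c("A", "B"), c("A", "C"), c("A", "B")))
#' @export
appearance_frequencies <- function(signatures) {
  sigs <- as_signature_list(signatures)
  tab <- table(unlist(lapply(sigs, unique)))
  tibble(feature_id = names(tab), frequency = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$feature_id)
}

as_signature_list <- function(signatures) {
  if (length(signatures) == 0L) abort("need at least one run signature.")
  sigs <- lapply(signatures, function(s) {
    if (inherits(s, "ibcga_run")) s$selected_features else as.character(s)
  })
  if (any(vapply(sigs, length, integer(1)) == 0L)) {
    abort("every run signature must be non-empty.")
  }
  sigs
}

#' Appearance score of one signature
#'
#' The mean appearance frequency over the signature's features:
#' `F_i = sum_t f(miR_it) / m_i`. A signature made of features that recur
#' across many runs scores close to the number of runs.
#'
#' @param signature character vector of feature ids.
#' @param freqs frequency table from [appearance_frequencies()].
#' @return A single number in `[1, Ns]`.
#' @export
appearance_score <- function(signature, freqs) {
  if (length(signature) == 0L) abort("empty signature.")
  idx <- match(signature, freqs$feature_id)
  if (anyNA(idx)) {
    abort(paste0("no frequency for feature(s): ",
                 paste(signature[is.na(idx)], collapse = ", ")))
  }
  mean(freqs$frequency[idx])
}

#' Select the robust signature by appearance score
#'
#' Scores every run's signature with [appearance_score()] and returns the
#' run maximizing it; ties are broken by fewer features, then lower run
#' index. The report carries the per-run scores, their mean, sample
#' standard deviation and maximum, and the winning signature.
#'
#' @param signatures list of character vectors or `ibcga_run` objects.
#' @return An `asc_report` with fields `scores` (tibble: `run`, `score`,
#'   `n_features`), `frequencies`, `selected_run`, `signature`,
#'   `mean_score`, `sd_score`, `max_score`.
#' @export
select_robust_signature <- function(signatures) {
  sigs <- as_signature_list(signatures)
  freqs <- appearance_frequencies(sigs)
  scores <- vapply(sigs, appearance_score, numeric(1), freqs = freqs)
  sizes <- vapply(sigs, length, integer(1))
  ord <- order(-scores, sizes, seq_along(sigs))
  sel <- ord[1L]
  structure(list(
    scores = tibble(run = seq_along(sigs), score = scores, n_features = sizes),
    frequencies = freqs,
    selected_run = sel,
    signature = sigs[[sel]],
    mean_score = mean(scores),
    sd_score = if (length(scores) > 1L) sd(scores) else NA_real_,
    max_score = max(scores)
  ), class = "asc_report")
}

#' @exportS3Method base::print
print.asc_report <- function(x, ...) {
  cat(sprintf(
    "<asc_report> %d runs; appearance score mean %.2f +/- %.2f, max %.2f\n",
    nrow(x$scores), x$mean_score, x$sd_score, x$max_score))
  cat(sprintf("robust signature: run %d with %d features\n",
              x$selected_run, length(x$signature)))
  invisible(x)
}

#' @export
tidy.asc_report <- function(x, ...) x$scores

#' @export
glance.asc_report <- function(x, ...) {
  tibble(n_runs = nrow(x$scores), mean_score = x$mean_score,
         sd_score = x$sd_score, max_score = x$max_score,
         selected_run = x$selected_run,
         signature_size = length(x$signature))
}

#' Rank signature features by main effect difference
#'
#' Measures each signature feature's marginal contribution to the fitted
#' model with a two-level orthogonal-array experiment: level 1 includes
#' the feature, level 2 excludes it. Each OA row induces a feature subset
#' whose pooled 10-fold CV squared correlation is evaluated with the
#' signature's own hyperparameters and fold partition (rows inducing the
#' empty subset are skipped). The MED of feature `j` is the absolute
#' difference between the mean fitness of rows including `j` and rows
#' excluding it; features are ranked by descending MED, exact ties broken
#' lexicographically by feature id.
#'
#' @param x an [expr_matrix()] aligned with `y`.
#' @param y survival times in years.
#' @param signature character vector of signature feature ids (m >= 2).
#' @param params decoded hyperparameters of the signature's model.
#' @param cv a [cv_config()] or precomputed fold ids (ideally the run's
#'   own partition).
#' @param standardize standardize features inside CV training folds.
#' @return A `med_table` tibble with columns `rank`, `feature_id`, `med`.
#' @export
med_rank <- function(x, y, signature, params = decode_hyperparams(7, 8, 7),
                     cv = cv_config(), standardize = TRUE) {
  m <- length(signature)
  if (m < 2L) abort("MED ranking needs at least two signature features.")
  if (m > 127L) abort("signature too wide for the supported orthogonal arrays (max 127); use a larger design.")
  xs <- as_sample_matrix(x, signature)
  folds <- if (is.numeric(cv)) as.integer(cv) else make_folds(nrow(xs), cv)
  oa <- orthogonal_array(m)
  fits <- rep(NA_real_, nrow(oa))
  for (i in seq_len(nrow(oa))) {
    inc <- oa[i, ] == 1L
    if (!any(inc)) next
    res <- suppressWarnings(
      cv_nusvr(xs[, inc, drop = FALSE], y, params = params, cv = folds,
               standardize = standardize))
    # same sign-guarded fitness as the GA: anti-predictive subsets score 0
    fits[i] <- max(res$r, 0)^2
  }
  med <- vapply(seq_len(m), function(j) {
    f1 <- fits[oa[, j] == 1L]
    f2 <- fits[oa[, j] == 2L]
    abs(mean(f1, na.rm = TRUE) - mean(f2, na.rm = TRUE))
  }, numeric(1))
  ord <- order(-med, signature)
  out <- tibble(rank = seq_len(m), feature_id = signature[ord],
                med = med[ord])
  class(out) <- c("med_table", class(out))
  out
}
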