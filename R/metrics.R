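#' Squared correlation coefficient between actual and predicted times
#'
#' The square of the Pearson correlation between the actual survival times
#' `y` and the predictions `z` — the package's fitness and headline
#' regression metric. It is symmetric in its arguments and invariant to
#' affine transformations with nonzero slope of either argument. When
#' either vector is constant the correlation is undefined; the value is
#' then defined as 0 (with a warning) so that optimisation over model
#' candidates remains total.
#'
#' @param y,z numeric vectors of equal length (>= 3 for a meaningful value).
#' @return A number in `[0, 1]`.
#' @examples
#' r_squared(c(1, 2, 3), c(2, 4, 6)) # 1
#' @export
r_squared <- function(y, z) {
  if (length(y) != length(z)) abort("`y` and `z` must have equal length.")
  if (length(y) < 2L) abort("need at least two observations.")
  if (sd(y) == 0 || sd(z) == 0) {
    warn("constant input: squared correlation defined as 0.")
    return(0)
  }
  unname(cor(y, z)^2)
}

#' Mean absolute error
#'
#' `mean(|z - y|)`, reported in years throughout the package.
#'
#' @param y,z numeric vectors of equal length.
#' @return A non-negative number.
#' @export
mean_abs_error <- function(y, z) {
  if (length(y) != length(z)) abort("`y` and `z` must have equal length.")
  if (length(y) < 1L) abort("need at least one observation.")
  mean(abs(z - y))
}

#' Cross-validation configuration
#'
#' Folds are a uniform random partition by seeded shuffle, without
#' stratification. Within an IBCGA run the partition is drawn once and
#' reused for every fitness evaluation so that fitness values are
#' comparable across individuals.
#'
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 10L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_config")
}

#' Assign samples to cross-validation folds
#'
#' @param n number of samples.
#' @param cv a [cv_config()].
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(n, cv = cv_config()) {
  if (cv$n_folds > n) abort("more folds than samples.")
  sizes <- rep(n %/% cv$n_folds, cv$n_folds)
  extra <- n %% cv$n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 2L)) abort("a fold would contain fewer than 2 samples.")
  perm <- withr::with_seed(cv$seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(cv$n_folds), times = sizes)
  folds
}
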