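#' Build a two-level orthogonal array
#'
#' Constructs the standard Taguchi-style two-level orthogonal array
#' `L_N(2^(N-1))` with `N = 2^ceiling(log2(n_factors + 1))` rows,
#' truncated to the first `n_factors` columns. Column `k` of the full
#' array is generated from a bit mask: the level of row `i` (0-based) is
#' `1 + parity(popcount(i AND mask_k))`, with masks ordered so the basic
#' columns and their interactions appear in the textbook order (a, b, ab,
#' c, ac, bc, abc, ...). Every column is balanced and every pair of
#' columns contains each of the four level combinations equally often;
#' `n_factors = 3` reproduces the textbook `L4(2^3)` table.
#'
#' @param n_factors number of factors (columns), `1..127`.
#' @return An integer matrix of levels 1/2, `N` rows x `n_factors` columns.
#' @examples
#' orthogonal_array(3)
#' @export
orthogonal_array <- function(n_factors) {
  if (!is.numeric(n_factors) || n_factors < 1 || n_factors != floor(n_factors)) {
    abort("`n_factors` must be a positive integer.")
  }
  if (n_factors > 127) abort("at most 127 factors supported (L128).")
  n_rows <- 2^ceiling(log2(n_factors + 1))
  m <- as.integer(log2(n_rows))
  masks <- integer(0)
  for (b in seq(m - 1, 0)) {
    basic <- bitwShiftL(1L, b)
    masks <- c(masks, basic, vapply(masks, bitwXor, integer(1), basic))
  }
  rows <- 0:(n_rows - 1L)
  oa <- vapply(masks[seq_len(n_factors)], function(k) {
    1L + vapply(bitwAnd(rows, k), function(v) sum(bitwAnd(v, 2^(0:7)) > 0L) %% 2L,
                integer(1))
  }, integer(n_rows))
  matrix(as.integer(oa), nrow = n_rows, ncol = n_factors)
}

#' Check orthogonal-array invariants
#'
#' Verifies two-level balance per column and, for every pair of columns,
#' equal counts of the four level combinations.
#'
#' @param oa a matrix of levels 1/2.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
check_orthogonal_array <- function(oa) {
  if (!all(oa %in% c(1L, 2L))) abort("orthogonal array levels must be 1/2.")
  n <- nrow(oa)
  for (j in seq_len(ncol(oa))) {
    if (sum(oa[, j] == 1L) != n / 2) {
      abort(sprintf("column %d is not balanced.", j))
    }
  }
  if (ncol(oa) >= 2L) {
    for (j in seq_len(ncol(oa) - 1L)) {
      for (k in (j + 1L):ncol(oa)) {
        combo <- table(factor(oa[, j], 1:2), factor(oa[, k], 1:2))
        if (length(unique(as.vector(combo))) != 1L) {
          abort(sprintf("columns %d and %d are not pairwise balanced.", j, k))
        }
      }
    }
  }
  invisible(TRUE)
}
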