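#' Decode 4-bit hyperparameter genes
#'
#' The GA chromosome carries three 4-bit genes encoding the nu-SVR
#' hyperparameters on powers-of-two grids:
#' `C = 2^(c_gene - 7)` (so `C` spans `2^-7 .. 2^8`),
#' `gamma = 2^(g_gene - 8)` (`2^-8 .. 2^7`), and
#' `nu = (n_gene + 1) / 16` (`1/16 .. 1`). The mapping is injective over
#' the 16^3 grid.
#'
#' @param c_gene,g_gene,n_gene integers in `0..15`.
#' @return A list with elements `cost`, `gamma`, `nu`.
#' @examples
#' decode_hyperparams(7, 8, 15) # C = 1, gamma = 1, nu = 1
#' @export
decode_hyperparams <- function(c_gene, g_gene, n_gene) {
  genes <- c(c_gene, g_gene, n_gene)
  if (any(genes != floor(genes)) || any(genes < 0) || any(genes > 15)) {
    abort("hyperparameter genes must be integers in 0..15.")
  }
  list(cost = 2^(c_gene - 7), gamma = 2^(g_gene - 8), nu = (n_gene + 1) / 16)
}

# Resolved lazily (at first use, inside the installed package) so the
# symbol lookup happens against the loaded e1071 namespace.
svm_symbols <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      requireNamespace("e1071", quietly = TRUE)
      cache <<- getNativeSymbolInfo("svmtrain", PACKAGE = "e1071")
    }
    cache
  }
})

# Minimal nu-regression training call into libsvm (e1071's registered C
# routine), returning just what RBF prediction needs: support vectors,
# dual coefficients and the bias. Argument order mirrors
# e1071:::svm.default; type 4 = nu-regression, kernel 2 = radial.
nusvr_fit_raw <- function(x, y, cost, gamma, nu, tolerance = 0.001) {
  nr <- nrow(x)
  cret <- .C(svm_symbols(),
    as.double(t(x)), as.integer(nr), as.integer(ncol(x)),
    as.double(y), 0L, 0L,
    4L, 2L, 3L,
    as.double(gamma), as.double(0), as.double(cost), as.double(nu),
    0L, as.double(0), 0L,
    as.double(4), as.double(tolerance), as.double(0.1), 1L,
    0L, 0L, 0L,
    nclasses = integer(1), nr = integer(1), index = integer(nr),
    labels = integer(1), nSV = integer(1), rho = double(1),
    coefs = double(nr), sigma = double(1), probA = double(1),
    probB = double(1), cresults = double(0), ctotal1 = double(1),
    ctotal2 = double(1), error = paste(rep(" ", 255), collapse = ""))
  nsv <- cret$nr
  # nsv == 0 is legal: a constant (or tube-covered) target needs no
  # support vectors and the model predicts the bias -rho everywhere
  idx <- cret$index[seq_len(nsv)]
  list(sv = x[idx, , drop = FALSE], coefs = cret$coefs[seq_len(nsv)],
       rho = cret$rho[1], gamma = gamma)
}

nusvr_predict_raw <- function(fit, newx) {
  if (nrow(fit$sv) == 0L) return(rep(-fit$rho, nrow(newx)))
  d2 <- outer(rowSums(fit$sv^2), rowSums(newx^2), "+") -
    2 * tcrossprod(fit$sv, newx)
  d2[d2 < 0] <- 0
  drop(crossprod(exp(-fit$gamma * d2), fit$coefs)) - fit$rho
}

#' Fit a nu-support-vector regression on a feature subset
#'
#' Trains an RBF-kernel nu-SVR (libsvm, via e1071) of survival time on the
#' selected features. Samples are columns of the expression matrix. With
#' `standardize = TRUE` (default) each feature is centred and scaled on
#' the training data and the same affine map is applied at prediction;
#' RBF kernels are not scale-invariant, so this is the sensible default
#' for abundance data. Refitting with identical inputs gives identical
#' predictions.
#'
#' @param x an [expr_matrix()] (features x samples) or numeric matrix
#'   samples x features.
#' @param y survival times in years, one per sample.
#' @param features feature ids (or indices) to use; all rows by default.
#' @param params hyperparameters from [decode_hyperparams()].
#' @param standardize centre/scale features on the training data.
#' @return A `nusvr_model` object with a [predict()] method.
#' @export
train_nusvr <- function(x, y, features = NULL,
                        params = decode_hyperparams(7, 8, 7),
                        standardize = TRUE) {
  xs <- as_sample_matrix(x, features)
  if (ncol(xs) == 0L) abort("no features selected.")
  if (nrow(xs) != length(y)) abort("sample count mismatch between x and y.")
  ctr <- rep(0, ncol(xs)); scl <- rep(1, ncol(xs))
  if (standardize) {
    ctr <- colMeans(xs)
    scl <- apply(xs, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    xs <- sweep(sweep(xs, 2L, ctr), 2L, scl, "/")
  }
  fit <- nusvr_fit_raw(xs, y, params$cost, params$gamma, params$nu)
  structure(list(fit = fit, params = params, center = ctr, scale = scl,
                 feature_ids = colnames(xs), n_train = nrow(xs)),
            class = "nusvr_model")
}

#' @export
predict.nusvr_model <- function(object, newdata, ...) {
  xs <- as_sample_matrix(newdata, object$feature_ids)
  xs <- sweep(sweep(xs, 2L, object$center), 2L, object$scale, "/")
  nusvr_predict_raw(object$fit, xs)
}

#' @exportS3Method base::print
print.nusvr_model <- function(x, ...) {
  cat(sprintf(
    "<nusvr_model> %d features, %d training samples, C=%g gamma=%g nu=%g\n",
    length(x$feature_ids), x$n_train,
    x$params$cost, x$params$gamma, x$params$nu))
  invisible(x)
}

# Accepts an expr_matrix (features x samples) or a samples x features
# matrix and returns samples x features restricted to `features`.
as_sample_matrix <- function(x, features = NULL) {
  if (inherits(x, "expr_matrix")) {
    m <- t(unclass(x))
  } else {
    m <- as.matrix(x)
  }
  if (!is.null(features)) {
    if (is.character(features)) {
      missing <- setdiff(features, colnames(m))
      if (length(missing)) {
        abort(paste0("unknown feature id(s): ", paste(missing, collapse = ", ")))
      }
    }
    m <- m[, features, drop = FALSE]
  }
  m
}

#' Cross-validated nu-SVR performance
#'
#' For each fold, trains on the complement and predicts the held-out
#' samples; all out-of-fold predictions are pooled and the squared
#' correlation and MAE are computed once on the pooled vectors (one
#' correlation over all samples, matching how a single R-squared is
#' reported against actual vs estimated survival times). Deterministic
#' given the fold partition.
#'
#' @inheritParams train_nusvr
#' @param cv a [cv_config()], or an integer vector of precomputed fold ids.
#' @param tolerance libsvm optimizer stopping tolerance; the GA uses a
#'   slightly relaxed value for fitness screening (predictions agree with
#'   the tight default to ~1e-5 in correlation).
#' @return A list with `r2`, the signed pooled correlation `r`, `mae`,
#'   and a tibble `predictions` (`sample`, `fold`, `actual`, `predicted`).
#' @export
cv_nusvr <- function(x, y, features = NULL,
                     params = decode_hyperparams(7, 8, 7),
                     cv = cv_config(), standardize = TRUE,
                     tolerance = 0.001) {
  xs <- as_sample_matrix(x, features)
  if (ncol(xs) == 0L) abort("no features selected.")
  n <- nrow(xs)
  folds <- if (is.numeric(cv)) as.integer(cv) else make_folds(n, cv)
  if (length(folds) != n) abort("fold vector length must match sample count.")
  z <- numeric(n)
  for (k in unique(folds)) {
    hold <- folds == k
    xtr <- xs[!hold, , drop = FALSE]
    ctr <- rep(0, ncol(xtr)); scl <- rep(1, ncol(xtr))
    if (standardize) {
      ctr <- colMeans(xtr)
      scl <- apply(xtr, 2L, sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      xtr <- sweep(sweep(xtr, 2L, ctr), 2L, scl, "/")
    }
    fit <- nusvr_fit_raw(xtr, y[!hold], params$cost, params$gamma,
                         params$nu, tolerance = tolerance)
    xte <- sweep(sweep(xs[hold, , drop = FALSE], 2L, ctr), 2L, scl, "/")
    z[hold] <- nusvr_predict_raw(fit, xte)
  }
  r <- if (sd(z) == 0) 0 else unname(cor(y, z))
  list(
    r2 = r^2,
    r = r,
    mae = mean(abs(z - y)),
    predictions = tibble(sample = seq_len(n), fold = folds,
                         actual = y, predicted = z)
  )
}
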