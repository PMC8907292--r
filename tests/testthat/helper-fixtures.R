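# Small in-code fixtures shared across test files.

toy_expr <- function(values = NULL, nf = 3, ns = 2) {
  if (is.null(values)) {
    values <- matrix(seq_len(nf * ns), nf, ns)
  }
  expr_matrix(values,
              feature_ids = sprintf("miR-%02d", seq_len(nrow(values))),
              sample_ids = sprintf("S%02d", seq_len(ncol(values))))
}

# deterministic small survival data with a single informative feature
toy_signal_data <- function(n = 60, p = 10, seed = 42, noise_sd = 0.2) {
  withr::with_seed(seed, {
    x <- matrix(rlnorm(p * n, 3, 0.5), p, n,
                dimnames = list(sprintf("miR-%02d", 1:p),
                                sprintf("S%03d", 1:n)))
    y <- 2 + scale(x[1, ])[, 1] + rnorm(n, 0, noise_sd)
    y <- pmax(y, 0.05)
    list(x = expr_matrix(x), y = y)
  })
}
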