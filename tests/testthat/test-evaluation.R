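# Exhaustive pair-counting oracle for the rank AUC
auc_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(sp) * length(sn))
}

test_that("rank AUC matches hand cases and the exhaustive pair count", {
  expect_equal(roc_auc(c(3, 5, 1, 4), c(1, 1, 0, 0), positive = 1)$auc, 0.75)
  expect_equal(roc_auc(c(10, 9, 1, 2), c("t", "t", "n", "n"),
                       positive = "t")$auc, 1)
  withr::with_seed(15, {
    for (i in 1:100) {
      n <- sample(6:50, 1)
      pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      scores <- sample(rnorm(n - 3), n, replace = TRUE) # force some ties
      got <- roc_auc(scores, pos, positive = TRUE)$auc
      expect_equal(got, auc_oracle(scores, pos), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "two classes")
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    for (i in 1:10) {
      scores <- rnorm(60)
      labels <- sample(rep(c("n", "t"), 30))
      got <- roc_auc(scores, labels, positive = "t")$auc
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("n", "t"),
                                            direction = "<", quiet = TRUE)))
      expect_equal(got, ref, tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant to monotone score transforms and direction is reported as-is", {
  withr::with_seed(16, {
    scores <- rnorm(40)
    pos <- rep(c(TRUE, FALSE), 20)
    a1 <- roc_auc(scores, pos, positive = TRUE)$auc
    expect_equal(roc_auc(exp(scores), pos, positive = TRUE)$auc, a1)
    # flipping the sign of the scores mirrors the AUC
    expect_equal(roc_auc(-scores, pos, positive = TRUE)$auc, 1 - a1)
  })
})

test_that("permuted labels give a null-centred AUC", {
  withr::with_seed(17, {
    scores <- rnorm(400)
    labels <- sample(rep(c(0, 1), 200))
    auc <- roc_auc(scores, labels, positive = 1)$auc
    se <- sqrt((400 + 1) / (12 * 200 * 200)) # Mann-Whitney null s.e.
    expect_lt(abs(auc - 0.5), 3 * se)
  })
})

test_that("differential-expression test covers the documented edge cases", {
  expect_equal(diff_expression_test(rep(1, 5), rep(1, 6)), 1)
  a <- 1:10; b <- 21:30
  expect_lt(diff_expression_test(a, b), 0.001)
  expect_equal(diff_expression_test(a, b), diff_expression_test(b, a))
  withr::with_seed(18, {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(diff_expression_test(x, y), diff_expression_test(y, x))
    # matches the reference implementation
    expect_equal(diff_expression_test(x, y),
                 wilcox.test(x, y, exact = FALSE)$p.value)
  })
  expect_error(diff_expression_test(1, 1:3), "at least two")
})

test_that("ridge keeps all features while lasso recovers sparse truth", {
  sim <- withr::with_seed(31, {
    n <- 120; p <- 200
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    beta <- numeric(p); beta[1:5] <- 1
    y <- drop(x %*% beta) + rnorm(n, 0, 0.5) + 3
    list(x = x, y = y)
  })
  ridge <- fit_baseline(sim$x, sim$y, "ridge", n_rep = 5, seed = 2)
  expect_identical(ridge$n_nonzero, 200L)
  expect_gt(ridge$r_squared, 0.2)

  lasso <- fit_baseline(sim$x, sim$y, "lasso", n_rep = 5, seed = 2)
  expect_lt(lasso$n_nonzero, 40L)
  hits <- sum(paste0("f", 1:5) %in% attr(lasso, "nonzero_features"))
  expect_gte(hits, 4L)
  expect_gt(lasso$r_squared, 0.7)
})

test_that("elastic net with mixing weight 1 selects the lasso's feature set", {
  sim <- withr::with_seed(32, {
    n <- 80; p <- 60
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- x[, 1] - x[, 2] + rnorm(n, 0, 0.4) + 2
    list(x = x, y = y)
  })
  lasso <- fit_baseline(sim$x, sim$y, "lasso", n_rep = 3, seed = 4)
  enet1 <- fit_baseline(sim$x, sim$y, "elastic_net", alpha = 1,
                        n_rep = 3, seed = 4)
  expect_identical(attr(lasso, "nonzero_features"),
                   attr(enet1, "nonzero_features"))
  expect_equal(lasso$lambda, enet1$lambda)
})

test_that("baseline metrics are invariant to feature order", {
  sim <- withr::with_seed(33, {
    x <- matrix(rnorm(60 * 20), 60, 20, dimnames = list(NULL, paste0("f", 1:20)))
    y <- x[, 3] + rnorm(60, 0, 0.5) + 2
    list(x = x, y = y)
  })
  perm <- withr::with_seed(34, sample(20))
  a <- fit_baseline(sim$x, sim$y, "lasso", n_rep = 3, seed = 9)
  b <- fit_baseline(sim$x[, perm], sim$y, "lasso", n_rep = 3, seed = 9)
  # glmnet's coordinate descent is order-sensitive only at its own
  # convergence threshold
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-5)
  expect_equal(a$mae_years, b$mae_years, tolerance = 1e-5)
  expect_identical(a$n_nonzero, b$n_nonzero)
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(1, 2, 3))
  # zero censoring: KM equals the empirical survival function
  withr::with_seed(35, {
    t <- rexp(50) + 0.1
    km2 <- km_curve(t, rep(1, 50))
    emp <- vapply(km2$time, function(u) mean(t > u), numeric(1))
    expect_equal(km2$survival, emp)
  })
  # all censored: survival stays 1
  km3 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
  expect_error(km_curve(numeric(0), integer(0)), "empty")
})

test_that("log-rank test separates distinct hazards and is null on identical groups", {
  lr0 <- logrank_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_lt(lr0$statistic, 1e-10)
  expect_gt(lr0$p_value, 0.99)
  withr::with_seed(36, {
    a <- rexp(60, rate = 1)
    b <- rexp(60, rate = 4)
    lr <- logrank_test(a, b)
    expect_lt(lr$p_value, 1e-4)
    # cross-check with the survival package front door
    ref <- survival::survdiff(
      survival::Surv(c(a, b), rep(1, 120)) ~ rep(1:2, each = 60))
    expect_equal(lr$statistic, ref$chisq)
  })
})

test_that("coverage accuracy is the fraction of non-contradicted predictions", {
  expect_equal(coverage_accuracy(c(2, 2, 2), c(1, 1, 1)), 1)
  expect_equal(coverage_accuracy(c(0.5, 0.5), c(1, 1)), 0)
  expect_equal(coverage_accuracy(c(2, 0.4), c(0.5, 0.5)), 0.5)
  expect_error(coverage_accuracy(c(1, 2), c(1, 2, 3)), "length")
  expect_error(coverage_accuracy(c(-1, 2), c(1, 1)), "> 0")
})

test_that("the combined classifier separates well-separated classes and stays null-calibrated", {
  sim <- simulate_diagnostic_cohort(n_tumor = 50, n_normal = 50, p = 8,
                                    k_diff = 5, shift = 3, seed = 41)
  res <- combined_classifier_cv(sim$expression, sim$labels$label,
                                positive = "tumor", n_rep = 3, ntree = 100,
                                seed = 1)
  acc <- res$summary$mean[res$summary$metric == "accuracy"]
  expect_gte(acc, 0.95)
  # accuracy equals the pooled confusion-matrix identity per repetition
  expect_true(all(res$per_rep$accuracy >= 0 & res$per_rep$accuracy <= 1))

  perm <- withr::with_seed(42, sample(as.character(sim$labels$label)))
  null_res <- combined_classifier_cv(sim$expression, perm,
                                     positive = "tumor", n_rep = 3,
                                     ntree = 100, seed = 1)
  null_auc <- null_res$summary$mean[null_res$summary$metric == "auc"]
  expect_lt(abs(null_auc - 0.5), 0.12)
})
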