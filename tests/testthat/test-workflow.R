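small_workflow <- function() {
  sim <- simulate_survival_cohort(n = 50, p = 25, k = 3, noise_sd = 0.4,
                                  missing_rate = 0.05, seed = 61)
  wf <- run_signature_workflow(
    sim$expression, sim$cohort, n_runs = 2L,
    config = ibcga_smoke_config(r_start = 2L, r_end = 5L, generations = 4L),
    master_seed = 3L, presence_threshold = 0.5)
  list(sim = sim, wf = wf)
}

test_that("the end-to-end workflow produces runs, a robust signature and a MED table", {
  out <- small_workflow()
  wf <- out$wf
  expect_length(wf$runs, 2L)
  expect_s3_class(wf$asc, "asc_report")
  expect_gte(length(wf$asc$signature), 2L)
  expect_s3_class(wf$med, "med_table")
  expect_setequal(wf$med$feature_id, wf$asc$signature)
  expect_s3_class(wf$model, "nusvr_model")
  expect_identical(wf$manifest$run_seeds, c(4L, 5L))
  g <- glance(wf)
  expect_identical(g$n_runs, 2L)
  expect_identical(g$signature_size, length(wf$asc$signature))
})

test_that("replaying the manifest seeds reproduces each run bit-for-bit", {
  out <- small_workflow()
  wf <- out$wf
  x <- wf$expression
  y <- wf$survival_years
  cfg <- do.call(ibcga_config, wf$manifest$config)
  replay <- run_ibcga(x, y, cfg = cfg, seed = wf$manifest$run_seeds[2])
  expect_identical(replay$selected_features, wf$runs[[2]]$selected_features)
  expect_identical(replay$fitness, wf$runs[[2]]$fitness)
  expect_identical(replay$trace, wf$runs[[2]]$trace)
})

test_that("workflow outputs serialize to the documented files", {
  out <- small_workflow()
  dir <- withr::local_tempdir()
  write_workflow(out$wf, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "asc_report.json")))
  expect_true(file.exists(file.path(dir, "runs.tsv")))
  runs_json <- jsonlite::read_json(file.path(dir, "runs.json"))
  expect_length(runs_json, 2L)
  expect_identical(unlist(runs_json[[1]]$selected_features),
                   out$wf$runs[[1]]$selected_features)
  expect_true(file.exists(file.path(dir, "frequencies.tsv")))
  expect_true(file.exists(file.path(dir, "signature.txt")))
  expect_true(file.exists(file.path(dir, "med_rank.tsv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$master_seed, 3L)
  sig <- readLines(file.path(dir, "signature.txt"))
  expect_identical(sig, out$wf$asc$signature)
})

test_that("the comparison table has the six method rows in Table-1 shape", {
  out <- small_workflow()
  tab <- compare_methods(out$wf, n_rep = 2, seed = 1)
  expect_identical(tab$method, c("ridge", "lasso", "elastic_net",
                                 "svr_asc", "svr_best", "svr_mean"))
  # ridge keeps every candidate feature
  expect_equal(tab$n_features[tab$method == "ridge"],
               nrow(out$wf$expression))
  # only the mean row carries dispersion
  expect_true(all(is.na(tab$r_squared_sd[1:5])))
  expect_false(is.na(tab$r_squared_sd[6]))
  # the best run is at least as fit as the across-run mean
  expect_gte(tab$r_squared[tab$method == "svr_best"],
             tab$r_squared[tab$method == "svr_mean"])
})

test_that("diagnostic tables rank planted differential features on top", {
  sim <- simulate_diagnostic_cohort(n_tumor = 60, n_normal = 40, p = 30,
                                    k_diff = 5, shift = 2.5, seed = 71)
  tab <- diagnose_features(sim$expression, sim$labels, positive = "tumor")
  expect_setequal(tab$feature_id[1:5], sim$truth$diff_features)
  expect_true(all(tab$p_value[1:5] < 0.05))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
})

test_that("prognostic log-rank table is calibrated on association-free data", {
  sim <- withr::with_seed(81, {
    p <- 120; n <- 100
    x <- matrix(rlnorm(p * n, 3, 0.6), p, n,
                dimnames = list(sprintf("miR-%03d", 1:p),
                                sprintf("S%03d", 1:n)))
    cohort <- tibble::tibble(sample_id = colnames(x),
                             time_years = rexp(n, 0.4) + 0.05,
                             is_followup = FALSE)
    list(x = expr_matrix(x), cohort = cohort)
  })
  tab <- prognose_features(sim$x, sim$cohort)
  expect_identical(nrow(tab), 120L)
  fpr <- mean(tab$p_value < 0.05)
  expect_lt(fpr, 0.12)
  expect_true(all(tab$n_high + tab$n_low == 100L))
})

test_that("follow-up validation reports per-patient verdicts and monotone accuracy", {
  sim <- simulate_survival_cohort(n = 40, p = 10, k = 2, missing_rate = 0,
                                  seed = 91)
  model <- train_nusvr(sim$expression, sim$cohort$time_years,
                       features = sim$truth$true_features,
                       params = list(cost = 8, gamma = 0.25, nu = 0.5))
  fup_sim <- simulate_survival_cohort(n = 30, p = 10, k = 2, missing_rate = 0,
                                      seed = 92)
  followup <- tibble::tibble(
    sample_id = fup_sim$cohort$sample_id,
    time_years = pmin(fup_sim$cohort$time_years, 0.9),
    is_followup = TRUE)
  val <- validate_followup(model, fup_sim$expression, followup)
  expect_identical(nrow(val$verdicts), 30L)
  expect_equal(val$accuracy, mean(val$verdicts$covered))

  # shrinking the predictions can only lower coverage
  shrunk <- val$verdicts$predicted_years * 0.3
  acc_shrunk <- coverage_accuracy(pmax(shrunk, 1e-9),
                                  val$verdicts$followup_years)
  expect_lte(acc_shrunk, val$accuracy)
})
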