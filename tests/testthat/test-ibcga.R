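# An additive fitness over the chromosome genome: position weights for
# mask bits plus a separable gene contribution. Main-effect composition
# is provably optimal for such landscapes.
additive_fitness <- function(weights, gene_weights = c(0, 0, 0)) {
  function(chrom) {
    sum(weights[chrom$mask]) + sum(gene_weights * chrom$genes)
  }
}

test_that("initial populations have exact popcounts and are seed-reproducible", {
  cfg <- ibcga_config(pop_size = 10, r_start = 3, r_end = 5)
  pop1 <- withr::with_seed(1, init_population(cfg, 12))
  pop2 <- withr::with_seed(1, init_population(cfg, 12))
  pop3 <- withr::with_seed(2, init_population(cfg, 12))
  expect_true(all(vapply(pop1, function(c) sum(c$mask), integer(1)) == 3L))
  expect_true(all(vapply(pop1, function(c) all(c$genes %in% 0:15), logical(1))))
  expect_identical(pop1, pop2)
  expect_false(identical(pop1, pop3))
  expect_error(init_population(ibcga_config(r_start = 20, r_end = 20), 12),
               "exceeds")
})

test_that("tournament selection favours the dominant individual about 3/4 of the time", {
  pop <- withr::with_seed(3, init_population(ibcga_config(pop_size = 4,
                                                          r_start = 2,
                                                          r_end = 2), 8))
  fits <- c(10, 1, 1, 1)
  share <- withr::with_seed(13, {
    wins <- 0
    for (i in 1:1000) {
      pool <- tournament_select(pop, fits)
      wins <- wins + sum(vapply(pool, identical, logical(1), pop[[1]]))
    }
    wins / (1000 * length(pop))
  })
  # dominant individual wins any tournament it enters:
  # P = 1 - (3/4)^2 = 7/16 per slot... with replacement pair draws the
  # expected share is P(draw includes #1) = 1 - (3/4)^2 = 0.4375
  expect_gt(share, 0.40)
  expect_lt(share, 0.48)
})

test_that("ties in a tournament keep the first-drawn individual and degenerate cases work", {
  pop <- withr::with_seed(4, init_population(ibcga_config(pop_size = 4,
                                                          r_start = 2,
                                                          r_end = 2), 6))
  pool <- withr::with_seed(5, tournament_select(pop, rep(1, 4)))
  expect_length(pool, 4L)
  solo <- tournament_select(pop[1], fitnesses = 5)
  expect_identical(solo[[1]], pop[[1]])
  expect_error(tournament_select(list(), numeric(0)), "empty")
})

test_that("crossover on additive landscapes composes the exhaustive optimum", {
  withr::with_seed(21, {
    for (trial in 1:100) {
      p <- 10
      weights <- rnorm(p)
      fit_fn <- additive_fitness(weights)
      base <- sample(c(TRUE, FALSE), p, replace = TRUE)
      d <- sample(1:3, 1)
      flip <- sample.int(p, d)
      mask_b <- base
      mask_b[flip] <- !mask_b[flip]
      genes <- sample(0:15, 3, replace = TRUE)
      pa <- survsig:::new_chromosome(base, genes)
      pb <- survsig:::new_chromosome(mask_b, genes)

      kids <- oa_crossover(pa, pb, fit_fn, max_factors = 3)
      best_kid <- max(vapply(kids, fit_fn, numeric(1)))

      # brute force over all 2^d recombinations of the differing positions
      combos <- expand.grid(rep(list(c(FALSE, TRUE)), d))
      brute <- max(apply(combos, 1, function(takeb) {
        m <- base
        m[flip[as.logical(takeb)]] <- mask_b[flip[as.logical(takeb)]]
        fit_fn(survsig:::new_chromosome(m, genes))
      }))
      expect_equal(best_kid, brute, tolerance = 1e-12)
    }
  })
})

test_that("crossover with identical parents returns them unchanged", {
  pa <- survsig:::new_chromosome(c(TRUE, FALSE, TRUE, FALSE), c(1, 2, 3))
  kids <- oa_crossover(pa, pa, function(chrom) 1, max_factors = 3)
  expect_identical(kids[[1]], pa)
  expect_identical(kids[[2]], pa)
})

test_that("crossover repair keeps the stage popcount when requested", {
  withr::with_seed(31, {
    p <- 12; r <- 4
    pa <- survsig:::new_chromosome(
      replace(logical(p), sample.int(p, r), TRUE), c(0, 8, 7))
    pb <- survsig:::new_chromosome(
      replace(logical(p), sample.int(p, r), TRUE), c(15, 3, 2))
    kids <- oa_crossover(pa, pb, function(chrom) sum(which(chrom$mask)),
                         max_factors = 3, repair_r = r)
    for (k in kids) expect_identical(sum(k$mask), as.integer(r))
  })
})

test_that("mutation preserves popcount and hits param genes at the binomial rate", {
  chrom <- survsig:::new_chromosome(c(TRUE, TRUE, FALSE, FALSE), c(5, 5, 5))
  expect_identical(mutate_chrom(chrom, pm = 0), chrom)
  withr::with_seed(41, {
    for (i in 1:50) {
      m <- mutate_chrom(chrom, pm = 1)
      expect_identical(sum(m$mask), 2L)
    }
    # param-gene change frequency: pm * 15/16 per gene
    changes <- 0
    n_trials <- 4000
    for (i in seq_len(n_trials)) {
      m <- mutate_chrom(chrom, pm = 0.5)
      changes <- changes + sum(m$genes != chrom$genes)
    }
    rate <- changes / (3 * n_trials)
    expect_gt(rate, 0.44); expect_lt(rate, 0.50) # 0.5 * 15/16 = 0.469
  })
})

test_that("inheritance increments every mask by exactly one bit", {
  cfg <- ibcga_config(pop_size = 20, r_start = 5, r_end = 9)
  pop <- withr::with_seed(51, init_population(cfg, 30))
  pop2 <- withr::with_seed(52, inherit_increment(pop))
  expect_true(all(vapply(pop2, function(c) sum(c$mask), integer(1)) == 6L))
  expect_identical(lapply(pop2, `[[`, "genes"), lapply(pop, `[[`, "genes"))
  # repeated inheritance walks r up deterministically
  pop_r9 <- withr::with_seed(53, {
    pp <- pop
    for (i in 1:4) pp <- inherit_increment(pp)
    pp
  })
  expect_true(all(vapply(pop_r9, function(c) sum(c$mask), integer(1)) == 9L))
  # flipped positions differ across individuals
  flipped <- vapply(seq_along(pop), function(i) {
    which(pop2[[i]]$mask & !pop[[i]]$mask)
  }, integer(1))
  expect_gt(length(unique(flipped)), 3L)
  full <- survsig:::new_chromosome(rep(TRUE, 4), c(0, 0, 0))
  expect_error(inherit_increment(list(full)), "full mask")
})

test_that("a small run recovers a planted single-feature signal and is reproducible", {
  d <- toy_signal_data(n = 60, p = 20, seed = 19, noise_sd = 0.15)
  cfg <- ibcga_smoke_config(r_start = 1L, r_end = 5L, generations = 6L)
  run1 <- run_ibcga(d$x, d$y, cfg = cfg, seed = 77)
  run2 <- run_ibcga(d$x, d$y, cfg = cfg, seed = 77)
  expect_identical(run1$selected_features, run2$selected_features)
  expect_identical(run1$fitness, run2$fitness)
  expect_identical(run1$trace, run2$trace)
  expect_true("miR-01" %in% run1$selected_features)
  expect_gt(run1$fitness, 0.5)
  # feature count within the sweep bounds
  expect_gte(length(run1$selected_features), 1L)
  expect_lte(length(run1$selected_features), 5L)
})

test_that("the stage-best fitness trace is non-decreasing under elitism", {
  d <- toy_signal_data(n = 50, p = 12, seed = 23, noise_sd = 0.3)
  run <- run_ibcga(d$x, d$y, cfg = ibcga_smoke_config(r_start = 2L, r_end = 5L),
                   seed = 5)
  for (rr in unique(run$trace$r)) {
    tr <- run$trace$best_fitness[run$trace$r == rr]
    expect_true(all(diff(tr) >= 0))
  }
  # overall best equals the max over stage bests
  expect_equal(run$fitness, max(run$stages$fitness))
})
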