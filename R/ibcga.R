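#' IBCGA configuration
#'
#' Settings for the inheritable bi-objective combinatorial genetic
#' algorithm. The chromosome couples a binary feature mask (exactly `r`
#' bits set at stage `r`) with three 4-bit genes encoding the nu-SVR
#' hyperparameters; the algorithm sweeps `r` from `r_start` to `r_end`,
#' inheriting each stage's population into the next by switching one
#' random 0-bit on per individual.
#'
#' @param pop_size population size (even, >= 4).
#' @param r_start,r_end feature-count sweep bounds.
#' @param generations generations per stage.
#' @param pc probability a mating pair undergoes orthogonal-array crossover.
#' @param pm mutation probability (mask swap per individual; per param gene).
#' @param max_oa_factors maximum factors per crossover design (7 gives L8).
#' @param elitism keep the stage-best individual alive each generation.
#' @param early_stop stop a stage after this many generations without
#'   improvement (`Inf` = always run all generations).
#' @param n_folds cross-validation folds for the fitness function.
#' @param standardize standardize features inside each CV training fold.
#' @param tolerance libsvm stopping tolerance used for fitness
#'   evaluations within the run.
#' @return An `ibcga_config` list.
#' @export
ibcga_config <- function(pop_size = 50L, r_start = 10L, r_end = 50L,
                         generations = 30L, pc = 0.8, pm = 0.05,
                         max_oa_factors = 7L, elitism = TRUE,
                         early_stop = Inf, n_folds = 10L,
                         standardize = TRUE, tolerance = 0.01) {
  cfg <- list(pop_size = as.integer(pop_size), r_start = as.integer(r_start),
              r_end = as.integer(r_end), generations = as.integer(generations),
              pc = pc, pm = pm, max_oa_factors = as.integer(max_oa_factors),
              elitism = isTRUE(elitism), early_stop = early_stop,
              n_folds = as.integer(n_folds), standardize = isTRUE(standardize),
              tolerance = tolerance)
  if (cfg$pop_size < 4L || cfg$pop_size %% 2L != 0L) {
    abort("`pop_size` must be an even integer >= 4.")
  }
  if (cfg$r_start < 1L || cfg$r_end < cfg$r_start) {
    abort("need 1 <= r_start <= r_end.")
  }
  structure(cfg, class = "ibcga_config")
}

#' Reduced-profile IBCGA configuration
#'
#' A compute-light profile for smoke tests, examples and continuous
#' integration: small population, few generations, compact L4 crossover
#' designs, sparing crossover rate and an early stop — chosen so a full
#' multi-run workflow completes in seconds to minutes on one core while
#' exercising every code path. Not intended for production signatures.
#'
#' @param ... overrides passed to [ibcga_config()].
#' @export
ibcga_smoke_config <- function(...) {
  defaults <- list(pop_size = 12L, r_start = 3L, r_end = 8L,
                   generations = 5L, pc = 0.25, pm = 0.05,
                   max_oa_factors = 3L, early_stop = 3L)
  do.call(ibcga_config, modifyList(defaults, list(...)))
}

new_chromosome <- function(mask, genes) {
  structure(list(mask = as.logical(mask), genes = as.integer(genes)),
            class = "ibcga_chrom")
}

chrom_key <- function(chrom) {
  paste(c(which(chrom$mask), "|", chrom$genes), collapse = ",")
}

#' Initialize an IBCGA population
#'
#' Each individual receives exactly `r_start` uniformly chosen mask bits
#' and uniform 4-bit parameter genes. Consumes the current RNG stream.
#'
#' @param cfg an [ibcga_config()].
#' @param p number of candidate features.
#' @return A list of chromosomes.
#' @export
init_population <- function(cfg, p) {
  if (cfg$r_start > p) abort("r_start exceeds the number of features.")
  lapply(seq_len(cfg$pop_size), function(i) {
    mask <- logical(p)
    mask[sample.int(p, cfg$r_start)] <- TRUE
    new_chromosome(mask, sample(0:15, 3L, replace = TRUE))
  })
}

#' Binary tournament selection
#'
#' Builds a mating pool of the population's size by repeated binary
#' tournaments: two individuals are drawn with replacement and the fitter
#' one (ties: the first drawn) is copied into the pool.
#'
#' @param population list of chromosomes.
#' @param fitnesses numeric vector, one per individual.
#' @return A list of chromosomes (copies).
#' @export
tournament_select <- function(population, fitnesses) {
  n <- length(population)
  if (n == 0L) abort("empty population.")
  if (n == 1L) return(rep(population, 1L))
  winners <- vapply(seq_len(n), function(i) {
    pair <- sample.int(n, 2L, replace = TRUE)
    if (fitnesses[pair[2L]] > fitnesses[pair[1L]]) pair[2L] else pair[1L]
  }, integer(1))
  population[winners]
}

# Repair a mask to exactly r set bits by random flips of surplus 1s or
# deficit 0s. No-op when the popcount already equals r.
repair_mask <- function(mask, r) {
  k <- sum(mask)
  if (k > r) {
    on <- which(mask)
    mask[sample_vec(on, k - r)] <- FALSE
  } else if (k < r) {
    off <- which(!mask)
    mask[sample_vec(off, r - k)] <- TRUE
  }
  mask
}

# sample() misbehaves for length-1 x; this never does.
sample_vec <- function(x, size) {
  if (length(x) == 1L) return(rep(x, length.out = size))
  x[sample.int(length(x), size)]
}

#' Orthogonal-array crossover
#'
#' The intelligent recombination at the core of the GA. Positions where
#' the two parents differ (mask bits and parameter genes jointly) are
#' grouped into at most `max_factors` contiguous factor groups of
#' near-equal size; a two-level orthogonal array over those factors
#' enumerates candidate children that take each factor from parent A
#' (level 1) or parent B (level 2). All candidates are evaluated, factor
#' main effects (mean fitness at level 1 vs level 2) compose a
#' predicted-best child, and the two fitness-best distinct chromosomes
#' among the candidates and the composed child are returned. When
#' `repair_r` is given, every mask is repaired to exactly that many set
#' bits before evaluation. Identical parents are returned unchanged.
#'
#' @param parent_a,parent_b chromosomes of equal mask length.
#' @param fitness_fn function(chromosome) -> numeric fitness (maximized).
#' @param max_factors maximum number of OA factors.
#' @param repair_r target mask popcount, or `NULL` to leave masks as
#'   composed.
#' @return List of two chromosomes (the better first).
#' @export
oa_crossover <- function(parent_a, parent_b, fitness_fn, max_factors = 7L,
                         repair_r = NULL) {
  p <- length(parent_a$mask)
  if (length(parent_b$mask) != p) abort("parents have different mask lengths.")
  ga <- c(as.integer(parent_a$mask), parent_a$genes)
  gb <- c(as.integer(parent_b$mask), parent_b$genes)
  diff_pos <- which(ga != gb)
  if (length(diff_pos) == 0L) {
    return(list(parent_a, parent_b))
  }
  g <- min(max_factors, length(diff_pos))
  groups <- if (g == 1L) list(diff_pos) else {
    split(diff_pos, cut(seq_along(diff_pos), g, labels = FALSE))
  }
  oa <- orthogonal_array(g)

  build_child <- function(levels) {
    genome <- ga
    for (f in seq_len(g)) {
      if (levels[f] == 2L) genome[groups[[f]]] <- gb[groups[[f]]]
    }
    mask <- genome[seq_len(p)] == 1L
    if (!is.null(repair_r)) mask <- repair_mask(mask, repair_r)
    new_chromosome(mask, genome[p + 1:3])
  }

  candidates <- lapply(seq_len(nrow(oa)), function(i) build_child(oa[i, ]))
  fits <- vapply(candidates, fitness_fn, numeric(1))

  # main effect per factor; compose the predicted-best levels
  best_levels <- vapply(seq_len(g), function(f) {
    m1 <- mean(fits[oa[, f] == 1L])
    m2 <- mean(fits[oa[, f] == 2L])
    if (m2 > m1) 2L else 1L
  }, integer(1))
  composed <- build_child(best_levels)
  candidates <- c(candidates, list(composed))
  fits <- c(fits, fitness_fn(composed))

  keys <- vapply(candidates, chrom_key, character(1))
  ord <- order(fits, decreasing = TRUE)
  first <- ord[1L]
  rest <- ord[-1L][keys[ord[-1L]] != keys[first]]
  second <- if (length(rest)) rest[1L] else first
  list(candidates[[first]], candidates[[second]])
}

#' Mutate a chromosome
#'
#' With probability `pm`, one set and one unset mask bit swap (the mask
#' popcount is preserved); independently, each parameter gene is replaced
#' by a uniform draw from `0..15` with probability `pm`.
#'
#' @param chrom a chromosome.
#' @param pm mutation probability in `[0, 1]`.
#' @return The mutated chromosome.
#' @export
mutate_chrom <- function(chrom, pm = 0.05) {
  if (pm > 0 && runif(1) < pm) {
    on <- which(chrom$mask)
    off <- which(!chrom$mask)
    if (length(on) && length(off)) {
      chrom$mask[sample_vec(on, 1L)] <- FALSE
      chrom$mask[sample_vec(off, 1L)] <- TRUE
    }
  }
  for (i in 1:3) {
    if (pm > 0 && runif(1) < pm) chrom$genes[i] <- sample(0:15, 1L)
  }
  chrom
}

#' Inheritance step: grow every mask by one feature
#'
#' Switches one uniformly chosen 0-bit to 1 in each individual's mask;
#' parameter genes are untouched. Used between stages to move the
#' population from feature count `r` to `r + 1`.
#'
#' @param population list of chromosomes.
#' @return The incremented population.
#' @export
inherit_increment <- function(population) {
  lapply(population, function(ch) {
    off <- which(!ch$mask)
    if (length(off) == 0L) abort("cannot increment a full mask.")
    ch$mask[sample_vec(off, 1L)] <- TRUE
    ch
  })
}

# Memoized 10-CV fitness over (mask, genes). The cache is transparent:
# identical chromosomes always map to the identical stored value.
#
# Fitness is the pooled out-of-fold squared correlation, clamped to 0
# when the pooled correlation is negative: uninformative kernel models
# shrink each fold's predictions toward the training-fold mean, which is
# anticorrelated with the held-out fold, so an unguarded r^2 objective
# rewards anti-predictive junk feature sets.
#
# The per-fold feature standardization depends only on the fold split,
# never on the mask, so the standardized training/test blocks for all p
# features are computed once up front and column-sliced per chromosome.
make_fitness_fn <- function(xs, y, folds, standardize, cache,
                            tolerance = 0.01) {
  fold_ids <- sort(unique(folds))
  blocks <- lapply(fold_ids, function(k) {
    hold <- folds == k
    xtr <- xs[!hold, , drop = FALSE]
    if (standardize) {
      ctr <- colMeans(xtr)
      scl <- sqrt(colSums(xtr^2) / nrow(xtr) - ctr^2) *
        sqrt(nrow(xtr) / (nrow(xtr) - 1))
      scl[scl == 0 | !is.finite(scl)] <- 1
      xtr <- sweep(sweep(xtr, 2L, ctr), 2L, scl, "/")
      xte <- sweep(sweep(xs[hold, , drop = FALSE], 2L, ctr), 2L, scl, "/")
    } else {
      xte <- xs[hold, , drop = FALSE]
    }
    list(xtr = xtr, xte = xte, ytr = y[!hold], hold = which(hold))
  })
  n <- length(y)
  function(chrom) {
    key <- chrom_key(chrom)
    hit <- cache$store[[key]]
    if (!is.null(hit)) return(hit)
    params <- decode_hyperparams(chrom$genes[1], chrom$genes[2], chrom$genes[3])
    val <- if (!any(chrom$mask)) {
      -Inf
    } else {
      z <- numeric(n)
      for (b in blocks) {
        fit <- nusvr_fit_raw(b$xtr[, chrom$mask, drop = FALSE], b$ytr,
                             params$cost, params$gamma, params$nu,
                             tolerance = tolerance)
        z[b$hold] <- nusvr_predict_raw(fit, b$xte[, chrom$mask, drop = FALSE])
      }
      r <- if (sd(z) == 0) 0 else cor(y, z)
      max(r, 0)^2
    }
    cache$store[[key]] <- val
    cache$n_evals <- cache$n_evals + 1L
    val
  }
}

#' Run the inheritable bi-objective combinatorial GA
#'
#' Evolves a population of (feature mask, hyperparameter genes)
#' chromosomes to maximize pooled 10-fold cross-validated squared
#' correlation between actual and predicted survival times. For each
#' feature count `r` from `r_start` to `r_end` the population is evolved
#' for the configured generations (evaluate, tournament selection,
#' orthogonal-array crossover, mutation, with elitism), the stage best is
#' recorded, and the population is inherited to `r + 1` by
#' [inherit_increment()]. The overall best across stages — ties broken by
#' higher fitness, then fewer features, then lower `r`, then first found
#' — is returned. The CV fold partition is drawn once from the run seed
#' and reused for every fitness evaluation.
#'
#' @param x an [expr_matrix()] (features x samples), filtered and aligned
#'   with `y`.
#' @param y survival times in years, one per sample (column) of `x`.
#' @param cfg an [ibcga_config()].
#' @param seed integer run seed; the run is a pure function of it.
#' @return An `ibcga_run` object: `selected_features`, `hyperparams`,
#'   `fitness` (pooled CV R-squared), `mae`, `stages` and `trace` tibbles,
#'   `predictions` (out-of-fold at the best chromosome), `n_evals`,
#'   `seed`, `config`.
#' @export
run_ibcga <- function(x, y, cfg = ibcga_config(), seed = 1L) {
  xs <- as_sample_matrix(x)
  n <- nrow(xs); p <- ncol(xs)
  if (length(y) != n) abort("sample count mismatch between x and y.")
  if (n < cfg$n_folds) abort("fewer samples than CV folds.")
  if (cfg$r_end > p) abort("r_end exceeds the number of features.")
  feature_ids <- colnames(xs)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(p))

  withr::with_seed(as.integer(seed), {
    folds <- integer(n)
    sizes <- rep(n %/% cfg$n_folds, cfg$n_folds)
    extra <- n %% cfg$n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    folds[sample.int(n)] <- rep(seq_len(cfg$n_folds), times = sizes)

    cache <- new.env(parent = emptyenv())
    cache$store <- new.env(parent = emptyenv())
    cache$n_evals <- 0L
    fitness_fn <- make_fitness_fn(xs, y, folds, cfg$standardize, cache,
                                  tolerance = cfg$tolerance)

    pop <- init_population(cfg, p)
    trace <- list()
    stage_best <- list()

    for (r in cfg$r_start:cfg$r_end) {
      elite <- NULL
      elite_fit <- -Inf
      stagnant <- 0L
      for (gen in seq_len(cfg$generations)) {
        fits <- vapply(pop, fitness_fn, numeric(1))
        gen_best <- max(fits)
        if (gen_best > elite_fit) {
          elite_fit <- gen_best
          elite <- pop[[which.max(fits)]]
          stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
        }
        trace[[length(trace) + 1L]] <-
          list(r = r, generation = gen, best_fitness = elite_fit,
               n_evals = cache$n_evals)
        if (stagnant >= cfg$early_stop || gen == cfg$generations) break

        pool <- tournament_select(pop, fits)
        children <- vector("list", cfg$pop_size)
        for (i in seq(1L, cfg$pop_size, by = 2L)) {
          pa <- pool[[i]]; pb <- pool[[i + 1L]]
          if (runif(1) < cfg$pc) {
            kids <- oa_crossover(pa, pb, fitness_fn,
                                 max_factors = cfg$max_oa_factors,
                                 repair_r = r)
            children[[i]] <- kids[[1L]]
            children[[i + 1L]] <- kids[[2L]]
          } else {
            children[[i]] <- pa
            children[[i + 1L]] <- pb
          }
        }
        children <- lapply(children, mutate_chrom, pm = cfg$pm)
        if (cfg$elitism) {
          cfits <- vapply(children, fitness_fn, numeric(1))
          if (max(cfits) < elite_fit) {
            children[[which.min(cfits)]] <- elite
          }
        }
        pop <- children
      }
      stage_best[[length(stage_best) + 1L]] <-
        list(r = r, fitness = elite_fit, chrom = elite)
      if (r < cfg$r_end) pop <- inherit_increment(pop)
    }

    stages <- tibble(
      r = vapply(stage_best, `[[`, integer(1), "r"),
      fitness = vapply(stage_best, `[[`, numeric(1), "fitness"),
      n_features = vapply(stage_best, function(s) sum(s$chrom$mask), integer(1))
    )
    # best overall: fitness desc, fewer features, lower r, first found
    ord <- order(-stages$fitness, stages$n_features, stages$r)
    best <- stage_best[[ord[1L]]]
    params <- decode_hyperparams(best$chrom$genes[1], best$chrom$genes[2],
                                 best$chrom$genes[3])
    final <- suppressWarnings(
      cv_nusvr(xs[, best$chrom$mask, drop = FALSE], y, params = params,
               cv = folds, standardize = cfg$standardize,
               tolerance = cfg$tolerance))

    structure(list(
      selected_features = feature_ids[best$chrom$mask],
      hyperparams = params,
      genes = best$chrom$genes,
      fitness = best$fitness,
      mae = final$mae,
      r = best$r,
      stages = stages,
      trace = dplyr::bind_rows(lapply(trace, tibble::as_tibble)),
      predictions = final$predictions,
      folds = folds,
      n_evals = cache$n_evals,
      seed = as.integer(seed),
      config = cfg
    ), class = "ibcga_run")
  })
}

#' @exportS3Method base::print
print.ibcga_run <- function(x, ...) {
  cat(sprintf(
    "<ibcga_run> seed %d: %d features at r=%d, CV R^2 = %.3f, MAE = %.3f yr (%d evals)\n",
    x$seed, length(x$selected_features), x$r, x$fitness, x$mae, x$n_evals))
  invisible(x)
}

#' @export
tidy.ibcga_run <- function(x, ...) x$stages

#' @export
glance.ibcga_run <- function(x, ...) {
  tibble(
    n_features = length(x$selected_features),
    r = x$r,
    cv_r_squared = x$fitness,
    cv_mae_years = x$mae,
    cost = x$hyperparams$cost,
    gamma = x$hyperparams$gamma,
    nu = x$hyperparams$nu,
    n_evals = x$n_evals,
    seed = x$seed
  )
}
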