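#' Genetic algorithm configuration
#'
#' Defaults mirror the optimization protocol the package implements: a
#' population of 50 wavelength sets, the best 15 copied unchanged into
#' the next generation (elitism), the remaining 35 offspring produced
#' from roulette-selected parents with a 20% crossover fraction
#' (round(0.20 x 35) = 7 crossovers, 28 mutations), and termination when
#' the generation minimum fitness is unchanged for 10 generations or
#' after 50 generations.
#'
#' @param n_wavelengths Number of center wavelengths per set (>= 5 for
#'   the physical inverse-model fitness; smaller values are allowed for
#'   custom fitness functions, e.g. toy benchmark problems).
#' @param grid The [wavelength_grid()] sets are drawn from.
#' @param population_size Individuals per generation.
#' @param elite_count Top sets copied unchanged each generation.
#' @param crossover_fraction Fraction of offspring produced by crossover.
#' @param mutation_sigma_nm Gaussian mutation scale; defaults to 3 grid
#'   steps.
#' @param max_generations,stall_generations Termination rules.
#' @param stall_rel_tol Relative tolerance for "unchanged" minimum fitness.
#' @param rng_seed Seed controlling the whole evolution trace.
#' @return A `ga_config` list.
#' @export
ga_config <- function(n_wavelengths, grid, population_size = 50,
                      elite_count = 15, crossover_fraction = 0.20,
                      mutation_sigma_nm = 3 * grid$step_nm,
                      max_generations = 50, stall_generations = 10,
                      stall_rel_tol = 1e-9, rng_seed = 1) {
  stopifnot(inherits(grid, "wavelength_grid"),
            n_wavelengths >= 2, n_wavelengths <= grid$count,
            elite_count >= 1, elite_count < population_size,
            crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_sigma_nm > 0, max_generations >= 1,
            stall_generations >= 1)
  structure(list(n_wavelengths = as.integer(n_wavelengths), grid = grid,
                 population_size = as.integer(population_size),
                 elite_count = as.integer(elite_count),
                 crossover_fraction = crossover_fraction,
                 mutation_sigma_nm = mutation_sigma_nm,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 stall_rel_tol = stall_rel_tol,
                 rng_seed = rng_seed),
            class = "ga_config")
}

#' Percentile-based training-set selection
#'
#' Picks, for each parameter summary, the samples sitting at the
#' requested percentiles of its empirical cumulative distribution
#' (nearest-rank convention), so the training spectra sample the
#' distributions evenly rather than the value ranges. With the default
#' five percentiles over three summaries this yields 15 indices;
#' duplicates across summaries are permitted.
#'
#' @param summaries A data frame or matrix with one row per sample and
#'   one column per parameter summary (e.g. THb, beta-carotene, mean
#'   mus').
#' @param percentiles Percentiles in (0, 100].
#' @return Integer vector of row indices, ordered column by column.
#' @export
select_percentile_spectra <- function(summaries,
                                      percentiles = c(10, 25, 50, 75, 90)) {
  summaries <- as.matrix(summaries)
  n <- nrow(summaries)
  if (n == 0) stop("empty population")
  if (n < length(percentiles)) stop("population smaller than number of percentiles")
  unlist(lapply(seq_len(ncol(summaries)), function(j) {
    x <- summaries[, j]
    xs <- sort(x)
    ranks <- pmin(pmax(ceiling(percentiles / 100 * n), 1L), n)
    # ties resolve to the first sample carrying the percentile value, so a
    # degenerate population selects one index for every percentile
    vapply(ranks, function(r) which(x == xs[r])[1], integer(1))
  }), use.names = FALSE)
}

#' Build a training set from parameter sets
#'
#' Simulates a noiseless spectrum for every parameter set and stores the
#' full-spectrum extraction of each as the gold-standard reference the
#' GA fitness compares against.
#'
#' @param params_list List of [tissue_parameters()].
#' @param basis,grid,model,geometry,records Forward model configuration.
#' @param ... Passed to [extract_properties()] for the references.
#' @return A `training_set` with `spectra`, `references` and the model
#'   configuration (reused by [ga_fitness()]).
#' @export
build_training_set <- function(params_list, basis = "surrogate",
                               grid = wavelength_grid(450, 600, 2.5),
                               model = "diffusion",
                               geometry = probe_geometry(), records = NULL,
                               ...) {
  basis <- resolve_basis(basis)
  spectra <- simulate_spectra(params_list, basis, grid, model = model,
                              geometry = geometry, records = records)
  references <- lapply(spectra, extract_properties, subset = NULL,
                       basis = basis, model = model, geometry = geometry,
                       records = records, ...)
  if (!all(vapply(references, function(r) isTRUE(r$converged), logical(1)))) {
    stop("full-spectrum reference extraction failed to converge")
  }
  structure(list(spectra = spectra, references = references, basis = basis,
                 model = model, geometry = geometry, records = records),
            class = "training_set")
}

#' GA fitness of a wavelength set
#'
#' Extracts THb, beta-carotene and mean mus' from every training
#' spectrum using only the candidate wavelengths, forms the signed
#' percent error of each summary against the full-spectrum reference
#' (3 summaries x n spectra comparisons), and aggregates the absolute
#' percent errors into a single root-mean-square fitness value (lower is
#' better). A failed extraction contributes the penalty error to each of
#' its comparisons.
#'
#' @param set A [wavelength_set()] or numeric wavelength vector.
#' @param training A `training_set` from [build_training_set()].
#' @param penalty_error Percent error charged per comparison when an
#'   extraction fails (default 100).
#' @param ... Passed to [extract_properties()].
#' @return A `fitness_record` with `wavelength_set`,
#'   `per_comparison_errors` (n x 3 matrix of signed percent errors) and
#'   scalar `fitness`.
#' @export
ga_fitness <- function(set, training, penalty_error = 100, ...) {
  stopifnot(inherits(training, "training_set"))
  wls <- if (inherits(set, "wavelength_set")) set$wavelengths else set
  errs <- t(vapply(seq_along(training$spectra), function(i) {
    ex <- tryCatch(
      extract_properties(training$spectra[[i]], subset = wls,
                         basis = training$basis, model = training$model,
                         geometry = training$geometry,
                         records = training$records, ...),
      error = function(e) NULL)
    if (is.null(ex) || !isTRUE(ex$converged)) {
      rep(penalty_error, 3)
    } else {
      extraction_errors(ex, training$references[[i]])
    }
  }, numeric(3)))
  colnames(errs) <- c("thb_uM", "bc_uM", "mean_musp")
  structure(list(wavelength_set = set, per_comparison_errors = errs,
                 fitness = sqrt(mean(abs(errs)^2))),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("<fitness_record> fitness %.3f%% over %d comparisons\n",
              x$fitness, length(x$per_comparison_errors)))
  invisible(x)
}

#' Initial GA population
#'
#' Each individual is `n_wavelengths` distinct grid points drawn
#' uniformly without replacement; seeded and reproducible.
#'
#' @param config A [ga_config()].
#' @return List of `population_size` [wavelength_set()] objects.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "ga_config"))
  wl <- grid_wavelengths(config$grid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$rng_seed)
  lapply(seq_len(config$population_size), function(i) {
    wavelength_set(sample(wl, config$n_wavelengths), config$grid)
  })
}

#' Roulette-wheel parent selection with inverse-fitness weights
#'
#' Draws parent indices with probability proportional to `1 / fitness`,
#' so lower-error sets are preferentially selected. Fitness values of
#' zero are floored at a small epsilon before inversion.
#'
#' @param fitnesses Numeric vector of fitness values (>= 0).
#' @param n Number of draws.
#' @param eps Floor applied before inversion.
#' @return Integer vector of `n` selected indices (uses the current RNG
#'   stream).
#' @export
roulette_select <- function(fitnesses, n = 1, eps = 1e-12) {
  if (!length(fitnesses)) stop("empty fitness vector")
  w <- 1 / pmax(fitnesses, eps)
  sample.int(length(fitnesses), size = n, replace = TRUE, prob = w / sum(w))
}

# draw one grid value not already in `exclude`
fresh_grid_value <- function(grid, exclude) {
  wl <- grid_wavelengths(grid)
  pool <- wl[!(wl %in% exclude)]
  if (!length(pool)) stop("grid exhausted: cannot repair duplicates")
  if (length(pool) == 1) pool else sample(pool, 1)
}

# replace duplicated members with fresh random grid values
repair_duplicates <- function(wls, grid) {
  while (anyDuplicated(wls)) {
    dup <- which(duplicated(wls))[1]
    wls[dup] <- fresh_grid_value(grid, wls)
  }
  wls
}

#' Single-point crossover of two wavelength sets
#'
#' The sorted parents break at a uniformly random cut point and join:
#' the child takes the head of the first parent and the tail of the
#' second. Any duplicate wavelength this creates is discarded and
#' replaced by a fresh uniformly drawn grid wavelength, so the child
#' always has the parents' length with distinct on-grid members.
#'
#' @param p1,p2 [wavelength_set()] objects of equal length.
#' @return The child [wavelength_set()] (uses the current RNG stream).
#' @export
ga_crossover <- function(p1, p2) {
  k <- length(p1$wavelengths)
  if (k != length(p2$wavelengths)) stop("parents must have equal length")
  cut <- sample.int(k - 1, 1)  # at least one member from each parent
  child <- c(p1$wavelengths[seq_len(cut)],
             p2$wavelengths[(cut + 1):k])
  wavelength_set(repair_duplicates(child, p1$increment_grid), p1$increment_grid)
}

#' Gaussian mutation of a wavelength set
#'
#' One uniformly chosen member is perturbed by a Gaussian of standard
#' deviation `sigma_nm`, snapped to the nearest grid point and clamped
#' to the grid range; duplicates arising from the snap are repaired with
#' fresh random grid values.
#'
#' @param p A [wavelength_set()].
#' @param sigma_nm Mutation scale (nm, > 0).
#' @return The mutated [wavelength_set()] (uses the current RNG stream).
#' @export
ga_mutate <- function(p, sigma_nm) {
  if (sigma_nm <= 0) stop("sigma_nm must be > 0")
  g <- p$increment_grid
  wls <- p$wavelengths
  pos <- sample.int(length(wls), 1)
  new_val <- wls[pos] + stats::rnorm(1, 0, sigma_nm)
  idx <- round((new_val - g$start_nm) / g$step_nm)
  idx <- min(max(idx, 0), g$count - 1)
  wls[pos] <- g$start_nm + idx * g$step_nm
  wavelength_set(repair_duplicates(wls, g), g)
}

#' Evolve wavelength sets by genetic search
#'
#' Runs the full generational loop: rank by fitness, copy the elites,
#' breed the remaining offspring from roulette-selected parents
#' (`round(crossover_fraction x offspring)` crossovers, the rest
#' mutations), and stop when the generation minimum fitness has not
#' improved for `stall_generations` generations or at
#' `max_generations`. Elitism makes the best-of-generation fitness
#' non-increasing. The whole trace is reproducible from
#' `config$rng_seed`.
#'
#' @param config A [ga_config()].
#' @param training A `training_set` (ignored when `fitness_fn` is given).
#' @param fitness_fn Optional function `(wavelength_set) -> scalar`
#'   replacing the inverse-model fitness (used for benchmark problems);
#'   with the default `NULL`, [ga_fitness()] on `training` is used and
#'   `config$n_wavelengths` must be at least 5 (the number of free
#'   parameters of the inverse model).
#' @param top_n Number of ranked solutions reported (default 3).
#' @param ... Passed to [ga_fitness()].
#' @return A `ga_result` with `top_sets` (list of `top_n` wavelength
#'   sets, best first), `top_fitness`, `history` (best and median fitness
#'   per generation), `generations` run and `stalled` flag.
#' @export
evolve <- function(config, training = NULL, fitness_fn = NULL, top_n = 3, ...) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(fitness_fn)) {
    if (is.null(training)) stop("either a training set or a fitness_fn is required")
    if (config$n_wavelengths < 5) {
      stop("at least 5 center wavelengths are needed to extract the 5 free parameters")
    }
    fitness_fn <- function(set) ga_fitness(set, training, ...)$fitness
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$rng_seed)

  wl_key <- function(s) paste(s$wavelengths, collapse = ",")
  cache <- new.env(parent = emptyenv())
  eval_fitness <- function(s) {
    key <- wl_key(s)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- fitness_fn(s)
    cache[[key]] <- val
    val
  }

  pop <- lapply(seq_len(config$population_size), function(i) {
    wavelength_set(sample(grid_wavelengths(config$grid), config$n_wavelengths),
                   config$grid)
  })
  fit <- vapply(pop, eval_fitness, numeric(1))

  n_off <- config$population_size - config$elite_count
  n_cross <- round(config$crossover_fraction * n_off)
  history <- data.frame(generation = integer(), best = numeric(),
                        median = numeric())
  best_min <- Inf
  stall <- 0L
  gen <- 0L
  stalled <- FALSE

  repeat {
    gen <- gen + 1L
    ord <- order(fit)
    pop <- pop[ord]; fit <- fit[ord]
    history <- rbind(history, data.frame(generation = gen, best = fit[1],
                                         median = stats::median(fit)))
    if (fit[1] < best_min * (1 - config$stall_rel_tol)) {
      best_min <- fit[1]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= config$stall_generations) { stalled <- TRUE; break }
    if (gen >= config$max_generations) break

    elites <- pop[seq_len(config$elite_count)]
    parents <- roulette_select(fit, n = n_off + n_cross)  # crossovers need 2 parents
    offspring <- vector("list", n_off)
    pi <- 1L
    for (j in seq_len(n_off)) {
      if (j <= n_cross) {
        offspring[[j]] <- ga_crossover(pop[[parents[pi]]], pop[[parents[pi + 1L]]])
        pi <- pi + 2L
      } else {
        offspring[[j]] <- ga_mutate(pop[[parents[pi]]], config$mutation_sigma_nm)
        pi <- pi + 1L
      }
    }
    pop <- c(elites, offspring)
    fit <- vapply(pop, eval_fitness, numeric(1))
  }

  ord <- order(fit)
  top <- seq_len(min(top_n, length(pop)))
  structure(list(top_sets = pop[ord[top]], top_fitness = fit[ord[top]],
                 history = history, generations = gen, stalled = stalled,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations (%s), best fitness %.4f\n",
              x$generations, if (x$stalled) "stalled" else "max generations",
              x$top_fitness[1]))
  for (i in seq_along(x$top_sets)) {
    cat(sprintf("  #%d (%.4f): %s\n", i, x$top_fitness[i],
                paste(x$top_sets[[i]]$wavelengths, collapse = " ")))
  }
  invisible(x)
}

#' Toy linear-unmixing benchmark problem
#'
#' A small, fully deterministic benchmark for the genetic search: a
#' 10-point wavelength grid carrying three disjoint narrow-band
#' absorbers, a handful of samples with known concentrations, and noisy
#' absorbance observations. The fitness of a 3-wavelength set is the RMS
#' percent error of recovering the concentrations by linear least
#' squares from those wavelengths alone, so fitness differences between
#' sets reflect the conditioning of the chosen wavelengths against the
#' fixed noise realization. With only choose(10, 3) = 120 candidate
#' sets, the global optimum is cheaply found by exhaustive search, which
#' makes the problem a sharp correctness check for [evolve()].
#'
#' @param noise_sd Additive noise SD on the absorbances.
#' @param seed Seed for the (fixed) noise realization.
#' @return List with `grid` (a 10-point [wavelength_grid()]), `fitness`
#'   (function mapping a [wavelength_set()] or numeric vector to a
#'   scalar), `extinction` (10 x 3 matrix) and `concentrations`
#'   (samples x 3).
#' @export
toy_unmixing_problem <- function(noise_sd = 0.02, seed = 7) {
  grid <- wavelength_grid(450, 540, 10)
  wl <- grid_wavelengths(grid)
  centers <- c(460, 490, 530)
  emat <- sapply(centers, function(cc) exp(-((wl - cc) / 8)^2))
  conc <- rbind(c(1.0, 0.5, 0.2),
                c(0.3, 1.2, 0.7),
                c(0.8, 0.2, 1.1),
                c(0.5, 0.9, 0.4))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  obs <- conc %*% t(emat) + matrix(stats::rnorm(nrow(conc) * length(wl),
                                                0, noise_sd),
                                   nrow(conc), length(wl))
  fitness <- function(set) {
    wls <- if (inherits(set, "wavelength_set")) set$wavelengths else set
    idx <- match(wls, wl)
    if (anyNA(idx)) stop("toy fitness: wavelengths must lie on the toy grid")
    es <- emat[idx, , drop = FALSE]
    errs <- vapply(seq_len(nrow(conc)), function(i) {
      ch <- tryCatch(qr.solve(es, obs[i, idx]), error = function(e) rep(Inf, 3))
      100 * (ch - conc[i, ]) / conc[i, ]
    }, numeric(3))
    sqrt(mean(errs^2))
  }
  list(grid = grid, fitness = fitness, extinction = emat,
       concentrations = conc)
}
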