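test_that("percentile selection follows the nearest-rank convention", {
  vals <- data.frame(a = c(10, 2, 7, 1, 9, 3, 8, 4, 6, 5))
  idx <- select_percentile_spectra(vals, percentiles = c(10, 50, 90))
  # sort-based oracle: nearest-rank percentile p of n = 10 values is the
  # ceiling(p/100 * 10)-th order statistic
  want <- vapply(c(10, 50, 90), function(p) {
    which(vals$a == sort(vals$a)[ceiling(p / 100 * 10)])
  }, integer(1))
  expect_equal(idx, want)

  # three summaries x five percentiles = 15 indices
  set.seed(8)
  pop <- matrix(runif(60), 20, 3)
  expect_length(select_percentile_spectra(pop), 15)

  # identical values: the same sample serves every percentile
  same <- data.frame(a = rep(4, 9))
  expect_equal(unique(select_percentile_spectra(same, c(10, 50, 90))),
               select_percentile_spectra(same, 50))
  expect_error(select_percentile_spectra(data.frame(a = numeric(0))), "empty")
})

test_that("initial populations are valid, complete and reproducible", {
  g16 <- wavelength_grid(450, 600, 10)
  cfg <- ga_config(n_wavelengths = 8, grid = g16, rng_seed = 7)
  pop <- init_population(cfg)
  expect_length(pop, 50)
  for (s in pop) {
    expect_length(s$wavelengths, 8)
    expect_false(anyDuplicated(s$wavelengths) > 0)
    expect_true(all(s$wavelengths %in% grid_wavelengths(g16)))
  }
  expect_identical(init_population(cfg), pop)

  cfg_full <- ga_config(n_wavelengths = 16, grid = g16)
  expect_true(all(vapply(init_population(cfg_full), function(s) {
    identical(s$wavelengths, grid_wavelengths(g16))
  }, logical(1))))
  expect_error(ga_config(n_wavelengths = 17, grid = g16))
})

test_that("the full grid is a (near) perfect wavelength set for the training data", {
  training <- tt_training()
  fr <- ga_fitness(grid_wavelengths(tt_grid()), training)
  expect_lte(fr$fitness, 0.5)
  expect_equal(dim(fr$per_comparison_errors), c(15L, 3L))
  expect_equal(length(fr$per_comparison_errors), 45L)
})

test_that("roulette selection weights parents by inverse fitness", {
  set.seed(123)
  draws <- roulette_select(c(1, 1, 1, 1), n = 4000)
  freq <- tabulate(draws, 4) / 4000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))

  draws2 <- roulette_select(c(1, 2), n = 6000)
  p1 <- mean(draws2 == 1)
  expect_equal(p1, 2 / 3, tolerance = 3 * sqrt(2 / 9 / 6000) / (2 / 3))
  expect_error(roulette_select(numeric(0)), "empty")
})

test_that("crossover always yields valid children that mix both parents", {
  g16 <- wavelength_grid(450, 600, 10)
  wl <- grid_wavelengths(g16)
  p_same <- wavelength_set(wl[c(1, 4, 8, 12)], g16)
  set.seed(21)
  expect_equal(ga_crossover(p_same, p_same)$wavelengths, p_same$wavelengths)

  p1 <- wavelength_set(wl[1:4], g16)
  p2 <- wavelength_set(wl[9:12], g16)
  set.seed(22)
  for (i in 1:50) {
    ch <- ga_crossover(p1, p2)$wavelengths
    n1 <- sum(ch %in% p1$wavelengths)
    # disjoint parents: the cut keeps c head members from p1, k - c from p2
    expect_true(n1 >= 1 && n1 <= 3)
    expect_length(ch, 4)
  }

  set.seed(23)
  for (i in 1:1000) {
    a <- wavelength_set(sample(wl, 6), g16)
    b <- wavelength_set(sample(wl, 6), g16)
    ch <- ga_crossover(a, b)$wavelengths
    expect_length(unique(ch), 6)
    expect_true(all(ch %in% wl))
  }
})

test_that("mutation perturbs one member, snaps to grid and respects the range", {
  g16 <- wavelength_grid(450, 600, 10)
  wl <- grid_wavelengths(g16)
  set.seed(31)
  for (i in 1:1000) {
    p <- wavelength_set(sample(wl, 5), g16)
    ch <- ga_mutate(p, sigma_nm = 30)$wavelengths
    expect_length(unique(ch), 5)
    expect_true(all(ch %in% wl))
    expect_true(all(ch >= 450 & ch <= 600))
  }
  # boundary sets never escape the range
  edge <- wavelength_set(c(450, 460, 590, 600), g16)
  set.seed(32)
  for (i in 1:200) {
    ch <- ga_mutate(edge, sigma_nm = 80)$wavelengths
    expect_true(all(ch >= 450 & ch <= 600))
  }
  # vanishing sigma: the snap returns the parent almost surely
  set.seed(33)
  same <- vapply(1:100, function(i) {
    identical(ga_mutate(edge, sigma_nm = 1e-6)$wavelengths, edge$wavelengths)
  }, logical(1))
  expect_true(all(same))
  expect_error(ga_mutate(edge, sigma_nm = 0), "sigma")
})

test_that("evolution is elitist, bounded, reproducible and stalls without improvement", {
  toy <- toy_unmixing_problem()
  cfg <- ga_config(n_wavelengths = 3, grid = toy$grid, population_size = 20,
                   elite_count = 6, max_generations = 25,
                   stall_generations = 5, rng_seed = 4)
  res <- evolve(cfg, fitness_fn = toy$fitness)
  expect_true(all(diff(res$history$best) <= 1e-12))
  expect_lte(res$generations, 25)
  expect_identical(evolve(cfg, fitness_fn = toy$fitness)$history, res$history)

  # constant fitness cannot improve: termination by stall
  cfg2 <- ga_config(n_wavelengths = 3, grid = toy$grid, population_size = 12,
                    elite_count = 4, max_generations = 50,
                    stall_generations = 6, rng_seed = 9)
  res2 <- evolve(cfg2, fitness_fn = function(s) 1)
  expect_true(res2$stalled)
  expect_lte(res2$generations, 6 + 1)

  # offspring split at the defaults: 35 offspring, 7 crossovers
  cfg3 <- ga_config(n_wavelengths = 8, grid = wavelength_grid(450, 600, 10))
  expect_equal(cfg3$population_size - cfg3$elite_count, 35L)
  expect_equal(round(cfg3$crossover_fraction * 35), 7)

  # the physical fitness path refuses under-determined set sizes
  expect_error(evolve(ga_config(n_wavelengths = 3, grid = toy$grid),
                      training = tt_training()),
               "at least 5")
})
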