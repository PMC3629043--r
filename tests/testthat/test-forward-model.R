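test_that("reflectance decreases when absorption rises uniformly", {
  g <- tt_grid()
  musp <- build_musp(scattering_powerlaw(9, 1), g)
  r_lo <- forward_reflectance(optical_properties(g, rep(0.3, g$count), musp))
  r_hi <- forward_reflectance(optical_properties(g, rep(0.9, g$count), musp))
  expect_true(all(r_hi$values < r_lo$values))
  expect_true(all(r_lo$values > 0))
})

test_that("diffusion output matches an independent dipole re-derivation to 10 digits", {
  cases <- list(c(0.2, 10), c(0.8, 6), c(0.05, 12))
  for (cs in cases) {
    g1 <- wavelength_grid(500, 510, 10)
    got <- forward_reflectance(
      optical_properties(g1, rep(cs[1], 2), rep(cs[2], 2)))$values[1]
    want <- oracle_diffusion(cs[1], cs[2], rho = 0.075, n_rel = 1.4)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("scaled MC with zero absorption returns the baseline detection level everywhere", {
  pr <- tt_records()
  g <- tt_grid()
  r0 <- forward_reflectance(optical_properties(g, rep(0, g$count),
                                               rep(10, g$count)),
                            model = "scaled_mc", records = pr)
  area <- pi * ((0.075 + 0.0125)^2 - (0.075 - 0.0125)^2)
  baseline <- sum(pr$weights) / (pr$n_launched * area)
  expect_equal(r0$values, rep(baseline, g$count))
  expect_error(
    forward_reflectance(optical_properties(g, rep(0, g$count),
                                           rep(10, g$count)),
                        model = "scaled_mc"),
    "photon_records")
})

test_that("photon records are reproducible and physically sane", {
  pr <- tt_records()
  pr2 <- simulate_photon_records(n_photons = 5e4, baseline_musp = 10, seed = 42)
  expect_identical(pr$path_lengths_cm, pr2$path_lengths_cm)
  expect_true(length(pr$weights) > 100)
  expect_true(all(pr$weights > 0 & pr$weights <= 1))
  expect_true(all(pr$path_lengths_cm > 0))
})

test_that("scaled MC and diffusion agree in the low-absorption sanity band", {
  pr <- tt_records()
  g1 <- wavelength_grid(500, 510, 10)
  for (ratio in c(0.01, 0.024, 0.038, 0.051, 0.065)) {
    props <- optical_properties(g1, rep(ratio * 10, 2), rep(10, 2))
    mc <- forward_reflectance(props, model = "scaled_mc", records = pr)$values[1]
    di <- forward_reflectance(props, model = "diffusion")$values[1]
    expect_lt(abs(mc - di) / di, 0.15)
  }
})

test_that("bandpass convolution preserves constants and fwhm = 0 is the identity", {
  g <- tt_grid()
  flat <- reflectance_spectrum(g, rep(2.7, g$count))
  for (f in c(1, 5, 10, 30, 50)) {
    expect_equal(convolve_bandpass(flat, f)$values, flat$values)
  }
  sp <- reflectance_spectrum(g, seq(1, 3, length.out = g$count))
  expect_identical(convolve_bandpass(sp, 0), sp)
  expect_error(convolve_bandpass(sp, -1), "fwhm")
})

test_that("impulse response is the unit-sum discretized Gaussian kernel", {
  g <- wavelength_grid(450, 600, 1)
  v <- rep(0, g$count); v[76] <- 1  # impulse at 525 nm, far from edges
  out <- convolve_bandpass(reflectance_spectrum(g, v), 10)
  sigma <- 10 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 4.2466, tolerance = 1e-4)
  half <- floor(3 * sigma)
  offs <- (-half):half
  kern <- exp(-offs^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  # away from boundaries every output sample uses the full kernel, so the
  # response at 525 + d is the kernel weight at offset d
  for (d in offs) {
    expect_equal(out$values[76 + d], kern[which(offs == -d)],
                 tolerance = 1e-12)
  }
  expect_equal(out$fwhm_nm, 10)
})

test_that("convolution commutes with scaling and smooths monotonically", {
  g <- tt_grid()
  set.seed(5)
  v <- abs(2 + cumsum(rnorm(g$count, 0, 0.2)))
  sp <- reflectance_spectrum(g, v)
  a <- convolve_bandpass(reflectance_spectrum(g, 3 * v), 20)$values
  b <- 3 * convolve_bandpass(sp, 20)$values
  expect_equal(a, b)

  rough <- function(x) sum(diff(diff(x))^2)
  r <- vapply(c(0, 1, 5, 10, 20, 30, 40, 50),
              function(f) rough(convolve_bandpass(sp, f)$values), numeric(1))
  expect_true(all(diff(r) <= 1e-12))
})

test_that("spectrum simulation is deterministic and shaped by scattering alone without absorbers", {
  basis <- tt_basis()
  g <- tt_grid()
  p <- tissue_parameters(40, 20, 15, scattering_powerlaw(9, 1.2))
  s1 <- simulate_spectra(list(p, p), basis, g)
  expect_identical(s1[[1]]$values, s1[[2]]$values)

  p0 <- tissue_parameters(0, 0, 0, scattering_powerlaw(9, 1.2))
  sp0 <- simulate_spectra(list(p0), basis, g)[[1]]
  # no absorbers: reflectance inherits the monotone decay of musp(lambda)
  expect_true(all(diff(sp0$values) < 0))
})
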