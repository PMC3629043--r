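test_that("cohort draws stay inside the design ranges and are reproducible", {
  spec <- cohort_spec(n = 1000, seed = 314)
  co <- suppressWarnings(generate_cohort(spec))
  expect_equal(nrow(co$truth), 1000L)
  expect_true(all(co$truth[, "thb_uM"] >= 10.7 & co$truth[, "thb_uM"] <= 97.9))
  expect_true(all(co$truth[, "bc_uM"] >= 7.0 & co$truth[, "bc_uM"] <= 37.6))
  expect_true(all(co$truth[, "mean_musp"] >= 3.7 &
                    co$truth[, "mean_musp"] <= 11.9))
  # drawn scattering targets are realized by the calibrated power law
  realized <- vapply(co$params[1:20], function(p) {
    unname(tissue_summaries(p)["mean_musp"])
  }, numeric(1))
  expect_equal(realized, unname(co$truth[1:20, "mean_musp"]), tolerance = 1e-10)

  co2 <- suppressWarnings(generate_cohort(spec))
  expect_identical(co$truth, co2$truth)
  expect_identical(co$spectra[[7]]$values, co2$spectra[[7]]$values)

  # spectra stay non-negative and clipping is rare at the default noise
  expect_true(all(vapply(co$spectra, function(s) all(s$values >= 0), logical(1))))
  expect_lt(co$clip_fraction, 0.001)
})

test_that("zero noise reproduces the forward model exactly", {
  spec <- cohort_spec(n = 3, multiplicative_sd = 0, additive_sd = 0, seed = 5)
  co <- suppressWarnings(generate_cohort(spec))
  clean <- suppressWarnings(
    simulate_spectra(co$params, surrogate_basis(), tt_grid()))
  for (i in 1:3) expect_equal(co$spectra[[i]]$values, clean[[i]]$values)
})

test_that("the phantom set realizes the factorial design with calibrated components", {
  ph <- fixture("phantoms", function() generate_phantom_set())
  expect_equal(nrow(ph$design), 20L)
  expect_length(ph$params, 20L)
  expect_equal(sort(unique(ph$design$scattering_level)), c(9, 12))

  # crocin-free phantoms really have a zero crocin component
  first <- ph$design[ph$design$absorber_level == 1 &
                       ph$design$target_crocin_mean_mua == 0, ]
  expect_true(all(first$crocin_mean_mua == 0))
  expect_equal(first$hb_mean_mua, rep(0.51, nrow(first)), tolerance = 0.01)

  # every component mean mua is within 1% of its design cell, and the
  # total is additive in the components
  nonzero <- ph$design$target_crocin_mean_mua > 0
  expect_true(all(abs(ph$design$hb_mean_mua / ph$design$target_hb_mean_mua - 1)
                  < 0.01))
  expect_true(all(abs(ph$design$crocin_mean_mua[nonzero] /
                        ph$design$target_crocin_mean_mua[nonzero] - 1) < 0.01))
  expect_equal(ph$design$total_mean_mua,
               ph$design$hb_mean_mua + ph$design$crocin_mean_mua)

  # both scattering levels are realized by the Mie suspensions
  for (m in c(9, 12)) {
    p <- ph$params[[which(ph$design$target_mean_musp == m)[1]]]
    expect_equal(mean(build_musp(p$scattering, ph$grid)), m,
                 tolerance = 0.1 / m)
  }
})

test_that("the training fixture carries the printed property triples", {
  params <- training_tissue_fixture()
  tab <- attr(params, "table")
  expect_length(params, 15L)
  expect_equal(tab$thb_uM[5], 97.9)
  expect_equal(tab$bc_uM[6], 7.0)
  expect_equal(tab$mean_musp[15], 11.9)
  got <- t(vapply(params, tissue_summaries, numeric(3)))
  expect_equal(unname(got[, "thb_uM"]), tab$thb_uM)
  expect_equal(unname(got[, "bc_uM"]), tab$bc_uM)
  expect_equal(unname(got[, "mean_musp"]), tab$mean_musp, tolerance = 1e-10)
})

test_that("simulating and re-extracting each training fixture recovers its triple", {
  training <- tt_training()
  tab <- attr(training_tissue_fixture(), "table")
  got <- t(vapply(training$references, function(r) r$summaries, numeric(3)))
  expect_true(all(abs(100 * (got[, "thb_uM"] - tab$thb_uM) / tab$thb_uM) < 1))
  expect_true(all(abs(100 * (got[, "bc_uM"] - tab$bc_uM) / tab$bc_uM) < 1))
  expect_true(all(abs(100 * (got[, "mean_musp"] - tab$mean_musp) /
                        tab$mean_musp) < 1))
})

test_that("the bundled coarse extinction tables load as valid absorbers", {
  b <- bundled_basis()
  expect_setequal(names(b), c("hbo2", "dhb", "bcar", "crocin"))
  for (ab in b) {
    expect_s3_class(ab, "absorber_spectrum")
    expect_true(all(diff(ab$wavelengths_nm) > 0))
    expect_true(all(ab$molar_extinction >= 0))
  }
  # the tables cover the working range
  expect_true(all(vapply(b, function(ab) {
    min(ab$wavelengths_nm) <= 450 && max(ab$wavelengths_nm) >= 600
  }, logical(1))))
})
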