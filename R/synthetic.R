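#' Cohort specification for synthetic tissue spectra
#'
#' Describes a download-free stand-in for a clinical training
#' population: parameter ranges (uniform draws), hemoglobin oxygen
#' saturation, and a two-component noise model applied to the simulated
#' reflectance, `R_noisy = R * (1 + eps_m) + eps_a`, with
#' `eps_m ~ N(0, multiplicative_sd)` and
#' `eps_a ~ N(0, additive_sd * mean(R))`.
#'
#' The default ranges span total hemoglobin 10.7-97.9 uM, beta-carotene
#' 7.0-37.6 uM and mean reduced scattering 3.7-11.9 cm^-1 over
#' 450-600 nm -- the spread of extracted ex vivo breast tissue
#' properties the wavelength-selection method is designed around. The
#' default noise (3% multiplicative, 0.5% additive) puts full-spectrum
#' extraction errors in the single-digit-percent regime; it is a tuning
#' knob, not a measured instrument characterization.
#'
#' @param n Cohort size.
#' @param thb_range,bc_range,musp_range Uniform draw ranges (uM, uM,
#'   cm^-1).
#' @param saturation Hemoglobin oxygen saturation splitting THb into
#'   oxy/deoxy.
#' @param b_range Range of the scattering power-law exponent.
#' @param multiplicative_sd,additive_sd Noise SDs (fractions).
#' @param seed RNG seed; the cohort is fully reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n, thb_range = c(10.7, 97.9), bc_range = c(7.0, 37.6),
                        musp_range = c(3.7, 11.9), saturation = 0.7,
                        b_range = c(0.5, 1.5), multiplicative_sd = 0.03,
                        additive_sd = 0.005, seed = 1) {
  stopifnot(n >= 1, diff(thb_range) >= 0, diff(bc_range) >= 0,
            diff(musp_range) >= 0, all(thb_range > 0), all(bc_range > 0),
            all(musp_range > 0), saturation >= 0, saturation <= 1,
            multiplicative_sd >= 0, additive_sd >= 0)
  structure(list(n = as.integer(n), thb_range = thb_range,
                 bc_range = bc_range, musp_range = musp_range,
                 saturation = saturation, b_range = b_range,
                 multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd, seed = seed),
            class = "cohort_spec")
}

# calibrate a power-law amplitude so the 450-600 nm mean musp hits target
calibrate_powerlaw <- function(target_mean, exponent_b, lambda0_nm = 525,
                               grid = wavelength_grid(450, 600, 2.5)) {
  unit <- mean(musp_powerlaw_at(1, exponent_b, lambda0_nm, grid_wavelengths(grid)))
  scattering_powerlaw(target_mean / unit, exponent_b, lambda0_nm)
}

#' Generate a synthetic tissue cohort
#'
#' Draws parameters uniformly within the spec ranges (total hemoglobin
#' split by the saturation; the power-law amplitude calibrated so the
#' 450-600 nm mean reduced scattering equals the drawn target),
#' simulates a spectrum for each and corrupts it with the spec's noise
#' model. Negative noisy values are clipped at zero and counted.
#'
#' @param spec A [cohort_spec()].
#' @param basis,grid,model,geometry,records Forward model configuration.
#' @return A `cohort` list: `params` (list of [tissue_parameters()]),
#'   `spectra` (list of noisy [reflectance_spectrum()]), `truth` (matrix
#'   of the drawn THb/bc/mean-musp), `clip_fraction` and the spec.
#' @export
generate_cohort <- function(spec, basis = "surrogate",
                            grid = wavelength_grid(450, 600, 2.5),
                            model = "diffusion",
                            geometry = probe_geometry(), records = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  basis <- resolve_basis(basis)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  thb <- stats::runif(spec$n, spec$thb_range[1], spec$thb_range[2])
  bc <- stats::runif(spec$n, spec$bc_range[1], spec$bc_range[2])
  musp_target <- stats::runif(spec$n, spec$musp_range[1], spec$musp_range[2])
  b <- stats::runif(spec$n, spec$b_range[1], spec$b_range[2])

  params <- lapply(seq_len(spec$n), function(i) {
    tissue_parameters(c_hbo2 = spec$saturation * thb[i],
                      c_dhb = (1 - spec$saturation) * thb[i],
                      c_bc = bc[i],
                      scattering = calibrate_powerlaw(musp_target[i], b[i],
                                                      grid = grid))
  })
  clean <- simulate_spectra(params, basis, grid, model = model,
                            geometry = geometry, records = records)
  n_clipped <- 0L
  n_values <- 0L
  spectra <- lapply(clean, function(sp) {
    v <- sp$values
    noisy <- v * (1 + stats::rnorm(length(v), 0, spec$multiplicative_sd)) +
      stats::rnorm(length(v), 0, spec$additive_sd * mean(v))
    n_clipped <<- n_clipped + sum(noisy < 0)
    n_values <<- n_values + length(noisy)
    reflectance_spectrum(sp$grid, pmax(noisy, 0), provenance = "simulated")
  })
  structure(list(params = params, spectra = spectra,
                 truth = cbind(thb_uM = thb, bc_uM = bc,
                               mean_musp = musp_target),
                 clip_fraction = n_clipped / n_values, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> n = %d, noise (mult %.3g, add %.3g), clip fraction %.2g\n",
              x$spec$n, x$spec$multiplicative_sd, x$spec$additive_sd,
              x$clip_fraction))
  invisible(x)
}

# Absorber mean-mua design of the 20-phantom study: 5 crocin steps x
# 2 hemoglobin levels, each run at 2 scattering levels.
phantom_design <- function() {
  data.frame(
    absorber_level = rep(1:2, each = 5),
    hb_mean_mua = c(0.51, 0.51, 0.51, 0.51, 0.50,
                    0.91, 0.90, 0.89, 0.89, 0.88),
    crocin_mean_mua = c(0.00, 0.48, 0.72, 0.96, 1.20,
                        0.00, 0.82, 1.23, 1.64, 2.05)
  )
}

#' Generate the liquid phantom validation set
#'
#' Builds the full factorial tissue-mimicking phantom design: 5 crocin
#' steps x 2 hemoglobin levels x 2 polystyrene-sphere scattering levels
#' (mean mus' of 9 cm^-1, representative of malignant, and 12 cm^-1,
#' representative of normal breast tissue) = 20 phantoms. Hemoglobin and
#' crocin concentrations are calibrated by linearity so each component's
#' 450-600 nm average absorption matches its design cell exactly; the
#' sphere number density is likewise calibrated to the target mean mus'.
#' Crocin plays the beta-carotene surrogate, so phantom spectra are
#' generated (and should be extracted) with a basis whose `bcar` slot
#' holds the crocin extinction curve.
#'
#' @param basis Basis list or name; must include `hbo2` and `crocin`.
#' @param musp_levels Target mean reduced scattering levels (cm^-1).
#' @param sphere_diameter_um,n_sphere,n_medium Mie sphere parameters
#'   (polystyrene in water by default).
#' @param grid Simulation grid.
#' @param geometry Probe geometry.
#' @return A `phantom_set`: `design` (one row per phantom with the
#'   achieved component mean-mua values), `params`, `spectra` and the
#'   `phantom_basis` to use for extraction.
#' @export
generate_phantom_set <- function(basis = "surrogate", musp_levels = c(9, 12),
                                 sphere_diameter_um = 1, n_sphere = 1.59,
                                 n_medium = 1.33,
                                 grid = wavelength_grid(450, 600, 2.5),
                                 geometry = probe_geometry()) {
  basis <- resolve_basis(basis)
  if (!all(c("hbo2", "crocin") %in% names(basis))) {
    stop("basis must include hbo2 and crocin absorbers")
  }
  # phantom extraction basis: crocin stands in for beta-carotene
  phantom_basis <- list(hbo2 = basis$hbo2, dhb = basis$dhb,
                        bcar = basis$crocin)
  wl <- grid_wavelengths(grid)
  unit_hb <- mean(log(10) * 1e-6 * eps_at(basis$hbo2, wl))     # mean mua at 1 uM
  unit_cr <- mean(log(10) * 1e-6 * eps_at(basis$crocin, wl))
  # Mie mean musp is linear in number density: calibrate from a probe density
  probe_density <- 1e9
  unit_musp <- mean(build_musp(scattering_mie(sphere_diameter_um, probe_density,
                                              n_sphere, n_medium), grid)) / probe_density

  des <- phantom_design()
  rows <- list()
  params <- list()
  k <- 0L
  for (m in musp_levels) {
    for (i in seq_len(nrow(des))) {
      k <- k + 1L
      scat <- scattering_mie(sphere_diameter_um, m / unit_musp,
                             n_sphere, n_medium)
      p <- tissue_parameters(c_hbo2 = des$hb_mean_mua[i] / unit_hb,
                             c_dhb = 0,
                             c_bc = if (des$crocin_mean_mua[i] > 0)
                               des$crocin_mean_mua[i] / unit_cr else 0,
                             scattering = scat)
      mua_hb <- mean(mua_at(c(hbo2 = p$c_hbo2), basis, wl))
      mua_cr <- mean(mua_at(c(crocin = p$c_bc), basis, wl))
      params[[k]] <- p
      rows[[k]] <- data.frame(
        phantom = k, absorber_level = des$absorber_level[i],
        scattering_level = m,
        hb_mean_mua = mua_hb, crocin_mean_mua = mua_cr,
        total_mean_mua = mua_hb + mua_cr,
        target_hb_mean_mua = des$hb_mean_mua[i],
        target_crocin_mean_mua = des$crocin_mean_mua[i],
        target_mean_musp = m)
    }
  }
  spectra <- simulate_spectra(params, phantom_basis, grid,
                              geometry = geometry)
  structure(list(design = do.call(rbind, rows), params = params,
                 spectra = spectra, phantom_basis = phantom_basis,
                 grid = grid),
            class = "phantom_set")
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> %d phantoms (%d absorber rows x %d scattering levels)\n",
              nrow(x$design), nrow(phantom_design()),
              length(unique(x$design$scattering_level))))
  invisible(x)
}

# Extracted ex vivo training-set property triples (THb uM, bc uM,
# mean musp cm^-1); rows 1-5, 6-10, 11-15 are the 10th-90th percentile
# selections of THb, bc and mean musp respectively.
training_triples <- function() {
  data.frame(
    sample = 1:15,
    thb_uM = c(10.7, 18.1, 32.7, 59.3, 97.9,
               55.7, 49.6, 32.8, 73.1, 95.9,
               24.2, 22.3, 40.3, 91.1, 11.5),
    bc_uM = c(7.5, 21.7, 18.6, 21.0, 16.6,
              7.0, 11.3, 17.5, 26.0, 37.6,
              13.6, 29.3, 31.3, 15.8, 30.8),
    mean_musp = c(4.1, 5.3, 11.5, 8.0, 4.4,
                  3.9, 9.2, 6.3, 8.8, 8.4,
                  3.7, 4.8, 6.5, 8.9, 11.9)
  )
}

#' Training-set tissue parameter fixture
#'
#' The 15 ex vivo breast tissue property triples used as the wavelength
#' optimization training set, materialized as full parameter sets: the
#' printed THb is split by a configurable oxygen saturation (the source
#' table does not report the oxy/deoxy split), and the power-law
#' amplitude is calibrated so the 450-600 nm mean reduced scattering
#' equals the printed value with the default exponent.
#'
#' @param saturation Assumed hemoglobin oxygen saturation (default 0.7).
#' @param exponent_b Scattering power-law exponent (default 1).
#' @return List of 15 [tissue_parameters()]; the printed triples are in
#'   `attr(, "table")`.
#' @export
training_tissue_fixture <- function(saturation = 0.7, exponent_b = 1) {
  tab <- training_triples()
  params <- lapply(seq_len(nrow(tab)), function(i) {
    tissue_parameters(c_hbo2 = saturation * tab$thb_uM[i],
                      c_dhb = (1 - saturation) * tab$thb_uM[i],
                      c_bc = tab$bc_uM[i],
                      scattering = calibrate_powerlaw(tab$mean_musp[i],
                                                      exponent_b))
  })
  attr(params, "table") <- tab
  params
}
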