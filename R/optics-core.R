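#' Wavelength grid
#'
#' Constructs an inclusive, evenly spaced wavelength grid. Grids are the
#' common currency of the package: spectra, absorber bases and optical
#' properties are all sampled on one. The endpoints are inclusive, so a
#' 450--600 nm grid in 10 nm steps has 16 points and the same range in
#' 2.5 nm steps has 61.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Increment (nm); `stop_nm - start_nm` must be an integer
#'   multiple of it (to within a small tolerance, so 2.5 nm steps are safe).
#'
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and `count`.
#' @examples
#' g <- wavelength_grid(450, 600, 2.5)
#' g$count            # 61
#' head(grid_wavelengths(g))
#' @export
wavelength_grid <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (stop_nm <= start_nm) stop("stop_nm must exceed start_nm")
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-8 * max(1, n_steps)) {
    stop("(stop_nm - start_nm) must be an integer multiple of step_nm")
  }
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         count = as.integer(round(n_steps)) + 1L),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g:%g:%g nm (%d points)\n",
              x$start_nm, x$step_nm, x$stop_nm, x$count))
  invisible(x)
}

#' Wavelengths of a grid
#'
#' Integer index arithmetic scaled by the step, so fractional steps such as
#' 2.5 nm do not accumulate floating drift.
#'
#' @param grid A [wavelength_grid()].
#' @return Ascending numeric vector of length `grid$count`.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + (seq_len(grid$count) - 1L) * grid$step_nm
}

#' Absorber extinction spectrum
#'
#' A tabulated molar extinction curve for one chromophore, on its own
#' (typically dense) wavelength support. Values are decadic molar
#' extinction coefficients in cm^-1 M^-1; the ln(10) conversion to a
#' natural-log absorption coefficient happens in [build_mua()].
#'
#' @param name Identifier, e.g. `"hbo2"`.
#' @param wavelengths_nm Strictly increasing wavelengths (nm).
#' @param molar_extinction Non-negative extinction values (cm^-1 M^-1),
#'   same length as `wavelengths_nm`.
#' @return An `absorber_spectrum` object.
#' @export
absorber_spectrum <- function(name, wavelengths_nm, molar_extinction) {
  stopifnot(length(wavelengths_nm) == length(molar_extinction),
            length(wavelengths_nm) >= 2)
  if (any(diff(wavelengths_nm) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(molar_extinction < 0)) stop("extinction values must be >= 0")
  structure(
    list(name = name,
         wavelengths_nm = as.numeric(wavelengths_nm),
         molar_extinction = as.numeric(molar_extinction)),
    class = "absorber_spectrum"
  )
}

#' @export
print.absorber_spectrum <- function(x, ...) {
  cat(sprintf("<absorber_spectrum> %s: %d points, %g-%g nm\n", x$name,
              length(x$wavelengths_nm), min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

# Linear interpolation of an absorber's extinction at arbitrary
# wavelengths; extrapolation beyond the tabulated support is refused.
eps_at <- function(absorber, wl) {
  rng <- range(absorber$wavelengths_nm)
  if (min(wl) < rng[1] - 1e-9 || max(wl) > rng[2] + 1e-9) {
    stop(sprintf("wavelengths %g-%g nm extend beyond support of absorber '%s' (%g-%g nm)",
                 min(wl), max(wl), absorber$name, rng[1], rng[2]))
  }
  stats::approx(absorber$wavelengths_nm, absorber$molar_extinction,
                xout = wl, rule = 1)$y
}

interp_absorber <- function(absorber, grid) {
  eps_at(absorber, grid_wavelengths(grid))
}

# mua at arbitrary wavelengths from raw concentrations (uM)
mua_at <- function(conc_uM, basis, wl) {
  mua <- numeric(length(wl))
  for (nm in names(conc_uM)) {
    if (conc_uM[[nm]] > 0) {
      mua <- mua + eps_at(basis[[nm]], wl) * conc_uM[[nm]] * 1e-6
    }
  }
  log(10) * mua
}

# power-law mus' at arbitrary wavelengths
musp_powerlaw_at <- function(amplitude_a, exponent_b, lambda0_nm, wl) {
  amplitude_a * (wl / lambda0_nm)^(-exponent_b)
}

#' Scattering models
#'
#' Two parameterizations of the reduced scattering coefficient mus'(lambda):
#' a wavelength power law `a * (lambda/lambda0)^(-b)` (the usual empirical
#' tissue model) and a monodisperse Mie sphere suspension (polystyrene
#' microsphere phantoms), for which mus' = rho * Csca * (1 - g) with the
#' scattering cross-section and asymmetry factor from Mie theory.
#'
#' @param amplitude_a Reduced scattering at the reference wavelength (cm^-1).
#' @param exponent_b Dimensionless scattering power (Mie-like ~0.5-2 in tissue).
#' @param lambda0_nm Reference wavelength (nm).
#' @return A `scattering_model` object.
#' @export
scattering_powerlaw <- function(amplitude_a, exponent_b, lambda0_nm = 525) {
  stopifnot(amplitude_a > 0, lambda0_nm > 0)
  structure(list(kind = "power_law", amplitude_a = amplitude_a,
                 exponent_b = exponent_b, lambda0_nm = lambda0_nm),
            class = "scattering_model")
}

#' @param sphere_diameter_um Sphere diameter (micrometers).
#' @param number_density_per_ml Spheres per milliliter (= per cm^3).
#' @param n_sphere Sphere refractive index (1.59 for polystyrene).
#' @param n_medium Medium refractive index (1.33 for water).
#' @rdname scattering_powerlaw
#' @export
scattering_mie <- function(sphere_diameter_um, number_density_per_ml,
                           n_sphere = 1.59, n_medium = 1.33) {
  stopifnot(sphere_diameter_um > 0, number_density_per_ml > 0,
            n_sphere > 0, n_medium > 0)
  structure(list(kind = "mie_sphere", sphere_diameter_um = sphere_diameter_um,
                 number_density_per_ml = number_density_per_ml,
                 n_sphere = n_sphere, n_medium = n_medium),
            class = "scattering_model")
}

#' Tissue parameter set
#'
#' The unknowns of the inverse problem: oxy- and deoxy-hemoglobin and
#' beta-carotene concentrations (micromolar) plus a scattering model.
#' Total hemoglobin `THb = c_hbo2 + c_dhb` and the 450--600 nm mean
#' reduced scattering are derived summaries, see [tissue_summaries()].
#'
#' @param c_hbo2,c_dhb,c_bc Concentrations in micromolar, all >= 0.
#' @param scattering A `scattering_model`.
#' @return A `tissue_parameters` object.
#' @export
tissue_parameters <- function(c_hbo2, c_dhb, c_bc, scattering) {
  stopifnot(c_hbo2 >= 0, c_dhb >= 0, c_bc >= 0,
            inherits(scattering, "scattering_model"))
  structure(list(c_hbo2 = c_hbo2, c_dhb = c_dhb, c_bc = c_bc,
                 scattering = scattering),
            class = "tissue_parameters")
}

#' @export
print.tissue_parameters <- function(x, ...) {
  cat(sprintf("<tissue_parameters> THb %.1f uM (sat %.2f), bc %.1f uM, %s scattering\n",
              x$c_hbo2 + x$c_dhb,
              if (x$c_hbo2 + x$c_dhb > 0) x$c_hbo2 / (x$c_hbo2 + x$c_dhb) else NA_real_,
              x$c_bc, x$scattering$kind))
  invisible(x)
}

#' Summaries of a tissue parameter set
#'
#' @param params A [tissue_parameters()] object.
#' @param lo_nm,hi_nm Averaging window for the mean reduced scattering.
#' @param step_nm Sampling step used for the average.
#' @return Named numeric vector with `thb_uM`, `bc_uM`, `mean_musp` (cm^-1).
#' @export
tissue_summaries <- function(params, lo_nm = 450, hi_nm = 600, step_nm = 2.5) {
  grid <- wavelength_grid(lo_nm, hi_nm, step_nm)
  musp <- build_musp(params$scattering, grid)
  c(thb_uM = params$c_hbo2 + params$c_dhb,
    bc_uM = params$c_bc,
    mean_musp = mean(musp))
}

#' Absorption coefficient from concentrations
#'
#' Builds mua(lambda) = ln(10) * sum_i eps_i(lambda) * c_i, with decadic
#' molar extinctions eps_i in cm^-1 M^-1 and concentrations converted from
#' micromolar to molar. Absorption is additive over chromophores.
#'
#' @param params A [tissue_parameters()] object.
#' @param basis Named list of [absorber_spectrum()] objects; must contain
#'   `hbo2`, `dhb` and `bcar` entries covering the grid range.
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of mua (cm^-1), one value per grid point.
#' @export
build_mua <- function(params, basis, grid) {
  stopifnot(inherits(params, "tissue_parameters"))
  needed <- c("hbo2", "dhb", "bcar")
  missing <- setdiff(needed, names(basis))
  if (length(missing)) stop("basis is missing absorbers: ", paste(missing, collapse = ", "))
  conc_uM <- c(hbo2 = params$c_hbo2, dhb = params$c_dhb, bcar = params$c_bc)
  mua <- numeric(grid$count)
  for (nm in needed) {
    if (conc_uM[[nm]] > 0) {
      mua <- mua + interp_absorber(basis[[nm]], grid) * conc_uM[[nm]] * 1e-6
    }
  }
  log(10) * mua
}

#' Reduced scattering coefficient on a grid
#'
#' @param scattering A `scattering_model` from [scattering_powerlaw()] or
#'   [scattering_mie()].
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of mus' (cm^-1), strictly positive.
#' @export
build_musp <- function(scattering, grid) {
  stopifnot(inherits(scattering, "scattering_model"))
  wl <- grid_wavelengths(grid)
  if (scattering$kind == "power_law") {
    scattering$amplitude_a * (wl / scattering$lambda0_nm)^(-scattering$exponent_b)
  } else if (scattering$kind == "mie_sphere") {
    radius_cm <- scattering$sphere_diameter_um / 2 * 1e-4
    vapply(wl, function(lam) {
      # size parameter in the medium; wavelength converted nm -> um
      x <- pi * scattering$sphere_diameter_um * scattering$n_medium / (lam * 1e-3)
      eff <- mie_efficiencies(x, scattering$n_sphere / scattering$n_medium)
      csca <- eff$qsca * pi * radius_cm^2
      scattering$number_density_per_ml * csca * (1 - eff$g)
    }, numeric(1))
  } else {
    stop("unsupported scattering model kind: ", scattering$kind)
  }
}

#' Mean reduced scattering over a wavelength window
#'
#' Arithmetic mean of the mus' samples with lo <= lambda <= hi.
#'
#' @param musp Numeric vector of mus' values matching `grid`.
#' @param grid The [wavelength_grid()] `musp` is sampled on.
#' @param lo_nm,hi_nm Window endpoints (inclusive).
#' @return Scalar mean (cm^-1).
#' @export
mean_musp <- function(musp, grid, lo_nm = 450, hi_nm = 600) {
  stopifnot(length(musp) == grid$count)
  wl <- grid_wavelengths(grid)
  sel <- wl >= lo_nm - 1e-9 & wl <= hi_nm + 1e-9
  if (!any(sel)) stop("averaging window contains no grid samples")
  mean(musp[sel])
}

#' Optical properties container
#'
#' @param grid A [wavelength_grid()].
#' @param mua,musp Numeric vectors (cm^-1) matching the grid count.
#' @return An `optical_properties` object.
#' @export
optical_properties <- function(grid, mua, musp) {
  stopifnot(inherits(grid, "wavelength_grid"),
            length(mua) == grid$count, length(musp) == grid$count)
  if (any(mua < 0) || any(musp < 0)) stop("mua and musp must be >= 0")
  structure(list(grid = grid, mua = as.numeric(mua), musp = as.numeric(musp)),
            class = "optical_properties")
}

#' Optical properties of a tissue parameter set
#'
#' Convenience composition of [build_mua()] and [build_musp()].
#'
#' @inheritParams build_mua
#' @return An [optical_properties()] object.
#' @export
tissue_optics <- function(params, basis, grid) {
  optical_properties(grid,
                     mua = build_mua(params, basis, grid),
                     musp = build_musp(params$scattering, grid))
}
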