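#' Calibrated diffuse reflectance spectrum
#'
#' @param grid A [wavelength_grid()].
#' @param values Non-negative reflectance values, one per grid point.
#' @param provenance `"simulated"` or `"measured"`.
#' @param fwhm_nm Bandpass tag: the Gaussian FWHM the spectrum has been
#'   degraded with (0 = ideal monochromatic sampling).
#' @return A `reflectance_spectrum` object.
#' @export
reflectance_spectrum <- function(grid, values,
                                 provenance = c("simulated", "measured"),
                                 fwhm_nm = 0) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(grid, "wavelength_grid"), length(values) == grid$count,
            fwhm_nm >= 0)
  if (any(values < 0)) stop("reflectance values must be >= 0")
  structure(list(grid = grid, values = as.numeric(values),
                 provenance = provenance, fwhm_nm = fwhm_nm),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d points %g-%g nm, %s, fwhm %g nm\n",
              x$grid$count, x$grid$start_nm, x$grid$stop_nm, x$provenance,
              x$fwhm_nm))
  invisible(x)
}

#' Probe geometry configuration
#'
#' Describes the source-detector arrangement the forward models evaluate:
#' a pencil source and a detector at a single source-detector separation
#' (the default 0.075 cm is the inner radius of an annular photodiode
#' epoxied around the illumination fiber). `n_rel` is the tissue/ambient
#' relative refractive index used for the boundary condition.
#'
#' @param sd_sep_cm Source-detector separation (cm).
#' @param n_rel Relative refractive index of the medium (> 1 for
#'   tissue against air/epoxy).
#' @param annulus_halfwidth_cm Half-width of the detection annulus used by
#'   the photon-record model (cm).
#' @return A list used by [forward_reflectance()].
#' @export
probe_geometry <- function(sd_sep_cm = 0.075, n_rel = 1.4,
                           annulus_halfwidth_cm = 0.0125) {
  stopifnot(sd_sep_cm > 0, n_rel > 0, annulus_halfwidth_cm > 0,
            annulus_halfwidth_cm < sd_sep_cm)
  list(sd_sep_cm = sd_sep_cm, n_rel = n_rel,
       annulus_halfwidth_cm = annulus_halfwidth_cm)
}

# Unpolarized Fresnel reflection coefficient for internal incidence,
# cosine(s) of the incidence angle, relative index n (medium/outside).
fresnel_reflect <- function(cos_i, n_rel) {
  cos_i <- pmin(pmax(cos_i, 0), 1)
  sin_i <- sqrt(1 - cos_i^2)
  sin_t <- n_rel * sin_i
  r <- numeric(length(cos_i))
  tir <- sin_t >= 1
  r[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    cos_t <- sqrt(1 - sin_t[ok]^2)
    rs <- ((n_rel * cos_i[ok] - cos_t) / (n_rel * cos_i[ok] + cos_t))^2
    rp <- ((n_rel * cos_t - cos_i[ok]) / (n_rel * cos_t + cos_i[ok]))^2
    r[ok] <- (rs + rp) / 2
  }
  r
}

.boundary_cache <- new.env(parent = emptyenv())

# First and second angular moments of the internal Fresnel reflection,
# used both for the extrapolated-boundary distance and for the
# partial-current radiance-to-reflectance coefficients. Memoized: the
# quadratures are constant for a given relative index and the inverse
# model evaluates the forward model thousands of times.
boundary_moments <- function(n_rel) {
  key <- sprintf("%.10g", n_rel)
  hit <- .boundary_cache[[key]]
  if (!is.null(hit)) return(hit)
  # split at the critical angle (integrand kink); beyond it total internal
  # reflection makes the tails analytic
  thc <- if (n_rel > 1) asin(1 / n_rel) else pi / 2
  tail_phi <- if (n_rel > 1) cos(thc)^2 else 0
  tail_j <- if (n_rel > 1) cos(thc)^3 else 0
  r_phi <- stats::integrate(function(th) {
    2 * sin(th) * cos(th) * fresnel_reflect(cos(th), n_rel)
  }, 0, thc, rel.tol = 1e-12)$value + tail_phi
  r_j <- stats::integrate(function(th) {
    3 * sin(th) * cos(th)^2 * fresnel_reflect(cos(th), n_rel)
  }, 0, thc, rel.tol = 1e-12)$value + tail_j
  reff <- (r_phi + r_j) / (2 - r_phi + r_j)
  out <- list(r_phi = r_phi, r_j = r_j, reff = reff,
              a_coef = (1 + reff) / (1 - reff))
  .boundary_cache[[key]] <- out
  out
}

# Steady-state dipole diffusion reflectance at radial distance rho on a
# semi-infinite medium: isotropic point source at depth z0 = 1/mut',
# negative image across the extrapolated boundary at -(z0 + 2 zb), and
# the detected signal assembled from fluence and flux with the
# partial-current coefficients (1 - R_phi)/4 and (1 - R_j)/2.
diffusion_reflectance <- function(mua, musp, rho, n_rel) {
  bm <- boundary_moments(n_rel)
  mut <- mua + musp
  d_coef <- 1 / (3 * mut)
  mueff <- sqrt(3 * mua * mut)
  z0 <- 1 / mut
  zb <- 2 * bm$a_coef * d_coef
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  phi <- (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * d_coef)
  jz <- (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
           (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
  (1 - bm$r_phi) / 4 * phi + (1 - bm$r_j) / 2 * jz
}

#' Photon record set for scaled Monte Carlo reflectance
#'
#' Runs a small seeded transport simulation in the reduced (isotropic
#' scattering, similarity) description of a semi-infinite, absorption-free
#' medium with scattering coefficient `baseline_musp`, and stores, for
#' every photon detected in the annulus at the probe separation, its exit
#' weight and total path length. [forward_reflectance()] with
#' `model = "scaled_mc"` then rescales these records to any target optical
#' properties via Beer-Lambert attenuation with path lengths scaled by
#' `baseline_musp / musp(lambda)`.
#'
#' Boundary handling: at each surface crossing the photon is either
#' internally reflected (probability given by the unpolarized Fresnel
#' coefficient at its incidence angle) and continues, or escapes and is
#' recorded. The exponential step distribution is memoryless, so a fresh
#' step is drawn after each internal reflection without bias.
#'
#' @param n_photons Number of photons launched.
#' @param baseline_musp Scattering coefficient of the baseline simulation
#'   (cm^-1; reduced/isotropic description).
#' @param geometry A [probe_geometry()].
#' @param seed Integer seed for the simulation RNG.
#' @param max_steps Walk-length cap; photons still inside after this many
#'   scattering events are dropped (a negligible, deep-wandering fraction).
#' @return A `photon_records` object with `weights`, `path_lengths_cm`,
#'   `baseline_musp`, `n_launched` and the geometry.
#' @export
simulate_photon_records <- function(n_photons = 1e5, baseline_musp = 10,
                                    geometry = probe_geometry(), seed = 1,
                                    max_steps = 4000) {
  stopifnot(n_photons >= 1, baseline_musp > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- as.integer(n_photons)
  pos <- matrix(0, n, 3)
  dir <- matrix(rep(c(0, 0, 1), each = n), n, 3)  # launched downward (+z into medium)
  path <- numeric(n)
  alive <- rep(TRUE, n)
  out_w <- numeric(0)
  out_l <- numeric(0)
  out_r <- numeric(0)

  for (step in seq_len(max_steps)) {
    idx <- which(alive)
    if (!length(idx)) break
    s <- stats::rexp(length(idx), rate = baseline_musp)
    newpos <- pos[idx, , drop = FALSE] + dir[idx, , drop = FALSE] * s
    crossing <- newpos[, 3] < 0
    if (any(crossing)) {
      ci <- idx[crossing]
      uz <- dir[ci, 3]
      # distance along the segment to the surface
      t_hit <- -pos[ci, 3] / uz
      bx <- pos[ci, 1] + dir[ci, 1] * t_hit
      by <- pos[ci, 2] + dir[ci, 2] * t_hit
      path[ci] <- path[ci] + t_hit
      rf <- fresnel_reflect(-uz, geometry$n_rel)
      escapes <- stats::runif(length(ci)) >= rf
      esc <- ci[escapes]
      if (length(esc)) {
        out_w <- c(out_w, rep(1, length(esc)))
        out_l <- c(out_l, path[esc])
        out_r <- c(out_r, sqrt(bx[escapes]^2 + by[escapes]^2))
        alive[esc] <- FALSE
      }
      refl <- ci[!escapes]
      if (length(refl)) {
        # move to the surface, flip direction, fresh memoryless step next round
        pos[refl, 1] <- bx[!escapes]
        pos[refl, 2] <- by[!escapes]
        pos[refl, 3] <- 0
        dir[refl, 3] <- -dir[refl, 3]
      }
      # photons that stayed inside scatter at their new position
      stay <- idx[!crossing]
      if (length(stay)) {
        pos[stay, ] <- newpos[!crossing, , drop = FALSE]
        path[stay] <- path[stay] + s[!crossing]
        dir[stay, ] <- .isotropic_dirs(length(stay))
      }
    } else {
      pos[idx, ] <- newpos
      path[idx] <- path[idx] + s
      dir[idx, ] <- .isotropic_dirs(length(idx))
    }
  }

  sel <- abs(out_r - geometry$sd_sep_cm) <= geometry$annulus_halfwidth_cm
  structure(list(weights = out_w[sel], path_lengths_cm = out_l[sel],
                 baseline_musp = baseline_musp, n_launched = n,
                 geometry = geometry, seed = seed),
            class = "photon_records")
}

#' @export
print.photon_records <- function(x, ...) {
  cat(sprintf("<photon_records> %d detected / %d launched, baseline musp %g cm^-1\n",
              length(x$weights), x$n_launched, x$baseline_musp))
  invisible(x)
}

.isotropic_dirs <- function(n) {
  uz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - uz^2)
  cbind(st * cos(phi), st * sin(phi), uz)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Forward diffuse reflectance
#'
#' Maps optical properties to the calibrated reflectance the probe would
#' record at each wavelength, under one of two interchangeable forward
#' models: `"diffusion"`, the closed-form extrapolated-boundary dipole
#' solution for a semi-infinite medium evaluated at the source-detector
#' separation, or `"scaled_mc"`, Beer-Lambert rescaling of a stored
#' absorption-free photon-record set (path lengths scaled by
#' `baseline_musp / musp(lambda)` before attenuation by `mua(lambda)`).
#'
#' @param props An [optical_properties()] object.
#' @param model `"diffusion"` or `"scaled_mc"`.
#' @param geometry A [probe_geometry()].
#' @param records A `photon_records` object (required for `"scaled_mc"`).
#' @return A [reflectance_spectrum()] on the same grid (cm^-2 sr-free
#'   calibrated units), strictly positive.
#' @export
forward_reflectance <- function(props, model = c("diffusion", "scaled_mc"),
                                geometry = probe_geometry(), records = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(props, "optical_properties"))
  if (any(props$musp <= 0)) stop("musp must be strictly positive")
  if (model == "diffusion") {
    # diffusion theory degrades when the separation falls well below a
    # transport mean free path; closer probes still evaluate, with a warning
    if (geometry$sd_sep_cm * min(props$mua + props$musp) < 0.25) {
      warning("source-detector separation is below half a transport mean ",
              "free path; diffusion model accuracy degrades")
    }
    vals <- diffusion_reflectance(props$mua, props$musp,
                                  rho = geometry$sd_sep_cm,
                                  n_rel = geometry$n_rel)
  } else {
    if (is.null(records) || !inherits(records, "photon_records")) {
      stop("scaled_mc requires a photon_records object (see simulate_photon_records)")
    }
    area <- pi * ((records$geometry$sd_sep_cm + records$geometry$annulus_halfwidth_cm)^2 -
                    (records$geometry$sd_sep_cm - records$geometry$annulus_halfwidth_cm)^2)
    scale <- records$baseline_musp / props$musp
    vals <- vapply(seq_len(props$grid$count), function(k) {
      sum(records$weights *
            exp(-props$mua[k] * records$path_lengths_cm * scale[k]))
    }, numeric(1)) / (records$n_launched * area)
  }
  reflectance_spectrum(props$grid, vals, provenance = "simulated", fwhm_nm = 0)
}

#' Gaussian bandpass degradation
#'
#' Convolves a spectrum with a Gaussian source profile of the given FWHM,
#' emulating illumination through a bandpass filter or LED instead of a
#' monochromatic line. The kernel has sigma = fwhm / (2 sqrt(2 ln 2)), is
#' discretized on the spectrum's grid, truncated at +/- 3 sigma, and
#' renormalized to unit sum per output sample so band edges are handled
#' without inventing out-of-band reflectance. `fwhm_nm = 0` is the
#' identity. A caller-supplied unit-sum `kernel` (e.g. a measured LED
#' line shape, already sampled on the grid step) overrides the Gaussian.
#'
#' @param spectrum A [reflectance_spectrum()] on a uniform grid.
#' @param fwhm_nm Full width at half maximum of the Gaussian (nm, >= 0).
#' @param kernel Optional numeric vector of odd length: a custom source
#'   shape centered on its middle element; normalized internally.
#' @return The degraded [reflectance_spectrum()], tagged with `fwhm_nm`.
#' @export
convolve_bandpass <- function(spectrum, fwhm_nm, kernel = NULL) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  if (is.null(kernel)) {
    if (fwhm_nm < 0) stop("fwhm_nm must be >= 0")
    if (fwhm_nm == 0) return(spectrum)
    sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
    half <- floor(3 * sigma / spectrum$grid$step_nm)
    offs <- (-half):half
    kernel <- exp(-(offs * spectrum$grid$step_nm)^2 / (2 * sigma^2))
  } else {
    if (length(kernel) %% 2 == 0) stop("custom kernel must have odd length")
    if (any(kernel < 0)) stop("kernel weights must be >= 0")
    half <- (length(kernel) - 1) / 2
    offs <- (-half):half
  }
  v <- spectrum$values
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    w <- kernel[ok]
    out[i] <- sum(w * v[j[ok]]) / sum(w)
  }
  reflectance_spectrum(spectrum$grid, out, provenance = spectrum$provenance,
                       fwhm_nm = fwhm_nm)
}

#' Simulate reflectance spectra for a list of tissue parameter sets
#'
#' @param params_list List of [tissue_parameters()].
#' @param basis Absorber basis (see [surrogate_basis()]).
#' @param grid A [wavelength_grid()].
#' @param model,geometry,records Passed to [forward_reflectance()].
#' @return List of [reflectance_spectrum()], one per parameter set;
#'   deterministic given the model and geometry.
#' @export
simulate_spectra <- function(params_list, basis, grid,
                             model = "diffusion",
                             geometry = probe_geometry(), records = NULL) {
  stopifnot(length(params_list) >= 1)
  lapply(params_list, function(p) {
    forward_reflectance(tissue_optics(p, basis, grid), model = model,
                        geometry = geometry, records = records)
  })
}
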