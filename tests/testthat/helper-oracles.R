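# Independent oracles and shared fixtures for the test suite.

# ---- shared fixtures (built once per test run) ----

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, create) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- create()
  .fixtures[[name]]
}

tt_grid <- function() wavelength_grid(450, 600, 2.5)

tt_basis <- function() fixture("basis", surrogate_basis)

tt_training <- function() {
  fixture("training", function() {
    suppressWarnings(build_training_set(training_tissue_fixture()))
  })
}

tt_records <- function() {
  fixture("records", function() {
    simulate_photon_records(n_photons = 5e4, baseline_musp = 10, seed = 42)
  })
}

# ---- Mie series oracle ----
# Brute-force Mie coefficients from half-integer-order Bessel functions
# (base R besselJ/besselY), Wiscombe-terminated upward summation. A
# deliberately different code path from the package's downward-recurrence
# implementation.
oracle_mie <- function(x, m) {
  nstop <- floor(x + 4 * x^(1/3) + 2)
  psi <- function(n, z) z * sqrt(pi / (2 * z)) * besselJ(z, n + 0.5)
  chi <- function(n, z) -z * sqrt(pi / (2 * z)) * besselY(z, n + 0.5)
  xi <- function(n, z) complex(real = psi(n, z), imaginary = -chi(n, z))
  dpsi <- function(n, z) psi(n - 1, z) - n / z * psi(n, z)
  dxi <- function(n, z) xi(n - 1, z) - n / z * xi(n, z)
  mx <- m * x
  n <- seq_len(nstop)
  an <- bn <- complex(length.out = nstop)
  for (k in n) {
    an[k] <- (m * psi(k, mx) * dpsi(k, x) - psi(k, x) * dpsi(k, mx)) /
      (m * psi(k, mx) * dxi(k, x) - xi(k, x) * dpsi(k, mx))
    bn[k] <- (psi(k, mx) * dpsi(k, x) - m * psi(k, x) * dpsi(k, mx)) /
      (psi(k, mx) * dxi(k, x) - m * xi(k, x) * dpsi(k, mx))
  }
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  qext <- (2 / x^2) * sum((2 * n + 1) * Re(an + bn))
  n1 <- n[-nstop]
  g <- 4 / (x^2 * qsca) *
    (sum(n1 * (n1 + 2) / (n1 + 1) *
           Re(an[n1] * Conj(an[n1 + 1]) + bn[n1] * Conj(bn[n1 + 1]))) +
       sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn))))
  list(qext = qext, qsca = qsca, g = g)
}

# ---- dipole diffusion oracle ----
# Independent re-derivation of the extrapolated-boundary dipole
# reflectance: boundary moments by composite Simpson quadrature (split at
# the critical angle, analytic total-internal-reflection tail), the flux
# by Richardson-extrapolated numerical differentiation of the analytic
# dipole fluence.
oracle_diffusion <- function(mua, musp, rho, n_rel) {
  fresnel <- function(th) {
    ci <- cos(th); si <- sin(th)
    st <- n_rel * si
    if (st >= 1) return(1)
    ct <- sqrt(1 - st^2)
    rs <- ((n_rel * ci - ct) / (n_rel * ci + ct))^2
    rp <- ((n_rel * ct - ci) / (n_rel * ct + ci))^2
    (rs + rp) / 2
  }
  simpson <- function(f, a, b, n = 4000) {
    h <- (b - a) / n
    xs <- a + h * 0:n
    ys <- vapply(xs, f, numeric(1))
    h / 3 * (ys[1] + ys[n + 1] + 4 * sum(ys[seq(2, n, 2)]) +
               2 * sum(ys[seq(3, n - 1, 2)]))
  }
  thc <- if (n_rel > 1) asin(1 / n_rel) else pi / 2
  # substitute th = thc - u^2: the Fresnel curve has a sqrt singularity in
  # its derivative at the critical angle, smooth in u
  moment <- function(f) {
    simpson(function(u) f(thc - u^2) * 2 * u, 0, sqrt(thc))
  }
  # analytic tails over (thc, pi/2) where total internal reflection gives
  # RF = 1: integral of 2 sin cos = cos^2(thc); of 3 sin cos^2 = cos^3(thc)
  r_phi <- moment(function(th) 2 * sin(th) * cos(th) * fresnel(th)) +
    if (n_rel > 1) cos(thc)^2 else 0
  r_j <- moment(function(th) 3 * sin(th) * cos(th)^2 * fresnel(th)) +
    if (n_rel > 1) cos(thc)^3 else 0
  reff <- (r_phi + r_j) / (2 - r_phi + r_j)
  a_coef <- (1 + reff) / (1 - reff)

  mut <- mua + musp
  d_coef <- 1 / (3 * mut)
  mueff <- sqrt(3 * mua * mut)
  z0 <- 1 / mut
  zb <- 2 * a_coef * d_coef
  fluence <- function(z) {
    r1 <- sqrt(rho^2 + (z - z0)^2)
    r2 <- sqrt(rho^2 + (z + z0 + 2 * zb)^2)
    (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * d_coef)
  }
  richardson <- function(f, x, h) {
    d1 <- (f(x + h) - f(x - h)) / (2 * h)
    d2 <- (f(x + h / 2) - f(x - h / 2)) / h
    d3 <- (f(x + h / 4) - f(x - h / 4)) / (h / 2)
    e1 <- (4 * d2 - d1) / 3
    e2 <- (4 * d3 - d2) / 3
    (16 * e2 - e1) / 15
  }
  # outward flux through the surface: J_out = +D dphi/dz at z = 0 (z into
  # the medium, true source at +z0, so the fluence gradient points inward)
  jz <- d_coef * richardson(fluence, 0, 1e-3 * z0)
  (1 - r_phi) / 4 * fluence(0) + (1 - r_j) / 2 * jz
}
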