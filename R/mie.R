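#' Mie efficiencies for a homogeneous sphere
#'
#' Scattering/extinction efficiencies and the asymmetry factor for a
#' sphere of size parameter `x` and relative refractive index `m`,
#' computed from the Bohren--Huffman series: the logarithmic derivative
#' of the internal field by downward recurrence, Riccati-Bessel functions
#' of the external field by upward recurrence, and the series truncated
#' at the Wiscombe order `x + 4 x^(1/3) + 2`.
#'
#' @param x Size parameter `pi * d * n_medium / lambda` (dimensionless, > 0).
#' @param m Refractive index of the sphere relative to the medium
#'   (real or complex).
#' @return List with `qext`, `qsca` (efficiencies) and `g` (asymmetry
#'   factor, the mean cosine of the scattering angle).
#' @examples
#' mie_efficiencies(5, 1.59 / 1.33)
#' @export
mie_efficiencies <- function(x, m) {
  stopifnot(is.numeric(x), length(x) == 1, x > 0)
  m <- as.complex(m)
  nstop <- floor(x + 4 * x^(1/3) + 2)
  mx <- m * x
  nmx <- max(nstop, ceiling(Mod(mx))) + 15

  # downward recurrence for D_n(mx) = d/d(mx) ln psi_n(mx)
  d <- complex(length.out = nmx + 1)  # d[k] holds D_{k-1}
  for (n in nmx:1) {
    d[n] <- n / mx - 1 / (d[n + 1] + n / mx)
  }

  an <- complex(length.out = nstop)
  bn <- complex(length.out = nstop)
  psi0 <- cos(x); psi1 <- sin(x)    # psi_{-1}, psi_0
  chi0 <- -sin(x); chi1 <- cos(x)   # chi_{-1}, chi_0
  xi1 <- complex(real = psi1, imaginary = -chi1)
  for (n in seq_len(nstop)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    dn <- d[n + 1]
    ta <- dn / m + n / x
    tb <- dn * m + n / x
    an[n] <- (ta * psi - psi1) / (ta * xi - xi1)
    bn[n] <- (tb * psi - psi1) / (tb * xi - xi1)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
    xi1 <- xi
  }

  n <- seq_len(nstop)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  qext <- (2 / x^2) * sum((2 * n + 1) * Re(an + bn))
  # asymmetry factor from the cross products of adjacent orders
  n1 <- n[-nstop]
  g_sum <- sum(n1 * (n1 + 2) / (n1 + 1) *
                 Re(an[n1] * Conj(an[n1 + 1]) + bn[n1] * Conj(bn[n1 + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn)))
  g <- 4 / (x^2 * qsca) * g_sum
  list(qext = qext, qsca = qsca, g = g)
}
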