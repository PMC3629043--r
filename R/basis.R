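#' Synthetic surrogate absorber basis
#'
#' A fully self-contained extinction basis built from Gaussian bands that
#' mimic the qualitative structure of the real chromophores in the
#' 450--600 nm window: an oxyhemoglobin alpha/beta doublet near 542 and
#' 577 nm with a blue-side (Soret tail) background, a single broad
#' deoxyhemoglobin band near 555 nm, a broad beta-carotene band below
#' 520 nm, and a crocin band near 440 nm (the water-soluble carotenoid
#' used as a beta-carotene stand-in in liquid phantoms). Band centers,
#' widths and peak extinctions are chosen to give tissue-realistic
#' absorption coefficients at the concentrations of interest; the basis
#' is synthetic by construction and is the one used throughout the test
#' suite, so every result in the package is reproducible without any
#' external data.
#'
#' @param step_nm Sampling step of the tabulated curves (nm).
#' @return Named list of [absorber_spectrum()] objects
#'   (`hbo2`, `dhb`, `bcar`, `crocin`) tabulated on 400--650 nm.
#' @examples
#' b <- surrogate_basis()
#' names(b)
#' @export
surrogate_basis <- function(step_nm = 1) {
  wl <- seq(400, 650, by = step_nm)
  gauss <- function(center, width) exp(-((wl - center) / width)^2)
  list(
    hbo2 = absorber_spectrum("hbo2", wl,
      52000 * gauss(542, 11) + 56000 * gauss(577, 9) +
        22000 * gauss(500, 45) + 150000 * gauss(420, 25)),
    dhb = absorber_spectrum("dhb", wl,
      50000 * gauss(555, 20) + 160000 * gauss(430, 30)),
    bcar = absorber_spectrum("bcar", wl, 130000 * gauss(462, 38)),
    crocin = absorber_spectrum("crocin", wl, 95000 * gauss(440, 36))
  )
}

#' Read an absorber extinction table from CSV
#'
#' Expects a header `wavelength_nm,extinction` with strictly increasing
#' wavelengths (nm) and non-negative decadic molar extinction values
#' (cm^-1 M^-1).
#'
#' @param path CSV file path.
#' @param name Absorber identifier; defaults to the file stem.
#' @return An [absorber_spectrum()].
#' @export
read_absorber_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "extinction") %in% names(df))) {
    stop("absorber CSV must have columns wavelength_nm,extinction: ", path)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  absorber_spectrum(name, df$wavelength_nm, df$extinction)
}

#' Bundled coarse extinction tables
#'
#' Loads the package's bundled CSV tables for oxy- and deoxyhemoglobin,
#' beta-carotene and crocin. These are coarse (10 nm) approximate curves
#' assembled to resemble the published shapes of the real chromophores;
#' they are provided for realistic-looking demonstrations and CSV
#' round-trip examples. Quantitative tests and the reproducible analyses
#' use [surrogate_basis()] instead.
#'
#' @return Named list of [absorber_spectrum()] objects.
#' @export
bundled_basis <- function() {
  dir <- system.file("extdata", package = "waveopt")
  files <- c(hbo2 = "hbo2_approx.csv", dhb = "dhb_approx.csv",
             bcar = "bcar_approx.csv", crocin = "crocin_approx.csv")
  out <- lapply(names(files), function(nm) {
    read_absorber_csv(file.path(dir, files[[nm]]), name = nm)
  })
  names(out) <- names(files)
  out
}

#' Resolve a basis by name
#'
#' @param basis Either a basis list, `"surrogate"` or `"bundled"`.
#' @return Named list of [absorber_spectrum()] objects.
#' @export
resolve_basis <- function(basis = "surrogate") {
  if (is.list(basis)) return(basis)
  switch(match.arg(basis, c("surrogate", "bundled")),
         surrogate = surrogate_basis(),
         bundled = bundled_basis())
}
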