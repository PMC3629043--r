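#' Bandpass degradation study
#'
#' Quantifies how widening the source bandpass degrades property
#' extraction. For every tissue parameter set a noiseless spectrum is
#' simulated and its full-spectrum extraction (of the undegraded
#' spectrum) taken as reference; the spectrum is then convolved with a
#' Gaussian of each FWHM and re-extracted at each candidate wavelength
#' set. The reported cell value is the mean absolute percent error over
#' all parameter sets and the three summaries, flagged acceptable when
#' below the threshold.
#'
#' @param training_params List of [tissue_parameters()].
#' @param sets Named list of [wavelength_set()] objects (or numeric
#'   vectors); use the full grid for a pure bandpass sweep.
#' @param fwhms Gaussian FWHM levels in nm (0 = undegraded).
#' @param threshold Acceptability threshold on the mean absolute percent
#'   error (default 10).
#' @param basis,grid,model,geometry,records Forward model configuration.
#' @param ... Passed to [extract_properties()].
#' @return A `bandpass_study` with a long-format `table`
#'   (set, fwhm_nm, mean_abs_error_pct, acceptable) and the per-cell
#'   signed error arrays in `details`.
#' @export
run_bandpass_study <- function(training_params, sets,
                               fwhms = c(0, 1, 5, 10, 20, 30, 40, 50),
                               threshold = 10, basis = "surrogate",
                               grid = wavelength_grid(450, 600, 2.5),
                               model = "diffusion",
                               geometry = probe_geometry(), records = NULL,
                               ...) {
  basis <- resolve_basis(basis)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  spectra <- simulate_spectra(training_params, basis, grid, model = model,
                              geometry = geometry, records = records)
  references <- lapply(spectra, extract_properties, subset = NULL,
                       basis = basis, model = model, geometry = geometry,
                       records = records, ...)

  rows <- list()
  details <- list()
  for (f in fwhms) {
    degraded <- lapply(spectra, convolve_bandpass, fwhm_nm = f)
    for (s in names(sets)) {
      wls <- sets[[s]]
      if (inherits(wls, "wavelength_set")) wls <- wls$wavelengths
      errs <- t(vapply(seq_along(degraded), function(i) {
        ex <- extract_properties(degraded[[i]], subset = wls, basis = basis,
                                 model = model, geometry = geometry,
                                 records = records, ...)
        extraction_errors(ex, references[[i]])
      }, numeric(3)))
      mae <- mean(abs(errs))
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, fwhm_nm = f, mean_abs_error_pct = mae,
        acceptable = mae < threshold)
      details[[paste(s, f, sep = "@")]] <- errs
    }
  }
  structure(list(table = do.call(rbind, rows), details = details,
                 fwhms = fwhms, threshold = threshold),
            class = "bandpass_study")
}

#' @export
print.bandpass_study <- function(x, ...) {
  cat("<bandpass_study>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `reduced - full`, so a positive bias means
#' the reduced-wavelength extraction over-estimates the parameter. The
#' limits of agreement are bias +/- 1.96 standard deviations of the
#' differences (sample SD, n - 1).
#'
#' @param full,reduced Paired numeric vectors (length >= 2).
#' @return A `bland_altman` list: `bias`, `loa_half_width`
#'   (1.96 x SD of the differences), `n`, and the `differences`.
#' @export
bland_altman <- function(full, reduced) {
  if (length(full) != length(reduced)) stop("inputs must have equal length")
  if (length(full) < 2) stop("need at least 2 paired values")
  d <- reduced - full
  structure(list(bias = mean(d), loa_half_width = 1.96 * stats::sd(d),
                 n = length(d), differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, 95%% limits of agreement +/- %.4g (n = %d)\n",
              x$bias, x$loa_half_width, x$n))
  invisible(x)
}

#' Margin map of a scalar endpoint
#'
#' A pixel grid of one extracted endpoint (typically the
#' beta-carotene / mean-scattering ratio used to read tumor margins),
#' with a validity mask for pixels where extraction succeeded.
#'
#' @param values Numeric matrix of pixel values.
#' @param mask Logical matrix of valid pixels (default: finite values).
#' @return A `margin_map`.
#' @export
margin_map <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(values), dim(mask)))
  if (any(!is.finite(values[mask]))) stop("masked-valid pixels must be finite")
  structure(list(values = values, mask = mask), class = "margin_map")
}

#' Pearson correlation between two margin maps
#'
#' @param map_a,map_b `margin_map` objects with identical masks.
#' @return Pearson correlation over the valid pixels.
#' @export
map_correlation <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "margin_map"), inherits(map_b, "margin_map"))
  if (!identical(map_a$mask, map_b$mask)) stop("maps must share the same mask")
  a <- map_a$values[map_a$mask]
  b <- map_b$values[map_b$mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant map")
  }
  stats::cor(a, b)
}

#' Classify a margin from its endpoint map
#'
#' A margin is called positive when at least `pixel_fraction` of the
#' valid pixels fall strictly below `ratio_threshold` (low
#' beta-carotene relative to scattering indicates loss of adipose
#' content, the malignancy signature).
#'
#' @param map A [margin_map()].
#' @param ratio_threshold Pixel-level threshold (default 6).
#' @param pixel_fraction Fraction of valid pixels required (default 0.98).
#' @return `"positive"` or `"negative"`.
#' @export
classify_margin <- function(map, ratio_threshold = 6, pixel_fraction = 0.98) {
  stopifnot(inherits(map, "margin_map"))
  v <- map$values[map$mask]
  if (!length(v)) stop("empty valid mask")
  frac <- mean(v < ratio_threshold)
  if (frac >= pixel_fraction) "positive" else "negative"
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Compares extracted optical properties between two groups of samples
#' with the rank-sum test (normal approximation with tie correction; no
#' continuity correction, so the statistic is the one the exact
#' enumeration of rank assignments produces).
#'
#' @param group_a,group_b Numeric vectors (nonempty).
#' @return List with `rank_sum` (sum of ranks of `group_a` in the pooled
#'   sample), `statistic` (the Mann-Whitney U of `group_a`), and
#'   `p_value`.
#' @export
rank_sum_compare <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = FALSE, correct = FALSE))
  u <- unname(ht$statistic)
  p <- ht$p.value
  # fully tied pooled sample: zero rank variance, no evidence of a shift
  if (is.nan(p)) p <- 1
  list(rank_sum = u + length(group_a) * (length(group_a) + 1) / 2,
       statistic = u,
       p_value = p)
}

#' Tissue-type error report
#'
#' Summarizes reduced-wavelength extraction errors stratified by tissue
#' type, in the report shape used for clinical validation tables: one
#' row per (tissue type, parameter), signed mean and mean absolute
#' percent error columns. Intended for synthetic cohorts carrying a
#' `tissue_type` label.
#'
#' @param errors Matrix or data frame of signed percent errors with
#'   columns `thb_uM`, `bc_uM`, `mean_musp` (one row per sample).
#' @param tissue_types Character vector, one label per row.
#' @return Data frame with columns `tissue`, `parameter`,
#'   `mean_signed_error_pct`, `mean_abs_error_pct`.
#' @export
tissue_error_report <- function(errors, tissue_types) {
  errors <- as.matrix(errors)
  stopifnot(nrow(errors) == length(tissue_types))
  out <- expand.grid(tissue = unique(tissue_types),
                     parameter = colnames(errors),
                     stringsAsFactors = FALSE)
  out$mean_signed_error_pct <- mapply(function(tt, p) {
    mean(errors[tissue_types == tt, p])
  }, out$tissue, out$parameter)
  out$mean_abs_error_pct <- mapply(function(tt, p) {
    mean(abs(errors[tissue_types == tt, p]))
  }, out$tissue, out$parameter)
  out
}
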