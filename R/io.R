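#' Parse a grid string
#'
#' Grids are written on the command line as `"start:step:stop"`, e.g.
#' `"450:10:600"` for the 16-point 10 nm grid.
#'
#' @param text A `"start:step:stop"` string.
#' @return A [wavelength_grid()].
#' @export
parse_grid <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3 || anyNA(suppressWarnings(as.numeric(parts)))) {
    stop("grid must be written as start:step:stop, e.g. 450:10:600")
  }
  v <- as.numeric(parts)
  wavelength_grid(v[1], v[3], v[2])
}

#' Format a grid as a string
#'
#' Inverse of [parse_grid()].
#' @param grid A [wavelength_grid()].
#' @return A `"start:step:stop"` string.
#' @export
format_grid <- function(grid) {
  sprintf("%g:%g:%g", grid$start_nm, grid$step_nm, grid$stop_nm)
}

#' Read reflectance spectra from CSV
#'
#' Canonical long form has columns `wavelength_nm,reflectance` and an
#' optional `id` column separating several spectra. Wide form (accepted
#' on read only) has `wavelength_nm` plus one column per spectrum.
#' Wavelengths must be strictly increasing and evenly spaced within each
#' spectrum.
#'
#' @param path CSV path.
#' @return List of [reflectance_spectrum()] objects (named by id for the
#'   long form with ids, by column name for the wide form).
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    stop("spectra CSV must have a wavelength_nm column")
  }
  grid_of <- function(wl) {
    if (length(wl) < 2 || any(diff(wl) <= 0)) {
      stop("wavelengths must be strictly increasing")
    }
    steps <- diff(wl)
    if (max(steps) - min(steps) > 1e-6 * steps[1]) {
      stop("wavelengths must be evenly spaced")
    }
    wavelength_grid(wl[1], wl[length(wl)], steps[1])
  }
  if ("reflectance" %in% names(df)) {
    ids <- if ("id" %in% names(df)) df$id else rep("spectrum", nrow(df))
    out <- lapply(split(df, ids), function(d) {
      reflectance_spectrum(grid_of(d$wavelength_nm), d$reflectance,
                           provenance = "measured")
    })
    out[unique(ids)]
  } else {
    cols <- setdiff(names(df), "wavelength_nm")
    if (!length(cols)) stop("spectra CSV has no reflectance columns")
    g <- grid_of(df$wavelength_nm)
    out <- lapply(cols, function(cn) {
      reflectance_spectrum(g, df[[cn]], provenance = "measured")
    })
    names(out) <- cols
    out
  }
}

#' Write reflectance spectra to long-form CSV
#'
#' @param spectra A [reflectance_spectrum()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "reflectance_spectrum")) spectra <- list(spectra)
  if (is.null(names(spectra))) {
    names(spectra) <- sprintf("s%02d", seq_along(spectra))
  }
  df <- do.call(rbind, lapply(names(spectra), function(nm) {
    sp <- spectra[[nm]]
    data.frame(id = nm, wavelength_nm = grid_wavelengths(sp$grid),
               reflectance = sp$values)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write ranked wavelength solutions to JSON
#'
#' Persists a finished optimization run with everything needed to
#' regenerate it: the ranked wavelength sets with their fitness values
#' and per-comparison errors, the grid, and the seed.
#'
#' @param result A `ga_result` from [evolve()].
#' @param path Output JSON path.
#' @param records Optional list of `fitness_record`s matching
#'   `result$top_sets`, to persist per-comparison errors.
#' @return `path`, invisibly.
#' @export
write_solutions <- function(result, path, records = NULL) {
  stopifnot(inherits(result, "ga_result"))
  sol <- lapply(seq_along(result$top_sets), function(i) {
    s <- list(rank = i,
              wavelengths = result$top_sets[[i]]$wavelengths,
              fitness = result$top_fitness[i])
    if (!is.null(records)) {
      s$per_comparison_errors <- unname(records[[i]]$per_comparison_errors)
    }
    s
  })
  payload <- list(
    solutions = sol,
    grid = format_grid(result$config$grid),
    n_wavelengths = result$config$n_wavelengths,
    generations = result$generations,
    stalled = result$stalled,
    seed = result$config$rng_seed,
    package_version = as.character(utils::packageVersion("waveopt")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a solutions JSON file
#'
#' @param path JSON written by [write_solutions()].
#' @return The parsed payload; `solutions[[i]]$wavelengths` are numeric
#'   vectors.
#' @export
read_solutions <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
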