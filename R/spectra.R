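#' Labelled spectra tables
#'
#' The pipeline's observation container is an ordinary tibble with one row per
#' pixel spectrum. Annotation columns (`species`, `class`, `individual`,
#' `roi_id`, `age_days`, and optionally `age_bin`, `i`, `j`) sit alongside a
#' numeric matrix column named `spectra` whose column names encode the
#' wavelength axis in nanometres. Because the wavelengths travel with the
#' matrix column, the table survives `dplyr` verbs (filter, slice, bind_rows)
#' without losing its spectral axis.
#'
#' @param spectra numeric matrix, one row per observation, one column per band.
#' @param wavelengths numeric vector of band-centre wavelengths (nm), strictly
#'   increasing, one per matrix column.
#' @param meta data frame of per-observation annotations with `nrow(spectra)`
#'   rows (may be omitted).
#' @return A tibble with the annotation columns of `meta` plus a `spectra`
#'   matrix column.
#' @examples
#' m <- matrix(runif(12), nrow = 3)
#' labelled_spectra(m, c(500, 550, 600, 650),
#'                  data.frame(species = c("human", "pig", "pig")))
#' @export
labelled_spectra <- function(spectra, wavelengths, meta = NULL) {
  spectra <- as.matrix(spectra)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(spectra) != length(wavelengths)) {
    abort(sprintf("spectra has %d columns but %d wavelengths were given",
                  ncol(spectra), length(wavelengths)))
  }
  check_wavelengths(wavelengths)
  colnames(spectra) <- format_wl(wavelengths)
  if (is.null(meta)) {
    meta <- tibble(.rows = nrow(spectra))
  } else {
    meta <- as_tibble(meta)
    if (nrow(meta) == 1 && nrow(spectra) > 1) {
      meta <- meta[rep(1L, nrow(spectra)), ]
    }
    if (nrow(meta) != nrow(spectra)) {
      abort("meta must have one row per spectrum")
    }
  }
  out <- meta
  out$spectra <- spectra
  out
}

# full double precision so the axis survives a name round trip exactly
format_wl <- function(wl) sprintf("%.17g", wl)

#' Wavelength axis of a labelled-spectra table
#'
#' @param x a labelled-spectra tibble (with a `spectra` matrix column) or a
#'   bare matrix with wavelength-named columns.
#' @return numeric vector of wavelengths in nm.
#' @export
spectra_wavelengths <- function(x) {
  m <- spectra_matrix(x)
  wl <- as.numeric(colnames(m))
  if (anyNA(wl)) abort("spectra column names do not encode wavelengths")
  wl
}

#' Extract the spectral matrix from a labelled-spectra table
#'
#' @inheritParams spectra_wavelengths
#' @return numeric matrix, observations by bands.
#' @export
spectra_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && "spectra" %in% names(x)) return(x[["spectra"]])
  abort("expected a labelled-spectra table with a `spectra` matrix column")
}

replace_spectra <- function(data, m, wavelengths) {
  colnames(m) <- format_wl(wavelengths)
  data$spectra <- m
  data
}

check_wavelengths <- function(wl) {
  if (length(wl) == 0) abort("wavelength axis is empty")
  if (anyNA(wl) || any(!is.finite(wl))) abort("wavelengths must be finite")
  if (any(diff(wl) <= 0)) abort("wavelengths must be strictly increasing")
  invisible(wl)
}

# indices of bands whose centre lies in [lo, hi]; errors if none survive
window_bands <- function(wl, lo, hi, what = "window") {
  idx <- which(wl >= lo & wl <= hi)
  if (length(idx) == 0) {
    abort(sprintf("no bands fall inside the %s [%g, %g] nm", what, lo, hi))
  }
  idx
}

#' Row-bind labelled-spectra tables, preserving the wavelength axis
#'
#' `dplyr::bind_rows()` drops the column names of matrix columns, which is
#' where the wavelength axis lives; this binder keeps it. All tables must
#' share an identical wavelength axis.
#'
#' @param ... labelled-spectra tibbles, or a single list of them.
#' @return One combined labelled-spectra tibble.
#' @export
bind_spectra <- function(...) {
  pieces <- list(...)
  if (length(pieces) == 1 && is.list(pieces[[1]]) && !is.data.frame(pieces[[1]])) {
    pieces <- pieces[[1]]
  }
  wl <- spectra_wavelengths(pieces[[1]])
  for (p in pieces[-1]) {
    if (!isTRUE(all.equal(spectra_wavelengths(p), wl))) {
      abort("all tables must share the same wavelength axis")
    }
  }
  meta <- bind_rows(lapply(pieces, function(p) p[setdiff(names(p), "spectra")]))
  m <- do.call(rbind, lapply(pieces, spectra_matrix))
  labelled_spectra(m, wl, meta)
}
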