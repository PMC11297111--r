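#' Spectral preprocessing configuration
#'
#' @param trunc_lo,trunc_hi truncation window in nm; bands whose centre lies
#'   in `[trunc_lo, trunc_hi]` (inclusive) are retained. The defaults cut the
#'   grid edges where camera sensitivity and halogen illumination are weak.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay window length in bands; must be odd and
#'   greater than `sg_order`.
#' @param snv logical, apply the standard normal variate transform.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(trunc_lo = 435, trunc_hi = 965,
                              sg_order = 2, sg_window = 9, snv = TRUE) {
  if (sg_window %% 2 != 1) abort("sg_window must be odd")
  if (sg_window <= sg_order) abort("sg_window must exceed sg_order")
  if (trunc_lo >= trunc_hi) abort("trunc_lo must be < trunc_hi")
  structure(list(trunc_lo = trunc_lo, trunc_hi = trunc_hi,
                 sg_order = sg_order, sg_window = sg_window, snv = snv),
            class = "preprocess_config")
}

#' Truncate the wavelength axis
#'
#' Keeps exactly the bands whose centre wavelength `w` satisfies
#' `lo <= w <= hi` and updates the wavelength axis accordingly.
#'
#' @param data labelled-spectra tibble.
#' @param lo,hi window endpoints in nm (`lo < hi`).
#' @return The table restricted to the surviving bands.
#' @export
truncate_bands <- function(data, lo = 435, hi = 965) {
  if (lo >= hi) abort("lo must be < hi")
  wl <- spectra_wavelengths(data)
  idx <- window_bands(wl, lo, hi, "truncation window")
  replace_spectra(data, spectra_matrix(data)[, idx, drop = FALSE], wl[idx])
}

# central Savitzky-Golay coefficients for (order, window)
sg_coef <- function(order, window) {
  b <- signal::sgolay(p = order, n = window)
  as.numeric(b[(window + 1) / 2, ])
}

#' Savitzky-Golay smoothing with edge-band drop
#'
#' Replaces each interior band by the value of the local least-squares
#' polynomial fit over the sliding window. The `floor(window / 2)` bands at
#' each end of the axis have no complete window; they are dropped rather than
#' padded, so the wavelength axis shrinks by `window - 1` bands.
#'
#' @param data labelled-spectra tibble.
#' @param order polynomial order (default 2).
#' @param window window length in bands (odd, > order).
#' @return Smoothed table on the shortened wavelength axis.
#' @export
savgol_smooth <- function(data, order = 2, window = 9) {
  if (window %% 2 != 1) abort("window must be odd")
  if (window <= order) abort("window must exceed the polynomial order")
  m <- spectra_matrix(data)
  wl <- spectra_wavelengths(data)
  if (ncol(m) < window) {
    abort(sprintf("need at least %d bands for window %d, have %d",
                  window, window, ncol(m)))
  }
  h <- (window - 1L) / 2L
  keep <- seq.int(h + 1L, ncol(m) - h)
  f <- sg_coef(order, window)
  sm <- matrix(0, nrow(m), length(keep))
  for (t in seq_len(window)) {
    sm <- sm + f[t] * m[, keep + (t - h - 1L), drop = FALSE]
  }
  replace_spectra(data, sm, wl[keep])
}

#' Standard normal variate (SNV) transform
#'
#' Autoscales each spectrum to zero mean and unit standard deviation (sample
#' `n - 1` convention), removing multiplicative scatter and baseline offsets.
#' Works on a single numeric spectrum or row-wise on a labelled-spectra
#' table.
#'
#' @param x numeric spectrum or labelled-spectra tibble.
#' @return Same shape as the input, each spectrum with moments (0, 1).
#' @export
snv_transform <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) abort("cannot SNV-transform a constant spectrum")
    return((x - mean(x)) / s)
  }
  m <- spectra_matrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad) > 0) {
    abort(sprintf("zero-variance spectrum cannot be SNV-transformed (observation%s %s)",
                  if (length(bad) > 1) "s" else "",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  replace_spectra(x, (m - mu) / s, spectra_wavelengths(x))
}

#' Full preprocessing pipeline: truncate, smooth, SNV
#'
#' Applies the stages in the fixed order truncation -> Savitzky-Golay
#' smoothing -> SNV. The resulting wavelength axis and the stages applied are
#' recorded in the `"preprocess"` attribute so downstream models can replay
#' the identical transformation on new cubes.
#'
#' @param data labelled-spectra tibble of calibrated reflectance.
#' @param config a [preprocess_config()].
#' @return Preprocessed labelled-spectra tibble with a `"preprocess"`
#'   provenance attribute.
#' @export
preprocess_pipeline <- function(data, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- truncate_bands(data, config$trunc_lo, config$trunc_hi)
  out <- savgol_smooth(out, config$sg_order, config$sg_window)
  stages <- c("truncate", "savgol")
  if (config$snv) {
    out <- snv_transform(out)
    stages <- c(stages, "snv")
  }
  attr(out, "preprocess") <- list(stages = stages, config = config,
                                  wavelengths = spectra_wavelengths(out))
  out
}

# replay a preprocess_config on a bare matrix + wavelength axis (used for
# per-pixel image segmentation, where there is no labelled table)
preprocess_matrix <- function(m, wl, config) {
  d <- labelled_spectra(m, wl)
  out <- preprocess_pipeline(d, config)
  list(spectra = spectra_matrix(out), wavelengths = spectra_wavelengths(out))
}
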