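#' Spectral background-detection parameters (ABD)
#'
#' The background detector reduces each pixel's reflectance spectrum to
#' three statistics and keeps the pixel as a bloodstain candidate only when
#' all three pass their thresholds:
#' * `A` — mean reflectance over a broad window; rejects constant
#'   high-reflectance spectra such as the white deposition cloth (`A < 0.6`);
#' * `B` — mean reflectance over the haem Q-band window; rejects
#'   near-black pixels that carry no signal (`B > 0.05`);
#' * `C` — ratio of far-red mean to Q-band mean; captures the steep red
#'   edge that typifies blood reflectance (`C > 1.7`).
#'
#' The thresholds are the detector's defining constants; the band windows
#' operationalise their meaning on this instrument's 400-1000 nm axis and
#' are fully configurable.
#'
#' @param a_window,b_window nm windows of statistics A and B.
#' @param c_num_window,c_den_window numerator (far-red) and denominator
#'   (Q-band) windows of statistic C.
#' @param a_max,b_min,c_min decision thresholds.
#' @param closing_radius disc radius (pixels) of the morphological closing
#'   applied to the raw mask; 0 disables it.
#' @return Object of class `abd_params`.
#' @export
abd_params <- function(a_window = c(445, 955), b_window = c(545, 585),
                       c_num_window = c(650, 800), c_den_window = c(545, 585),
                       a_max = 0.6, b_min = 0.05, c_min = 1.7,
                       closing_radius = 1) {
  if (closing_radius < 0) abort("closing_radius must be >= 0")
  stopifnot(is.finite(a_max), is.finite(b_min), is.finite(c_min))
  structure(list(a_window = a_window, b_window = b_window,
                 c_num_window = c_num_window, c_den_window = c_den_window,
                 a_max = a_max, b_min = b_min, c_min = c_min,
                 closing_radius = closing_radius),
            class = "abd_params")
}

#' ABD statistics of one reflectance spectrum
#'
#' @param spectrum numeric reflectance spectrum (calibrated scale, pre-SNV).
#' @param wavelengths its wavelength axis in nm.
#' @param params an [abd_params()].
#' @return Named numeric vector `c(A, B, C)`.
#' @export
abd_statistics <- function(spectrum, wavelengths, params = abd_params()) {
  wa <- window_bands(wavelengths, params$a_window[1], params$a_window[2], "A window")
  wb <- window_bands(wavelengths, params$b_window[1], params$b_window[2], "B window")
  wn <- window_bands(wavelengths, params$c_num_window[1], params$c_num_window[2],
                     "C numerator window")
  wd <- window_bands(wavelengths, params$c_den_window[1], params$c_den_window[2],
                     "C denominator window")
  c(A = mean(spectrum[wa]), B = mean(spectrum[wb]),
    C = mean(spectrum[wn]) / mean(spectrum[wd]))
}

#' Bloodstain-candidate mask from the ABD decision rule
#'
#' Evaluates the three statistics per pixel and marks a pixel as foreground
#' iff `A < a_max` and `B > b_min` and `C > c_min` (short-circuit
#' conjunction in A, B, C order). No morphological cleanup is applied here;
#' see [close_mask()].
#'
#' @param cube reflectance-kind [hypercube()].
#' @param params an [abd_params()].
#' @return Logical foreground mask (rows x cols).
#' @export
abd_mask <- function(cube, params = abd_params()) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") abort("abd_mask needs a reflectance cube")
  wl <- cube$wavelengths
  band_mean <- function(win, what) {
    idx <- window_bands(wl, win[1], win[2], what)
    apply(cube$values[, , idx, drop = FALSE], c(1, 2), mean)
  }
  A <- band_mean(params$a_window, "A window")
  fg <- A < params$a_max
  if (any(fg)) {
    B <- band_mean(params$b_window, "B window")
    fg <- fg & (B > params$b_min)
  }
  if (any(fg)) {
    Cn <- band_mean(params$c_num_window, "C numerator window")
    Cd <- band_mean(params$c_den_window, "C denominator window")
    fg <- fg & (Cn / Cd > params$c_min)
  }
  fg
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disc structuring element, filling
#' pinholes and thin gaps in the foreground; the output always contains the
#' input. Radius 0 is the identity.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return Logical matrix of the same shape.
#' @export
close_mask <- function(mask, radius = 1) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (radius == 0) return(mask)
  # pad by the brush radius so the closing behaves as on an unbounded plane
  # (guarantees output >= input at the image border)
  r <- as.integer(radius)
  padded <- matrix(0, nrow(mask) + 2 * r, ncol(mask) + 2 * r)
  padded[(r + 1):(r + nrow(mask)), (r + 1):(r + ncol(mask))] <- mask * 1
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  out <- EBImage::closing(EBImage::Image(padded), brush)
  out <- matrix(as.numeric(out) > 0.5, nrow(padded), ncol(padded))
  out[(r + 1):(r + nrow(mask)), (r + 1):(r + ncol(mask))]
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of equal shape.
#' @return IoU in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
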