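#' Hyperspectral data cube
#'
#' A light container around the 3-D array produced by a push-broom imaging
#' spectrometer: two spatial axes (row `i`, column `j`, 0-based in exported
#' coordinates) and one spectral axis with band-centre wavelengths in nm.
#'
#' @param values numeric 3-D array `[row, col, band]`, all finite.
#' @param wavelengths strictly increasing band centres (nm), one per band.
#' @param kind `"raw"` (sensor counts) or `"reflectance"`.
#' @param meta optional named list of acquisition metadata (integration time,
#'   working distance, ...), informational only.
#' @return Object of class `hypercube`. Reflectance cubes with values above 1
#'   are kept as-is but flagged in `meta$over_unity_count`; negative
#'   reflectance is an error.
#' @export
hypercube <- function(values, wavelengths, kind = c("raw", "reflectance"),
                      meta = list()) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3) {
    abort("values must be a 3-D array [row, col, band]")
  }
  check_wavelengths(wavelengths)
  if (dim(values)[3] != length(wavelengths)) {
    abort(sprintf("cube has %d bands but %d wavelengths were given",
                  dim(values)[3], length(wavelengths)))
  }
  if (any(!is.finite(values))) abort("cube values must all be finite")
  if (kind == "reflectance") {
    if (any(values < 0)) abort("reflectance values must be >= 0")
    meta$over_unity_count <- sum(values > 1)
  }
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 kind = kind, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.4g-%.4g nm), kind: %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Calibrate a raw cube to reflectance
#'
#' Applies the standard white-reference relation
#' `R_ij(lambda) = (RAW_ij - Dark_ij) / White_ij` element-wise. The dark and
#' white references may be full cubes matching the RAW dimensions or per-band
#' vectors broadcast over the image. Setting `dark_corrected_white = TRUE`
#' uses `White - Dark` in the denominator instead, for instruments whose
#' white reference is not internally dark-corrected.
#'
#' @param raw raw-kind [hypercube()].
#' @param dark,white dark and white reference frames: per-band numeric
#'   vectors or arrays with the RAW dimensions.
#' @param dark_corrected_white logical; see above. Default `FALSE` (divide by
#'   White as measured).
#' @return Reflectance-kind hypercube.
#' @export
calibrate_reflectance <- function(raw, dark, white,
                                  dark_corrected_white = FALSE) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$kind != "raw") abort("raw must be a raw-kind hypercube")
  d <- dim(raw$values)
  expand <- function(x, what) {
    if (is.array(x) && length(dim(x)) == 3) {
      if (!all(dim(x) == d)) abort(sprintf("%s frame dimensions do not match RAW", what))
      return(x)
    }
    if (length(x) != d[3]) {
      abort(sprintf("%s must be a per-band vector of length %d or a full cube", what, d[3]))
    }
    array(rep(x, each = d[1] * d[2]), dim = d)
  }
  dk <- expand(dark, "dark")
  wt <- expand(white, "white")
  denom <- if (dark_corrected_white) wt - dk else wt
  if (any(wt <= 0)) abort("white reference must be > 0 everywhere")
  if (any(wt <= dk)) abort("white reference must exceed the dark frame everywhere")
  r <- (raw$values - dk) / denom
  r[r < 0] <- 0  # sensor noise can push RAW below Dark; negative reflectance is unphysical
  hypercube(r, raw$wavelengths, kind = "reflectance", meta = raw$meta)
}

#' Theoretical spatial resolution of the imaging geometry
#'
#' @param width_cm viewable width of the scene in cm.
#' @param pixels number of pixels across that width.
#' @return resolution in mm per pixel.
#' @examples
#' spatial_resolution(16.4, 512)  # 0.32 mm
#' @export
spatial_resolution <- function(width_cm = 16.4, pixels = 512) {
  width_cm * 10 / pixels
}

# ---- ENVI-style persistence --------------------------------------------

#' Write / read a hypercube in an ENVI-style container
#'
#' `write_cube()` stores the cube as a flat binary file (little-endian
#' doubles, BSQ or BIL interleave) plus a plain-text `<path>.hdr` header
#' carrying dimensions, interleave, data type and the wavelength list.
#' `read_cube()` reverses it; the round trip is bit-identical.
#'
#' @param cube a [hypercube()].
#' @param path data-file path; the header is written to `paste0(path, ".hdr")`.
#' @param interleave `"bsq"` (band-sequential) or `"bil"` (band-interleaved
#'   by line).
#' @return `write_cube()` returns `path` invisibly; `read_cube()` a
#'   [hypercube()].
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("cube kind = %s", cube$kind),
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(sprintf("%.17g", cube$wavelengths), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  v <- cube$values
  con <- file(path, "wb")
  on.exit(close(con))
  if (interleave == "bsq") {
    # band-major; within a band, line-major (row by row)
    writeBin(as.numeric(aperm(v, c(2, 1, 3))), con, size = 8, endian = "little")
  } else {
    # line-major; within a line, band-major rows of samples
    writeBin(as.numeric(aperm(v, c(2, 3, 1))), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) abort(sprintf("header not found: %s", hdr_path))
  if (!file.exists(path)) abort(sprintf("data file not found: %s", path))
  txt <- paste(readLines(hdr_path), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("%s\\s*=\\s*[0-9]+", key), txt))
    if (length(m) == 0) abort(sprintf("header is missing '%s'", key))
    as.integer(sub(".*=\\s*", "", m))
  }
  samples <- get_num("samples"); lines <- get_num("lines"); bands <- get_num("bands")
  il <- regmatches(txt, regexpr("interleave\\s*=\\s*\\w+", txt))
  interleave <- if (length(il)) tolower(sub(".*=\\s*", "", il)) else "bsq"
  if (!interleave %in% c("bsq", "bil")) {
    abort(sprintf("unsupported interleave '%s'", interleave))
  }
  kd <- regmatches(txt, regexpr("cube kind\\s*=\\s*\\w+", txt))
  kind <- if (length(kd)) sub(".*=\\s*", "", kd) else "raw"
  wl_m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (length(wl_m) == 0) abort("header is missing the wavelength list")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_m), ",")[[1]])
  if (length(wl) != bands) {
    abort(sprintf("header declares %d bands but lists %d wavelengths", bands, length(wl)))
  }
  if (any(diff(wl) <= 0)) abort("header wavelengths are not strictly increasing")
  n_expect <- samples * lines * bands
  n_file <- file.size(path) / 8
  if (n_file != n_expect) {
    abort(sprintf("data file holds %d values but header declares %d (%d bands)",
                  n_file, n_expect, bands))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n_expect, size = 8, endian = "little")
  arr <- if (interleave == "bsq") {
    aperm(array(v, dim = c(samples, lines, bands)), c(2, 1, 3))
  } else {
    aperm(array(v, dim = c(samples, bands, lines)), c(3, 1, 2))
  }
  hypercube(arr, wl, kind = kind)
}

# ---- ROI handling -------------------------------------------------------

#' Region-of-interest set
#'
#' Bundles per-ROI boolean pixel masks with their annotations. Masks are
#' logical matrices aligned to the cube's spatial grid.
#'
#' @param masks list of logical matrices (or a single matrix).
#' @param roi_id unique ROI identifiers.
#' @param species,individual,age_days per-ROI annotations, recycled if scalar.
#' @return Tibble of class `roi_set` with a `mask` list-column.
#' @export
roi_set <- function(masks, roi_id, species, individual = NA_character_,
                    age_days = NA_real_) {
  if (is.matrix(masks)) masks <- list(masks)
  n <- length(masks)
  if (anyDuplicated(roi_id)) abort("ROI IDs must be unique")
  if (any(is.na(species)) || length(species) == 0) {
    abort("every ROI needs a species label")
  }
  out <- tibble(roi_id = as.character(roi_id),
                species = rep_len(as.character(species), n),
                individual = rep_len(as.character(individual), n),
                age_days = rep_len(as.numeric(age_days), n),
                mask = masks)
  class(out) <- c("roi_set", class(out))
  out
}

#' Extract labelled pixel spectra from a reflectance cube
#'
#' One observation per masked pixel, annotated with the ROI's species,
#' individual and age; species `"human"` receives binary class 1, everything
#' else class 0.
#'
#' @param cube reflectance-kind [hypercube()].
#' @param rois a [roi_set()].
#' @return Labelled-spectra tibble (`roi_id`, `species`, `class`,
#'   `individual`, `age_days`, pixel coordinates `i`, `j` (0-based), and the
#'   `spectra` matrix column).
#' @export
extract_roi <- function(cube, rois) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") {
    abort("extract_roi needs a reflectance cube; calibrate first")
  }
  d <- dim(cube$values)
  pieces <- lapply(seq_len(nrow(rois)), function(k) {
    m <- rois$mask[[k]]
    if (!is.logical(m)) abort("ROI masks must be logical matrices")
    if (!all(dim(m) == d[1:2])) {
      abort(sprintf("ROI '%s' mask lies outside the image bounds (mask %dx%d, image %dx%d)",
                    rois$roi_id[k], nrow(m), ncol(m), d[1], d[2]))
    }
    px <- which(m, arr.ind = TRUE)
    if (nrow(px) == 0) abort(sprintf("ROI '%s' has an empty mask", rois$roi_id[k]))
    lin <- px[, 1] + (px[, 2] - 1L) * d[1]
    spec <- matrix(0, nrow(px), d[3])
    for (b in seq_len(d[3])) {
      spec[, b] <- cube$values[lin + (b - 1L) * d[1] * d[2]]
    }
    labelled_spectra(spec, cube$wavelengths,
                     tibble(roi_id = rois$roi_id[k],
                            species = rois$species[k],
                            class = as.integer(rois$species[k] == "human"),
                            individual = rois$individual[k],
                            age_days = rois$age_days[k],
                            i = px[, 1] - 1L, j = px[, 2] - 1L))
  })
  bind_spectra(pieces)
}

#' Write / read a boolean mask as an 8-bit PNG image
#'
#' @param mask logical matrix.
#' @param path output file.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()` a
#'   logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
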