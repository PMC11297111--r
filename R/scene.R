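#' Configuration of one synthetic bloodstain scene
#'
#' A scene is a circular bloodstain on white cloth imaged by a push-broom
#' hyperspectral camera: the generator produces the RAW intensity cube plus
#' the per-band dark and white reference frames that the calibration step
#' consumes, together with the ground-truth stain mask.
#'
#' @param species species label (must exist in the chromophore model).
#' @param age_days stain age in days.
#' @param width,height image size in pixels.
#' @param wavelengths band-centre grid in nm; default 204 uniform bands over
#'   400-1000 nm.
#' @param centre stain centre `c(row, col)` in pixels.
#' @param radius stain radius in pixels (> 0).
#' @param noise_sd sensor noise standard deviation in reflectance units;
#'   additive i.i.d. Gaussian noise of sd `noise_sd * white_level` is applied
#'   per band on the RAW cube.
#' @param seed integer random seed fixing the scene exactly.
#' @param dark_level,white_level sensor baseline and white-reference
#'   intensities (arbitrary counts).
#' @param amp_mult per-individual absorbance multiplier (1 = nominal).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(species = "human", age_days = 0.1,
                         width = 64, height = 64,
                         wavelengths = seq(400, 1000, length.out = 204),
                         centre = c(height / 2, width / 2), radius = 20,
                         noise_sd = 0.01, seed = 1,
                         dark_level = 100, white_level = 4000,
                         amp_mult = 1) {
  check_wavelengths(wavelengths)
  if (radius <= 0) abort("stain radius must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (age_days < 0) abort("age_days must be >= 0")
  if (centre[1] - radius < 1 || centre[1] + radius > height ||
      centre[2] - radius < 1 || centre[2] + radius > width) {
    abort("stain must fit inside the image")
  }
  if (white_level <= dark_level) abort("white_level must exceed dark_level")
  structure(
    list(species = species, age_days = age_days, width = width,
         height = height, wavelengths = wavelengths, centre = centre,
         radius = radius, noise_sd = noise_sd, seed = as.integer(seed),
         dark_level = dark_level, white_level = white_level,
         amp_mult = amp_mult),
    class = "scene_config"
  )
}

#' Render a synthetic bloodstain scene
#'
#' Builds the true reflectance cube (cloth background, blood disc), then the
#' RAW cube as `RAW = White * R_true + Dark + noise` so that reflectance
#' calibration recovers the truth up to sensor noise. Identical configs give
#' bit-identical output.
#'
#' @param config a [scene_config()].
#' @param model a [chromophore_model()].
#' @return List with elements `raw` (raw-kind [hypercube()]), `dark` and
#'   `white` (per-band reference vectors), `mask` (logical ground-truth stain
#'   mask, rows x cols), `truth` (reflectance-kind hypercube without noise)
#'   and `meta` (one-row tibble).
#' @export
render_scene <- function(config, model = chromophore_model()) {
  if (!inherits(config, "scene_config")) abort("config must be a scene_config")
  wl <- config$wavelengths
  nb <- length(wl)
  h <- config$height; w <- config$width

  blood <- blood_reflectance(wl, config$species, config$age_days, model,
                             amp_mult = config$amp_mult)
  cloth <- rep(model$cloth_reflectance, nb)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (rows - config$centre[1])^2 + (cols - config$centre[2])^2 <=
    config$radius^2

  truth <- array(rep(cloth, each = h * w), dim = c(h, w, nb))
  idx <- which(mask)
  for (b in seq_len(nb)) truth[idx + (b - 1L) * h * w] <- blood[b]

  raw_vals <- withr::with_seed(config$seed, {
    noise <- if (config$noise_sd > 0) {
      array(rnorm(h * w * nb, sd = config$noise_sd * config$white_level),
            dim = c(h, w, nb))
    } else 0
    config$white_level * truth + config$dark_level + noise
  })

  meta <- tibble(species = config$species, age_days = config$age_days,
                 seed = config$seed, width = w, height = h,
                 radius = config$radius, noise_sd = config$noise_sd)
  list(
    raw = hypercube(raw_vals, wl, kind = "raw"),
    dark = rep(config$dark_level, nb),
    white = rep(config$white_level, nb),
    mask = mask,
    truth = hypercube(truth, wl, kind = "reflectance"),
    meta = meta
  )
}

#' Generate a longitudinal cohort of synthetic scenes
#'
#' One scene per (individual, age) combination, mirroring a study design in
#' which every donor's stain is re-imaged as it ages. Individuals carry a
#' small lognormal absorbance multiplier (2% sd) so pixels from the same
#' individual are more alike than pixels from different individuals — the
#' structure that individual-level train/test splitting protects against.
#'
#' @param counts named integer vector of individuals per species,
#'   e.g. `c(human = 4, pig = 4)`.
#' @param ages numeric vector of imaging ages in days.
#' @param template a [scene_config()] supplying image geometry, noise and
#'   reference levels for every scene.
#' @param model a [chromophore_model()].
#' @param seed master seed; all per-scene seeds and individual effects derive
#'   from it.
#' @return List of class `blood_cohort`: `metadata` (tibble with one row per
#'   scene: scene_id, species, individual, age_days, seed, amp_mult),
#'   `configs` (list of scene_config), `model`.
#' @export
generate_cohort <- function(counts, ages, template = scene_config(),
                            model = chromophore_model(), seed = 1) {
  if (length(counts) == 0) abort("counts must name at least one species")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("counts must be a named vector of individuals per species")
  }
  if (any(counts < 1)) abort("counts must be >= 1 per included species")
  unknown <- setdiff(names(counts), model$species$species)
  if (length(unknown) > 0) {
    abort(sprintf("unknown species: %s", paste(unknown, collapse = ", ")))
  }

  individuals <- tibble(
    species = rep(names(counts), times = counts),
    individual = unlist(lapply(names(counts), function(s)
      sprintf("%s_%02d", s, seq_len(counts[[s]]))))
  )
  individuals$amp_mult <- withr::with_seed(seed,
    exp(rnorm(nrow(individuals), mean = 0, sd = 0.02)))

  meta <- tidyr::crossing(individuals, age_days = as.numeric(ages)) %>%
    arrange(.data$species, .data$individual, .data$age_days) %>%
    mutate(scene_id = sprintf("scene_%03d", row_number()),
           seed = seed + 1000L + row_number()) %>%
    select("scene_id", "species", "individual", "age_days", "seed", "amp_mult")

  configs <- lapply(seq_len(nrow(meta)), function(k) {
    cfg <- template
    cfg$species <- meta$species[k]
    cfg$age_days <- meta$age_days[k]
    cfg$seed <- as.integer(meta$seed[k])
    cfg$amp_mult <- meta$amp_mult[k]
    cfg
  })
  structure(list(metadata = meta, configs = configs, model = model),
            class = "blood_cohort")
}

#' Render a cohort and extract calibrated ROI spectra
#'
#' For each scene: render, calibrate reflectance against the scene's dark and
#' white references, place a square region of interest at the stain centre,
#' and collect the pixel spectra into one labelled-spectra table. Scenes are
#' rendered one at a time and discarded, so cohort size is limited by the
#' table, not by cube memory.
#'
#' @param cohort a [generate_cohort()] result.
#' @param roi_half half-width of the square ROI in pixels (ROI side is
#'   `2 * roi_half + 1`).
#' @return Labelled-spectra tibble with species, class (1 = human,
#'   0 = animal), individual, roi_id, age_days and age_bin columns.
#' @export
cohort_spectra <- function(cohort, roi_half = 4) {
  stopifnot(inherits(cohort, "blood_cohort"))
  pieces <- lapply(seq_len(nrow(cohort$metadata)), function(k) {
    m <- cohort$metadata[k, ]
    sc <- render_scene(cohort$configs[[k]], cohort$model)
    refl <- calibrate_reflectance(sc$raw, sc$dark, sc$white)
    cfg <- cohort$configs[[k]]
    roi <- matrix(FALSE, cfg$height, cfg$width)
    r0 <- round(cfg$centre[1]); c0 <- round(cfg$centre[2])
    roi[(r0 - roi_half):(r0 + roi_half), (c0 - roi_half):(c0 + roi_half)] <- TRUE
    rs <- roi_set(list(roi), roi_id = paste0(m$scene_id, "_roi"),
                  species = m$species, individual = m$individual,
                  age_days = m$age_days)
    extract_roi(refl, rs)
  })
  out <- bind_spectra(pieces)
  out$age_bin <- assign_bin(out$age_days)
  out
}
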