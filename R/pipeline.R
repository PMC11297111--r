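#' End-to-end synthetic bloodstain discrimination pipeline
#'
#' Runs the complete analysis on generated data: cohort simulation, scene
#' rendering, reflectance calibration, ROI extraction, spectral
#' preprocessing, age-binned hierarchical balancing, individual-level
#' train/holdout splitting, validation/test splitting, NCFS wavelength
#' selection, SVM training and test-set evaluation. All randomness descends
#' from `seed`.
#'
#' @param counts named vector of individuals per species.
#' @param ages imaging ages in days (should populate all five age bins).
#' @param roi_half ROI half-width in pixels per scene.
#' @param template scene configuration shared by all scenes.
#' @param model chromophore model.
#' @param preprocess a [preprocess_config()].
#' @param ncfs an [ncfs_config()]; its seed is overridden by `seed`.
#' @param threshold NCFS selection threshold (fraction of max weight).
#' @param svm an [svm_spec()]; its band subset is replaced by the NCFS
#'   selection.
#' @param seed master seed.
#' @return Object of class `blood_pipeline`: the balanced data splits, the
#'   NCFS fit, selected bands, the trained model and test-set metrics.
#' @export
run_blood_pipeline <- function(counts = c(human = 4, pig = 4),
                               ages = c(0.1, 2, 5, 14, 30),
                               roi_half = 4,
                               template = scene_config(),
                               model = chromophore_model(),
                               preprocess = preprocess_config(),
                               ncfs = ncfs_config(batch_size = 256, epochs = 5),
                               threshold = 0.55,
                               svm = svm_spec(),
                               seed = 1) {
  cohort <- generate_cohort(counts, ages, template = template, model = model,
                            seed = seed)
  raw_spectra <- cohort_spectra(cohort, roi_half = roi_half)
  spectra <- preprocess_pipeline(raw_spectra, preprocess)
  prov <- attr(spectra, "preprocess")

  balanced <- hierarchical_balance(spectra, seed = seed + 1L)
  attr(balanced, "preprocess") <- prov
  parts <- split_by_individual(balanced, seed = seed + 2L)
  vt <- split_validation_test(parts$holdout, seed = seed + 3L)

  # leakage guard: no individual on both sides of the split
  overlap <- intersect(unique(parts$train$individual),
                       unique(c(vt$validation$individual, vt$test$individual)))
  stopifnot(length(overlap) == 0)

  ncfs$seed <- as.integer(seed + 4L)
  fit <- ncfs_fit(parts$train, config = ncfs)
  bands <- select_features(fit, threshold)

  svm$bands <- bands
  train <- parts$train
  attr(train, "preprocess") <- prov
  clf <- train_svm(train, svm)

  pred <- predict(clf, vt$test)
  metrics <- compute_metrics(vt$test$class, pred)

  structure(list(cohort = cohort, train = parts$train,
                 validation = vt$validation, test = vt$test,
                 ncfs_fit = fit, bands = bands, model = clf,
                 metrics = metrics, seed = seed),
            class = "blood_pipeline")
}

#' @export
print.blood_pipeline <- function(x, ...) {
  cat(sprintf("<blood_pipeline> %d train / %d validation / %d test spectra, %d/%d bands selected\n",
              nrow(x$train), nrow(x$validation), nrow(x$test),
              length(x$bands), length(x$ncfs_fit$weights)))
  cat(sprintf("  test ACC %.4f, F1 %.4f\n", x$metrics$ACC, x$metrics$F1))
  invisible(x)
}

#' @export
glance.blood_pipeline <- function(x, ...) x$metrics

#' @export
tidy.ncfs_fit <- function(x, ...) {
  tibble(feature = seq_along(x$weights),
         wavelength = if (is.null(x$wavelengths)) NA_real_ else x$wavelengths,
         weight = x$weights)
}

#' @export
glance.ncfs_fit <- function(x, ...) {
  tibble(n_features = length(x$weights), lambda = x$lambda, sigma = x$sigma,
         learning_rate = x$learning_rate, objective = x$objective,
         epochs = x$epochs, n = x$n)
}
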