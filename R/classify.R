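#' Polynomial-kernel SVM specification
#'
#' The classifier is a C-SVM with the polynomial kernel
#' `K(u, v) = (u'v / s^2 + 1)^d`, parameterised the way imaging-spectroscopy
#' practitioners quote it: a kernel scale `s` and a box constraint `C`
#' (margin-violation cost). Internally the kernel scale maps to
#' `gamma = 1 / s^2` with `coef0 = 1`.
#'
#' @param degree polynomial degree (default 3).
#' @param box_constraint cost parameter C (default 74.185).
#' @param kernel_scale kernel scale s (default 2.7558).
#' @param bands integer indices of the feature subset the model uses
#'   (`NULL` = all bands).
#' @param seed integer seed carried along for reproducibility bookkeeping.
#' @return Object of class `svm_spec`.
#' @export
svm_spec <- function(degree = 3, box_constraint = 74.185,
                     kernel_scale = 2.7558, bands = NULL, seed = 1) {
  if (degree < 1) abort("degree must be >= 1")
  if (box_constraint <= 0) abort("box_constraint must be > 0")
  if (kernel_scale <= 0) abort("kernel_scale must be > 0")
  structure(list(degree = degree, box_constraint = box_constraint,
                 kernel_scale = kernel_scale, bands = bands,
                 seed = as.integer(seed)),
            class = "svm_spec")
}

#' Train the human/animal SVM
#'
#' @param train labelled-spectra tibble with a binary `class` column
#'   (1 = human, 0 = animal); spectra should already be preprocessed.
#' @param spec an [svm_spec()].
#' @return Object of class `blood_svm` wrapping the fitted e1071 model
#'   together with the band subset, wavelength axis and preprocessing
#'   provenance needed to replay the transform on new cubes.
#' @export
train_svm <- function(train, spec = svm_spec()) {
  y <- train$class
  if (length(unique(y)) < 2) abort("training set must contain both classes")
  X <- spectra_matrix(train)
  bands <- spec$bands %||% seq_len(ncol(X))
  fit <- e1071::svm(X[, bands, drop = FALSE], factor(y, levels = c(0, 1)),
                    type = "C-classification", kernel = "polynomial",
                    degree = spec$degree, cost = spec$box_constraint,
                    gamma = 1 / spec$kernel_scale^2, coef0 = 1,
                    scale = FALSE)
  structure(list(fit = fit, spec = spec, bands = bands,
                 wavelengths = spectra_wavelengths(train),
                 preprocess = attr(train, "preprocess")),
            class = "blood_svm")
}

#' @export
print.blood_svm <- function(x, ...) {
  cat(sprintf("<blood_svm> degree-%d polynomial, C = %.4g, scale = %.4g, %d bands\n",
              x$spec$degree, x$spec$box_constraint, x$spec$kernel_scale,
              length(x$bands)))
  invisible(x)
}

#' Predict human (1) / animal (0) labels
#'
#' @param object a [train_svm()] model.
#' @param newdata labelled-spectra tibble or bare matrix on the model's
#'   wavelength axis.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.blood_svm <- function(object, newdata, ...) {
  X <- spectra_matrix(newdata)
  if (ncol(X) != length(object$wavelengths)) {
    abort(sprintf("model expects %d bands, data has %d",
                  length(object$wavelengths), ncol(X)))
  }
  p <- predict(object$fit, X[, object$bands, drop = FALSE])
  as.integer(as.character(p))
}

#' k-fold cross-validation of an SVM specification
#'
#' Folds are stratified by class; when every class has at least `k`
#' individuals the fold unit is the individual (grouped CV), which prevents
#' pixel spectra of one donor from straddling a fold boundary, otherwise
#' folds are drawn at the observation level. Loss is the misclassification
#' rate.
#'
#' @param spec an [svm_spec()].
#' @param data labelled-spectra tibble with `class` (and optionally
#'   `individual`) columns.
#' @param k number of folds.
#' @param seed integer seed for the fold draw.
#' @param group_by_individual prefer individual-level folds when feasible.
#' @return Tibble of class `cv_result` (one row): `degree`,
#'   `box_constraint`, `kernel_scale`, `cv_mean`, `cv_se` and a `fold_loss`
#'   list-column of per-fold losses.
#' @export
cross_validate <- function(spec, data, k = 10, seed = 1,
                           group_by_individual = TRUE) {
  if (k < 2) abort("k must be >= 2")
  y <- data$class
  classes <- unique(y)
  folds <- integer(nrow(data))
  grouped <- group_by_individual && "individual" %in% names(data) &&
    all(vapply(classes, function(cl)
      length(unique(data$individual[y == cl])) >= k, logical(1)))
  withr::with_seed(seed, {
    if (grouped) {
      for (cl in classes) {
        ids <- unique(data$individual[y == cl])
        fid <- sample(rep_len(seq_len(k), length(ids)))
        map <- setNames(fid, ids)
        rows <- which(y == cl)
        folds[rows] <- map[data$individual[rows]]
      }
    } else {
      for (cl in classes) {
        rows <- which(y == cl)
        folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
      }
    }
  })
  loss <- vapply(seq_len(k), function(f) {
    tr <- data[folds != f, ]; te <- data[folds == f, ]
    if (nrow(te) == 0) return(NA_real_)
    if (length(unique(tr$class)) < 2 || length(unique(te$class)) < 2) {
      abort(sprintf("fold %d lost a class after stratification", f))
    }
    fit <- train_svm(tr, spec)
    mean(predict(fit, te) != te$class)
  }, numeric(1))
  loss <- loss[!is.na(loss)]
  out <- tibble(degree = spec$degree,
                box_constraint = spec$box_constraint,
                kernel_scale = spec$kernel_scale,
                cv_mean = mean(loss),
                cv_se = sd(loss) / sqrt(length(loss)),
                fold_loss = list(loss))
  class(out) <- c("cv_result", class(out))
  out
}

#' One-standard-error model selection
#'
#' Among candidates whose mean cross-validation loss is within one standard
#' error of the smallest mean loss, pick the simplest: smallest kernel scale,
#' then smallest box constraint, ties broken by input order.
#'
#' @param candidates tibble with `cv_mean`, `cv_se`, `kernel_scale`,
#'   `box_constraint` columns (e.g. rows from [cross_validate()]).
#' @return The chosen candidate row.
#' @export
select_model_1se <- function(candidates) {
  if (nrow(candidates) == 0) abort("candidate list is empty")
  i_best <- which.min(candidates$cv_mean)
  cutoff <- candidates$cv_mean[i_best] + candidates$cv_se[i_best]
  ok <- which(candidates$cv_mean <= cutoff)
  ord <- ok[order(candidates$kernel_scale[ok], candidates$box_constraint[ok])]
  candidates[ord[1], ]
}

#' Seeded grid search over SVM hyperparameters
#'
#' Evaluates every (box constraint, kernel scale) pair by k-fold
#' cross-validation. A deterministic grid search replaces time-dependent
#' acquisition-driven optimisers: identical seeds give identical tables.
#'
#' @param data labelled-spectra tibble.
#' @param grid data frame with `box_constraint` and `kernel_scale` columns;
#'   the default small log-grid contains the package's default operating
#'   point (74.185, 2.7558).
#' @param degree polynomial degree shared by all candidates.
#' @param k,seed cross-validation settings.
#' @return Tibble of candidates with CV losses, ordered as the grid.
#' @export
hyperparameter_search <- function(data,
                                  grid = default_svm_grid(),
                                  degree = 3, k = 10, seed = 1) {
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("hyperparameter grid is empty")
  stopifnot(all(c("box_constraint", "kernel_scale") %in% names(grid)))
  bind_rows(lapply(seq_len(nrow(grid)), function(r) {
    cross_validate(svm_spec(degree = degree,
                            box_constraint = grid$box_constraint[r],
                            kernel_scale = grid$kernel_scale[r]),
                   data, k = k, seed = seed)
  }))
}

#' @rdname hyperparameter_search
#' @export
default_svm_grid <- function() {
  tidyr::crossing(box_constraint = c(1, 10, 74.185),
                  kernel_scale = c(1, 2.7558, 8))
}

#' Confusion-matrix metrics of a binary classifier
#'
#' @param y_true,y_pred equal-length binary label vectors (positive class 1).
#' @return One-row tibble: `TOT` (observations), `PREV` (positive
#'   prevalence), `ACC`, `PPV` (precision), `TPR` (sensitivity/recall),
#'   `TNR` (specificity) and `F1 = 2 * PPV * TPR / (PPV + TPR)`. Ratios with
#'   zero denominators are reported as `NA`, never as 0.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("label vectors must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) abort("labels must be binary 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  tot <- tp + fp + tn + fn
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  ppv <- safe(tp, tp + fp)
  tpr <- safe(tp, tp + fn)
  f1 <- if (is.na(ppv) || is.na(tpr) || (ppv + tpr) == 0) NA_real_ else
    2 * ppv * tpr / (ppv + tpr)
  tibble(TOT = tot, PREV = safe(tp + fn, tot), ACC = safe(tp + tn, tot),
         PPV = ppv, TPR = tpr, TNR = safe(tn, tn + fp), F1 = f1)
}

#' Per-pixel segmentation of a bloodstain scene
#'
#' Runs the full inference chain on one reflectance cube: ABD background
#' masking (plus morphological closing), per-pixel replay of the model's
#' preprocessing, and per-pixel SVM classification of the surviving pixels.
#' Background pixels are left untouched; no post-processing is applied to
#' the classified labels.
#'
#' @param cube reflectance-kind [hypercube()] on the model's original
#'   (pre-truncation) wavelength axis.
#' @param model a [train_svm()] model trained on preprocessed spectra and
#'   carrying preprocessing provenance.
#' @param params an [abd_params()].
#' @return Object of class `blood_segmentation`: `labels` (integer matrix,
#'   0 background / 1 human / 2 animal), `mask` (the closed ABD mask) and
#'   `overlay` (RGB array: yellow = human, blue = animal, alpha 0.5 over a
#'   pseudo-colour rendering from the bands nearest 640/550/460 nm).
#' @export
segment_image <- function(cube, model, params = abd_params()) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "blood_svm"))
  if (cube$kind != "reflectance") abort("segment_image needs a reflectance cube")
  if (is.null(model$preprocess)) {
    abort("model carries no preprocessing provenance; train on preprocess_pipeline() output")
  }
  mask <- close_mask(abd_mask(cube, params), params$closing_radius)
  d <- dim(cube$values)
  labels <- matrix(0L, d[1], d[2])
  if (any(mask)) {
    px <- which(mask, arr.ind = TRUE)
    lin <- px[, 1] + (px[, 2] - 1L) * d[1]
    spec <- matrix(0, nrow(px), d[3])
    for (b in seq_len(d[3])) spec[, b] <- cube$values[lin + (b - 1L) * d[1] * d[2]]
    pp <- preprocess_matrix(spec, cube$wavelengths, model$preprocess$config)
    if (length(pp$wavelengths) != length(model$wavelengths) ||
        max(abs(pp$wavelengths - model$wavelengths)) > 1e-6) {
      abort("cube wavelength axis does not match the model's preprocessing provenance")
    }
    pred <- predict(model, pp$spectra)
    labels[mask] <- ifelse(pred == 1L, 1L, 2L)
  }
  structure(list(labels = labels, mask = mask,
                 overlay = segmentation_overlay(cube, labels)),
            class = "blood_segmentation")
}

# alpha-blend class colours over a pseudo-RGB rendering of the cube
segmentation_overlay <- function(cube, labels, alpha = 0.5) {
  wl <- cube$wavelengths
  rgb_bands <- vapply(c(640, 550, 460), function(t) which.min(abs(wl - t)),
                      integer(1))
  base <- cube$values[, , rgb_bands, drop = FALSE]
  base <- pmin(pmax(base, 0), 1)
  cols <- list(`1` = c(1, 1, 0), `2` = c(0, 0, 1))  # human yellow, animal blue
  out <- base
  for (lab in c(1L, 2L)) {
    sel <- labels == lab
    if (!any(sel)) next
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * cols[[as.character(lab)]][ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Fraction of ground-truth stain pixels given a label
#'
#' Convenience accuracy measure for synthetic scenes where the true stain
#' mask is known.
#'
#' @param segmentation a [segment_image()] result.
#' @param truth_mask logical ground-truth stain mask.
#' @param label target label (1 human, 2 animal).
#' @return fraction in `[0, 1]`.
#' @export
stain_label_fraction <- function(segmentation, truth_mask, label) {
  mean(segmentation$labels[truth_mask] == label)
}
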