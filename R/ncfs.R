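#' Neighbourhood component feature selection (NCFS)
#'
#' NCFS learns one nonnegative weight per wavelength by maximising the
#' expected leave-one-out accuracy of a soft nearest-neighbour classifier
#' under a weighted L1 distance with squared weights,
#' `d_w(x_i, x_j) = sum_l w_l^2 |x_il - x_jl|`. Each observation picks a
#' reference neighbour with probability `p_ij` proportional to
#' `exp(-d_w(x_i, x_j) / sigma)` over `j != i`; the objective is
#' `sum_i sum_{j : y_j = y_i} p_ij - lambda * sum_l w_l^2`. An L2 penalty
#' `lambda` of order `1 / n` drives irrelevant weights to zero; with
#' `lambda = 0` essentially every feature keeps a positive weight, which is
#' why downstream selection thresholds on a fraction of the maximum weight.
#'
#' @param lambda regularisation strength; `NULL` means the `1 / n` heuristic
#'   is filled in at fit time from the training-set size.
#' @param sigma kernel width of the reference-probability kernel. SNV puts
#'   every band on a comparable scale, so 1 is a sensible default.
#' @param batch_size mini-batch size of the stochastic gradient solver.
#' @param learning_rates candidate initial rates; the solver tunes among
#'   them on a subset of the data before the main run.
#' @param tuning_subset number of observations used for rate tuning.
#' @param epochs passes over the data.
#' @param seed integer seed for batching and tuning.
#' @return Object of class `ncfs_config`.
#' @export
ncfs_config <- function(lambda = NULL, sigma = 1, batch_size = 1000,
                        learning_rates = 10^seq(-3, 0), tuning_subset = 10000,
                        epochs = 10, seed = 1) {
  if (!is.null(lambda) && lambda < 0) abort("lambda must be >= 0")
  if (sigma <= 0) abort("sigma must be > 0")
  if (batch_size < 1) abort("batch_size must be >= 1")
  structure(list(lambda = lambda, sigma = sigma, batch_size = batch_size,
                 learning_rates = learning_rates,
                 tuning_subset = tuning_subset, epochs = epochs,
                 seed = as.integer(seed)),
            class = "ncfs_config")
}

#' The lambda = 1/n regularisation heuristic
#'
#' The regularisation value minimising generalisation error is expected to
#' be a multiple of the inverse observation count; for large n it is
#' effectively zero.
#'
#' @param n training observation count.
#' @return `1 / n`.
#' @examples
#' lambda_heuristic(144020)  # 6.943e-06
#' @export
lambda_heuristic <- function(n) {
  if (n <= 0) abort("n must be positive")
  1 / n
}

#' NCFS objective function
#'
#' Exact (full-batch) evaluation of the regularised expected leave-one-out
#' accuracy. Quadratic in the number of observations; intended for small
#' instances, solver diagnostics and oracle tests.
#'
#' @param weights numeric weight vector, one per feature.
#' @param X observations-by-features matrix.
#' @param y class labels (any type; compared by equality).
#' @param lambda,sigma as in [ncfs_config()].
#' @return scalar objective value (higher is better).
#' @export
ncfs_objective <- function(weights, X, y, lambda = 0, sigma = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) abort("need at least 2 observations")
  if (length(unique(y)) < 2) abort("need at least 2 classes")
  w2 <- weights^2
  acc <- 0
  for (i in seq_len(n)) {
    D <- abs(sweep(X[-i, , drop = FALSE], 2, X[i, ]))
    d <- as.numeric(D %*% w2)
    k <- exp(-(d - min(d)) / sigma)      # shift for numerical stability
    p <- k / sum(k)
    acc <- acc + sum(p[y[-i] == y[i]])
  }
  acc / n - lambda * sum(w2)
}

# gradient of the (per-observation-averaged) objective on a batch
ncfs_gradient <- function(weights, X, y, lambda, sigma) {
  n <- nrow(X)
  w2 <- weights^2
  g <- numeric(length(weights))
  for (i in seq_len(n)) {
    D <- abs(sweep(X[-i, , drop = FALSE], 2, X[i, ]))
    d <- as.numeric(D %*% w2)
    k <- exp(-(d - min(d)) / sigma)
    p <- k / sum(k)
    same <- y[-i] == y[i]
    p_i <- sum(p[same])
    g <- g + (p_i * as.numeric(p %*% D) - as.numeric((p * same) %*% D)) / sigma
  }
  2 * weights * g / n - 2 * lambda * weights
}

#' Fit NCFS feature weights with a stochastic gradient solver
#'
#' Weights start at one, are updated by mini-batch gradient ascent and are
#' clipped at zero after each step. The initial learning rate is tuned by a
#' one-epoch run for each candidate rate on a subset of the data, scored by
#' the exact objective on that subset (capped at 2000 observations for the
#' scoring pass); the best rate then drives the main run with a mild
#' per-epoch decay.
#'
#' @param X observations-by-features matrix, or a labelled-spectra tibble
#'   (its `spectra` column and `class` labels are used).
#' @param y class labels; ignored when `X` is a labelled-spectra tibble.
#' @param config an [ncfs_config()].
#' @return Object of class `ncfs_fit`: `weights`, `wavelengths` (if known),
#'   `lambda`, `sigma`, `learning_rate`, `objective` (final exact objective
#'   on the scoring subset), `epochs`.
#' @export
ncfs_fit <- function(X, y = NULL, config = ncfs_config()) {
  wl <- NULL
  if (is.data.frame(X)) {
    if (is.null(y)) y <- X$class
    wl <- spectra_wavelengths(X)
    X <- spectra_matrix(X)
  }
  X <- as.matrix(X)
  if (any(!is.finite(X))) abort("X must be finite")
  if (length(y) != nrow(X)) abort("labels must match the observation count")
  if (length(unique(y)) < 2) abort("need at least 2 classes")
  n <- nrow(X); p <- ncol(X)
  lambda <- config$lambda %||% lambda_heuristic(n)
  sigma <- config$sigma
  bs <- min(config$batch_size, n)

  run_sgd <- function(X, y, w, rate, epochs, seed) {
    withr::with_seed(seed, {
      for (ep in seq_len(epochs)) {
        lr <- rate / (1 + (ep - 1) / max(epochs, 1))
        ord <- sample.int(nrow(X))
        starts <- seq(1, nrow(X), by = bs)
        for (s0 in starts) {
          b <- ord[s0:min(s0 + bs - 1, nrow(X))]
          if (length(b) < 2 || length(unique(y[b])) < 2) next
          g <- ncfs_gradient(w, X[b, , drop = FALSE], y[b], lambda, sigma)
          w <- pmax(w + lr * g, 0)
        }
      }
      w
    })
  }
  score_rows <- withr::with_seed(config$seed,
    sample.int(n, min(n, config$tuning_subset, 2000)))
  tune_rows <- withr::with_seed(config$seed + 1L,
    sample.int(n, min(n, config$tuning_subset)))

  w0 <- rep(1, p)
  scores <- vapply(config$learning_rates, function(r) {
    wt <- run_sgd(X[tune_rows, , drop = FALSE], y[tune_rows], w0, r,
                  epochs = 1, seed = config$seed + 2L)
    ncfs_objective(wt, X[score_rows, , drop = FALSE], y[score_rows],
                   lambda, sigma)
  }, numeric(1))
  rate <- config$learning_rates[which.max(scores)]

  w <- run_sgd(X, y, w0, rate, config$epochs, config$seed + 3L)
  obj <- ncfs_objective(w, X[score_rows, , drop = FALSE], y[score_rows],
                        lambda, sigma)
  structure(list(weights = w, wavelengths = wl, lambda = lambda,
                 sigma = sigma, learning_rate = rate, objective = obj,
                 epochs = config$epochs, n = n),
            class = "ncfs_fit")
}

#' @export
print.ncfs_fit <- function(x, ...) {
  cat(sprintf("<ncfs_fit> %d features, lambda = %.4g, objective = %.4f\n",
              length(x$weights), x$lambda, x$objective))
  invisible(x)
}

#' Select features above a fraction of the maximum weight
#'
#' @param weights an [ncfs_fit()] or a numeric weight vector.
#' @param fraction threshold as a fraction of the maximum weight; features
#'   with `w >= fraction * max(w)` (inclusive) are kept. Fraction 0 keeps
#'   all features; fraction 1 keeps the arg-max (ties included).
#' @return integer vector of selected feature indices.
#' @export
select_features <- function(weights, fraction = 0.55) {
  w <- if (inherits(weights, "ncfs_fit")) weights$weights else as.numeric(weights)
  if (all(w == 0)) abort("all feature weights are zero; nothing to select")
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1]")
  which(w >= fraction * max(w))
}

#' F1 score of a 1-nearest-neighbour classifier on a band subset
#'
#' Trains Euclidean 1-NN on the training spectra restricted to `bands` and
#' scores the validation set by F1 (positive class = 1). Used to evaluate
#' how much discriminative information a candidate feature set retains.
#'
#' @param train,validation labelled-spectra tibbles with `class` columns.
#' @param bands integer band indices (default: all).
#' @return F1 score in `[0, 1]`.
#' @export
knn1_f1 <- function(train, validation, bands = NULL) {
  if (nrow(validation) == 0) abort("validation set is empty")
  Xtr <- spectra_matrix(train); Xva <- spectra_matrix(validation)
  bands <- bands %||% seq_len(ncol(Xtr))
  if (length(bands) == 0) abort("band subset is empty")
  pred <- class::knn(Xtr[, bands, drop = FALSE], Xva[, bands, drop = FALSE],
                     factor(train$class), k = 1)
  compute_metrics(validation$class, as.integer(as.character(pred)))$F1
}

#' Feature-count / F1 trade-off curve over threshold fractions
#'
#' For each threshold fraction, selects the surviving bands, evaluates a
#' 1-NN classifier on the validation set, and reports the dimensionality
#' reduction relative to the full band set.
#'
#' @param fit an [ncfs_fit()] (or numeric weights).
#' @param train,validation labelled-spectra tibbles.
#' @param fractions ascending threshold fractions; include 0 for the
#'   no-selection baseline.
#' @return Tibble of class `feature_curve`: `fraction`, `n_bands`,
#'   `reduction_pct`, `f1`.
#' @export
feature_curve <- function(fit, train, validation,
                          fractions = c(0, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75)) {
  if (is.unsorted(fractions)) abort("fractions must be sorted ascending")
  w <- if (inherits(fit, "ncfs_fit")) fit$weights else as.numeric(fit)
  total <- length(w)
  rows <- lapply(fractions, function(f) {
    idx <- select_features(w, f)
    tibble(fraction = f, n_bands = length(idx),
           reduction_pct = dimensionality_reduction_pct(total, length(idx)),
           f1 = knn1_f1(train, validation, idx))
  })
  out <- bind_rows(rows)
  class(out) <- c("feature_curve", class(out))
  out
}

#' Dimensionality-reduction percentage
#'
#' @param from,to band counts before and after selection.
#' @return percentage reduction, `100 * (1 - to / from)`.
#' @examples
#' dimensionality_reduction_pct(170, 68)  # 60
#' @export
dimensionality_reduction_pct <- function(from, to) {
  if (from <= 0) abort("from must be positive")
  100 * (1 - to / from)
}
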