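#' Exponential age bins for bloodstain spectra
#'
#' Stain composition drifts roughly exponentially with age, so age bins that
#' follow the natural exponential series `f(x) = e^x`, `x = 0..3`, represent
#' the drift evenly: raw boundaries 1, 2.718, 7.389, 20.086 days, rounded
#' operationally to the edges 0 / 1 / 3 / 7 / 20 / 55 days (five bins).
#'
#' @return Object of class `age_binning` with fields `raw_boundaries`
#'   (`e^x` for `x = 0..3`), `edges` (rounded bin edges) and `n_bins`.
#' @export
exp_bin_edges <- function() {
  structure(
    list(raw_boundaries = exp(0:3),
         edges = c(0, 1, 3, 7, 20, 55),
         n_bins = 5L),
    class = "age_binning"
  )
}

#' Assign an age to its bin
#'
#' Bins are half-open `[lo, hi)` on the rounded edges, with the last bin
#' closed at 55 days. Indices are 0-based (0-4), matching the five printed
#' intervals.
#'
#' @param age numeric vector of ages in days, within `[0, 55]`.
#' @param binning an [exp_bin_edges()] result.
#' @return integer bin indices in 0..4.
#' @export
assign_bin <- function(age, binning = exp_bin_edges()) {
  if (any(age < binning$edges[1] | age > binning$edges[6])) {
    abort(sprintf("ages must lie within [%g, %g] days",
                  binning$edges[1], binning$edges[6]))
  }
  idx <- findInterval(age, binning$edges[1:5])  # 1..5; half-open, last closed
  as.integer(idx - 1L)
}

#' Three-pass hierarchical undersampling balance
#'
#' Balances pixel-spectrum counts without replacement, in three seeded
#' passes:
#' 1. within each species, every age bin is undersampled to that species'
#'    smallest bin;
#' 2. animal species are undersampled to equal per-species sizes;
#' 3. the larger class (human vs animal) is undersampled to the smaller,
#'    stratified by age bin so the age distribution is maintained.
#'
#' After the passes, every animal (species, bin) cell holds the same count,
#' every human bin holds `n_animal_species` times that count, and the two
#' class totals are exactly equal. When the limiting class total is not
#' divisible by the animal cell grid, the handful of observations that would
#' break exact equality are dropped from both classes.
#'
#' @param data labelled-spectra tibble with `species`, `class` and `age_bin`
#'   columns (see [assign_bin()]).
#' @param seed integer seed; same seed, same selected rows.
#' @return The balanced subset of `data` (rows are a subset of the input).
#' @export
hierarchical_balance <- function(data, seed = 1) {
  need <- c("species", "class", "age_bin")
  if (!all(need %in% names(data))) {
    abort("data needs species, class and age_bin columns")
  }
  bins <- sort(unique(data$age_bin))
  species <- unique(data$species)
  for (s in species) {
    for (b in bins) {
      if (sum(data$species == s & data$age_bin == b) == 0) {
        abort(sprintf("empty cell: species '%s' has no observations in age bin %d", s, b))
      }
    }
  }
  withr::with_seed(seed, {
    # pass 1: equalise bins within species
    keep <- unlist(lapply(species, function(s) {
      rows_s <- which(data$species == s)
      tab <- table(data$age_bin[rows_s])
      target <- min(tab)
      unlist(lapply(bins, function(b) {
        r <- rows_s[data$age_bin[rows_s] == b]
        sort(sample(r, target))
      }))
    }))
    d1 <- data[sort(keep), ]

    # pass 2: equalise animal species (per (species, bin) cell)
    animals <- unique(d1$species[d1$class == 0])
    if (length(animals) > 0) {
      per_bin <- vapply(animals, function(s)
        sum(d1$species == s & d1$age_bin == bins[1]), integer(1))
      cell2 <- min(per_bin)
      keep2 <- unlist(lapply(animals, function(s) {
        unlist(lapply(bins, function(b) {
          r <- which(d1$species == s & d1$age_bin == b)
          sort(sample(r, cell2))
        }))
      }))
      keep2 <- c(keep2, which(d1$class == 1))
      d2 <- d1[sort(keep2), ]
    } else {
      d2 <- d1
    }

    # pass 3: equalise class totals, stratified by bin; exact equality is
    # enforced by sizing every animal cell to `cell3` and every human bin to
    # `n_animals * cell3`
    humans_present <- any(d2$class == 1)
    if (humans_present && length(animals) > 0) {
      n_h <- sum(d2$class == 1)
      n_a <- sum(d2$class == 0)
      nb <- length(bins)
      na_sp <- length(animals)
      cell3 <- min(floor(n_h / (nb * na_sp)), floor(n_a / (nb * na_sp)))
      if (cell3 < 1) abort("too few observations to balance classes")
      keep3 <- unlist(lapply(bins, function(b) {
        hr <- which(d2$class == 1 & d2$age_bin == b)
        ar <- unlist(lapply(animals, function(s) {
          r <- which(d2$species == s & d2$age_bin == b)
          sort(sample(r, cell3))
        }))
        c(sort(sample(hr, cell3 * na_sp)), ar)
      }))
      d3 <- d2[sort(keep3), ]
    } else {
      d3 <- d2
    }
    d3
  })
}

# Table-2-style per-species train fractions of individuals
default_train_fractions <- function() {
  c(human = 0.75, pig = 0.8, cow = 0.8, mouse = 0.8125, rat = 0.8, rabbit = 0.8)
}

#' Split a cohort into train and holdout sets by individual
#'
#' Individuals (not pixels) are the sampling unit, so no donor contributes
#' spectra to both sides — the leakage guard pixel-level splits lack.
#'
#' @param data labelled-spectra tibble with `species` and `individual`.
#' @param train_fraction scalar fraction, or a named per-species vector of
#'   fractions of individuals to place in training. Defaults mirror a
#'   15/5 human, 16/4 pig and cow, 13/3 mouse, 4/1 rat and rabbit layout.
#' @param seed integer seed.
#' @return List with `train` and `holdout` labelled-spectra tibbles.
#' @export
split_by_individual <- function(data, train_fraction = default_train_fractions(),
                                seed = 1) {
  stopifnot(all(c("species", "individual") %in% names(data)))
  species <- unique(data$species)
  frac_for <- function(s) {
    if (length(train_fraction) == 1 && is.null(names(train_fraction))) {
      return(train_fraction)
    }
    if (s %in% names(train_fraction)) return(train_fraction[[s]])
    0.75
  }
  train_ids <- withr::with_seed(seed, {
    unlist(lapply(species, function(s) {
      ids <- sort(unique(data$individual[data$species == s]))
      if (length(ids) < 2) {
        abort(sprintf("species '%s' has a single individual; cannot split", s))
      }
      n_tr <- round(length(ids) * frac_for(s))
      n_tr <- max(1L, min(length(ids) - 1L, n_tr))
      sample(ids, n_tr)
    }))
  })
  in_train <- data$individual %in% train_ids
  list(train = data[in_train, ], holdout = data[!in_train, ])
}

#' Split a holdout pool into validation and test sets
#'
#' Observation-level random split: a `validation_fraction` share goes to
#' validation (used to compare optimised models) and the remainder to the
#' final independent test set.
#'
#' @param holdout labelled-spectra tibble.
#' @param validation_fraction share assigned to validation (default 0.66).
#' @param seed integer seed.
#' @return List with `validation` and `test` tibbles; together they
#'   partition the input.
#' @export
split_validation_test <- function(holdout, validation_fraction = 0.66, seed = 1) {
  n <- nrow(holdout)
  if (n == 0) abort("holdout pool is empty")
  n_test <- round(n * (1 - validation_fraction))
  test_rows <- withr::with_seed(seed, sample.int(n, n_test))
  list(validation = holdout[-test_rows, ], test = holdout[test_rows, ])
}
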