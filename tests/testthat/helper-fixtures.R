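# Small fixtures shared across the suite; everything is generated in code.

# a compact scene that renders in well under a second
small_scene_config <- function(seed = 1, noise_sd = 0.01, species = "human",
                               age_days = 0.1, n_bands = 204) {
  scene_config(species = species, age_days = age_days,
               width = 48, height = 48, centre = c(24, 24), radius = 15,
               wavelengths = seq(400, 1000, length.out = n_bands),
               noise_sd = noise_sd, seed = seed)
}

render_small_reflectance <- function(...) {
  sc <- render_scene(small_scene_config(...))
  list(refl = calibrate_reflectance(sc$raw, sc$dark, sc$white),
       scene = sc)
}

# a labelled-spectra table with two species and all five age bins, sized for
# balance/split tests (counts chosen unequal on purpose)
toy_cohort_spectra <- function(seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    specs <- list(human = 1:4, pig = 1:3, cow = 1:3)
    ages <- c(0.5, 2, 5, 10, 30)
    for (sp in names(specs)) {
      for (ind in specs[[sp]]) {
        for (a in ages) {
          n <- sample(8:16, 1)
          rows[[length(rows) + 1]] <- labelled_spectra(
            matrix(rnorm(n * 6), n, 6) + (sp == "human"),
            c(450, 500, 550, 600, 650, 700),
            tibble::tibble(species = sp,
                           class = as.integer(sp == "human"),
                           individual = sprintf("%s_%d", sp, ind),
                           roi_id = sprintf("%s_%d_%g", sp, ind, a),
                           age_days = a))
        }
      }
    }
    out <- bind_spectra(rows)
    out$age_bin <- assign_bin(out$age_days)
    out$obs_id <- seq_len(nrow(out))
    out
  })
}

# Independent brute-force NCFS objective: scalar double loop, no shared code
# with the package implementation.
ncfs_objective_brute <- function(w, X, y, lambda = 0, sigma = 1) {
  n <- nrow(X)
  acc <- 0
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), i)
    d <- vapply(js, function(j) sum(w^2 * abs(X[i, ] - X[j, ])), numeric(1))
    k <- exp(-d / sigma)
    p <- k / sum(k)
    acc <- acc + sum(p[y[js] == y[i]])
  }
  acc / n - lambda * sum(w^2)
}

# Independent brute-force 1-NN prediction
knn1_brute <- function(Xtr, ytr, Xte) {
  apply(Xte, 1, function(x) {
    ytr[which.min(colSums((t(Xtr) - x)^2))]
  })
}

# planted-band instance: bands `planted` carry a class shift of `effect`
planted_instance <- function(n = 80, p = 15, planted = c(4, 11), effect = 2,
                             noise_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(rnorm(n * p, sd = noise_sd), n, p)
    for (b in planted) X[, b] <- X[, b] + effect * y
    list(X = X, y = y)
  })
}
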