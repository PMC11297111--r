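test_that("the lambda heuristic is 1/n", {
  expect_equal(signif(lambda_heuristic(144020), 4), 6.943e-6)
  expect_error(lambda_heuristic(0), "positive")
})

test_that("objective matches forced small-instance structure", {
  # two observations of different classes: the only neighbour is wrong, so
  # the accuracy term is zero and the objective is the bare penalty
  X <- rbind(c(0, 0), c(1, 1)); y <- c(0, 1)
  w <- c(0.5, 2)
  expect_equal(ncfs_objective(w, X, y, lambda = 0.3), -0.3 * sum(w^2))

  # all-zero weights: distances vanish, reference probabilities are uniform,
  # objective is the mean same-class neighbour fraction
  X4 <- matrix(rnorm(8), 4, 2); y4 <- c(0, 0, 1, 1)
  expect_equal(ncfs_objective(rep(0, 2), X4, y4), 1 / 3)

  expect_error(ncfs_objective(w, X, c(1, 1)), "classes")
  expect_error(ncfs_objective(w, X[1, , drop = FALSE], 1), "observations")
})

test_that("objective agrees with a brute-force double loop", {
  withr::with_seed(8, {
    for (rep in 1:3) {
      n <- 20; p <- 6
      X <- matrix(rnorm(n * p), n, p)
      y <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1] <- 1 - y[1]
      w <- runif(p, 0, 2)
      lam <- runif(1, 0, 0.5); sig <- runif(1, 0.5, 3)
      expect_equal(ncfs_objective(w, X, y, lam, sig),
                   ncfs_objective_brute(w, X, y, lam, sig),
                   tolerance = 1e-8)
    }
  })
})

test_that("objective is invariant to observation order", {
  withr::with_seed(12, {
    X <- matrix(rnorm(60), 15, 4)
    y <- rep(c(0, 1), length.out = 15)
    w <- runif(4)
    perm <- sample(15)
    expect_equal(ncfs_objective(w, X, y, 0.1, 1.5),
                 ncfs_objective(w, X[perm, ], y[perm], 0.1, 1.5))
  })
})

test_that("analytic gradient matches finite differences", {
  withr::with_seed(30, {
    n <- 25; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(0, 1), length.out = n)
    w <- runif(p, 0.2, 1.5)
    lam <- 0.05; sig <- 1.3
    g <- bloodhsi:::ncfs_gradient(w, X, y, lam, sig)
    eps <- 1e-6
    g_fd <- vapply(seq_len(p), function(l) {
      wp <- w; wp[l] <- wp[l] + eps
      wm <- w; wm[l] <- wm[l] - eps
      (ncfs_objective(wp, X, y, lam, sig) -
         ncfs_objective(wm, X, y, lam, sig)) / (2 * eps)
    }, numeric(1))
    expect_equal(g, g_fd, tolerance = 1e-4)
  })
})

test_that("the solver recovers a planted informative band", {
  inst <- planted_instance(n = 100, p = 20, planted = 5, effect = 3, seed = 2)
  fit <- ncfs_fit(inst$X, inst$y,
                  ncfs_config(lambda = 0, batch_size = 50, epochs = 10, seed = 3))
  expect_equal(which.max(fit$weights), 5)
  expect_true(all(fit$weights >= 0))

  # huge regularisation drives every weight to zero
  fit0 <- ncfs_fit(inst$X, inst$y,
                   ncfs_config(lambda = 1e3, batch_size = 50, epochs = 3, seed = 3))
  expect_true(all(fit0$weights <= 1e-6))

  # reproducibility under a fixed config
  fit2 <- ncfs_fit(inst$X, inst$y,
                   ncfs_config(lambda = 0, batch_size = 50, epochs = 10, seed = 3))
  expect_identical(fit$weights, fit2$weights)

  bad <- inst$X; bad[1, 1] <- NA
  expect_error(ncfs_fit(bad, inst$y), "finite")
})

test_that("planted bands are recovered across seeded replicates", {
  hits <- vapply(1:20, function(s) {
    inst <- planted_instance(n = 80, p = 15, planted = c(4, 11), effect = 2,
                             noise_sd = 1, seed = s)
    fit <- ncfs_fit(inst$X, inst$y,
                    ncfs_config(lambda = 0, batch_size = 40, epochs = 8,
                                seed = s + 100))
    top2 <- order(fit$weights, decreasing = TRUE)[1:2]
    sum(top2 %in% c(4, 11)) >= 1  # at least k - 1 of the k planted bands
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fraction-of-max selection is inclusive and nested", {
  w <- c(26.12, 13.0, 14.0)
  expect_equal(select_features(w, 0.5), c(1L, 3L))  # cutoff 13.06
  expect_equal(select_features(w, 0), 1:3)
  expect_equal(select_features(w, 1), 1L)
  expect_equal(select_features(c(2, 2, 1), 1), c(1L, 2L))  # max ties kept
  expect_error(select_features(c(0, 0, 0), 0.5), "zero")

  # nestedness over increasing fractions
  withr::with_seed(5, wr <- runif(40))
  sets <- lapply(seq(0, 1, by = 0.1), function(f) select_features(wr, f))
  for (k in seq_along(sets)[-1]) {
    expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  }
})

test_that("1-NN F1 evaluation matches a brute-force search", {
  withr::with_seed(14, {
    wl <- seq(500, 950, length.out = 10)
    Xtr <- matrix(rnorm(50 * 10), 50, 10)
    ytr <- rep(c(0L, 1L), 25)
    Xte <- matrix(rnorm(30 * 10), 30, 10)
    yte <- rep(c(0L, 1L), 15)
    tr <- labelled_spectra(Xtr, wl, tibble::tibble(class = ytr))
    te <- labelled_spectra(Xte, wl, tibble::tibble(class = yte))
    pred_brute <- knn1_brute(Xtr, ytr, Xte)
    f1_brute <- compute_metrics(yte, pred_brute)$F1
    expect_equal(knn1_f1(tr, te), f1_brute)

    # duplicated validation data matches itself exactly
    expect_equal(knn1_f1(tr, tr), 1)
    expect_error(knn1_f1(tr, te[0, ]), "empty")
  })
})

test_that("shuffled labels give chance-level F1", {
  withr::with_seed(15, {
    wl <- seq(500, 950, length.out = 8)
    f1s <- vapply(1:200, function(k) {
      Xtr <- matrix(rnorm(40 * 8), 40, 8)
      Xte <- matrix(rnorm(40 * 8), 40, 8)
      tr <- labelled_spectra(Xtr, wl, tibble::tibble(class = sample(rep(0:1, 20))))
      te <- labelled_spectra(Xte, wl, tibble::tibble(class = sample(rep(0:1, 20))))
      knn1_f1(tr, te)
    }, numeric(1))
    expect_lt(abs(mean(f1s) - 0.5), 0.1)
  })
})

test_that("the feature curve reports counts, reduction and F1 per threshold", {
  inst <- planted_instance(n = 60, p = 12, planted = c(3, 9), effect = 3, seed = 4)
  wl <- seq(450, 950, length.out = 12)
  d <- labelled_spectra(inst$X, wl, tibble::tibble(class = inst$y))
  fit <- ncfs_fit(d, config = ncfs_config(lambda = 0, batch_size = 30,
                                          epochs = 6, seed = 9))
  fc <- feature_curve(fit, d, d, fractions = c(0, 0.5, 0.9))
  expect_equal(nrow(fc), 3)
  expect_equal(fc$n_bands[1], 12)
  expect_equal(fc$reduction_pct[1], 0)
  expect_true(all(diff(fc$n_bands) <= 0))  # non-increasing in fraction
  expect_true(all(fc$f1 >= 0 & fc$f1 <= 1))

  fc1 <- feature_curve(fit, d, d, fractions = 0.5)
  expect_equal(nrow(fc1), 1)
  expect_error(feature_curve(fit, d, d, fractions = c(0.5, 0.1)), "ascending")

  # the reference reduction arithmetic
  expect_equal(dimensionality_reduction_pct(170, 68), 60)
})
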