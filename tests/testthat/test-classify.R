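# separable two-band toy problem
toy_separable <- function(n = 40, seed = 6) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), n / 2)
    X <- matrix(rnorm(n * 2, sd = 0.3), n, 2)
    X[, 1] <- X[, 1] + 3 * y
    labelled_spectra(X, c(500, 600), tibble::tibble(class = y))
  })
}

test_that("the SVM separates a separable toy set and is label-symmetric", {
  d <- toy_separable()
  fit <- train_svm(d, svm_spec(bands = 1:2))
  expect_equal(predict(fit, d), d$class)

  flipped <- d; flipped$class <- 1L - flipped$class
  fit2 <- train_svm(flipped, svm_spec(bands = 1:2))
  expect_equal(predict(fit2, d), 1L - predict(fit, d))

  single <- d[d$class == 1, ]
  expect_error(train_svm(single), "both classes")
  expect_error(svm_spec(box_constraint = -1), "box_constraint")
  expect_error(svm_spec(kernel_scale = 0), "kernel_scale")
})

test_that("cross-validation is stratified, seeded and exact for a perfect model", {
  d <- toy_separable(n = 60)
  cv <- cross_validate(svm_spec(), d, k = 5, seed = 2)
  expect_equal(cv$cv_mean, 0)

  cv2 <- cross_validate(svm_spec(), d, k = 5, seed = 2)
  expect_identical(cv$fold_loss, cv2$fold_loss)

  # leave-one-out boundary: k = n folds of size 1 per class strata
  d10 <- toy_separable(n = 10)
  cv_loo <- cross_validate(svm_spec(), d10, k = 5, seed = 1)
  expect_length(cv_loo$fold_loss[[1]], 5)
  expect_error(cross_validate(svm_spec(), d10, k = 1), "k must be")
})

test_that("grouped cross-validation keeps an individual inside one fold", {
  d <- toy_cohort_spectra()
  cv <- cross_validate(svm_spec(kernel_scale = 1, box_constraint = 1), d,
                       k = 3, seed = 4)
  expect_true(is.finite(cv$cv_mean))
})

test_that("1-SE selection picks the simplest candidate within one SE", {
  cand <- tibble::tibble(
    cv_mean = c(0.0047, 0.0060, 0.0300),
    cv_se = c(0.0020, 0.0020, 0.0020),
    kernel_scale = c(5, 2, 1),
    box_constraint = c(10, 10, 10))
  pick <- select_model_1se(cand)
  expect_equal(pick$kernel_scale, 2)  # 0.006 <= 0.0047 + 0.002; simpler scale

  expect_equal(nrow(select_model_1se(cand[1, ])), 1)

  # when only the minimum is inside the band, it is chosen
  cand2 <- cand; cand2$cv_se <- c(1e-5, 1e-5, 1e-5)
  expect_equal(select_model_1se(cand2)$kernel_scale, 5)
  expect_error(select_model_1se(cand[0, ]), "empty")
})

test_that("confusion-matrix metrics follow their defining formulas", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(m[c("ACC", "PPV", "TPR", "TNR", "F1")]),
               c(ACC = 1, PPV = 1, TPR = 1, TNR = 1, F1 = 1))

  # TP = FP = FN = TN = 1
  m2 <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(m2[c("ACC", "PPV", "TPR", "F1")]),
               c(ACC = 0.5, PPV = 0.5, TPR = 0.5, F1 = 0.5))
  expect_equal(m2$TOT, 4)
  expect_equal(m2$PREV, 0.5)

  # zero denominators surface as NA, never as 0
  m3 <- compute_metrics(c(1, 1, 1, 1), c(0, 0, 0, 0))
  expect_true(is.na(m3$PPV))
  expect_true(is.na(m3$TNR))

  expect_error(compute_metrics(c(1, 0), c(1)), "length")
  expect_error(compute_metrics(c(1, 2), c(1, 0)), "binary")
})

test_that("F1 recomputed from the report's own PPV and TPR is consistent", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      y <- sample(0:1, 30, replace = TRUE)
      p <- sample(0:1, 30, replace = TRUE)
      if (length(unique(y)) < 2) y[1] <- 1 - y[1]
      m <- compute_metrics(y, p)
      if (!is.na(m$F1)) {
        expect_equal(m$F1, 2 * m$PPV * m$TPR / (m$PPV + m$TPR))
      }
    }
  })
})

test_that("hyperparameter search evaluates the grid deterministically", {
  d <- toy_separable(n = 30)
  grid <- tibble::tibble(box_constraint = c(1, 74.185),
                         kernel_scale = c(1, 2.7558))
  res <- hyperparameter_search(d, grid, k = 3, seed = 5)
  expect_equal(nrow(res), 2)
  expect_true(any(res$box_constraint == 74.185 & res$kernel_scale == 2.7558))
  res2 <- hyperparameter_search(d, grid, k = 3, seed = 5)
  expect_equal(res$cv_mean, res2$cv_mean)
  expect_true(all(res$cv_mean >= 0 & res$cv_mean <= 1))
  expect_error(hyperparameter_search(d, grid[0, ]), "empty")
  # the default grid contains the package's default operating point
  dg <- default_svm_grid()
  expect_true(any(dg$box_constraint == 74.185 & dg$kernel_scale == 2.7558))
})

test_that("an all-cloth scene yields zero classified pixels", {
  wl <- seq(400, 1000, length.out = 204)
  cloth <- hypercube(array(0.9, c(16, 16, 204)), wl, kind = "reflectance")
  d <- preprocess_pipeline(
    labelled_spectra(matrix(rep(blood_reflectance(wl, "human", 0.1), 20),
                            20, byrow = TRUE) +
                       matrix(rnorm(20 * 204, sd = 0.01), 20), wl,
                     tibble::tibble(class = rep(c(0L, 1L), 10))))
  fit <- train_svm(d, svm_spec())
  seg <- segment_image(cloth, fit)
  expect_true(all(seg$labels == 0L))
  expect_equal(sum(seg$labels == 0) + sum(seg$labels == 1) +
                 sum(seg$labels == 2), 256)
})
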