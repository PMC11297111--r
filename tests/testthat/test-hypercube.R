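test_that("calibration implements the white-reference relation", {
  wl <- c(500, 600, 700)
  raw_of <- function(v) hypercube(array(v, c(2, 2, 3)), wl, kind = "raw")

  # RAW = White, Dark = 0 -> R = 1
  r1 <- calibrate_reflectance(raw_of(1), rep(0, 3), rep(1, 3))
  expect_true(all(r1$values == 1))
  # RAW = Dark -> R = 0
  r0 <- calibrate_reflectance(raw_of(0.1), rep(0.1, 3), rep(1, 3))
  expect_true(all(r0$values == 0))
  # direct substitution
  r <- calibrate_reflectance(raw_of(0.6), rep(0.1, 3), rep(1, 3))
  expect_equal(unique(as.numeric(r$values)), 0.5)
  # optional dark-corrected white denominator
  rdc <- calibrate_reflectance(raw_of(0.6), rep(0.1, 3), rep(1, 3),
                               dark_corrected_white = TRUE)
  expect_equal(unique(as.numeric(rdc$values)), 0.5 / 0.9)

  expect_error(calibrate_reflectance(raw_of(1), rep(0, 3), rep(0, 3)), "white")
  expect_error(calibrate_reflectance(raw_of(1), rep(0, 3), rep(1, 4)), "per-band")
})

test_that("calibration agrees with an element-wise scalar oracle", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      wl <- sort(runif(5, 400, 1000))
      raw <- array(runif(3 * 3 * 5, 0.2, 1), c(3, 3, 5))
      dark <- runif(5, 0, 0.1)
      white <- runif(5, 1.1, 2)
      cube <- hypercube(raw, wl, kind = "raw")
      r <- calibrate_reflectance(cube, dark, white)
      for (i in 1:3) for (j in 1:3) for (b in 1:5) {
        expect_equal(r$values[i, j, b],
                     max((raw[i, j, b] - dark[b]) / white[b], 0))
      }
    }
  })
})

test_that("ENVI-style persistence round-trips losslessly", {
  withr::with_seed(4, {
    wl <- seq(400, 1000, length.out = 204)
    cube <- hypercube(array(runif(16 * 16 * 204), c(16, 16, 204)), wl,
                      kind = "reflectance")
    for (il in c("bsq", "bil")) {
      path <- tempfile()
      write_cube(cube, path, interleave = il)
      back <- read_cube(path)
      expect_identical(back$values, cube$values)
      expect_identical(back$wavelengths, cube$wavelengths)
      expect_identical(back$kind, "reflectance")
      unlink(c(path, paste0(path, ".hdr")))
    }
  })
})

test_that("malformed ENVI input is rejected", {
  wl <- seq(400, 500, length.out = 10)
  cube <- hypercube(array(1, c(4, 4, 10)), wl, kind = "raw")
  path <- tempfile()
  write_cube(cube, path)

  # band-count mismatch between header and data
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(sub("bands = 10", "bands = 8", hdr), paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelengths|bands")

  # non-monotonic wavelengths
  bad_wl <- sub("^wavelength = .*",
                sprintf("wavelength = { %s }",
                        paste(rev(wl), collapse = ", ")), hdr)
  writeLines(bad_wl, paste0(path, ".hdr"))
  expect_error(read_cube(path), "increasing")

  # missing wavelength list
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelength")
  unlink(c(path, paste0(path, ".hdr")))
})

test_that("ROI extraction yields one observation per masked pixel", {
  out <- render_small_reflectance()
  refl <- out$refl

  m1 <- matrix(FALSE, 48, 48); m1[12:36, 12:36] <- TRUE  # 25 x 25
  rs <- roi_set(list(m1), roi_id = "roi1", species = "human",
                individual = "h1", age_days = 0.1)
  obs <- extract_roi(refl, rs)
  expect_equal(nrow(obs), 625)
  expect_true(all(obs$class == 1L))

  m2 <- matrix(FALSE, 48, 48); m2[1:2, 1:2] <- TRUE
  m3 <- matrix(FALSE, 48, 48); m3[40:41, 40:41] <- TRUE
  rs2 <- roi_set(list(m2, m3), roi_id = c("a", "b"), species = "pig")
  obs2 <- extract_roi(refl, rs2)
  expect_equal(nrow(obs2), 8)
  expect_equal(length(unique(obs2$roi_id)), 2)

  empty <- matrix(FALSE, 48, 48)
  expect_error(extract_roi(refl, roi_set(list(empty), "e", "pig")), "'e'")
  small <- matrix(TRUE, 10, 10)
  expect_error(extract_roi(refl, roi_set(list(small), "s", "pig")), "bounds")
  expect_error(extract_roi(out$scene$raw, rs), "reflectance")
  expect_error(roi_set(list(m2, m3), roi_id = c("a", "a"), species = "pig"),
               "unique")
})

test_that("PNG mask round trip preserves the mask", {
  m <- matrix(FALSE, 20, 30); m[5:10, 8:20] <- TRUE
  path <- tempfile(fileext = ".png")
  write_mask_png(m, path)
  expect_identical(read_mask_png(path), m)
  unlink(path)
})

test_that("imaging geometry arithmetic", {
  expect_equal(spatial_resolution(16.4, 512), 0.3203125)
  expect_equal(round(spatial_resolution(16.4, 512), 2), 0.32)
})

test_that("hypercube invariants are enforced", {
  expect_error(hypercube(array(1, c(2, 2, 3)), c(500, 400, 600)), "increasing")
  expect_error(hypercube(array(1, c(2, 2, 3)), c(400, 500)), "bands")
  expect_error(hypercube(array(c(NA, rep(1, 11)), c(2, 2, 3)),
                         c(400, 500, 600)), "finite")
  expect_error(hypercube(array(-1, c(2, 2, 3)), c(400, 500, 600),
                         kind = "reflectance"), ">= 0")
  # over-unity reflectance is kept but flagged
  h <- hypercube(array(1.2, c(2, 2, 3)), c(400, 500, 600), kind = "reflectance")
  expect_equal(h$meta$over_unity_count, 12)
})
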