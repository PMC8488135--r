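test_that("percentile normalization follows the 0-95% rule exactly", {
  vol <- image_volume(array(as.double(0:100), c(101, 1, 1)))
  nv <- normalize_intensity(vol)
  # p95 of {0..100} is 95; clipping maps 95 and 100 to 1, 47.5 to 0.5
  expect_equal(nv$data[96, 1, 1], 1)
  expect_equal(nv$data[101, 1, 1], 1)
  v2 <- vol; v2$data[1, 1, 1] <- 47.5
  expect_equal(normalize_intensity(v2)$data[1, 1, 1], 0.5)
  expect_true(all(nv$data >= 0 & nv$data <= 1))
})

test_that("normalization is idempotent and bounded on random images", {
  set.seed(91)
  for (i in 1:20) {
    vol <- image_volume(array(rexp(200, 1 / 50), c(10, 5, 4)))
    nv <- normalize_intensity(vol)
    expect_true(all(nv$data >= 0 & nv$data <= 1))
    nv2 <- normalize_intensity(nv)
    expect_equal(nv2$data, nv$data, tolerance = 1e-12)
  }
})

test_that("degenerate images warn or error as appropriate", {
  expect_warning(normalize_intensity(image_volume(array(3, c(4, 4, 4)))),
                 "constant")
  expect_error(normalize_intensity(image_volume(array(0, c(4, 4, 4)))),
               "degenerate")
})

intensity_fixture <- function(targets = NULL, speckle_sd = 0, spacing = 1.5) {
  ph <- make_phantom(quick_spec(10, misalign_rotation_deg = 0,
                                misalign_translation_mm = 0))
  vol <- make_echo_volume(ph, segment_intensity = targets,
                          speckle_sd = speckle_sd, spacing = spacing)
  f <- build_frame(ph$cmr$ED$landmarks)
  ext <- function(m) max((m$vertices -
                            matrix(f$origin, nrow(m$vertices), 3, byrow = TRUE)) %*%
                           f$e_long)
  list(vol = vol,
       endo = fit_surface(ph$cmr$ED$endo$vertices, f, surface_tag = "endo",
                          apex_extent = ext(ph$cmr$ED$endo)),
       epi = fit_surface(ph$cmr$ED$epi$vertices, f, surface_tag = "epi",
                         apex_extent = ext(ph$cmr$ED$epi)))
}

test_that("a uniform normalized volume reports 100% in every segment", {
  fx <- intensity_fixture()
  uni <- fx$vol
  uni$data <- array(1, dim(uni$data))
  rep <- suppressWarnings(
    segment_mean_intensity(normalize_intensity(uni), fx$endo, fx$epi))
  expect_setequal(rep$segment, 1:17)
  expect_true(all(abs(rep$mean_intensity - 100) < 1e-9))
  expect_true(all(rep$n_voxels >= 1))
})

test_that("unit shell targets round-trip within boundary discretization", {
  fx <- intensity_fixture(targets = stats::setNames(rep(1, 17), 1:17))
  rep <- segment_mean_intensity(normalize_intensity(fx$vol), fx$endo, fx$epi)
  # the thin apical cap is most affected by shell-boundary voxels
  expect_true(all(abs(rep$mean_intensity - 100) < 4))
  expect_true(all(abs(rep$mean_intensity[rep$segment <= 16] - 100) < 1))
})

test_that("generated dropout targets round-trip through the report", {
  fx <- intensity_fixture(targets = c("1" = 0.39, "10" = 0.68))
  rep <- segment_mean_intensity(normalize_intensity(fx$vol), fx$endo, fx$epi)
  expect_equal(rep$mean_intensity[rep$segment == 1], 39, tolerance = 0.02)
  expect_equal(rep$mean_intensity[rep$segment == 10], 68, tolerance = 0.02)
  ratio <- rep$mean_intensity[rep$segment == 10] /
    rep$mean_intensity[rep$segment == 1]
  expect_equal(ratio, 1.74, tolerance = 0.02)
})

test_that("scaling one segment's true intensity scales only its report", {
  fx1 <- intensity_fixture(targets = c("5" = 0.30))
  fx2 <- intensity_fixture(targets = c("5" = 0.60))
  r1 <- segment_mean_intensity(normalize_intensity(fx1$vol), fx1$endo, fx1$epi)
  r2 <- segment_mean_intensity(normalize_intensity(fx2$vol), fx2$endo, fx2$epi)
  expect_equal(r2$mean_intensity[r2$segment == 5] /
                 r1$mean_intensity[r1$segment == 5], 2, tolerance = 0.02)
  others <- r1$segment != 5
  expect_equal(r1$mean_intensity[others], r2$mean_intensity[others],
               tolerance = 0.02)
})

test_that("intensity report shifts by under 1% when volume and surfaces move together", {
  fx <- intensity_fixture(targets = c("1" = 0.39, "10" = 0.68), spacing = 2)
  rep0 <- segment_mean_intensity(normalize_intensity(fx$vol), fx$endo, fx$epi)
  T <- rigid_transform(rotation_z(25), c(8, -5, 3))
  volT <- fx$vol
  volT$origin <- apply_transform(volT$origin, T)
  volT$direction <- T$rotation %*% volT$direction
  repT <- segment_mean_intensity(normalize_intensity(volT),
                                 transform_fitted(fx$endo, T),
                                 transform_fitted(fx$epi, T))
  expect_equal(repT$mean_intensity, rep0$mean_intensity, tolerance = 0.01)
})

test_that("a volume far from the surfaces is a coverage error", {
  fx <- intensity_fixture(spacing = 2)
  far <- image_volume(array(1, c(5, 5, 5)), origin = c(500, 500, 500))
  expect_error(segment_mean_intensity(far, fx$endo, fx$epi), "coverage")
})
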