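test_that("phantom generation is bit-identical for a fixed seed", {
  a <- make_phantom(quick_spec(4))
  b <- make_phantom(quick_spec(4))
  expect_identical(a$cmr$ED$endo$vertices, b$cmr$ED$endo$vertices)
  expect_identical(a$echo$ES$epi$vertices, b$echo$ES$epi$vertices)
  expect_identical(a$gt_transforms$ED$rotation, b$gt_transforms$ED$rotation)
  # a different seed draws different misalignments (the CMR-side geometry
  # is a deterministic function of the anatomy parameters alone)
  c_ <- make_phantom(quick_spec(5))
  expect_false(identical(a$gt_transforms$ED$rotation,
                         c_$gt_transforms$ED$rotation))
  expect_false(identical(a$echo$ED$endo$vertices, c_$echo$ED$endo$vertices))
})

test_that("fitted phantom cavity volume matches the analytic closed form", {
  sp <- phantom_spec(seed = 3, n_points = 6000L)
  ph <- make_phantom(sp)
  f <- build_frame(ph$cmr$ED$landmarks)
  ext <- max((ph$cmr$ED$endo$vertices -
                matrix(f$origin, nrow(ph$cmr$ED$endo$vertices), 3,
                       byrow = TRUE)) %*% f$e_long)
  fs <- fit_surface(ph$cmr$ED$endo$vertices, f, n_u = 48, n_v = 48,
                    surface_tag = "endo", apex_extent = ext)
  expect_equal(cavity_volume(fs), phantom_analytic_volumes(sp)$EDV,
               tolerance = 0.01)
})

test_that("the ES radial scaling hits the target ejection fraction", {
  ph <- make_phantom(quick_spec(6, ef_target = 0.60))
  res <- fuse_subject(ph$echo, ph$cmr, refine = FALSE)
  ef <- res$volumetrics$EF[res$volumetrics$method == "CMR"]
  expect_equal(ef, 60, tolerance = 0.005 / 0.60)
  v <- phantom_analytic_volumes(ph$spec)
  expect_equal(v$EF, 60)
  expect_equal(v$ESV / v$EDV, 0.4, tolerance = 1e-12)
})

test_that("regional bias displaces the segment plateau by exactly its amplitude", {
  base <- make_phantom(quick_spec(7, misalign_rotation_deg = 0,
                                  misalign_translation_mm = 0))
  ph <- apply_regional_bias(base, segment = 6, amplitude = 5)
  expect_equal(unname(ph$deformations["6"]), 5)
  f <- build_frame(base$cmr$ED$landmarks)
  uv0 <- to_cardiac_coords(base$echo$ED$endo$vertices, f)
  uv1 <- to_cardiac_coords(ph$echo$ED$endo$vertices, f)
  dr <- uv0[, "r"] - uv1[, "r"]
  # full amplitude across the whole segment box
  in_core <- uv0[, "u"] < 1 / 3 & uv0[, "phi"] >= 120 & uv0[, "phi"] <= 180
  expect_true(all(abs(dr[in_core] - 5) < 1e-9))
  # outside the window nothing moves
  far <- uv0[, "phi"] > 200 & uv0[, "phi"] < 280
  expect_true(all(abs(dr[far]) < 1e-9))
  # amplitude 0 is a no-op; absurd amplitude is a spec error
  expect_identical(apply_regional_bias(base, 6, 0), base)
  expect_error(apply_regional_bias(base, 6, 100), "amplitude")
  expect_error(apply_regional_bias(base, 17, 1), "1..16")
})

test_that("undistorted, unmisaligned phantoms close the loop almost exactly", {
  ph <- make_phantom(quick_spec(8, misalign_rotation_deg = 0,
                                misalign_translation_mm = 0))
  res <- fuse_subject(ph$echo, ph$cmr)
  for (phs in c("ED", "ES")) {
    expect_lt(rt_angle_deg(res$registration[[phs]]$total), 0.01)
    expect_lt(sqrt(sum(res$registration[[phs]]$total$translation^2)), 0.01)
  }
  expect_lt(max(res$msd$msd), 0.05)
})

test_that("echo volumes are deterministic and fail on impossible extents", {
  ph <- make_phantom(quick_spec(9, misalign_rotation_deg = 0,
                                misalign_translation_mm = 0))
  v1 <- make_echo_volume(ph, speckle_sd = 0.1, spacing = 2)
  v2 <- make_echo_volume(ph, speckle_sd = 0.1, spacing = 2)
  expect_identical(v1$data, v2$data)
  expect_error(make_echo_volume(ph, segment_intensity = c("1" = 2)), "\\[0, 1\\]")
})

test_that("cohorts are reproducible, distinct, and match their population mean", {
  co <- make_cohort(5, seed = 42, n_points = 400L)
  co2 <- make_cohort(5, seed = 42, n_points = 400L)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$subjects[[3]]$cmr$ED$endo$vertices,
                   co2$subjects[[3]]$cmr$ED$endo$vertices)
  expect_equal(nrow(co$metadata), 5L)
  expect_equal(length(unique(vapply(co$subjects, function(s)
    s$cmr$ED$endo$vertices[1, 1], numeric(1)))), 5L)

  # Monte-Carlo cohort mean EDV vs the analytic expectation of the
  # population distribution: E[pi a^2 c (2/3 + tau - tau^3/3)]
  big <- make_cohort(200, seed = 7, n_points = 400L)
  edv <- vapply(big$subjects, function(s)
    phantom_analytic_volumes(s$spec)$EDV, numeric(1))
  tau_term <- 2 / 3 + 0.5 - 0.5^3 / 3
  expected <- pi * (28^2 + 2^2) * 52 * tau_term / 1000
  expect_equal(mean(edv), expected, tolerance = 0.05)
})
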