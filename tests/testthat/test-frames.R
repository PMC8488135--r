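test_that("axis-aligned landmark set yields the canonical frame", {
  lm <- landmark_set(c(0, 0, 80), c(0, 0, 0),
                     rbind(c(30, 0, 20), c(30, 0, 60)))
  f <- build_frame(lm)
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$e_long, c(0, 0, 1))
  expect_equal(f$e_rv, c(1, 0, 0))
  expect_equal(f$e_norm, c(0, 1, 0))
  expect_equal(f$apex_extent, 80)
})

test_that("frames are right-handed orthonormal triads", {
  set.seed(21)
  for (i in 1:20) {
    lm <- apply_transform(landmark_set(c(0, 0, 80), c(0, 0, 0),
                                       rbind(c(25, 8, 15), c(28, -5, 55))),
                          random_transform())
    f <- build_frame(lm)
    M <- cbind(f$e_rv, f$e_norm, f$e_long)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
  }
})

test_that("frame construction is equivariant under rigid transforms", {
  set.seed(22)
  lm <- landmark_set(c(5, -3, 78), c(1, 2, -1),
                     rbind(c(30, 6, 20), c(28, -4, 58)))
  f0 <- build_frame(lm)
  for (i in 1:50) {
    T <- random_transform()
    f1 <- build_frame(apply_transform(lm, T))
    expect_lt(max(abs(f1$origin - apply_transform(f0$origin, T))), 1e-9)
    for (ax in c("e_long", "e_rv", "e_norm"))
      expect_lt(max(abs(f1[[ax]] - as.vector(T$rotation %*% f0[[ax]]))), 1e-9)
  }
})

test_that("degenerate landmark configurations are rejected", {
  expect_error(landmark_set(c(0, 0, 0), c(0, 0, 0), rbind(c(30, 0, 0))),
               "degenerate axis")
  # RV centroid collinear with the long axis
  lm <- landmark_set(c(0, 0, 80), c(0, 0, 0), rbind(c(0, 0, 40)))
  expect_error(build_frame(lm), "degenerate orientation")
  # echo convention needs an inferior insertion
  expect_error(landmark_set(c(0, 0, 80), c(0, 0, 0),
                            data.frame(x = 30, y = 0, z = 0, label = "anterior"),
                            convention = "echo"),
               "inferior")
})

test_that("the 70-degree echo rule matches the explicit rotation-matrix oracle", {
  e_long <- c(0, 0, 1)
  # clockwise viewed from apex toward base = -70 deg about e_long
  oracle <- as.vector(rotation_z(-70) %*% c(1, 0, 0))
  got <- estimate_rv_direction_echo(c(1, 0, 0), c(0, 0, 0), e_long)
  expect_lt(max(abs(got - oracle)), 1e-9)
  # rotating the result back by +70 deg recovers the projected input
  back <- as.vector(rotation_z(70) %*% got)
  expect_lt(max(abs(back - c(1, 0, 0))), 1e-9)
  # the angle between projected input and output is exactly 70 degrees
  expect_equal(acos(sum(got * c(1, 0, 0))) * 180 / pi, 70, tolerance = 1e-9)
})

test_that("echo rule recovers an RV direction placed 70 deg counterclockwise", {
  set.seed(23)
  for (i in 1:10) {
    T <- random_transform()
    e_long <- as.vector(T$rotation %*% c(0, 0, 1))
    origin <- T$translation
    rv_dir <- as.vector(T$rotation %*% c(1, 0, 0))
    # inferior insertion 70 deg counterclockwise (apex-to-base view) from rv_dir
    ins_dir <- as.vector(lvfuse:::rotation_about_axis(e_long, 70 * pi / 180) %*%
                           rv_dir)
    got <- estimate_rv_direction_echo(origin + 40 * ins_dir, origin, e_long)
    ang <- acos(min(1, sum(got * rv_dir))) * 180 / pi
    expect_lt(ang, 0.01)
  }
})

test_that("CMR and echo conventions agree for the phantom insertion layout", {
  sp <- quick_spec()
  ph <- make_phantom(sp)
  f_cmr <- build_frame(ph$cmr$ED$landmarks)
  lm_echo <- ph$cmr$ED$landmarks
  lm_echo$rv_insertions <- lm_echo$rv_insertions[
    lm_echo$rv_insertions$label == "inferior", ]
  lm_echo$convention <- "echo"
  f_echo <- build_frame(lm_echo)
  expect_lt(max(abs(f_cmr$e_rv - f_echo$e_rv)), 1e-9)
})

test_that("cardiac coordinates match their defining geometry and invert", {
  f <- axis_frame(80)
  p <- c(0, 0, 0) + 0.5 * 80 * f$e_long + 20 * f$e_rv
  expect_equal(as.vector(to_cardiac_coords(p, f)), c(0.5, 0, 20))
  p2 <- 20 * f$e_norm
  expect_equal(as.vector(to_cardiac_coords(p2, f)), c(0, 90, 20))
  expect_error(to_cardiac_coords(p, f, apex_extent = -1), "positive")

  set.seed(24)
  lm <- apply_transform(landmark_set(c(0, 0, 70), c(0, 0, 0),
                                     rbind(c(30, 5, 20))), random_transform())
  fr <- build_frame(lm)
  P <- matrix(rnorm(300, sd = 25), ncol = 3)
  expect_lt(max(abs(from_cardiac_coords(to_cardiac_coords(P, fr), fr) - P)),
            1e-9)
})
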