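test_that("coarse alignment maps one frame exactly onto another", {
  lm <- landmark_set(c(0, 0, 80), c(0, 0, 0),
                     rbind(c(30, 0, 20), c(30, 0, 60)))
  f <- build_frame(lm)
  # identical frames -> identity
  T_id <- coarse_align(f, f)
  expect_lt(max(abs(T_id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(T_id$translation)), 1e-9)

  set.seed(31)
  for (i in 1:20) {
    T <- random_transform()
    f2 <- build_frame(apply_transform(lm, T))
    got <- coarse_align(f, f2)
    expect_transform_close(got, T, 1e-4, 1e-6)
    # maps the source basal centroid exactly onto the reference one
    expect_lt(max(abs(apply_transform(f$origin, got) - f2$origin)), 1e-9)
  }
})

test_that("ICP on already-aligned points returns identity quickly", {
  sp <- quick_spec(1)
  pts <- make_phantom(sp)$cmr$ED$endo$vertices
  res <- icp_refine(pts, pts)
  expect_true(res$converged)
  expect_lte(res$n_iterations, 2L)
  expect_lt(rt_angle_deg(res$refinement), 1e-6)
  expect_lt(max(abs(res$refinement$translation)), 1e-6)
  expect_equal(res$rms_residual, 0)
})

test_that("ICP recovers a known rigid transform from identity start", {
  # scattered endo+epi surface samples of a non-axisymmetric LV: with
  # a = b the axial rotation would be unidentifiable for shape-only ICP,
  # and regular slice lattices admit column-shifted local minima
  set.seed(32)
  a <- 30; b <- 24; c <- 52; L <- 1.5 * c
  samp <- function(n, a, b, c) {
    u <- runif(n, 0, 0.995); z <- u * L
    s <- sqrt(pmax(0, 1 - ((z - 0.5 * c) / c)^2)); phi <- runif(n, 0, 2 * pi)
    cbind(a * s * cos(phi), b * s * sin(phi), z)
  }
  pts <- rbind(samp(1200, a, b, c), samp(1200, a + 9, b + 9, c + 9))
  for (i in 1:5) {
    T <- random_transform(max_rot = 10, max_trans = 10 / sqrt(3))
    ref <- apply_transform(pts, T)
    res <- suppressWarnings(icp_refine(pts, ref, max_iter = 200L))
    expect_transform_close(res$total, T, 0.5, 0.5)
    # correspondence RMS never increases across iterations
    expect_true(all(diff(res$rms_trace) <= 1e-9))
  }
})

test_that("ICP translation error shrinks with point count under noise", {
  errs <- sapply(c(500L, 2000L), function(N) {
    e <- numeric(3)
    for (s in 1:3) {
      set.seed(s)
      ref <- make_phantom(quick_spec(s, n_points = N))$cmr$ED$endo$vertices
      src <- ref + matrix(rnorm(length(ref), 0, 1 / sqrt(3)), ncol = 3)
      T <- rigid_transform(rotation_z(3), c(2, -1, 1))
      res <- suppressWarnings(icp_refine(apply_transform(src, rt_invert(T)),
                                         ref, max_iter = 60L))
      err <- rt_compose(res$total, rt_invert(T))
      e[s] <- sqrt(sum(err$translation^2))
    }
    mean(e)
  })
  # sigma = 1 mm: error of order sigma/sqrt(N), decreasing in N
  expect_lt(errs[2], errs[1])
  expect_lt(errs[1], 4 * 1 / sqrt(500))
  expect_lt(errs[2], 4 * 1 / sqrt(2000))
})

test_that("per-phase registration recovers distinct ED and ES misalignments", {
  ph <- make_phantom(quick_spec(5, misalign_rotation_deg = 8,
                                misalign_translation_mm = 8))
  reg <- register_subject(ph$echo, ph$cmr)
  for (phs in c("ED", "ES"))
    expect_transform_close(reg[[phs]]$total,
                           rt_invert(ph$gt_transforms[[phs]]), 0.5, 0.5)
  # the two ground-truth transforms differ, and so do the recovered ones
  d <- rt_compose(reg$ED$total, rt_invert(reg$ES$total))
  expect_gt(rt_angle_deg(d), 0.5)
})

test_that("refinement can be disabled or replaced by a manual override", {
  ph <- make_phantom(quick_spec(6))
  reg <- register_subject(ph$echo, ph$cmr, refine = FALSE)
  for (phs in c("ED", "ES")) {
    expect_identical(reg[[phs]]$total, reg[[phs]]$coarse)
    expect_lt(rt_angle_deg(reg[[phs]]$refinement), 1e-12)
  }
  # aligned phantom + identity override: total = coarse = identity
  ph0 <- make_phantom(quick_spec(7, misalign_rotation_deg = 0,
                                 misalign_translation_mm = 0))
  reg0 <- register_subject(ph0$echo, ph0$cmr,
                           manual_override = list(ED = rt_identity(),
                                                  ES = rt_identity()))
  expect_lt(rt_angle_deg(reg0$ED$total), 1e-6)
  expect_lt(max(abs(reg0$ED$total$translation)), 1e-6)
  # missing phase is an input error
  expect_error(register_subject(ph$echo["ED"], ph$cmr), "ED and ES")
})

test_that("total transform equals refinement composed with coarse", {
  ph <- make_phantom(quick_spec(8))
  reg <- register_subject(ph$echo, ph$cmr)
  for (phs in c("ED", "ES")) {
    comp <- rt_compose(reg[[phs]]$refinement, reg[[phs]]$coarse)
    expect_lt(max(abs(comp$rotation - reg[[phs]]$total$rotation)), 1e-9)
    expect_lt(max(abs(comp$translation - reg[[phs]]$total$translation)), 1e-9)
  }
})
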