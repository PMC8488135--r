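# dense sample of a radial field r(u, phi) around an axis-aligned frame
field_points <- function(r_fn, extent = 60, n_z = 60, n_phi = 72) {
  g <- expand.grid(u = seq(0, 1, length.out = n_z),
                   phi = seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)])
  r <- r_fn(g$u, g$phi)
  cbind(r * cos(g$phi), r * sin(g$phi), g$u * extent)
}

test_that("constant-radius surface is recovered to 0.01 mm", {
  f <- axis_frame(60)
  pts <- field_points(function(u, phi) rep(25, length(u)))
  fs <- fit_surface(pts, f, lambda_smooth = 1e-6)
  expect_lt(max(abs(fs$template$radii - 25)), 0.01)
  expect_lt(fs$fit_rms, 0.01)
})

test_that("analytic angular harmonic r = 25 + 3 cos(phi) is recovered", {
  f <- axis_frame(60)
  pts <- field_points(function(u, phi) 25 + 3 * cos(phi))
  fs <- fit_surface(pts, f, n_u = 24, n_v = 24, lambda_smooth = 1e-6)
  target <- outer(rep(1, 24), 25 + 3 * cos(fs$template$phi * pi / 180))
  expect_lt(max(abs(fs$template$radii - target)), 0.1)
})

test_that("stronger smoothing monotonically reduces surface roughness", {
  set.seed(41)
  f <- axis_frame(60)
  pts <- field_points(function(u, phi) 25 + rnorm(length(u)))
  rough <- sapply(c(1e-6, 1e-2, 1, 1e2), function(lam) {
    fs <- fit_surface(pts, f, lambda_smooth = lam)
    D <- lvfuse:::second_difference_operator(24, 24)
    sum((D %*% as.vector(t(fs$template$radii)))^2)
  })
  expect_true(all(diff(rough) < 0))
})

test_that("fitting a resampled mesh's own vertices is idempotent", {
  f <- axis_frame(60)
  pts <- field_points(function(u, phi) 26 + 2 * sin(phi) - 4 * u)
  fs <- fit_surface(pts, f, lambda_smooth = 1e-6)
  refit <- fit_surface(fs$mesh$vertices[seq_len(24 * 24), ], f,
                       lambda_smooth = 1e-8)
  expect_lt(max(abs(refit$template$radii - fs$template$radii)), 1e-6)
})

test_that("smoothing suppresses i.i.d. radial noise below its input SD", {
  set.seed(42)
  f <- axis_frame(60)
  pts <- field_points(function(u, phi) 25 + rnorm(length(u), 0, 1))
  fs <- fit_surface(pts, f)  # default lambda_smooth = 1
  expect_lt(sqrt(mean((fs$template$radii - 25)^2)), 1)
})

test_that("parameterization clamps a tolerated band and rejects poor coverage", {
  f <- axis_frame(60)
  set.seed(43)
  phi <- runif(500, 0, 2 * pi)
  ok <- cbind(25 * cos(phi), 25 * sin(phi), runif(500, -0.04 * 60, 1.04 * 60))
  uvr <- parameterize_points(ok, f)
  expect_true(all(uvr[, "u"] >= 0 & uvr[, "u"] <= 1))
  # phi = 0 on the e_rv half-plane
  on_rv <- cbind(seq(10, 30, length.out = 20), 0, 30)
  expect_true(all(abs(parameterize_points(on_rv, f)[, "phi"]) < 1e-9))
  bad <- ok
  bad[seq_len(50), 3] <- -10   # 10% far below the base
  expect_error(parameterize_points(bad, f), "coverage error")
})

test_that("under-supported grids fail without smoothing and warn with it", {
  f <- axis_frame(60)
  set.seed(44)
  phi <- runif(400, 0, pi)   # half the circumference only
  pts <- cbind(25 * cos(phi), 25 * sin(phi), runif(400, 0, 60))
  expect_error(fit_surface(pts, f, lambda_smooth = 0), "singular")
  expect_warning(fit_surface(pts, f, lambda_smooth = 1), "sparse")
})

test_that("non-star-shaped point sets are rejected", {
  f <- axis_frame(60)
  phi <- seq(0, 2 * pi, length.out = 300)
  inner <- cbind(10 * cos(phi), 10 * sin(phi), seq(0, 60, length.out = 300))
  outer_s <- cbind(40 * cos(phi), 40 * sin(phi), seq(0, 60, length.out = 300))
  expect_error(fit_surface(rbind(inner, outer_s), f), "star-shaped")
})

test_that("resampled meshes have canonical structure and closed topology", {
  f <- axis_frame(60)
  pts <- field_points(function(u, phi) 25 + 2 * cos(phi))
  fs <- fit_surface(pts, f, n_u = 16, n_v = 20, lambda_smooth = 1e-4)
  mesh <- fs$mesh
  expect_equal(nrow(mesh$vertices), 16 * 20 + 1)
  expect_true(mesh$parameterized)
  # vertices reproduce the nodal radii exactly
  uvr <- to_cardiac_coords(mesh$vertices[seq_len(16 * 20), ], f, fs$apex_extent)
  expect_lt(max(abs(uvr[, "r"] - as.vector(t(fs$template$radii)))), 1e-9)
  # disk topology (closed above the open basal ring): V - E + F = 1
  edges <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
                 mesh$triangles[, c(3, 1)])
  n_edges <- nrow(unique(t(apply(edges, 1, sort))))
  expect_equal(nrow(mesh$vertices) - n_edges + nrow(mesh$triangles), 1L)
})

test_that("equal grids give node-wise correspondence: identical input, zero MSD", {
  f <- axis_frame(60)
  pts <- field_points(function(u, phi) 27 - 3 * u + cos(2 * phi))
  a <- fit_surface(pts, f, lambda_smooth = 1e-4)
  b <- fit_surface(pts, f, lambda_smooth = 1e-4)
  rep <- mean_surface_distance(a, b)
  expect_true(all(rep$msd < 1e-12))
})
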