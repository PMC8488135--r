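# shared fixture builders (all generated in code; no stored data)

# axis-aligned frame: base at origin, apex at (0, 0, extent), e_rv = +x
axis_frame <- function(extent = 80) {
  build_frame(landmark_set(c(0, 0, extent), c(0, 0, 0),
                           rbind(c(30, 0, extent / 4), c(30, 0, extent / 2))))
}

# a uniformly random rigid transform (rotation <= max_rot deg)
random_transform <- function(max_rot = 180, max_trans = 50) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_rot)
  rigid_transform(lvfuse:::rotation_about_axis(ax, ang * pi / 180),
                  runif(3, -max_trans, max_trans))
}

# analytic hemispheroid template: semi-axes a (radial) and c (long),
# truncated at the equator (u = 0), apex pole at u = 1
hemispheroid_fit <- function(a = 25, c_ax = 50, n = 48) {
  f <- build_frame(landmark_set(c(0, 0, c_ax), c(0, 0, 0), rbind(c(40, 0, 0))))
  u <- seq(0, 1, length.out = n)
  radii <- outer(a * sqrt(pmax(0, 1 - u^2)), rep(1, n))
  fitted_surface_from_template(lv_template(radii), f, apex_extent = c_ax)
}

# small, fast phantom
quick_spec <- function(seed = 1, ...) {
  args <- list(...)
  do.call(phantom_spec, utils::modifyList(list(n_points = 900L, seed = seed), args))
}

# rigidly transform a fitted surface (mesh, frame and origin together)
transform_fitted <- function(fitted, T) {
  fitted$mesh$vertices <- apply_transform(fitted$mesh$vertices, T)
  fr <- fitted$frame
  fr$origin <- apply_transform(fr$origin, T)
  fr$e_long <- as.vector(T$rotation %*% fr$e_long)
  fr$e_rv <- as.vector(T$rotation %*% fr$e_rv)
  fr$e_norm <- as.vector(T$rotation %*% fr$e_norm)
  fitted$frame <- fr
  fitted
}

expect_transform_close <- function(T, T_ref, rot_tol_deg, trans_tol_mm) {
  err <- rt_compose(T, rt_invert(T_ref))
  expect_lt(rt_angle_deg(err), rot_tol_deg)
  expect_lt(sqrt(sum(err$translation^2)), trans_tol_mm)
}
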