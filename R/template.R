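#' Canonical LV radial-field template
#'
#' The common template is a single-valued radial field \eqn{r(u, \phi)}
#' sampled on a regular grid: `n_u` longitudinal positions
#' \eqn{u_i = (i-1)/(n_u-1) \in [0, 1]} (base to apex) and `n_v`
#' circumferential angles \eqn{\phi_j = 360 (j-1)/n_v} degrees, periodic in
#' \eqn{\phi}. Node ordering is canonical (u-major, then phi), so node
#' index \eqn{k = (i-1) n_v + j} is a fixed bijection with \eqn{(i, j)};
#' two surfaces fitted on equal grids are therefore in node-wise
#' correspondence by index. The apex is closed by a single pole vertex
#' beyond the apical-most grid ring.
#'
#' Radii are floored at a small positive value (`r_floor`) so the apical
#' ring never degenerates when a surface closes onto the long axis.
#'
#' @param radii n_u x n_v matrix of radii (mm), row i = longitudinal
#'   position u_i, column j = circumferential angle phi_j.
#' @param r_floor minimum admissible nodal radius in mm (default 1e-3).
#' @return An object of class `lv_template` with elements `n_u`, `n_v`,
#'   `u` (grid positions), `phi` (grid angles, degrees), `radii`.
#' @export
lv_template <- function(radii, r_floor = 1e-3) {
  radii <- as.matrix(radii)
  storage.mode(radii) <- "double"
  stopifnot_finite(radii, "radii")
  if (nrow(radii) < 3L || ncol(radii) < 4L)
    stop("template grid must be at least 3 x 4")
  radii <- pmax(radii, r_floor)
  n_u <- nrow(radii); n_v <- ncol(radii)
  structure(list(n_u = n_u, n_v = n_v,
                 u = seq(0, 1, length.out = n_u),
                 phi = seq(0, 360, length.out = n_v + 1L)[seq_len(n_v)],
                 radii = radii),
            class = "lv_template")
}

## bilinear interpolation weights of (u, phi) on the periodic template grid;
## returns a list(i0, i1, j0, j1, w00, w01, w10, w11) of vectors
template_weights <- function(u, phi, n_u, n_v) {
  u <- pmin(1, pmax(0, u))
  du <- 1 / (n_u - 1L)
  fi <- pmin(u / du, n_u - 1L - 1e-12)
  i0 <- floor(fi)
  tu <- fi - i0
  dv <- 360 / n_v
  phi <- phi %% 360
  fj <- phi / dv
  j0 <- floor(fj) %% n_v
  tv <- fj - floor(fj)
  list(i0 = i0 + 1L, i1 = i0 + 2L,
       j0 = j0 + 1L, j1 = (j0 + 1L) %% n_v + 1L,
       w00 = (1 - tu) * (1 - tv), w01 = (1 - tu) * tv,
       w10 = tu * (1 - tv), w11 = tu * tv)
}

#' Interpolate template radii at arbitrary (u, phi)
#'
#' Bilinear interpolation on the periodic template grid (clamped in u).
#'
#' @param template an [lv_template()].
#' @param u,phi numeric vectors (u normalized, phi in degrees).
#' @return Vector of interpolated radii (mm).
#' @export
template_radius <- function(template, u, phi) {
  stopifnot(inherits(template, "lv_template"))
  w <- template_weights(u, phi, template$n_u, template$n_v)
  r <- template$radii
  idx <- function(i, j) r[cbind(i, j)]
  w$w00 * idx(w$i0, w$j0) + w$w01 * idx(w$i0, w$j1) +
    w$w10 * idx(w$i1, w$j0) + w$w11 * idx(w$i1, w$j1)
}

#' Express surface points in cardiac coordinates for template fitting
#'
#' Thin wrapper around [to_cardiac_coords()] with the coverage policy of
#' the template fit: points slightly outside the longitudinal range
#' (u in `[-0.05, 1.05]`) are clamped to `[0, 1]`; if more than 5% of
#' points fall outside that tolerated band the surface does not cover the
#' frame's extent and an error is raised.
#'
#' @param points n x 3 matrix (mm).
#' @param frame a `cardiac_frame`.
#' @param apex_extent base-to-apex distance (mm); default from the frame.
#' @return Matrix with columns `u`, `phi`, `r`.
#' @export
parameterize_points <- function(points, frame, apex_extent = frame$apex_extent) {
  uvr <- to_cardiac_coords(points, frame, apex_extent)
  out_of_band <- uvr[, "u"] < -0.05 | uvr[, "u"] > 1.05
  if (mean(out_of_band) > 0.05)
    stop("coverage error: ", sprintf("%.1f", 100 * mean(out_of_band)),
         "% of points fall outside the tolerated longitudinal range")
  uvr <- uvr[!out_of_band, , drop = FALSE]
  uvr[, "u"] <- pmin(1, pmax(0, uvr[, "u"]))
  uvr
}

#' Fit the canonical radial template to surface points by least squares
#'
#' Solves the linear regularized least-squares problem
#' \deqn{\min_r \sum_j (B(u_j, \phi_j) r - r_j)^2 +
#'       \lambda \lVert D r \rVert^2}
#' where \eqn{B} is bilinear interpolation on the periodic (u, phi) grid
#' and \eqn{D} stacks second-difference operators along u and (periodically)
#' along phi. The surface must be star-shaped about the long axis
#' (single-valued radius); two points in one grid cell whose radii differ
#' by more than 15 mm trigger a shape error.
#'
#' @param points n x 3 matrix of surface points (mm).
#' @param frame a `cardiac_frame` (shared by both modalities after
#'   registration).
#' @param n_u,n_v template grid size (defaults 24 x 24).
#' @param lambda_smooth Tikhonov smoothing weight (default 1.0).
#' @param surface_tag,phase carried into the fitted mesh.
#' @param apex_extent base-to-apex distance (mm); default from the frame.
#' @return An object of class `fitted_surface`: `template`, `frame`,
#'   `apex_extent`, `surface_tag`, `phase`, `mesh` (a parameterized
#'   [surface_model()] from [resample_mesh()]) and `fit_rms` (mm).
#' @examples
#' lm <- landmark_set(c(0, 0, 60), c(0, 0, 0), rbind(c(40, 0, 0)))
#' f <- build_frame(lm)
#' g <- expand.grid(z = seq(0, 60, length.out = 50),
#'                  ph = seq(0, 2 * pi, length.out = 60)[-60])
#' pts <- cbind(25 * cos(g$ph), 25 * sin(g$ph), g$z)  # radius-25 tube
#' fs <- fit_surface(pts, f, lambda_smooth = 1e-6)
#' range(fs$template$radii)  # all close to 25
#' @export
fit_surface <- function(points, frame, n_u = 24L, n_v = 24L,
                        lambda_smooth = 1.0,
                        surface_tag = c("endo", "epi"),
                        phase = c("ED", "ES"),
                        apex_extent = frame$apex_extent) {
  surface_tag <- match.arg(surface_tag)
  phase <- match.arg(phase)
  n_u <- as.integer(n_u); n_v <- as.integer(n_v)
  if (n_u < 3L || n_v < 4L) stop("template grid must be at least 3 x 4")
  uvr <- parameterize_points(points, frame, apex_extent)
  n_pts <- nrow(uvr)
  if (n_pts < 4L) stop("too few usable points for a template fit")

  ## star-shapedness pre-check: radius spread within one grid cell
  du <- 1 / (n_u - 1L); dv <- 360 / n_v
  ci <- pmin(floor(uvr[, "u"] / du), n_u - 2L)
  cj <- floor((uvr[, "phi"] %% 360) / dv)
  cell <- ci * n_v + cj
  rng <- vapply(split(uvr[, "r"], cell),
                function(r) diff(range(r)), numeric(1))
  if (any(rng > 15))
    stop("shape error: surface is not star-shaped about the long axis ",
         "(radius spread ", sprintf("%.1f", max(rng)), " mm within one grid cell)")

  w <- template_weights(uvr[, "u"], uvr[, "phi"], n_u, n_v)
  node <- function(i, j) (i - 1L) * n_v + j
  n_nodes <- n_u * n_v
  B <- Matrix::sparseMatrix(
    i = rep(seq_len(n_pts), 4L),
    j = c(node(w$i0, w$j0), node(w$i0, w$j1), node(w$i1, w$j0), node(w$i1, w$j1)),
    x = c(w$w00, w$w01, w$w10, w$w11),
    dims = c(n_pts, n_nodes))

  D <- second_difference_operator(n_u, n_v)
  support <- Matrix::colSums(B) > 0
  if (!all(support)) {
    if (lambda_smooth <= 0)
      stop("singular system: ", sum(!support),
           " template node(s) have no supporting data and lambda_smooth = 0")
    warning("sparse template coverage: ", sum(!support),
            " node(s) have no supporting data (regularization fills them)")
  }
  M <- Matrix::crossprod(B) + lambda_smooth * Matrix::crossprod(D)
  rhs <- Matrix::crossprod(B, uvr[, "r"])
  r_hat <- tryCatch(as.vector(Matrix::solve(M, rhs)),
                    error = function(e)
                      stop("singular system in template fit: ",
                           conditionMessage(e)))
  resid <- as.vector(B %*% r_hat) - uvr[, "r"]
  template <- lv_template(matrix(r_hat, n_u, n_v, byrow = TRUE))
  fitted <- structure(list(template = template, frame = frame,
                           apex_extent = apex_extent,
                           surface_tag = surface_tag, phase = phase,
                           mesh = NULL,
                           fit_rms = sqrt(mean(resid^2))),
                      class = "fitted_surface")
  fitted$mesh <- resample_mesh(fitted)
  fitted
}

## stacked second differences: plain along u (per column), periodic along phi
second_difference_operator <- function(n_u, n_v) {
  node <- function(i, j) (i - 1L) * n_v + j
  ## u-direction rows
  iu <- rep(seq_len(n_v), each = n_u - 2L)
  uu <- rep(seq(2L, n_u - 1L), times = n_v)
  rows_u <- seq_along(uu)
  ## phi-direction rows (periodic wrap)
  jv <- rep(seq_len(n_v), times = n_u)
  vv <- rep(seq_len(n_u), each = n_v)
  rows_v <- length(rows_u) + seq_along(jv)
  jm1 <- (jv - 2L) %% n_v + 1L
  jp1 <- jv %% n_v + 1L
  Matrix::sparseMatrix(
    i = c(rows_u, rows_u, rows_u, rows_v, rows_v, rows_v),
    j = c(node(uu - 1L, iu), node(uu, iu), node(uu + 1L, iu),
          node(vv, jm1), node(vv, jv), node(vv, jp1)),
    x = c(rep(1, length(rows_u)), rep(-2, length(rows_u)), rep(1, length(rows_u)),
          rep(1, length(rows_v)), rep(-2, length(rows_v)), rep(1, length(rows_v))),
    dims = c(length(rows_u) + length(rows_v), n_u * n_v))
}

#' Construct a fitted surface directly from a template
#'
#' Builds a `fitted_surface` from an explicit [lv_template()] (e.g. an
#' analytic phantom shape) without running the least-squares fit.
#'
#' @param template an [lv_template()].
#' @param frame a `cardiac_frame`.
#' @param surface_tag,phase mesh metadata.
#' @param apex_extent base-to-apex distance (mm); default from the frame.
#' @return A `fitted_surface`.
#' @export
fitted_surface_from_template <- function(template, frame,
                                         surface_tag = c("endo", "epi"),
                                         phase = c("ED", "ES"),
                                         apex_extent = frame$apex_extent) {
  surface_tag <- match.arg(surface_tag)
  phase <- match.arg(phase)
  stopifnot(inherits(template, "lv_template"), inherits(frame, "cardiac_frame"))
  fitted <- structure(list(template = template, frame = frame,
                           apex_extent = apex_extent,
                           surface_tag = surface_tag, phase = phase,
                           mesh = NULL, fit_rms = 0),
                      class = "fitted_surface")
  fitted$mesh <- resample_mesh(fitted)
  fitted
}

#' Triangulate a fitted surface over its template grid
#'
#' Vertices are the template nodes in canonical (u-major) order, positioned
#' at cardiac coordinates \eqn{(u_i, \phi_j, r(u_i, \phi_j))} in world
#' space, plus one apex pole vertex on the long axis at u = 1 (index
#' `n_u * n_v + 1`), giving a fan closure of the apical ring. The basal
#' edge (u = 0 ring) is left open, as LV models are truncated at the base.
#'
#' @param fitted a `fitted_surface`.
#' @return A parameterized [surface_model()] with `n_u * n_v + 1` vertices.
#' @export
resample_mesh <- function(fitted) {
  stopifnot(inherits(fitted, "fitted_surface"))
  tpl <- fitted$template
  n_u <- tpl$n_u; n_v <- tpl$n_v
  g <- cbind(u = rep(tpl$u, each = n_v),
             phi = rep(tpl$phi, times = n_u),
             r = as.vector(t(tpl$radii)))
  verts <- from_cardiac_coords(g, fitted$frame, fitted$apex_extent)
  pole <- from_cardiac_coords(c(1, 0, 0), fitted$frame, fitted$apex_extent)
  verts <- rbind(verts, pole)

  node <- function(i, j) (i - 1L) * n_v + (j - 1L) %% n_v + 1L
  i <- rep(seq_len(n_u - 1L), each = n_v)
  j <- rep(seq_len(n_v), times = n_u - 1L)
  ## outward-oriented quads split into two triangles
  t1 <- cbind(node(i, j), node(i + 1L, j), node(i, j + 1L))
  t2 <- cbind(node(i, j + 1L), node(i + 1L, j), node(i + 1L, j + 1L))
  jj <- seq_len(n_v)
  fan <- cbind(node(n_u, jj), rep(n_u * n_v + 1L, n_v), node(n_u, jj + 1L))
  surface_model(verts, rbind(t1, t2, fan),
                surface_tag = fitted$surface_tag, phase = fitted$phase,
                parameterized = TRUE)
}

#' @export
print.fitted_surface <- function(x, ...) {
  cat("Fitted LV surface [", x$surface_tag, ", ", x$phase, "]: grid ",
      x$template$n_u, " x ", x$template$n_v, ", fit RMS ",
      sprintf("%.3f", x$fit_rms), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.lv_template <- function(x, ...) {
  cat("LV radial template: ", x$n_u, " x ", x$n_v, " grid, radii ",
      sprintf("%.1f", min(x$radii)), "-", sprintf("%.1f", max(x$radii)),
      " mm\n", sep = "")
  invisible(x)
}
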