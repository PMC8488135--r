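#' Fiducial landmark set anchoring the cardiac coordinate frame
#'
#' The cardiac frame is anchored by the apical and basal centroids (defining
#' the LV long axis) and the right-ventricular (RV) insertion points
#' (defining the circumferential orientation). Two labelling conventions are
#' supported: `"cmr"`, where all visible insertion points are given (the RV
#' centroid is their mean position), and `"echo"`, where typically only the
#' inferior insertion is identifiable and the RV direction is estimated from
#' it by the 70-degree rule (see [estimate_rv_direction_echo()]).
#'
#' @param apical_centroid,basal_centroid numeric length-3 points (mm).
#' @param rv_insertions data.frame with columns `x`, `y`, `z` (mm) and
#'   `label` (one of `"anterior"`, `"inferior"`, `"unlabeled"`), or an
#'   n x 3 matrix (all rows then `"unlabeled"`).
#' @param convention `"cmr"` or `"echo"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(apical_centroid, basal_centroid, rv_insertions,
                         convention = c("cmr", "echo")) {
  convention <- match.arg(convention)
  apical_centroid <- as.double(apical_centroid)
  basal_centroid <- as.double(basal_centroid)
  stopifnot(length(apical_centroid) == 3L, length(basal_centroid) == 3L)
  stopifnot_finite(apical_centroid, "apical_centroid")
  stopifnot_finite(basal_centroid, "basal_centroid")
  if (sqrt(sum((apical_centroid - basal_centroid)^2)) < 1e-9)
    stop("degenerate axis: apical and basal centroids coincide")
  if (is.matrix(rv_insertions)) {
    rv_insertions <- data.frame(x = rv_insertions[, 1L], y = rv_insertions[, 2L],
                                z = rv_insertions[, 3L],
                                label = "unlabeled")
  }
  stopifnot(is.data.frame(rv_insertions),
            all(c("x", "y", "z") %in% names(rv_insertions)))
  if (is.null(rv_insertions$label)) rv_insertions$label <- "unlabeled"
  rv_insertions$label[is.na(rv_insertions$label)] <- "unlabeled"
  if (!all(rv_insertions$label %in% c("anterior", "inferior", "unlabeled")))
    stop("rv insertion labels must be 'anterior', 'inferior' or 'unlabeled'")
  if (nrow(rv_insertions) < 1L)
    stop("at least one RV insertion point is required")
  if (convention == "echo" && !any(rv_insertions$label == "inferior"))
    stop("echo convention requires at least one inferior RV insertion")
  structure(list(apical_centroid = apical_centroid,
                 basal_centroid = basal_centroid,
                 rv_insertions = rv_insertions,
                 convention = convention),
            class = "landmark_set")
}

#' Subject-specific cardiac coordinate frame
#'
#' A right-handed orthonormal triad shared by both modalities:
#' `e_long` points from the basal centroid (the origin) toward the apex,
#' `e_rv` points toward the RV centroid (projected orthogonal to the long
#' axis), and `e_norm = e_long x e_rv` completes the triad. The
#' circumferential angle phi is measured from `e_rv` toward `e_norm`.
#'
#' For CMR-style landmarks the RV centroid is the mean position of all
#' insertion points. For echo-style landmarks, where the anterior insertion
#' is generally not visible, the RV direction is approximated as lying 70
#' degrees clockwise from the inferior insertion when viewed from the apex
#' toward the base ([estimate_rv_direction_echo()]).
#'
#' @param landmarks a [landmark_set()].
#' @return An object of class `cardiac_frame` with elements `origin`
#'   (basal centroid, mm), `e_long`, `e_rv`, `e_norm` (unit vectors) and
#'   `apex_extent` (base-to-apex distance along `e_long`, mm).
#' @examples
#' lm <- landmark_set(c(0, 0, 80), c(0, 0, 0),
#'                    rbind(c(30, 0, 20), c(30, 0, 60)))
#' f <- build_frame(lm)
#' f$e_long  # (0, 0, 1)
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  origin <- landmarks$basal_centroid
  axis <- landmarks$apical_centroid - origin
  apex_extent <- sqrt(sum(axis^2))
  if (apex_extent < 1e-9) stop("degenerate axis: apical and basal centroids coincide")
  e_long <- axis / apex_extent

  ins <- unname(as.matrix(landmarks$rv_insertions[, c("x", "y", "z")]))
  if (landmarks$convention == "echo") {
    inf <- ins[landmarks$rv_insertions$label == "inferior", , drop = FALSE]
    e_rv <- estimate_rv_direction_echo(colMeans(inf), origin, e_long)
  } else {
    rv_centroid <- colMeans(ins)
    d <- rv_centroid - origin
    d_perp <- d - sum(d * e_long) * e_long
    nrm <- sqrt(sum(d_perp^2))
    if (nrm < sqrt(sum(d^2)) * sin(deg2rad(1)) || nrm < 1e-12)
      stop("degenerate orientation: RV centroid is collinear with the long axis")
    e_rv <- d_perp / nrm
  }
  e_norm <- cross3(e_long, e_rv)
  structure(list(origin = origin, e_long = e_long, e_rv = e_rv,
                 e_norm = e_norm, apex_extent = apex_extent),
            class = "cardiac_frame")
}

#' Estimate the RV direction from the inferior insertion (echo convention)
#'
#' In 3D echo the anterior RV insertion is generally not visible, so the RV
#' centroid direction is approximated as lying 70 degrees clockwise from the
#' inferior RV insertion when viewed from the apex toward the base. With
#' `e_long` pointing base-to-apex, clockwise for that viewer corresponds to
#' rotation by -70 degrees about `e_long` (right-hand rule); this sign
#' convention is fixed package-wide.
#'
#' @param inferior_insertion length-3 point (mm).
#' @param origin frame origin (basal centroid, mm).
#' @param e_long unit base-to-apex axis.
#' @param angle_deg rule angle in degrees (default 70).
#' @return Unit vector orthogonal to `e_long` pointing toward the estimated
#'   RV centroid.
#' @export
estimate_rv_direction_echo <- function(inferior_insertion, origin, e_long,
                                       angle_deg = 70) {
  d <- as.double(inferior_insertion) - as.double(origin)
  d_perp <- d - sum(d * e_long) * e_long
  nrm <- sqrt(sum(d_perp^2))
  if (nrm < sqrt(sum(d^2)) * sin(deg2rad(1)) || nrm < 1e-12)
    stop("degenerate orientation: inferior insertion is collinear with the long axis")
  R <- rotation_about_axis(e_long, -deg2rad(angle_deg))
  as.vector(R %*% (d_perp / nrm))
}

#' Convert points to cardiac coordinates (u, phi, r)
#'
#' Cardiac coordinates are: `u`, the normalized longitudinal position along
#' the long axis (0 at the base, 1 at the apex, scaled by `apex_extent`);
#' `phi`, the circumferential angle in degrees in `[0, 360)` measured from
#' `e_rv` toward `e_norm`; and `r`, the radial distance from the long axis
#' in mm.
#'
#' @param p length-3 point or n x 3 matrix (mm).
#' @param frame a `cardiac_frame` from [build_frame()].
#' @param apex_extent base-to-apex distance in mm; defaults to the frame's.
#' @return A matrix with columns `u`, `phi` (degrees), `r` (mm).
#' @export
to_cardiac_coords <- function(p, frame, apex_extent = frame$apex_extent) {
  stopifnot(inherits(frame, "cardiac_frame"))
  if (!is.numeric(apex_extent) || length(apex_extent) != 1L || apex_extent <= 0)
    stop("apex_extent must be a positive scalar (mm)")
  P <- as_points3(p)
  D <- P - matrix(frame$origin, nrow(P), 3L, byrow = TRUE)
  lu <- as.vector(D %*% frame$e_long) / apex_extent
  a <- as.vector(D %*% frame$e_rv)
  b <- as.vector(D %*% frame$e_norm)
  phi <- rad2deg(atan2(b, a)) %% 360
  cbind(u = lu, phi = phi, r = sqrt(a^2 + b^2))
}

#' Convert cardiac coordinates back to world points
#'
#' Inverse of [to_cardiac_coords()].
#'
#' @param uvr matrix with columns `u`, `phi` (degrees), `r` (mm), or a
#'   length-3 vector.
#' @inheritParams to_cardiac_coords
#' @return n x 3 matrix of points (mm), or a length-3 vector for a single
#'   input point.
#' @export
from_cardiac_coords <- function(uvr, frame, apex_extent = frame$apex_extent) {
  stopifnot(inherits(frame, "cardiac_frame"))
  single <- !is.matrix(uvr)
  if (single) uvr <- matrix(as.double(uvr), 1L, 3L)
  u <- uvr[, 1L]; phi <- deg2rad(uvr[, 2L]); r <- uvr[, 3L]
  P <- matrix(frame$origin, nrow(uvr), 3L, byrow = TRUE) +
    outer(u * apex_extent, frame$e_long) +
    outer(r * cos(phi), frame$e_rv) +
    outer(r * sin(phi), frame$e_norm)
  colnames(P) <- c("x", "y", "z")
  if (single) as.vector(P) else P
}

#' @export
print.cardiac_frame <- function(x, ...) {
  cat("Cardiac frame\n")
  cat("  origin (basal centroid):", sprintf("%.2f", x$origin), "mm\n")
  cat("  e_long:", sprintf("%.4f", x$e_long), "\n")
  cat("  e_rv:  ", sprintf("%.4f", x$e_rv), "\n")
  cat("  apex extent:", sprintf("%.2f", x$apex_extent), "mm\n")
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set (", x$convention, " convention), ",
      nrow(x$rv_insertions), " RV insertion(s)\n", sep = "")
  invisible(x)
}
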