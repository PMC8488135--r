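#' Rigid (rotation + translation) transform in 3D
#'
#' A rigid transform maps a point \eqn{p} to \eqn{R p + t}, where \eqn{R} is
#' a proper rotation (orthonormal, determinant +1) and \eqn{t} a translation
#' in millimetres. Rigid transforms form a group: they can be composed and
#' inverted, and composition is applied right-to-left (as for matrices).
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' T1 <- rigid_transform(rotation_z(30), c(5, 0, 0))
#' p  <- c(10, 0, 0)
#' apply_transform(p, T1)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  storage.mode(rotation) <- "double"
  translation <- as.double(translation)
  if (length(translation) != 3L) stop("translation must have length 3")
  stopifnot_finite(rotation, "rotation")
  stopifnot_finite(translation, "translation")
  err_orth <- max(abs(crossprod(rotation) - diag(3)))
  if (err_orth > 1e-9)
    stop("rotation is not orthonormal (max |R'R - I| = ",
         format(err_orth), ")")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1); got det = ", format(det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `rt_compose(T2, T1)` returns the transform equivalent to applying `T1`
#' first and `T2` second.
#'
#' @param T2,T1 `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(T2, T1) {
  stopifnot(inherits(T2, "rigid_transform"), inherits(T1, "rigid_transform"))
  R <- T2$rotation %*% T1$rotation
  ## re-orthonormalize via polar projection to keep long compositions clean
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, as.vector(T2$rotation %*% T1$translation) + T2$translation)
}

#' Invert a rigid transform
#' @param T a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_invert <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% T$translation))
}

#' Rotation matrices about the coordinate axes
#'
#' Convenience constructors for proper rotations about the x, y or z axis by
#' an angle in degrees (right-hand rule).
#'
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_z <- function(angle_deg) rotation_about_axis(c(0, 0, 1), deg2rad(angle_deg))

#' @rdname rotation_z
#' @export
rotation_x <- function(angle_deg) rotation_about_axis(c(1, 0, 0), deg2rad(angle_deg))

#' @rdname rotation_z
#' @export
rotation_y <- function(angle_deg) rotation_about_axis(c(0, 1, 0), deg2rad(angle_deg))

#' Rotation angle of a rigid transform
#'
#' The geodesic rotation angle (degrees) of the rotation part, computed from
#' its trace. Useful for quantifying registration errors.
#'
#' @param T a `rigid_transform`.
#' @return Angle in degrees in `[0, 180]`.
#' @export
rt_angle_deg <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  ct <- (sum(diag(T$rotation)) - 1) / 2
  rad2deg(acos(min(1, max(-1, ct))))
}

#' Apply a rigid transform
#'
#' Generic applying a `rigid_transform` to points (length-3 vector or
#' n x 3 matrix), to a [surface_model()], or to a [landmark_set()].
#'
#' @param x object to transform.
#' @param T a `rigid_transform`.
#' @return The transformed object, same type as `x`.
#' @export
apply_transform <- function(x, T) UseMethod("apply_transform")

#' @export
apply_transform.default <- function(x, T) {
  stopifnot(inherits(T, "rigid_transform"))
  P <- as_points3(x)
  out <- P %*% t(T$rotation) +
    matrix(T$translation, nrow(P), 3L, byrow = TRUE)
  if (!is.matrix(x)) as.vector(out) else out
}

#' @export
apply_transform.surface_model <- function(x, T) {
  x$vertices <- apply_transform(x$vertices, T)
  x
}

#' @export
apply_transform.landmark_set <- function(x, T) {
  x$apical_centroid <- apply_transform(x$apical_centroid, T)
  x$basal_centroid <- apply_transform(x$basal_centroid, T)
  if (nrow(x$rv_insertions) > 0L)
    x$rv_insertions[, c("x", "y", "z")] <-
      apply_transform(as.matrix(x$rv_insertions[, c("x", "y", "z")]), T)
  x
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rotation", sprintf("%.3f", rt_angle_deg(x)),
      "deg, translation", sprintf("%.3f", sqrt(sum(x$translation^2))), "mm\n")
  invisible(x)
}
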