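# internal geometry helpers; all lengths mm, internal angles radians

`%||%` <- function(a, b) if (is.null(a)) b else a

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps * 100) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## rotation by `angle_rad` about unit axis `axis` (right-hand rule), Rodrigues form
rotation_about_axis <- function(axis, angle_rad) {
  n <- unit3(axis)
  K <- matrix(c(0, n[3L], -n[2L],
                -n[3L], 0, n[1L],
                n[2L], -n[1L], 0), 3L, 3L)
  diag(3L) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

## coerce a point or an n x 3 matrix of points to matrix form
as_points3 <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("point matrix must have 3 columns")
    storage.mode(p) <- "double"
    return(p)
  }
  if (is.numeric(p) && length(p) == 3L) return(matrix(as.double(p), 1L, 3L))
  stop("points must be a numeric length-3 vector or an n x 3 matrix")
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must contain only finite values")
}
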