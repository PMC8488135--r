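#' Triangle-mesh model of one LV surface
#'
#' Container for an endocardial or epicardial LV surface at one cardiac
#' phase. Vertices are in mm in a common world space; triangles index into
#' the vertex list (1-based).
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of vertex indices (1-based); may be
#'   a 0-row matrix for a pure point set.
#' @param surface_tag `"endo"` or `"epi"`.
#' @param phase `"ED"` or `"ES"`.
#' @param parameterized logical; set only by the template-fitting stage,
#'   marking that vertex order follows the canonical template grid.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(vertices, triangles = NULL,
                          surface_tag = c("endo", "epi"),
                          phase = c("ED", "ES"),
                          parameterized = FALSE) {
  surface_tag <- match.arg(surface_tag)
  phase <- match.arg(phase)
  vertices <- as_points3(vertices)
  stopifnot_finite(vertices, "vertices")
  if (is.null(triangles)) triangles <- matrix(integer(0), 0L, 3L)
  triangles <- as.matrix(triangles)
  if (nrow(triangles) > 0L) {
    storage.mode(triangles) <- "integer"
    if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle indices out of range")
    a <- vertices[triangles[, 2L], ] - vertices[triangles[, 1L], ]
    b <- vertices[triangles[, 3L], ] - vertices[triangles[, 1L], ]
    cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
    cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
    cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    area2 <- sqrt(cx^2 + cy^2 + cz^2)
    if (any(area2 / 2 <= 1e-9))
      stop("mesh contains degenerate (zero-area) triangles")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 surface_tag = surface_tag, phase = phase,
                 parameterized = isTRUE(parameterized)),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat("LV surface model [", x$surface_tag, ", ", x$phase, "]: ",
      nrow(x$vertices), " vertices, ", nrow(x$triangles), " triangles",
      if (x$parameterized) ", parameterized" else "", "\n", sep = "")
  invisible(x)
}
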