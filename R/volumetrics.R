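#' Cavity volume of a fitted endocardial surface
#'
#' The basal opening (u = 0 ring) is capped by a triangle fan to the basal
#' ring centroid, closing the mesh; the enclosed volume is then computed by
#' the divergence theorem as the sum of signed tetrahedra to the origin.
#' The result is orientation-independent (absolute value after consistent
#' mesh orientation) and returned in ml (1 ml = 1000 mm^3).
#'
#' @param endo a `fitted_surface` (typically endocardial).
#' @return Volume in ml.
#' @examples
#' # hemispheroid a = b = 25, c = 50 truncated at the equator:
#' # V = (1/2)(4/3) pi a b c = 65.45 ml
#' lm <- landmark_set(c(0, 0, 50), c(0, 0, 0), rbind(c(40, 0, 0)))
#' f <- build_frame(lm)
#' u <- seq(0, 1, length.out = 48)
#' radii <- outer(25 * sqrt(pmax(0, 1 - u^2)), rep(1, 48))
#' fs <- fitted_surface_from_template(lv_template(radii), f)
#' cavity_volume(fs)
#' @export
cavity_volume <- function(endo) {
  stopifnot(inherits(endo, "fitted_surface"))
  mesh_volume_ml(closed_mesh(endo))
}

## cap the basal ring with a fan to its centroid; returns vertices+triangles
closed_mesh <- function(fitted) {
  mesh <- fitted$mesh
  n_v <- fitted$template$n_v
  verts <- mesh$vertices
  basal <- seq_len(n_v)                       # u = 0 ring, canonical order
  centroid <- colMeans(verts[basal, , drop = FALSE])
  verts <- rbind(verts, centroid)
  cid <- nrow(verts)
  jj <- seq_len(n_v)
  cap <- cbind(basal[jj %% n_v + 1L], rep(cid, n_v), basal[jj])
  list(vertices = verts, triangles = rbind(mesh$triangles, cap))
}

mesh_volume_ml <- function(m) {
  v1 <- m$vertices[m$triangles[, 1L], , drop = FALSE]
  v2 <- m$vertices[m$triangles[, 2L], , drop = FALSE]
  v3 <- m$vertices[m$triangles[, 3L], , drop = FALSE]
  ## signed tetra volume to the origin: det(v1, v2, v3) / 6
  detv <- v1[, 1L] * (v2[, 2L] * v3[, 3L] - v2[, 3L] * v3[, 2L]) -
    v1[, 2L] * (v2[, 1L] * v3[, 3L] - v2[, 3L] * v3[, 1L]) +
    v1[, 3L] * (v2[, 1L] * v3[, 2L] - v2[, 2L] * v3[, 1L])
  abs(sum(detv)) / 6 / 1000
}

#' Left-ventricular myocardial mass
#'
#' LV mass is the myocardial shell volume (epicardial minus endocardial
#' cavity volume) times the myocardial density. The epicardium must
#' enclose the endocardium: the epicardial template radius must be at
#' least the endocardial radius at every shared grid node (tolerance
#' 0.1 mm).
#'
#' @param endo,epi `fitted_surface` objects on equal template grids.
#' @param density myocardial density in g/ml (default 1.05, the standard
#'   echocardiographic convention).
#' @return Mass in g.
#' @export
lv_mass <- function(endo, epi, density = 1.05) {
  stopifnot(inherits(endo, "fitted_surface"), inherits(epi, "fitted_surface"))
  if (endo$template$n_u != epi$template$n_u ||
      endo$template$n_v != epi$template$n_v)
    stop("correspondence error: template grids differ")
  ## enclosure check at shared physical height: endo node u rescaled into
  ## the epicardial parameterization (extents may differ)
  tpl <- endo$template
  u_endo <- rep(tpl$u, each = tpl$n_v)
  phi <- rep(tpl$phi, times = tpl$n_u)
  u_epi <- pmin(1, u_endo * endo$apex_extent / epi$apex_extent)
  r_epi_at <- template_radius(epi$template, u_epi, phi)
  crossing <- r_epi_at - as.vector(t(tpl$radii)) < -0.1
  if (any(crossing))
    stop("geometry error: epicardium crosses inside the endocardium at ",
         sum(crossing), " node(s)")
  (cavity_volume(epi) - cavity_volume(endo)) * density
}

#' Ejection fraction
#'
#' @param EDV end-diastolic volume (ml), must be > 0.
#' @param ESV end-systolic volume (ml).
#' @return EF in percent: `100 * (EDV - ESV) / EDV`.
#' @export
ejection_fraction <- function(EDV, ESV) {
  if (any(EDV <= 0)) stop("EDV must be positive")
  100 * (EDV - ESV) / EDV
}

#' Global volumetric report for one subject and method
#'
#' Bundles the standard global LV indices: end-diastolic and end-systolic
#' cavity volumes, ejection fraction and LV mass, computed on fitted
#' (template) surfaces so that all methods share one volume operator.
#'
#' @param endo_ed,endo_es endocardial `fitted_surface`s at ED and ES.
#' @param epi_ed optional epicardial `fitted_surface` at ED (for LVM,
#'   calculated from the ED models).
#' @param method method label (e.g. `"CMR"`, `"TOMTEC"`).
#' @param subject subject identifier.
#' @param density myocardial density g/ml (default 1.05).
#' @return An object of class `volumetric_report` (one-row data.frame with
#'   columns `subject`, `method`, `EDV`, `ESV`, `EF`, `LVM`).
#' @export
volumetric_report <- function(endo_ed, endo_es, epi_ed = NULL,
                              method = "unknown", subject = "unknown",
                              density = 1.05) {
  EDV <- cavity_volume(endo_ed)
  ESV <- cavity_volume(endo_es)
  LVM <- if (!is.null(epi_ed)) lv_mass(endo_ed, epi_ed, density) else NA_real_
  out <- data.frame(subject = subject, method = method,
                    EDV = EDV, ESV = ESV,
                    EF = ejection_fraction(EDV, ESV), LVM = LVM)
  class(out) <- c("volumetric_report", "data.frame")
  out
}

#' Index global LV measurements by body surface area
#'
#' Adds BSA-indexed columns (`EDVI`, `ESVI` in ml/m^2, `LVMI` in g/m^2) to
#' a [volumetric_report()].
#'
#' @param report a `volumetric_report`.
#' @param bsa body surface area in m^2, must be > 0.
#' @return The report with indexed columns appended.
#' @export
index_by_bsa <- function(report, bsa) {
  if (!is.numeric(bsa) || any(bsa <= 0)) stop("BSA must be positive (m^2)")
  report$BSA <- bsa
  report$EDVI <- report$EDV / bsa
  report$ESVI <- report$ESV / bsa
  report$LVMI <- report$LVM / bsa
  report
}
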