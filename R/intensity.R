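#' 3D scalar image volume
#'
#' Minimal container for a 3D image on a regular grid: voxel intensities,
#' voxel spacing (mm), world origin of the first voxel centre, and an
#' orthonormal direction matrix mapping voxel axes to world axes. Voxel
#' centre (i, j, k) (1-based) maps to world position
#' `origin + direction %*% (spacing * (c(i, j, k) - 1))`.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing positive length-3 voxel spacing in mm.
#' @param origin length-3 world position (mm) of the first voxel centre.
#' @param direction 3x3 orthonormal direction matrix (default identity).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  storage.mode(data) <- "double"
  stopifnot_finite(data, "intensities")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  origin <- as.double(origin)
  stopifnot(length(origin) == 3L)
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("geometry error: direction matrix is not orthonormal")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("Image volume ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(sprintf("%.2f", x$spacing), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

## world coordinates (n x 3) of all voxel centres, in array order
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(rep(seq_len(d[1L]), times = d[2L] * d[3L]),
               rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
               rep(seq_len(d[3L]), each = d[1L] * d[2L]))
  local <- sweep(idx - 1, 2L, vol$spacing, "*")
  local %*% t(vol$direction) +
    matrix(vol$origin, nrow(local), 3L, byrow = TRUE)
}

#' Normalize image intensities to the 0-95th percentile range
#'
#' Per-image normalization: intensities are clipped to `[0, p95]`, where
#' p95 is the 95th percentile over all voxels (inverse-ECDF order
#' statistic), then divided by p95 so output values lie in `[0, 1]`.
#' Relative signal intensity reports are then percentages of this
#' normalized peak. Using the order-statistic percentile makes the
#' operation exactly idempotent: re-normalizing a clipped image finds its
#' 95th percentile at the clipped value 1 and leaves it unchanged.
#'
#' @param vol an [image_volume()].
#' @param probs percentile defining the peak (default 0.95).
#' @return The normalized `image_volume`.
#' @export
normalize_intensity <- function(vol, probs = 0.95) {
  stopifnot(inherits(vol, "image_volume"))
  v <- vol$data
  if (diff(range(v)) == 0) {
    if (all(v == 0)) stop("degenerate image: constant zero intensity")
    warning("constant image: normalization returns all ones")
    vol$data <- array(1, dim(v))
    return(vol)
  }
  p95 <- unname(stats::quantile(as.vector(v), probs = probs, type = 1))
  if (p95 <= 0) stop("degenerate image: 95th percentile is not positive")
  vol$data <- pmin(pmax(v, 0), p95) / p95
  vol
}

#' Per-AHA-segment mean relative signal intensity
#'
#' Samples a normalized image volume inside the myocardial shell and
#' averages per AHA segment. Shell membership is tested in cardiac
#' coordinates: a voxel centre at (u, phi, r) is myocardial when
#' `r_endo(u, phi) <= r <= r_epi(u, phi)` and `0 <= u <= 1` (exact for
#' star-shaped surfaces). Each myocardial voxel receives the AHA label of
#' its (u, phi) under the same partition rules as
#' [assign_aha_segments()], using the epicardial convention (17 segments
#' including the cap).
#'
#' @param vol a normalized [image_volume()] (see [normalize_intensity()]),
#'   co-registered with the surfaces.
#' @param endo,epi `fitted_surface` objects on equal template grids.
#' @param cap_u apical-cap boundary (default 0.90), as in
#'   [assign_aha_segments()].
#' @return A data.frame of class `segment_intensity_report` with columns
#'   `segment`, `segment_name`, `mean_intensity` (percent of normalized
#'   peak, in `[0, 100]`) and `n_voxels`.
#' @export
segment_mean_intensity <- function(vol, endo, epi, cap_u = 0.90) {
  stopifnot(inherits(vol, "image_volume"),
            inherits(endo, "fitted_surface"), inherits(epi, "fitted_surface"))
  if (endo$template$n_u != epi$template$n_u ||
      endo$template$n_v != epi$template$n_v)
    stop("correspondence error: template grids differ")
  ctr <- voxel_centers(vol)
  uvr <- to_cardiac_coords(ctr, endo$frame, endo$apex_extent)
  ## the epicardium can extend beyond the endocardial apex: evaluate its
  ## radius in its own longitudinal parameterization
  u_epi <- uvr[, "u"] * endo$apex_extent / epi$apex_extent
  inside <- uvr[, "u"] >= 0 & u_epi <= 1
  r_en <- rep(-Inf, nrow(uvr)); r_ep <- rep(-Inf, nrow(uvr))
  ue <- pmin(1, uvr[inside, "u"])
  r_en[inside] <- template_radius(endo$template, ue, uvr[inside, "phi"])
  r_ep[inside] <- template_radius(epi$template, u_epi[inside],
                                  uvr[inside, "phi"])
  above_endo <- uvr[, "u"] > 1     # apical cap region above the endo apex
  myo <- inside & uvr[, "r"] <= r_ep &
    (above_endo | uvr[, "r"] >= r_en)
  if (!any(myo)) stop("coverage error: no myocardial voxels inside the volume")
  u <- pmin(1, uvr[myo, "u"]); phi <- uvr[myo, "phi"]
  lab <- voxel_aha_label(u, phi, cap_u)
  val <- as.vector(vol$data)[myo] * 100
  agg <- vapply(split(val, lab), mean, numeric(1))
  n <- vapply(split(val, lab), length, integer(1))
  out <- data.frame(segment = as.integer(names(agg)),
                    segment_name = aha_segment_names()[as.integer(names(agg))],
                    mean_intensity = unname(agg), n_voxels = unname(n))
  out <- out[order(out$segment), ]
  rownames(out) <- NULL
  class(out) <- c("segment_intensity_report", "data.frame")
  out
}

## vectorized AHA id for arbitrary (u, phi); epicardial convention (cap = 17)
voxel_aha_label <- function(u, phi, cap_u = 0.90) {
  phi <- phi %% 360
  lab <- integer(length(u))
  base <- u < 1 / 3
  mid <- u >= 1 / 3 & u < 2 / 3
  api <- u >= 2 / 3 & u < cap_u
  cap <- u >= cap_u
  lab[base] <- .aha_basal[floor(phi[base] / 60) + 1L]
  lab[mid] <- .aha_basal[floor(phi[mid] / 60) + 1L] + 6L
  lab[api] <- c(14L, 13L, 16L, 15L)[floor(((phi[api] + 45) %% 360) / 90) + 1L]
  lab[cap] <- 17L
  lab
}
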