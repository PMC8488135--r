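## Synthetic LV phantom cohort generator.
## Geometry: truncated-ellipsoid endocardium (semi-axes a, b short, c long),
## epicardium offset by the wall thickness (semi-axes a+t, b+t, c+t, same
## centre, truncated at the same basal plane). Local coordinates: basal
## plane z = 0, apex pole at z = L = c (1 + truncation); ellipsoid centre
## at z = truncation * c. Surfaces are smooth (no trabeculae or papillary
## muscles, matching the CMR contouring convention); echo-style regional
## underestimation is modelled explicitly via apply_regional_bias().

## evaluate an expression with a private, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic LV phantom
#'
#' Parameters of one ground-truth phantom subject. Defaults emulate a
#' healthy adult LV: end-diastolic cavity of roughly 145 ml, 9 mm wall,
#' ejection fraction 60%, and a per-phase rigid misalignment between the
#' "echo" and "CMR" copies of up to a few degrees / millimetres.
#'
#' @param a,b,c endocardial semi-axes in mm (short, short, long).
#' @param wall_thickness basal wall thickness in mm.
#' @param hypertrophy wall-thickness multiplier (1 = normal; about 1.6
#'   emulates LV hypertrophy).
#' @param truncation fraction of the long semi-axis below the ellipsoid
#'   centre at which the base is truncated (0 < truncation < 1).
#' @param rv_insertion_angles named angles (degrees, from `e_rv` toward
#'   `e_norm`) of the inferior and anterior RV insertions on the epicardial
#'   base ring. The defaults (+70 / -70) make the CMR convention (mean of
#'   insertions) and the echo 70-degree rule agree exactly.
#' @param n_points approximate number of surface points per surface.
#' @param noise_sd radial Gaussian noise SD (mm) added to the echo-side
#'   surface points (0 = noiseless).
#' @param ef_target target ejection fraction (fraction, e.g. 0.60).
#' @param bsa body surface area in m^2.
#' @param misalign_rotation_deg,misalign_translation_mm magnitudes of the
#'   ground-truth rigid misalignment applied to the echo copy (random
#'   axis/direction per phase, drawn from `seed`).
#' @param seed integer RNG seed; regeneration from the same spec is
#'   bit-identical.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(a = 28, b = 28, c = 52, wall_thickness = 9,
                         hypertrophy = 1, truncation = 0.5,
                         rv_insertion_angles = c(inferior = 70, anterior = -70),
                         n_points = 2000L, noise_sd = 0,
                         ef_target = 0.60, bsa = 1.88,
                         misalign_rotation_deg = 5,
                         misalign_translation_mm = 5,
                         seed = 1L) {
  if (any(c(a, b, c) <= 0)) stop("semi-axes must be positive")
  if (truncation <= 0 || truncation >= 1)
    stop("truncation fraction must lie in (0, 1)")
  th <- wall_thickness * hypertrophy
  if (th <= 0) stop("wall thickness must be positive")
  if (ef_target <= 0 || ef_target >= 1) stop("ef_target must lie in (0, 1)")
  structure(list(a = a, b = b, c = c, wall_thickness = wall_thickness,
                 hypertrophy = hypertrophy, truncation = truncation,
                 rv_insertion_angles = rv_insertion_angles,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 ef_target = ef_target, bsa = bsa,
                 misalign_rotation_deg = misalign_rotation_deg,
                 misalign_translation_mm = misalign_translation_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## truncated-ellipsoid volume (mm^3): semi-axes a,b,c, base plane a fraction
## tau of c below the centre, closed at the apex pole
truncated_ellipsoid_volume <- function(a, b, c, tau) {
  pi * a * b * c * (2 / 3 + tau - tau^3 / 3)
}

#' Closed-form ground-truth volumetrics of a phantom spec
#'
#' Analytic EDV, ESV, EF and LV mass of the continuous phantom solid
#' (before any surface discretization), for use as an independent oracle.
#'
#' @param spec a [phantom_spec()].
#' @param density myocardial density g/ml (default 1.05).
#' @return Named list: `EDV`, `ESV` (ml), `EF` (percent), `LVM` (g),
#'   `radial_scale_endo`, `radial_scale_epi` (the ES scale factors).
#' @export
phantom_analytic_volumes <- function(spec, density = 1.05) {
  th <- spec$wall_thickness * spec$hypertrophy
  tau_e <- spec$truncation * spec$c / (spec$c + th)
  v_endo <- truncated_ellipsoid_volume(spec$a, spec$b, spec$c, spec$truncation)
  v_epi <- truncated_ellipsoid_volume(spec$a + th, spec$b + th, spec$c + th, tau_e)
  s_endo <- sqrt(1 - spec$ef_target)
  v_endo_es <- v_endo * s_endo^2          # x-y scaling multiplies volume by s^2
  v_epi_es <- v_epi - v_endo + v_endo_es  # wall volume conserved at ES
  list(EDV = v_endo / 1000, ESV = v_endo_es / 1000,
       EF = 100 * spec$ef_target,
       LVM = (v_epi - v_endo) / 1000 * density,
       radial_scale_endo = s_endo,
       radial_scale_epi = sqrt(v_epi_es / v_epi))
}

## structured surface sample of a truncated ellipsoid (local coordinates);
## returns a surface_model. radial_scale scales x-y about the long axis.
ellipsoid_surface <- function(a, b, c, tau, n_points, surface_tag, phase,
                              radial_scale = 1, apex_extent,
                              noise_sd = 0) {
  n_rows <- max(8L, round(sqrt(n_points * 0.8)))
  n_cols <- max(12L, round(n_points / n_rows))
  z0 <- tau * c
  L_own <- z0 + c                    # own apex height; may differ from frame extent
  u <- seq(0, 0.995, length.out = n_rows)
  z <- u * L_own
  s <- sqrt(pmax(0, 1 - ((z - z0) / c)^2))
  phi <- seq(0, 2 * pi, length.out = n_cols + 1L)[seq_len(n_cols)]
  Z <- rep(z, each = n_cols)
  S <- rep(s, each = n_cols)
  ## incommensurate (golden-ratio) per-row phase shift: a plain grid is a
  ## circumferential lattice whose column-shifted copies trap shape-only
  ## ICP in local minima; the aperiodic stagger removes that degeneracy
  ## while keeping the row structure (and hence the triangulation) intact
  golden <- (sqrt(5) - 1) / 2
  PH <- rep(phi, times = n_rows) +
    rep(((seq_len(n_rows) - 1L) * golden) %% 1, each = n_cols) * 2 * pi / n_cols
  x <- radial_scale * a * S * cos(PH)
  y <- radial_scale * b * S * sin(PH)
  if (noise_sd > 0) {
    r <- sqrt(x^2 + y^2)
    pert <- pmax(0.2, 1 + stats::rnorm(length(r), 0, noise_sd) / pmax(r, 1))
    x <- x * pert
    y <- y * pert
  }
  verts <- cbind(x, y, Z)
  node <- function(i, j) (i - 1L) * n_cols + (j - 1L) %% n_cols + 1L
  i <- rep(seq_len(n_rows - 1L), each = n_cols)
  j <- rep(seq_len(n_cols), times = n_rows - 1L)
  tris <- rbind(cbind(node(i, j), node(i + 1L, j), node(i, j + 1L)),
                cbind(node(i, j + 1L), node(i + 1L, j), node(i + 1L, j + 1L)))
  surface_model(verts, tris, surface_tag = surface_tag, phase = phase)
}

## a uniformly random rigid transform with fixed magnitudes
random_rigid <- function(rot_deg, trans_mm) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  rigid_transform(rotation_about_axis(ax, deg2rad(rot_deg)), trans_mm * dir)
}

#' Generate one ground-truth phantom subject
#'
#' Builds per-phase (ED/ES) endocardial and epicardial surfaces and
#' landmark sets in the CMR convention, plus echo-convention copies
#' displaced by known ground-truth rigid transforms (drawn independently
#' per phase, as transducer position can shift between frames). The ES
#' geometry is derived from ED by uniform inward radial scaling about the
#' long axis, chosen so the continuous solid hits the target ejection
#' fraction exactly, with the epicardium rescaled to conserve wall volume.
#' Everything is deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_subject`: lists `cmr` and `echo`
#'   (each with `ED`/`ES` elements holding `endo`, `epi`, `landmarks`),
#'   `gt_transforms` (named per phase; the transform carrying CMR pose to
#'   echo pose), `deformations` (segment -> amplitude mm, updated by
#'   [apply_regional_bias()]), `bsa` and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  th <- spec$wall_thickness * spec$hypertrophy
  tau <- spec$truncation
  a <- spec$a; b <- spec$b; c <- spec$c
  L <- (1 + tau) * c
  tau_e <- tau * c / (c + th)
  if ((c + th) * (1 - tau_e) <= 0) stop("non-physical spec: epicardium self-intersects")
  vols <- phantom_analytic_volumes(spec)

  base_ring_scale <- sqrt(1 - (tau * c / (c + th))^2)
  ins_xy <- function(angle_deg) {
    t_ang <- deg2rad(angle_deg)
    c((a + th) * base_ring_scale * cos(t_ang),
      (b + th) * base_ring_scale * sin(t_ang), 0)
  }
  ins <- rbind(ins_xy(spec$rv_insertion_angles[["inferior"]]),
               ins_xy(spec$rv_insertion_angles[["anterior"]]))
  lm_cmr <- landmark_set(c(0, 0, L), c(0, 0, 0),
                         data.frame(x = ins[, 1L], y = ins[, 2L], z = ins[, 3L],
                                    label = c("inferior", "anterior")),
                         convention = "cmr")
  lm_echo_local <- landmark_set(c(0, 0, L), c(0, 0, 0),
                                data.frame(x = ins[1L, 1L], y = ins[1L, 2L],
                                           z = ins[1L, 3L], label = "inferior"),
                                convention = "echo")

  make_phase <- function(phase, s_endo, s_epi, noise_sd) {
    list(endo = ellipsoid_surface(a, b, c, tau, spec$n_points, "endo", phase,
                                  radial_scale = s_endo, noise_sd = noise_sd),
         epi = ellipsoid_surface(a + th, b + th, c + th, tau_e, spec$n_points,
                                 "epi", phase, radial_scale = s_epi,
                                 noise_sd = noise_sd))
  }

  with_seed(spec$seed, {
    cmr <- list(ED = make_phase("ED", 1, 1, 0),
                ES = make_phase("ES", vols$radial_scale_endo,
                                vols$radial_scale_epi, 0))
    cmr$ED$landmarks <- lm_cmr
    cmr$ES$landmarks <- lm_cmr
    echo_local <- list(ED = make_phase("ED", 1, 1, spec$noise_sd),
                       ES = make_phase("ES", vols$radial_scale_endo,
                                       vols$radial_scale_epi, spec$noise_sd))
    gt <- list(ED = random_rigid(spec$misalign_rotation_deg,
                                 spec$misalign_translation_mm),
               ES = random_rigid(spec$misalign_rotation_deg,
                                 spec$misalign_translation_mm))
    echo <- lapply(c(ED = "ED", ES = "ES"), function(ph) {
      list(endo = apply_transform(echo_local[[ph]]$endo, gt[[ph]]),
           epi = apply_transform(echo_local[[ph]]$epi, gt[[ph]]),
           landmarks = apply_transform(lm_echo_local, gt[[ph]]))
    })
    structure(list(cmr = cmr, echo = echo, gt_transforms = gt,
                   deformations = numeric(0), bsa = spec$bsa, spec = spec),
              class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  v <- phantom_analytic_volumes(x$spec)
  cat(sprintf("Phantom subject: EDV %.1f ml, EF %.0f%%, wall %.1f mm, BSA %.2f m^2\n",
              v$EDV, v$EF, x$spec$wall_thickness * x$spec$hypertrophy, x$bsa))
  if (length(x$deformations))
    cat("  regional biases (mm):",
        paste(sprintf("seg %s: %.1f", names(x$deformations), x$deformations),
              collapse = ", "), "\n")
  invisible(x)
}

## (u, phi) box of an AHA segment (1..16); returns list(u0, u1, phi0, phi1)
aha_segment_box <- function(segment) {
  if (segment <= 6L) {
    u0 <- 0; u1 <- 1 / 3
    sector <- which(.aha_basal == segment)
  } else if (segment <= 12L) {
    u0 <- 1 / 3; u1 <- 2 / 3
    sector <- which(.aha_basal == segment - 6L)
  } else {
    u0 <- 2 / 3; u1 <- 0.9
    ## apical sectors: 13 anterior [45,135), 16 lateral [135,225),
    ## 15 inferior [225,315), 14 septal [315,45)
    return(list(u0 = u0, u1 = u1,
                phi0 = switch(as.character(segment),
                              "13" = 45, "16" = 135, "15" = 225, "14" = 315),
                phi1 = switch(as.character(segment),
                              "13" = 135, "16" = 225, "15" = 315, "14" = 45)))
  }
  list(u0 = u0, u1 = u1, phi0 = (sector - 1L) * 60, phi1 = sector * 60)
}

## smooth plateau window: full amplitude on [x0, x1] (boundaries
## included), raised-cosine decay to zero over `falloff` outside;
## `wrap` = 360 for circular coordinates
plateau_window <- function(x, x0, x1, falloff, wrap = NULL) {
  if (!is.null(wrap)) {
    x <- x %% wrap
    inside <- if (x0 <= x1) x >= x0 & x <= x1 else x >= x0 | x <= x1
    d0 <- pmin(abs(x - x0), wrap - abs(x - x0))
    d1 <- pmin(abs(x - x1), wrap - abs(x - x1))
    d <- ifelse(inside, 0, pmin(d0, d1))        # outward distance
  } else {
    d <- pmax(0, pmax(x0 - x, x - x1))
  }
  ifelse(d >= falloff, 0, 0.5 * (1 + cos(pi * d / falloff)))
}

#' Apply a known inward regional deformation to the echo copy
#'
#' Displaces the echo-side endocardial and epicardial surfaces radially
#' inward by `amplitude * w`, where `w` is a smooth window equal to 1
#' across the target AHA segment with a raised-cosine falloff outside it.
#' This emulates the echo underestimation observed regionally in fused
#' studies, with exact ground truth: the displacement at the segment
#' centre equals `amplitude`. The subject's ground-truth deformation table
#' is updated.
#'
#' The window carries full amplitude across the whole segment, with a
#' raised-cosine decay over the falloff widths outside its boundaries, so
#' the segment-mean displacement is close to the nominal amplitude. For
#' experiments that need the displacement strictly confined to the
#' segment interior (e.g. leakage studies), positive insets shrink the
#' windowed box away from the boundaries before the falloff is applied.
#'
#' @param subject a [make_phantom()] subject.
#' @param segment target AHA segment id in 1..16.
#' @param amplitude inward displacement in mm (must be smaller than the
#'   local radius).
#' @param falloff_deg angular raised-cosine falloff width (degrees).
#' @param falloff_u longitudinal falloff width (normalized u units).
#' @param inset_deg,inset_u zero-displacement margins inside the segment
#'   boundaries (default 0).
#' @return The modified `phantom_subject`.
#' @export
apply_regional_bias <- function(subject, segment, amplitude,
                                falloff_deg = 10, falloff_u = 0.05,
                                inset_deg = 0, inset_u = 0) {
  stopifnot(inherits(subject, "phantom_subject"))
  segment <- as.integer(segment)
  if (segment < 1L || segment > 16L) stop("segment must be in 1..16")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (amplitude == 0) return(subject)
  box <- aha_segment_box(segment)
  box$phi0 <- (box$phi0 + inset_deg) %% 360
  box$phi1 <- (box$phi1 - inset_deg) %% 360
  box$u0 <- box$u0 + inset_u
  box$u1 <- box$u1 - inset_u
  frame <- build_frame(subject$cmr$ED$landmarks)
  for (ph in c("ED", "ES")) {
    Tgt <- subject$gt_transforms[[ph]]
    Tinv <- rt_invert(Tgt)
    for (sf in c("endo", "epi")) {
      m <- subject$echo[[ph]][[sf]]
      local <- apply_transform(m$vertices, Tinv)   # back to CMR pose
      uvr <- to_cardiac_coords(local, frame)
      w <- plateau_window(uvr[, "phi"], box$phi0, box$phi1, falloff_deg,
                          wrap = 360) *
        plateau_window(uvr[, "u"], box$u0, box$u1, falloff_u)
      new_r <- uvr[, "r"] - amplitude * w
      if (any(new_r <= 0.5 & w > 0))
        stop("spec error: bias amplitude reaches the long axis")
      uvr[, "r"] <- new_r
      m$vertices <- apply_transform(from_cardiac_coords(uvr, frame), Tgt)
      subject$echo[[ph]][[sf]] <- m
    }
  }
  dn <- as.character(segment)
  subject$deformations[dn] <- (subject$deformations[dn] %||% 0)
  subject$deformations[dn] <- ifelse(is.na(subject$deformations[dn]), 0,
                                     subject$deformations[dn]) + amplitude
  subject
}

#' Synthesize an echo-like intensity volume with regional dropout
#'
#' Builds a regular image grid around the phantom (CMR pose) and fills the
#' myocardial shell with piecewise-constant per-AHA-segment target
#' intensities (emulating the circumferential signal-dropout structure of
#' 3D echo), a low-intensity blood pool, near-zero background, and a small
#' deterministic population of peak-intensity clutter voxels (just over 5%
#' of the volume) so that the per-image 95th-percentile normalization maps
#' the intended peak to 1. Optional multiplicative speckle noise is
#' applied to shell and blood-pool voxels.
#'
#' @param subject a [make_phantom()] subject.
#' @param segment_intensity named numeric vector mapping AHA segment id to
#'   target mean intensity in `[0, 1]`; unnamed segments use `default_intensity`.
#' @param default_intensity intensity for segments not listed (default 0.5).
#' @param speckle_sd multiplicative speckle SD (default 0 = none).
#' @param spacing isotropic voxel spacing in mm (default 1).
#' @param margin padding around the epicardial bounding box in mm.
#' @param phase phantom phase to voxelize (default `"ED"`).
#' @param seed RNG seed for the speckle noise.
#' @return An [image_volume()] in the CMR (registered) space.
#' @export
make_echo_volume <- function(subject, segment_intensity = NULL,
                             default_intensity = 0.5, speckle_sd = 0,
                             spacing = 1, margin = 8, phase = "ED",
                             seed = subject$spec$seed) {
  stopifnot(inherits(subject, "phantom_subject"))
  targets <- rep(default_intensity, 17L)
  if (!is.null(segment_intensity)) {
    ids <- as.integer(names(segment_intensity))
    if (any(is.na(ids)) || any(ids < 1L | ids > 17L))
      stop("segment_intensity must be named by AHA segment ids 1..17")
    if (any(segment_intensity < 0 | segment_intensity > 1))
      stop("intensity targets must lie in [0, 1]")
    targets[ids] <- segment_intensity
  }
  spec <- subject$spec
  th <- spec$wall_thickness * spec$hypertrophy
  tau <- spec$truncation
  L <- (1 + tau) * spec$c
  lim <- c(spec$a + th + margin, spec$b + th + margin)
  x <- seq(-lim[1L], lim[1L], by = spacing)
  y <- seq(-lim[2L], lim[2L], by = spacing)
  z <- seq(-margin, L + margin, by = spacing)
  d <- c(length(x), length(y), length(z))
  X <- rep(x, times = d[2L] * d[3L])
  Y <- rep(rep(y, each = d[1L]), times = d[3L])
  Z <- rep(z, each = d[1L] * d[2L])

  u <- Z / L
  phi <- rad2deg(atan2(Y, X)) %% 360
  r <- sqrt(X^2 + Y^2)
  ell_r <- function(a, b, cc, tau_s, u_pt, phi_pt) {
    z0 <- tau_s * cc
    zz <- u_pt * L
    s2 <- 1 - ((zz - z0) / cc)^2
    out <- rep(-1, length(u_pt))
    ok <- s2 > 0
    pr <- deg2rad(phi_pt[ok])
    out[ok] <- sqrt(s2[ok]) * a * b / sqrt((b * cos(pr))^2 + (a * sin(pr))^2)
    out
  }
  tau_e <- tau * spec$c / (spec$c + th)
  r_en <- ell_r(spec$a, spec$b, spec$c, tau, u, phi)
  r_ep <- ell_r(spec$a + th, spec$b + th, spec$c + th, tau_e, u, phi)
  ## myocardium: inside the epicardium and outside the endocardium; above
  ## the endocardial apex (r_en < 0) the whole epicardial cap is wall
  shell <- u >= 0 & r_ep >= 0 & r <= r_ep & (r_en < 0 | r >= r_en)
  pool <- u >= 0 & u <= 1 & r_en >= 0 & r < r_en

  vals <- rep(0.02, length(u))                 # background
  vals[pool] <- 0.05                           # blood pool
  lab <- voxel_aha_label(pmin(u[shell], 1), phi[shell])
  vals[shell] <- targets[lab]

  ## deterministic peak-intensity clutter so the image p95 equals the peak
  bg_idx <- which(!shell & !pool)
  n_bright <- ceiling(0.055 * length(vals))
  if (length(bg_idx) < n_bright)
    stop("extent error: grid too small to contain the phantom and clutter")
  vals[bg_idx[seq_len(n_bright)]] <- 1.0

  if (speckle_sd > 0) {
    with_seed(seed, {
      tissue <- shell | pool
      vals[tissue] <- pmax(0, vals[tissue] *
                             (1 + stats::rnorm(sum(tissue), 0, speckle_sd)))
    })
  }
  image_volume(array(vals, d), spacing = rep(spacing, 3L),
               origin = c(-lim[1L], -lim[2L], -margin))
}

#' Generate a reproducible synthetic cohort
#'
#' Draws `n` phantom subjects with anatomies and acquisition conditions
#' sampled from population distributions chosen to resemble a mixed
#' adult cohort: endocardial short semi-axes ~ N(28, 2) mm, long semi-axis
#' ~ N(52, 3) mm, wall thickness ~ N(9, 1) mm, EF ~ N(0.62, 0.05), BSA ~
#' N(1.88, 0.22) truncated to [1.41, 2.37] m^2, about 14% of subjects with
#' hypertrophic walls (multiplier 1.6), and per-phase misalignments with
#' rotation ~ U(0, 10) degrees and translation ~ U(0, 10) mm. Each subject
#' has its own RNG stream derived from the cohort seed, so subjects are
#' independent yet individually reproducible.
#'
#' @param n number of subjects.
#' @param seed cohort seed.
#' @param n_points surface points per surface.
#' @param noise_sd radial noise SD (mm) on echo surfaces.
#' @return A list with `subjects` (list of [make_phantom()] outputs) and
#'   `metadata` (data.frame with one row per subject: id, BSA and the
#'   generator parameters).
#' @export
make_cohort <- function(n, seed = 1L, n_points = 2000L, noise_sd = 0) {
  if (n < 1L) stop("n must be at least 1")
  seed <- as.integer(seed) %% 2000000L
  draws <- with_seed(seed, {
    data.frame(
      subject = sprintf("P%03d", seq_len(n)),
      a = stats::rnorm(n, 28, 2),
      c = stats::rnorm(n, 52, 3),
      wall_thickness = pmax(5, stats::rnorm(n, 9, 1)),
      hypertrophy = ifelse(stats::runif(n) < 0.14, 1.6, 1),
      ef_target = pmin(0.8, pmax(0.35, stats::rnorm(n, 0.62, 0.05))),
      bsa = pmin(2.37, pmax(1.41, stats::rnorm(n, 1.88, 0.22))),
      misalign_rotation_deg = stats::runif(n, 0, 10),
      misalign_translation_mm = stats::runif(n, 0, 10))
  })
  subjects <- lapply(seq_len(n), function(i) {
    sp <- phantom_spec(a = draws$a[i], b = draws$a[i], c = draws$c[i],
                       wall_thickness = draws$wall_thickness[i],
                       hypertrophy = draws$hypertrophy[i],
                       ef_target = draws$ef_target[i], bsa = draws$bsa[i],
                       misalign_rotation_deg = draws$misalign_rotation_deg[i],
                       misalign_translation_mm = draws$misalign_translation_mm[i],
                       n_points = n_points, noise_sd = noise_sd,
                       seed = seed * 1000L + i)
    make_phantom(sp)
  })
  names(subjects) <- draws$subject
  list(subjects = subjects, metadata = draws)
}
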