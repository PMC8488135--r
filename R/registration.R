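#' Coarse frame-based alignment of two cardiac frames
#'
#' Returns the unique rigid transform mapping the source (echo) cardiac
#' frame onto the reference (CMR) frame: origins coincide and the
#' (e_rv, e_norm, e_long) triads are superposed. Because both frames are
#' right-handed orthonormal triads anchored at the basal centroid, aligning
#' the LV long axis and RV direction fixes all six rigid degrees of freedom.
#'
#' @param frame_src source frame (typically echo), a `cardiac_frame`.
#' @param frame_ref reference frame (typically CMR), a `cardiac_frame`.
#' @return A [rigid_transform()] such that applying it to the source
#'   geometry expresses it in the reference pose.
#' @export
coarse_align <- function(frame_src, frame_ref) {
  stopifnot(inherits(frame_src, "cardiac_frame"),
            inherits(frame_ref, "cardiac_frame"))
  A <- cbind(frame_src$e_rv, frame_src$e_norm, frame_src$e_long)
  B <- cbind(frame_ref$e_rv, frame_ref$e_norm, frame_ref$e_long)
  R <- B %*% t(A)
  rigid_transform(R, frame_ref$origin - as.vector(R %*% frame_src$origin))
}

## one-way nearest-neighbour indices of rows of src in rows of ref
## (vectorized cross-distance; ties resolve to the lowest ref index)
nn_index <- function(src, ref) {
  d2 <- outer(rowSums(src^2), rowSums(ref^2), "+") - 2 * src %*% t(ref)
  max.col(-d2, ties.method = "first")
}

## closed-form least-squares rigid fit src -> dst (Kabsch / SVD)
kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2L, cs), sweep(dst, 2L, cd))
  s <- svd(H)
  R <- s$v %*% t(s$u)
  if (det(R) < 0) R <- s$v %*% diag(c(1, 1, -1)) %*% t(s$u)
  rigid_transform(R, cd - as.vector(R %*% cs))
}

#' Iterative-closest-point refinement of a rigid alignment
#'
#' Point-to-point ICP: starting from the initial transform `T0` (normally
#' the coarse frame alignment), alternately (i) matches every transformed
#' source point to its nearest reference point (one-way, ties to the lowest
#' index) and (ii) solves the closed-form least-squares rigid update by SVD.
#' Iteration stops when the RMS correspondence distance changes by less
#' than `tol` mm, or after `max_iter` iterations (then `converged = FALSE`
#' with a warning, not an error).
#'
#' With `trim < 1` only that fraction of correspondences with the smallest
#' distances enters each rigid update (trimmed ICP). This keeps genuine
#' regional shape differences between the two models - e.g. local echo
#' underestimation - from biasing the rigid alignment; classic ICP
#' (`trim = 1`) guarantees a monotone non-increasing RMS objective.
#'
#' @param src_points n x 3 matrix of source points (mm), n >= 100 advised.
#' @param ref_points m x 3 matrix of reference points (mm).
#' @param T0 initial [rigid_transform()] (default identity).
#' @param max_iter maximum number of iterations (default 100).
#' @param tol RMS-change convergence tolerance in mm (default 1e-4).
#' @param trim fraction (0.5-1] of best correspondences used in each
#'   update (default 1 = classic ICP).
#' @param phase cardiac phase recorded in the result.
#' @return An object of class `registration_result` with elements `phase`,
#'   `coarse` (= `T0`), `refinement`, `total` (= refinement after coarse),
#'   `rms_residual` (mm), `n_iterations`, `converged`.
#' @export
icp_refine <- function(src_points, ref_points, T0 = rt_identity(),
                       max_iter = 100L, tol = 1e-4, trim = 1, phase = "ED") {
  src_points <- as_points3(src_points)
  ref_points <- as_points3(ref_points)
  if (nrow(src_points) == 0L || nrow(ref_points) == 0L)
    stop("ICP requires non-empty point sets")
  if (trim <= 0.5 || trim > 1) stop("trim must lie in (0.5, 1]")
  n_keep <- max(3L, floor(trim * nrow(src_points)))
  T_ref <- rt_identity()
  cur <- apply_transform(src_points, T0)
  rms_prev <- Inf
  it <- 0L
  converged <- FALSE
  rms <- NA_real_
  rms_trace <- numeric(0)
  while (it < max_iter) {
    it <- it + 1L
    idx <- nn_index(cur, ref_points)
    matched <- ref_points[idx, , drop = FALSE]
    d2 <- rowSums((cur - matched)^2)
    keep <- if (n_keep < length(d2))
      order(d2)[seq_len(n_keep)] else seq_along(d2)
    rms <- sqrt(mean(d2[keep]))
    rms_trace <- c(rms_trace, rms)
    if (is.finite(rms_prev) && abs(rms_prev - rms) < tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    upd <- kabsch(cur[keep, , drop = FALSE], matched[keep, , drop = FALSE])
    T_ref <- rt_compose(upd, T_ref)
    cur <- apply_transform(cur, upd)
  }
  if (!converged)
    warning("ICP did not converge within ", max_iter, " iterations (RMS ",
            sprintf("%.4f", rms), " mm)")
  structure(list(phase = phase, coarse = T0, refinement = T_ref,
                 total = rt_compose(T_ref, T0),
                 rms_residual = rms, n_iterations = it,
                 converged = converged, rms_trace = rms_trace),
            class = "registration_result")
}

#' Register one subject's echo models to its CMR models, per phase
#'
#' End-diastole (ED) and end-systole (ES) are registered independently with
#' no shared parameters, because transducer position relative to the heart
#' can shift between the frames of an acquisition. For each phase the echo
#' frame is coarse-aligned onto the CMR frame by [coarse_align()]; the
#' alignment is then refined by ICP on the union of sampled endocardial and
#' epicardial surface points, unless `refine = FALSE` or a manual override
#' transform is supplied for that phase.
#'
#' @param echo a list with per-phase elements `ED` and `ES`, each a list
#'   with `endo`, `epi` ([surface_model()]s) and `landmarks`
#'   ([landmark_set()]).
#' @param cmr same structure as `echo`, for the reference modality.
#' @param refine logical; run ICP refinement (default `TRUE`).
#' @param manual_override optional named list (`ED`, `ES`) of
#'   [rigid_transform()]s replacing ICP refinement for a phase.
#' @param max_iter,tol passed to [icp_refine()].
#' @param trim trimmed-ICP fraction passed to [icp_refine()] (default
#'   0.85, so localized genuine shape differences between modalities do
#'   not bias the rigid alignment).
#' @param rms_threshold alignment residuals above this (mm) are flagged
#'   with a warning as poor fusions (default 5 mm).
#' @param max_src_points,max_ref_points deterministic (evenly strided)
#'   subsampling caps on the ICP point sets, bounding the cost of the
#'   nearest-neighbour searches.
#' @return Named list (`ED`, `ES`) of `registration_result` objects.
#' @export
register_subject <- function(echo, cmr, refine = TRUE,
                             manual_override = NULL,
                             max_iter = 100L, tol = 1e-4, trim = 0.85,
                             rms_threshold = 5,
                             max_src_points = 800L, max_ref_points = 2000L) {
  phases <- c("ED", "ES")
  if (!all(phases %in% names(echo)) || !all(phases %in% names(cmr)))
    stop("both ED and ES must be present for both modalities")
  out <- lapply(phases, function(ph) {
    fe <- build_frame(echo[[ph]]$landmarks)
    fc <- build_frame(cmr[[ph]]$landmarks)
    T0 <- coarse_align(fe, fc)
    ov <- manual_override[[ph]]
    if (!is.null(ov)) {
      stopifnot(inherits(ov, "rigid_transform"))
      res <- structure(list(phase = ph, coarse = T0, refinement = ov,
                            total = rt_compose(ov, T0),
                            rms_residual = NA_real_, n_iterations = 0L,
                            converged = TRUE),
                       class = "registration_result")
    } else if (!refine) {
      res <- structure(list(phase = ph, coarse = T0,
                            refinement = rt_identity(), total = T0,
                            rms_residual = NA_real_, n_iterations = 0L,
                            converged = TRUE),
                       class = "registration_result")
    } else {
      src <- rbind(echo[[ph]]$endo$vertices, echo[[ph]]$epi$vertices)
      ref <- rbind(cmr[[ph]]$endo$vertices, cmr[[ph]]$epi$vertices)
      stride <- function(P, cap) {
        if (nrow(P) > cap)
          P[unique(round(seq(1L, nrow(P), length.out = cap))), , drop = FALSE]
        else P
      }
      src <- stride(src, max_src_points)
      ref <- stride(ref, max_ref_points)
      res <- icp_refine(src, ref, T0 = T0, max_iter = max_iter, tol = tol,
                        trim = trim, phase = ph)
      if (is.finite(res$rms_residual) && res$rms_residual > rms_threshold)
        warning("phase ", ph, ": alignment residual ",
                sprintf("%.2f", res$rms_residual),
                " mm exceeds acceptance threshold (", rms_threshold, " mm)")
    }
    res
  })
  names(out) <- phases
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Registration [", x$phase, "]: total rotation ",
      sprintf("%.3f", rt_angle_deg(x$total)), " deg, RMS residual ",
      ifelse(is.na(x$rms_residual), "NA",
             sprintf("%.4f mm", x$rms_residual)),
      ", ", x$n_iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}
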