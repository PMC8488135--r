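## AHA 17-segment circumferential conventions.
## phi = 0 (the e_rv direction) is the mid-septum, i.e. the boundary between
## the anteroseptal and inferoseptal sectors; increasing phi walks from the
## septum toward the anterior wall. Basal/mid rings use 60-degree sectors,
## the apical ring 90-degree sectors; half-open intervals, ties to the lower
## sector.

## AHA id by 60-degree sector index (floor(phi/60)), basal ring
.aha_basal <- c(2L, 1L, 6L, 5L, 4L, 3L)

aha_sector_id <- function(phi, ring) {
  phi <- phi %% 360
  if (ring == "basal") .aha_basal[floor(phi / 60) + 1L]
  else if (ring == "mid") .aha_basal[floor(phi / 60) + 1L] + 6L
  else { # apical: anterior [45,135) = 13, lateral [135,225) = 16,
         # inferior [225,315) = 15, septal [315,45) = 14
    c(14L, 13L, 16L, 15L)[floor(((phi + 45) %% 360) / 90) + 1L]
  }
}

#' Segment names of the AHA 17-segment model
#'
#' @return Character vector of length 17, indexed by AHA segment id.
#' @export
aha_segment_names <- function() {
  c("basal anterior", "basal anteroseptal", "basal inferoseptal",
    "basal inferior", "basal inferolateral", "basal anterolateral",
    "mid anterior", "mid anteroseptal", "mid inferoseptal",
    "mid inferior", "mid inferolateral", "mid anterolateral",
    "apical anterior", "apical septal", "apical inferior",
    "apical lateral", "apical cap")
}

#' Assign AHA segment labels to the nodes of a fitted surface
#'
#' Partitions template nodes into the AHA model: longitudinal thirds by u
#' (basal `[0, 1/3)`, mid `[1/3, 2/3)`, apical `[2/3, cap_u)`) and the
#' apical cap `[cap_u, 1]`. The cap (segment 17) exists only on the
#' epicardium; endocardial nodes at `u >= cap_u` are masked (the
#' endocardium carries 16 segments, excluding the apical cap).
#' Circumferential sectors are anchored at `e_rv` (phi = 0 at the
#' mid-septum); see the package vignette for the declared layout.
#'
#' @param fitted a `fitted_surface` from [fit_surface()].
#' @param cap_u normalized longitudinal position where the apical cap
#'   begins; must lie in (2/3, 1) (default 0.90).
#' @return An object of class `aha_label_map`: integer vector `labels`
#'   (length `n_u * n_v + 1`, `NA` for masked nodes), logical `mask`,
#'   plus grid metadata.
#' @export
assign_aha_segments <- function(fitted, cap_u = 0.90) {
  stopifnot(inherits(fitted, "fitted_surface"))
  if (!is.numeric(cap_u) || length(cap_u) != 1L || cap_u <= 2 / 3 || cap_u >= 1)
    stop("cap_u must lie strictly between 2/3 and 1")
  tpl <- fitted$template
  n_u <- tpl$n_u; n_v <- tpl$n_v
  u <- rep(tpl$u, each = n_v)
  phi <- rep(tpl$phi, times = n_u)
  is_endo <- fitted$surface_tag == "endo"

  lab <- integer(n_u * n_v)
  ring <- ifelse(u < 1 / 3, "basal", ifelse(u < 2 / 3, "mid", "apical"))
  for (k in seq_along(lab)) {
    if (u[k] >= cap_u) {
      lab[k] <- if (is_endo) NA_integer_ else 17L
    } else {
      lab[k] <- aha_sector_id(phi[k], ring[k])
    }
  }
  ## apex pole vertex (u = 1)
  lab <- c(lab, if (is_endo) NA_integer_ else 17L)
  structure(list(labels = lab, mask = is.na(lab),
                 surface_tag = fitted$surface_tag,
                 n_u = n_u, n_v = n_v, cap_u = cap_u),
            class = "aha_label_map")
}

#' @export
print.aha_label_map <- function(x, ...) {
  cat("AHA label map (", x$surface_tag, "): segments {",
      paste(sort(unique(stats::na.omit(x$labels))), collapse = ","),
      "}, ", sum(x$mask), " masked node(s)\n", sep = "")
  invisible(x)
}

#' Per-segment mean surface distance between two fitted surfaces
#'
#' For two surfaces re-fitted to the same template grid, corresponding
#' points share a node index, and the regional error statistic for each
#' AHA segment is
#' \deqn{MSD_{AHA} = \frac{1}{N_p} \sum_{p=1}^{N_p} d(M_p, E_p)}
#' where \eqn{d(M_p, E_p)} is the Euclidean distance between corresponding
#' points of the reference model (\eqn{M_p}, typically CMR) and the test
#' model (\eqn{E_p}, typically re-fitted echo), and \eqn{N_p} the number of
#' surface points in the segment. Labels are computed on the reference
#' surface and applied to both via node correspondence.
#'
#' `method = "nearest"` replaces corresponding-node distances by distances
#' from each reference node to the nearest test-mesh vertex; this variant
#' is not symmetric in its arguments and is offered for comparison only.
#'
#' @param ref,test `fitted_surface` objects on equal template grids.
#' @param labels an [assign_aha_segments()] map computed on `ref`; default
#'   computes it from `ref`.
#' @param method `"corresponding"` (default) or `"nearest"`.
#' @return A data.frame of class `regional_msd_report` with columns
#'   `segment`, `segment_name`, `msd` (mm), `n_points`, and attributes
#'   `surface_tag` and `phase`.
#' @export
mean_surface_distance <- function(ref, test, labels = assign_aha_segments(ref),
                                  method = c("corresponding", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(ref, "fitted_surface"), inherits(test, "fitted_surface"))
  if (ref$template$n_u != test$template$n_u ||
      ref$template$n_v != test$template$n_v)
    stop("correspondence error: template grids differ between surfaces")
  stopifnot(inherits(labels, "aha_label_map"))
  M <- ref$mesh$vertices
  E <- test$mesh$vertices
  if (method == "corresponding") {
    d <- sqrt(rowSums((M - E)^2))
  } else {
    d <- sqrt(rowSums((M - E[nn_index(M, E), , drop = FALSE])^2))
  }
  keep <- !labels$mask
  seg <- labels$labels[keep]
  d <- d[keep]
  agg <- vapply(split(d, seg), mean, numeric(1))
  n <- vapply(split(d, seg), length, integer(1))
  out <- data.frame(segment = as.integer(names(agg)),
                    segment_name = aha_segment_names()[as.integer(names(agg))],
                    msd = unname(agg), n_points = unname(n))
  out <- out[order(out$segment), ]
  rownames(out) <- NULL
  attr(out, "surface_tag") <- ref$surface_tag
  attr(out, "phase") <- ref$phase
  attr(out, "method") <- method
  class(out) <- c("regional_msd_report", "data.frame")
  out
}
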