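# Outline morphometrics for membrane rings.
#
# All quantities are computed from the membrane beads taken in ring order
# (recovered by walking the membrane bonds, so bead numbering is irrelevant)
# and are invariant under rigid motions of the cell.

# membrane bead ids in ring order; errors if the ring is broken
membrane_ring <- function(state) {
  members <- which(state$roles == "membrane")
  if (length(members) < 3L)
    stop("geometry error: fewer than 3 membrane beads", call. = FALSE)
  bsub <- state$bonds[state$bonds$kind == "membrane", , drop = FALSE]
  path <- walk_ring(bsub, members)
  if (is.null(path))
    stop("geometry error: membrane bonds do not form a closed ring",
         call. = FALSE)
  path
}

# radial profile of the membrane: distances from the membrane centroid, in
# ring order, plus the robust baseline radius (median)
radial_profile <- function(state) {
  ring <- membrane_ring(state)
  pos <- state$positions[ring, , drop = FALSE]
  centroid <- colMeans(pos)
  r <- sqrt((pos[, 1] - centroid[1])^2 + (pos[, 2] - centroid[2])^2)
  list(ring = ring, pos = pos, r = r, r_base = median(r))
}

#' Projection length of the membrane outline
#'
#' The maximal radial excursion of any membrane bead beyond the baseline
#' radius: `max_i(|r_i - centroid|) - R_base`, floored at zero, where
#' `R_base` is the *median* membrane-bead distance from the membrane
#' centroid.  The median baseline is robust: a single long neurite does not
#' inflate its own baseline.  This is the package's operationalization of
#' "neurite projection length" for simulated outlines.
#'
#' @param state a `cell_state` with a valid membrane ring.
#' @return Non-negative length (same units as positions).
#' @export
projection_length <- function(state) {
  prof <- radial_profile(state)
  max(0, max(prof$r) - prof$r_base)
}

#' Count membrane protrusions
#'
#' A protrusion is a maximal contiguous arc of membrane beads (in ring
#' order) whose radial excess over the baseline radius exceeds `threshold`.
#' Arcs spanning the index seam are counted once (circular wrap-around).
#'
#' @param state a `cell_state`.
#' @param threshold radial-excess threshold (> 0); defaults to half the
#'   baseline radius.
#' @return Integer protrusion count.
#' @export
count_protrusions <- function(state, threshold = NULL) {
  prof <- radial_profile(state)
  if (is.null(threshold)) threshold <- 0.5 * prof$r_base
  if (threshold <= 0) stop("argument error: threshold must be > 0",
                           call. = FALSE)
  above <- prof$r - prof$r_base > threshold
  n <- length(above)
  if (!any(above)) return(0L)
  if (all(above)) return(1L)
  starts <- sum(above & !above[c(n, 1:(n - 1L))])
  as.integer(starts)
}

#' Circularity of the membrane outline
#'
#' `4 * pi * Area / Perimeter^2` of the membrane polygon (shoelace area
#' magnitude).  Equals `(pi/N) / tan(pi/N)` for a regular N-gon (-> 1 as
#' N grows) and decreases as protrusions form.  If the polygon
#' self-intersects a warning is issued and the value is still returned from
#' the absolute shoelace area.
#'
#' @param state a `cell_state`.
#' @param check_simple check for self-intersection (O(N^2); default TRUE).
#' @return Circularity in (0, 1].
#' @export
circularity <- function(state, check_simple = TRUE) {
  prof <- radial_profile(state)
  p <- prof$pos
  n <- nrow(p)
  nx <- p[c(2:n, 1L), ]
  area <- abs(sum(p[, 1] * nx[, 2] - nx[, 1] * p[, 2])) / 2
  perim <- sum(sqrt(rowSums((nx - p)^2)))
  if (check_simple && polygon_self_intersects(p))
    warning("geometry warning: membrane polygon self-intersects; ",
            "circularity computed from the absolute shoelace area")
  4 * pi * area / perim^2
}

# segment-pair self-intersection test for a closed polygon (excluding shared
# endpoints between adjacent edges)
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a1 <- p
  a2 <- p[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n shares vertex 1 with edge 1
    if (length(js) == 0L) next
    d1 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a1[js, 1], a1[js, 2])
    d2 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a2[js, 1], a2[js, 2])
    d3 <- cross2(a1[js, 1], a1[js, 2], a2[js, 1], a2[js, 2],
                 rep(a1[i, 1], length(js)), rep(a1[i, 2], length(js)))
    d4 <- cross2(a1[js, 1], a1[js, 2], a2[js, 1], a2[js, 2],
                 rep(a2[i, 1], length(js)), rep(a2[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Protrusion stability over the late trajectory
#'
#' The fraction of frames in the final `window` frames that carry at least
#' one protrusion (per [count_protrusions()]) *and* a projection length of
#' at least `threshold`.  High values mean a persistent neurite-like
#' protrusion; low values mean transient blebs or none.
#'
#' @param trajectory a `trajectory`.
#' @param threshold radial-excess threshold (length units).
#' @param window number of final frames to consider (<= frame count).
#' @return Fraction in \[0, 1\].
#' @export
protrusion_stability <- function(trajectory, threshold, window) {
  n <- length(trajectory$snapshots)
  if (window > n || window < 1L)
    stop("argument error: window must be in [1, number of frames]",
         call. = FALSE)
  frames <- trajectory$snapshots[(n - window + 1L):n]
  ok <- vapply(frames, function(st) {
    count_protrusions(st, threshold) >= 1L &&
      projection_length(st) >= threshold
  }, logical(1))
  mean(ok)
}

#' Morphometric analysis of a trajectory
#'
#' Applies the per-frame morphometrics to every snapshot and summarizes:
#' per-frame projection length, protrusion count and circularity; the
#' maximum projection length over frames; and the protrusion stability over
#' the final window.
#'
#' @param trajectory a `trajectory`.
#' @param threshold protrusion threshold; `NULL` uses half the baseline
#'   radius of the first frame.
#' @param window stability window (frames); `NULL` uses the final 25% of
#'   frames (at least 1).
#' @return An object of class `morphometrics_result`: list with `per_frame`
#'   (data frame `time`, `projection_length`, `protrusion_count`,
#'   `circularity`), `max_projection_length`, `stability`, `threshold`,
#'   `window`.
#' @export
analyze_trajectory <- function(trajectory, threshold = NULL, window = NULL) {
  n <- length(trajectory$snapshots)
  if (n == 0L) stop("argument error: trajectory has no frames", call. = FALSE)
  if (is.null(threshold))
    threshold <- 0.5 * radial_profile(trajectory$snapshots[[1]])$r_base
  if (is.null(window)) window <- max(1L, floor(0.25 * n))
  per <- data.frame(
    time = trajectory$times,
    projection_length = vapply(trajectory$snapshots, projection_length,
                               numeric(1)),
    protrusion_count = vapply(trajectory$snapshots, function(s)
      count_protrusions(s, threshold), integer(1)),
    circularity = vapply(trajectory$snapshots, function(s)
      circularity(s, check_simple = FALSE), numeric(1))
  )
  out <- list(per_frame = per,
              max_projection_length = max(per$projection_length),
              stability = protrusion_stability(trajectory, threshold, window),
              threshold = threshold, window = as.integer(window))
  class(out) <- "morphometrics_result"
  out
}

#' @export
print.morphometrics_result <- function(x, ...) {
  cat(sprintf("morphometrics over %d frames:\n", nrow(x$per_frame)))
  cat(sprintf("  max projection length: %.3f\n", x$max_projection_length))
  cat(sprintf("  stability (last %d frames, threshold %.3g): %.2f\n",
              x$window, x$threshold, x$stability))
  cat(sprintf("  final: %d protrusion(s), circularity %.3f\n",
              x$per_frame$protrusion_count[nrow(x$per_frame)],
              x$per_frame$circularity[nrow(x$per_frame)]))
  invisible(x)
}

#' Export per-frame morphometrics as a delimited table
#'
#' @param result a `morphometrics_result`.
#' @param path output path for a tab-separated table (one row per frame).
#' @return `path`, invisibly.
#' @export
write_morphometrics <- function(result, path) {
  write.table(result$per_frame, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
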