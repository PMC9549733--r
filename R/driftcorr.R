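#' Pairwise cosine similarity of fiducial track motion
#'
#' For every pair of fiducial tracks, each track's displacement series over
#' the common frame range is flattened into one long vector and compared by
#' cosine similarity. Displacements are start-anchored
#' (`position[t] - position[first frame]`), never absolute positions:
#' absolute positions would make the similarity depend on where a fiducial
#' sits in the construct, while shared motion shows up as parallel anchored
#' series. Anchoring also accumulates a slow shared drift across frames, so
#' correlated fiducials stay above a high threshold even when the per-frame
#' drift step is comparable to the localisation jitter; a per-step variant
#' (`on = "steps"`) is available for fast, jerky drift. Tracks with small
#' frame gaps are linearly interpolated first; a stationary fiducial
#' (zero-norm series) has undefined similarity and its pairs are `NA`, with
#' the offending ids flagged in the `flagged` attribute.
#'
#' @param fiducials A [trackset()] of >= 2 fiducial tracks sharing a common
#'   frame range of >= 3 frames.
#' @param max_gap Largest frame gap bridged by interpolation.
#' @param on `"anchored"` (default) compares start-anchored displacement
#'   series; `"steps"` compares per-frame step vectors.
#' @return Symmetric similarity matrix with unit diagonal, dimnames the
#'   fiducial ids.
#' @export
pairwise_track_similarity <- function(fiducials, max_gap = 2L,
                                      on = c("anchored", "steps")) {
  on <- match.arg(on)
  if (length(fiducials) < 2L) stop("need at least 2 fiducial tracks")
  reg <- lapply(fiducials$tracks, regularize_track, max_gap = max_gap)
  bad <- vapply(reg, is.null, logical(1))
  if (any(bad))
    stop("fiducial track(s) with gaps > max_gap: ",
         paste(names(fiducials$tracks)[bad], collapse = ", "))
  common <- Reduce(intersect, lapply(reg, function(t) t$frames))
  if (length(common) < 3L)
    stop("fiducials share fewer than 3 common frames")
  common <- sort(common)
  stepvecs <- lapply(reg, function(t) {
    pos <- t$positions[match(common, t$frames), , drop = FALSE]
    if (on == "anchored") {
      as.vector(sweep(pos, 2L, pos[1L, ])[-1L, , drop = FALSE])
    } else {
      as.vector(diff(pos))
    }
  })
  norms <- vapply(stepvecs, function(v) sqrt(sum(v^2)), numeric(1))
  n <- length(stepvecs)
  sim <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sim[i, j] <- sim[j, i] <-
        if (norms[i] == 0 || norms[j] == 0) NA_real_
        else sum(stepvecs[[i]] * stepvecs[[j]]) / (norms[i] * norms[j])
    }
  }
  ids <- names(fiducials$tracks)
  dimnames(sim) <- list(ids, ids)
  attr(sim, "common_frames") <- common
  attr(sim, "flagged") <- ids[norms == 0]
  sim
}

#' Estimate rigid drift from correlated fiducial tracks
#'
#' Fiducials are connected by an edge when their motion cosine similarity is
#' at least `threshold`; the correlated set is the largest connected
#' component with at least 2 members (ties broken by higher mean internal
#' similarity). The drift path at each frame is the mean over members of
#' their start-anchored displacement `position[t] - position[0]` —
#' start-anchoring means spatially dispersed fiducials do not bias the path.
#'
#' @param fiducials A [trackset()] of fiducial tracks.
#' @param threshold Cosine similarity threshold, default 0.95.
#' @param max_gap Largest frame gap bridged by interpolation.
#' @param on Similarity variant, see [pairwise_track_similarity()].
#' @return An object of class `"drift_estimate"`: list with `member_ids`,
#'   `similarity` (full matrix), `threshold`, `frames` (common frame range)
#'   and `drift_path` (frames x dim, first row zero).
#' @export
estimate_drift <- function(fiducials, threshold = 0.95, max_gap = 2L,
                           on = c("anchored", "steps")) {
  sim <- pairwise_track_similarity(fiducials, max_gap, on = on)
  ids <- rownames(sim)
  adj <- !is.na(sim) & sim >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  if (max(sizes) < 2L)
    stop("no correlated fiducial set at threshold ", threshold)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    mean_sim <- vapply(cand, function(ci) {
      m <- sim[comp$membership == ci, comp$membership == ci, drop = FALSE]
      mean(m[upper.tri(m)], na.rm = TRUE)
    }, numeric(1))
    cand <- cand[which.max(mean_sim)]
  }
  members <- ids[comp$membership == cand[1L]]
  common <- attr(sim, "common_frames")
  reg <- lapply(fiducials$tracks[members], regularize_track,
                max_gap = max_gap)
  anchored <- lapply(reg, function(t) {
    pos <- t$positions[match(common, t$frames), , drop = FALSE]
    sweep(pos, 2L, pos[1L, ])
  })
  drift <- Reduce(`+`, anchored) / length(anchored)
  structure(list(member_ids = members, similarity = sim,
                 threshold = threshold, frames = common,
                 drift_path = drift),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  span <- sqrt(max(rowSums(x$drift_path^2)))
  cat(sprintf(
    "<drift_estimate> %d/%d fiducials correlated at %.2f; %d frames, max drift %.2f um\n",
    length(x$member_ids), nrow(x$similarity), x$threshold,
    length(x$frames), span))
  invisible(x)
}

#' Subtract the estimated drift from cell trajectories
#'
#' Every cell position at frame `t` is shifted by minus the drift path at
#' `t`. All cell frames must lie inside the drift estimate's frame range.
#'
#' @param cells A [trackset()] of cell tracks.
#' @param d A [estimate_drift()] result (or any list with `frames` and
#'   `drift_path`).
#' @return A corrected [trackset()]; the applied drift estimate is attached
#'   as the `drift_applied` attribute.
#' @export
apply_drift_correction <- function(cells, d) {
  tracks <- cells$tracks
  for (i in seq_along(tracks)) {
    t <- tracks[[i]]
    idx <- match(t$frames, d$frames)
    if (anyNA(idx))
      stop("track '", t$track_id, "' has frames outside the drift range")
    t$positions <- t$positions - d$drift_path[idx, , drop = FALSE]
    tracks[[i]] <- t
  }
  out <- trackset(tracks, cells$field_bounds)
  attr(out, "drift_applied") <- list(member_ids = d$member_ids,
                                     threshold = d$threshold)
  out
}
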