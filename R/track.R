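#' Construct a single-cell track
#'
#' A track is one cell's time-ordered sequence of positions, in micrometres,
#' sampled at (possibly gapped) integer frame indices. Tracks are the atomic
#' unit of all downstream motility analysis.
#'
#' @param track_id Character scalar identifying the cell.
#' @param frames Integer vector of frame indices, strictly increasing,
#'   0-based by convention.
#' @param positions Numeric matrix with one row per frame and 2 or 3 columns
#'   (x, y\[, z\] in micrometres).
#' @param frame_interval Minutes per frame.
#' @param condition Character scalar condition label (e.g. `"untreated"`).
#'
#' @return An object of class `"track"`: a list with elements `track_id`,
#'   `condition`, `frame_interval`, `frames` and `positions`.
#' @examples
#' tr <- track("cell-1", 0:4, cbind(x = 0:4, y = 0), frame_interval = 10)
#' track_length(tr)
#' @export
track <- function(track_id, frames, positions, frame_interval,
                  condition = "unspecified") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  frames <- as.integer(frames)
  if (length(frames) < 2L)
    stop("a track needs at least 2 points, got ", length(frames))
  if (nrow(positions) != length(frames))
    stop("positions (", nrow(positions), " rows) and frames (",
         length(frames), ") differ in length")
  if (!ncol(positions) %in% c(2L, 3L))
    stop("positions must have 2 or 3 columns, got ", ncol(positions))
  if (any(diff(frames) <= 0L))
    stop("frames must be strictly increasing for track '", track_id, "'")
  if (!all(is.finite(positions)))
    stop("non-finite coordinate in track '", track_id, "'")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("frame_interval must be a positive scalar (minutes per frame)")
  dimnames(positions) <- NULL
  structure(
    list(track_id = as.character(track_id),
         condition = as.character(condition),
         frame_interval = as.numeric(frame_interval),
         frames = frames,
         positions = positions),
    class = "track"
  )
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s'> %d points, %dD, %.3g min/frame, condition '%s'\n",
              x$track_id, track_length(x), track_dim(x), x$frame_interval,
              x$condition))
  invisible(x)
}

#' Number of observed points in a track
#' @param t A `track`.
#' @return Integer count of observed (frame, position) pairs.
#' @export
track_length <- function(t) length(t$frames)

#' Spatial dimensionality of a track (2 or 3)
#' @param t A `track`.
#' @export
track_dim <- function(t) ncol(t$positions)

#' True when a track has no skipped frames
#' @param t A `track`.
#' @export
is_gap_free <- function(t) all(diff(t$frames) == 1L)

#' Construct a set of dimension-consistent tracks
#'
#' A `trackset` bundles tracks that share acquisition constants: frame
#' interval and spatial dimensionality, optionally with the axis-aligned
#' field-of-view bounds used by the in-field filter.
#'
#' @param tracks List of `track` objects.
#' @param field_bounds Optional numeric matrix `rbind(lower, upper)` with one
#'   column per axis, in micrometres.
#' @return An object of class `"trackset"`.
#' @examples
#' a <- track("a", 0:2, cbind(0:2, 0), 10)
#' b <- track("b", 0:2, cbind(0, 0:2), 10)
#' ts <- trackset(list(a, b))
#' length(ts)
#' @export
trackset <- function(tracks, field_bounds = NULL) {
  if (!is.list(tracks))
    stop("tracks must be a list of track objects")
  if (length(tracks)) {
    ok <- vapply(tracks, inherits, logical(1), what = "track")
    if (!all(ok)) stop("all elements must be track objects")
    dims <- vapply(tracks, track_dim, integer(1))
    if (length(unique(dims)) > 1L)
      stop("tracks mix dimensionalities: ", paste(unique(dims), collapse = ", "))
    ivals <- vapply(tracks, function(t) t$frame_interval, numeric(1))
    if (diff(range(ivals)) > 1e-9)
      stop("tracks mix frame intervals")
    names(tracks) <- vapply(tracks, function(t) t$track_id, character(1))
    if (anyDuplicated(names(tracks)))
      stop("duplicate track_id in trackset")
  }
  if (!is.null(field_bounds)) {
    field_bounds <- as.matrix(field_bounds)
    if (nrow(field_bounds) != 2L)
      stop("field_bounds must be rbind(lower, upper)")
    if (length(tracks) && ncol(field_bounds) != track_dim(tracks[[1L]]))
      stop("field_bounds dimensionality does not match tracks")
  }
  structure(list(tracks = tracks, field_bounds = field_bounds),
            class = "trackset")
}

#' @export
length.trackset <- function(x) length(x$tracks)

#' @export
`[.trackset` <- function(x, i) trackset(x$tracks[i], x$field_bounds)

#' @export
print.trackset <- function(x, ...) {
  if (!length(x)) {
    cat("<trackset> empty\n")
    return(invisible(x))
  }
  lens <- vapply(x$tracks, track_length, integer(1))
  cat(sprintf("<trackset> %d tracks, %dD, %.3g min/frame, lengths %d-%d\n",
              length(x), trackset_dim(x), trackset_interval(x),
              min(lens), max(lens)))
  invisible(x)
}

#' @rdname track_dim
#' @param ts A `trackset`.
#' @export
trackset_dim <- function(ts) {
  if (!length(ts)) stop("empty trackset has no dimensionality")
  track_dim(ts$tracks[[1L]])
}

#' Shared frame interval of a trackset, in minutes
#' @param ts A `trackset`.
#' @export
trackset_interval <- function(ts) {
  if (!length(ts)) stop("empty trackset has no frame interval")
  ts$tracks[[1L]]$frame_interval
}

#' Step vectors and step speeds of a track
#'
#' Displacement vectors between consecutive observed points and the
#' corresponding speeds. Speeds are time-normalised: a step spanning a frame
#' gap of `g` frames is divided by `g * frame_interval` minutes, so gapped
#' steps are not inflated.
#'
#' @param t A `track` of length >= 2.
#' @return A list with `vectors` (an (n-1) x d matrix of step displacements,
#'   micrometres), `lengths` (step magnitudes, micrometres), `speeds`
#'   (micrometres/minute) and `dframes` (frame gap of each step).
#' @examples
#' tr <- track("a", c(0L, 2L), rbind(c(0, 0), c(4, 0)), frame_interval = 10)
#' track_steps(tr)$speeds  # 4 um over 20 min = 0.2 um/min
#' @export
track_steps <- function(t) {
  n <- track_length(t)
  if (n < 2L) stop("track_steps needs length >= 2")
  vec <- t$positions[-1L, , drop = FALSE] - t$positions[-n, , drop = FALSE]
  len <- sqrt(rowSums(vec^2))
  dfr <- diff(t$frames)
  list(vectors = vec, lengths = len,
       speeds = len / (dfr * t$frame_interval), dframes = dfr)
}

#' Fill small frame gaps by linear interpolation
#'
#' Lag-based statistics (MSD, Hurst, displacement autocorrelation, the
#' non-Gaussian parameter) require evenly sampled tracks. Tracks whose gaps
#' are all `<= max_gap` frames are resampled onto the full frame grid by
#' per-axis linear interpolation; tracks with any larger gap are rejected.
#'
#' @param t A `track`.
#' @param max_gap Largest frame gap (in skipped-frame count, a gap of 1 means
#'   consecutive frames) that will be bridged. Default 2.
#' @return A gap-free `track`, or `NULL` when the track has a gap larger
#'   than `max_gap` (with the reason in `attr(, "reason")` of the `NULL`
#'   surrogate returned via `regularize_track`'s contract: callers treat
#'   `NULL` as "excluded").
#' @export
regularize_track <- function(t, max_gap = 2L) {
  d <- diff(t$frames)
  if (all(d == 1L)) return(t)
  if (any(d > max_gap)) return(NULL)
  full <- seq(t$frames[1L], t$frames[track_length(t)])
  pos <- apply(t$positions, 2L, function(p)
    stats::approx(t$frames, p, xout = full)$y)
  track(t$track_id, full, pos, t$frame_interval, t$condition)
}
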