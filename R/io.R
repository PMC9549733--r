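#' Read a tracking table into a trackset
#'
#' Reads per-cell tracking tables exported as delimited text (comma or tab,
#' auto-detected from the header line). Two column dialects are supported:
#'
#' * `generic`: `track_id, frame, x, y[, z]`
#' * `trackmate`: `TRACK_ID, FRAME, POSITION_X, POSITION_Y[, POSITION_Z]`
#'   (the TrackMate "spots" CSV export; extra columns are ignored)
#'
#' Rows are grouped by track id and sorted by frame. Single-point tracks are
#' dropped (tracking exports routinely contain them) with a message giving
#' the count; duplicated (id, frame) pairs are an error.
#'
#' @param path Path to the delimited text file. Lines starting with `#` are
#'   treated as comments.
#' @param dialect `"generic"` or `"trackmate"`.
#' @param frame_interval Minutes per frame.
#' @param condition Condition label applied to every track in the file.
#' @param field_bounds Optional `rbind(lower, upper)` field-of-view bounds.
#' @return A [trackset()].
#' @seealso [write_tracks_table()], [filter_tracks()]
#' @export
read_tracks_table <- function(path, dialect = c("generic", "trackmate"),
                              frame_interval, condition = "unspecified",
                              field_bounds = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  cols <- switch(dialect,
    generic   = c(id = "track_id", frame = "frame", x = "x", y = "y", z = "z"),
    trackmate = c(id = "TRACK_ID", frame = "FRAME", x = "POSITION_X",
                  y = "POSITION_Y", z = "POSITION_Z"))
  required <- cols[c("id", "frame", "x", "y")]
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  has_z <- cols[["z"]] %in% names(df)
  axes <- if (has_z) cols[c("x", "y", "z")] else cols[c("x", "y")]
  for (ax in axes) {
    v <- df[[ax]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v))
        stop("non-numeric coordinate in column '", ax, "'")
      df[[ax]] <- vn
    }
    if (anyNA(df[[ax]]) || any(!is.finite(df[[ax]])))
      stop("non-finite or missing coordinate in column '", ax, "'")
  }
  ids <- as.character(df[[cols[["id"]]]])
  frames <- df[[cols[["frame"]]]]
  if (anyDuplicated(paste(ids, frames, sep = "\r"))) {
    dup <- ids[duplicated(paste(ids, frames, sep = "\r"))][1L]
    stop("duplicate (track_id, frame) rows for track '", dup, "'")
  }
  split_idx <- split(seq_len(nrow(df)), factor(ids, levels = unique(ids)))
  dropped <- 0L
  tracks <- list()
  for (id in names(split_idx)) {
    rows <- split_idx[[id]]
    if (length(rows) < 2L) {
      dropped <- dropped + 1L
      next
    }
    ord <- rows[order(frames[rows])]
    tracks[[id]] <- track(id, frames[ord],
                          as.matrix(df[ord, axes, drop = FALSE]),
                          frame_interval, condition)
  }
  if (dropped > 0L)
    message("dropped ", dropped, " single-point track(s)")
  ts <- trackset(tracks, field_bounds)
  attr(ts, "n_dropped_single_point") <- dropped
  ts
}

detect_sep <- function(path) {
  for (ln in readLines(path, n = 50L, warn = FALSE)) {
    if (!startsWith(ln, "#") && nzchar(ln))
      return(if (grepl("\t", ln, fixed = TRUE)) "\t" else ",")
  }
  ","
}

#' Write a trackset as a generic-dialect delimited table
#'
#' Writes the `track_id, frame, x, y[, z], condition` table with a `#`
#' provenance header (package version and, when supplied, a configuration
#' hash). Coordinates are printed with full double precision so a
#' read/write/read round trip is value-identical.
#'
#' @param ts A [trackset()].
#' @param path Output file path.
#' @param sep Field separator, default tab.
#' @param config_hash Optional hash string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tracks_table <- function(ts, path, sep = "\t", config_hash = NULL) {
  df <- tracks_as_table(ts)
  write_output_table(df, path, sep = sep, config_hash = config_hash)
}

#' Flatten a trackset to a long data frame
#' @param ts A [trackset()].
#' @return Data frame with columns `track_id, frame, x, y[, z], condition`.
#' @export
tracks_as_table <- function(ts) {
  if (!length(ts)) {
    return(data.frame(track_id = character(), frame = integer(),
                      x = numeric(), y = numeric(), condition = character()))
  }
  axes <- c("x", "y", "z")[seq_len(trackset_dim(ts))]
  do.call(rbind, lapply(ts$tracks, function(t) {
    pos <- as.data.frame(t$positions)
    names(pos) <- axes
    cbind(data.frame(track_id = t$track_id, frame = t$frames,
                     row.names = NULL),
          pos, condition = t$condition)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Apply the track-level inclusion filters
#'
#' Keeps tracks with at least `min_length` observed frames (the default of 61
#' encodes the "length greater than 60 frames" inclusion rule used for the
#' 10-minute-interval motility assays) and, optionally, drops any track that
#' ever leaves the field of view.
#'
#' @param ts A [trackset()].
#' @param min_length Minimum observed points per track; must be >= 2.
#' @param require_in_field When `TRUE`, drop tracks with any position outside
#'   `ts$field_bounds` (which must then be set).
#' @return A filtered [trackset()]; track order is preserved. The counts of
#'   tracks removed by each rule are attached as attributes
#'   `n_dropped_short` and `n_dropped_out_of_field`.
#' @export
filter_tracks <- function(ts, min_length = 61L, require_in_field = FALSE) {
  if (min_length < 2L) stop("min_length must be >= 2")
  if (require_in_field && is.null(ts$field_bounds))
    stop("require_in_field = TRUE but trackset has no field_bounds")
  keep_len <- vapply(ts$tracks, function(t) track_length(t) >= min_length,
                     logical(1))
  keep_field <- rep(TRUE, length(ts))
  if (require_in_field && length(ts)) {
    lo <- ts$field_bounds[1L, ]
    hi <- ts$field_bounds[2L, ]
    keep_field <- vapply(ts$tracks, function(t) {
      all(sweep(t$positions, 2L, lo, `>=`)) &&
        all(sweep(t$positions, 2L, hi, `<=`))
    }, logical(1))
  }
  out <- trackset(ts$tracks[keep_len & keep_field], ts$field_bounds)
  attr(out, "n_dropped_short") <- sum(!keep_len)
  attr(out, "n_dropped_out_of_field") <- sum(keep_len & !keep_field)
  out
}

#' Write a data frame as delimited text with a provenance header
#'
#' All pipeline outputs go through this writer: a `#`-prefixed header line
#' records the package version and the run configuration hash so any table
#' can be traced back to the exact run that produced it.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param sep Field separator.
#' @param config_hash Optional configuration hash string.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(df, path, sep = "\t", config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("cellmotility"))
  hash <- if (is.null(config_hash)) "none" else config_hash
  writeLines(sprintf("# cellmotility %s  config_hash=%s", ver, hash), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
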