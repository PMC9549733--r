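#' Tunable parameters of the motility feature battery
#'
#' The source tracking literature defines these features only up to one-line
#' glosses, so every window, lag and threshold is explicit here.
#'
#' @param msd_lag_max Largest lag (frames) of the MSD log-log fit; `NULL`
#'   means `min(20, floor(L/4))` per track.
#' @param rw_n_sim Number of simulated random walks behind the random-walk
#'   baseline deltas.
#' @param rw_seed Integer seed of those simulations.
#' @param move_thresholds Speed thresholds (um/min) for the movement
#'   occupancy features.
#' @param subtrack_len Sub-track length (frames) for movement occupancy and
#'   the random-walk kurtosis delta.
#' @param autocorr_lags Frame lags of the displacement autocorrelation.
#' @param hurst_min_window Smallest window (frames) of the rescaled-range
#'   Hurst fit.
#' @param max_gap Largest frame gap bridged by linear interpolation before
#'   lag-based statistics; larger gaps exclude the track from those features.
#' @return An object of class `"feature_params"`.
#' @export
feature_params <- function(msd_lag_max = NULL, rw_n_sim = 100L,
                           rw_seed = 99L, move_thresholds = c(0.5, 1, 2, 5),
                           subtrack_len = 20L, autocorr_lags = c(1L, 2L, 5L),
                           hurst_min_window = 8L, max_gap = 2L) {
  stopifnot(rw_n_sim >= 1, subtrack_len >= 2, hurst_min_window >= 2,
            all(move_thresholds >= 0), all(autocorr_lags >= 1))
  structure(list(msd_lag_max = msd_lag_max, rw_n_sim = as.integer(rw_n_sim),
                 rw_seed = as.integer(rw_seed),
                 move_thresholds = move_thresholds,
                 subtrack_len = as.integer(subtrack_len),
                 autocorr_lags = as.integer(autocorr_lags),
                 hurst_min_window = as.integer(hurst_min_window),
                 max_gap = as.integer(max_gap)),
            class = "feature_params")
}

#' Path and speed metrics of a track
#'
#' `total_distance` is the summed step length, `net_distance` the straight
#' line from first to last position, and `progressivity` their ratio (1 for
#' perfectly directed motion, 0 for a closed path; defined as 0 for a track
#' that never moves). Speeds are per-step, time-normalised.
#'
#' @param t A `track` of length >= 2.
#' @return Named list: `total_distance`, `net_distance`, `progressivity`
#'   (um, um, unitless), `max_speed`, `min_speed`, `avg_speed` (um/min).
#' @export
path_metrics <- function(t) {
  st <- track_steps(t)
  total <- sum(st$lengths)
  net <- sqrt(sum((t$positions[track_length(t), ] - t$positions[1L, ])^2))
  list(total_distance = total, net_distance = net,
       progressivity = if (total > 0) net / total else 0,
       max_speed = max(st$speeds), min_speed = min(st$speeds),
       avg_speed = mean(st$speeds))
}

#' Linearity and monotonicity of a track's coordinates
#'
#' `linearity` is the squared Pearson correlation of the x and y coordinate
#' series and `spearmanrsq` the squared Spearman rank correlation (average
#' ranks on ties). The squared-correlation form is symmetric in x and y, so
#' vertical tracks are not a singular case. When either coordinate is
#' constant the track is exactly axis-aligned and both metrics are defined
#' as 1. For 3D tracks the two largest-variance axes are used.
#'
#' @param t A `track` of length >= 3.
#' @return Named list with `linearity` and `spearmanrsq`, both in \[0, 1\].
#' @export
linearity_metrics <- function(t) {
  if (track_length(t) < 3L) stop("linearity_metrics needs length >= 3")
  pos <- t$positions
  if (ncol(pos) > 2L) {
    vars <- apply(pos, 2L, stats::var)
    pos <- pos[, order(vars, decreasing = TRUE)[1:2], drop = FALSE]
  }
  x <- pos[, 1L]
  y <- pos[, 2L]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(linearity = 1, spearmanrsq = 1))
  list(linearity = stats::cor(x, y)^2,
       spearmanrsq = stats::cor(x, y, method = "spearman")^2)
}

#' Time-averaged mean-squared displacement and its power-law slope
#'
#' `MSD(tau)` averages squared displacements over all origin pairs `tau`
#' frames apart; `msd_slope` is the least-squares slope of `log MSD` against
#' `log tau` over lags `1..lag_max`. Slope 1 indicates diffusive, 2
#' ballistic motion. A stationary track (any fitted-lag MSD equal to 0)
#' yields `NA` with the reason attached, never an error.
#'
#' @param t A gap-free `track`.
#' @param lag_max Largest fitted lag in frames; default `min(20,
#'   floor(L/4))`, and never more than `floor(L/4)`.
#' @return List with `lags` (frames), `msd` (um^2) and `msd_slope`
#'   (`NA_real_` when undefined).
#' @export
msd_profile <- function(t, lag_max = NULL) {
  if (!is_gap_free(t)) stop("msd_profile needs a gap-free track")
  L <- track_length(t)
  cap <- max(L %/% 4L, 1L)
  lag_max <- if (is.null(lag_max)) min(20L, cap) else min(lag_max, cap)
  lags <- seq_len(lag_max)
  msd <- vapply(lags, function(tau) {
    dd <- t$positions[(1L + tau):L, , drop = FALSE] -
      t$positions[1L:(L - tau), , drop = FALSE]
    mean(rowSums(dd^2))
  }, numeric(1))
  slope <- NA_real_
  if (all(msd > 0)) {
    slope <- unname(stats::coef(stats::lm(log(msd) ~ log(lags)))[2L])
  }
  out <- list(lags = lags, msd = msd, msd_slope = slope)
  if (is.na(slope)) attr(out, "reason") <- "zero MSD at a fitted lag"
  out
}

# Expected range of a w-step standard Gaussian random walk (Spitzer's
# identity: E[max] = sum_{k<=w} E[S_k^+]/k = sum (2 pi k)^{-1/2}).
expected_walk_range <- function(w) sqrt(2 / pi) * sum(1 / sqrt(seq_len(w)))

rescaled_range <- function(x) {
  s <- sqrt(mean(x^2))
  if (s == 0) return(NA_real_)
  cs <- c(0, cumsum(x))
  (max(cs) - min(cs)) / s
}

#' Rescaled-range Hurst exponent of a track
#'
#' A directional-persistence index: 0.5 for memoryless (Brownian) motion,
#' near 1 for persistent/directed motion, below 0.5 for anti-persistent
#' motion. Per axis, the per-frame increment series is split into
#' non-overlapping windows of dyadic sizes from `min_window` up to half the
#' series length; each window contributes its cumulative range divided by
#' its root-mean-square increment. The Hurst exponent is 0.5 plus the
#' log-log slope of the window-averaged statistic relative to its white
#' noise expectation (from Spitzer's identity), which removes the strong
#' small-window bias of the raw statistic. Per-axis estimates are averaged
#' and clipped to \[0, 1\].
#'
#' The cumulative range is deliberately not mean-adjusted: subtracting each
#' window's mean increment would erase the drift that makes directed motion
#' persistent, and this feature is used as a persistence readout.
#'
#' @param t A gap-free `track` of length >= 16.
#' @param min_window Smallest window size in frames (default 8).
#' @return Hurst estimate in \[0, 1\], or `NA_real_` for zero-variance
#'   increments.
#' @export
hurst_rs <- function(t, min_window = 8L) {
  if (!is_gap_free(t)) stop("hurst_rs needs a gap-free track")
  if (track_length(t) < 16L) stop("hurst_rs needs length >= 16")
  inc <- diff(t$positions)
  h <- apply(inc, 2L, hurst_axis, min_window = min_window)
  if (all(is.na(h))) return(NA_real_)
  min(max(mean(h, na.rm = TRUE), 0), 1)
}

hurst_axis <- function(x, min_window) {
  n <- length(x)
  ws <- integer(0)
  w <- as.integer(min_window)
  while (w <= n %/% 2L) {
    ws <- c(ws, w)
    w <- w * 2L
  }
  if (length(ws) < 2L) return(NA_real_)
  rs <- vapply(ws, function(w) {
    k <- n %/% w
    vals <- vapply(seq_len(k), function(j)
      rescaled_range(x[((j - 1L) * w + 1L):(j * w)]), numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (any(!is.finite(rs)) || any(rs <= 0)) return(NA_real_)
  expect <- vapply(ws, expected_walk_range, numeric(1))
  0.5 + unname(stats::coef(
    stats::lm(log(rs / expect) ~ log(ws)))[2L])
}

#' Non-Gaussian parameter of the displacement distribution
#'
#' The kurtosis-based parameter `alpha_2 = <dx^4> / (3 <dx^2>^2) - 1`,
#' computed per axis on lag-`lag` displacements and averaged over axes. It
#' is 0 for Gaussian displacements, negative for lighter tails (e.g. -2/3
#' for fixed-magnitude steps) and positive for heavy tails.
#'
#' @param t A gap-free `track` with at least 8 displacements at the lag.
#' @param lag Displacement lag in frames, default 1.
#' @return `alpha_2`, or `NA_real_` when any axis has zero second moment.
#' @export
nongauss_alpha2 <- function(t, lag = 1L) {
  if (!is_gap_free(t)) stop("nongauss_alpha2 needs a gap-free track")
  L <- track_length(t)
  if (L - lag < 8L) stop("need >= 8 displacements at lag ", lag)
  dd <- t$positions[(1L + lag):L, , drop = FALSE] -
    t$positions[1L:(L - lag), , drop = FALSE]
  a2 <- apply(dd, 2L, function(dx) {
    m2 <- mean(dx^2)
    if (m2 == 0) return(NA_real_)
    mean(dx^4) / (3 * m2^2) - 1
  })
  if (anyNA(a2)) return(NA_real_)
  mean(a2)
}

# Isotropic random walk with step lengths resampled from `lens`.
resampled_walk <- function(lens, dim) {
  n <- length(lens)
  steps <- unit_directions(n, dim) * sample(lens, n, replace = TRUE)
  rbind(rep(0, dim), apply(steps, 2L, cumsum))
}

# All n_sim resampled-walk position arrays at once: a list of (nstep+1) x
# n_sim coordinate matrices, one per axis. Vectorised because the baseline
# runs for every track.
resampled_walk_ensemble <- function(lens, dim, n_sim) {
  n <- length(lens)
  len <- matrix(sample(lens, n * n_sim, replace = TRUE), n, n_sim)
  dirs <- unit_directions(n * n_sim, dim)
  lapply(seq_len(dim), function(ax) {
    steps <- matrix(dirs[, ax], n, n_sim) * len
    rbind(rep(0, n_sim), apply(steps, 2L, cumsum))
  })
}

# Squared Pearson correlation between the first two coordinate series of
# each simulated walk (the linearity statistic), vectorised over columns.
# Constant-coordinate walks map to 1, matching linearity_metrics.
colwise_linearity <- function(xs, ys) {
  n <- nrow(xs)
  mx <- colMeans(xs)
  my <- colMeans(ys)
  vx <- colMeans(xs^2) - mx^2
  vy <- colMeans(ys^2) - my^2
  cxy <- colMeans(xs * ys) - mx * my
  r2 <- cxy^2 / (vx * vy)
  r2[vx == 0 | vy == 0] <- 1
  r2
}

excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

subtrack_kurtosis <- function(pos, subtrack_len) {
  # excess kurtosis of the displacement-magnitude series, averaged over
  # non-overlapping sub-tracks (displacements measured from each sub-track's
  # first point)
  L <- nrow(pos)
  n_sub <- max(L %/% subtrack_len, 1L)
  ks <- vapply(seq_len(n_sub), function(j) {
    idx <- ((j - 1L) * subtrack_len + 1L):min(j * subtrack_len, L)
    sub <- pos[idx, , drop = FALSE]
    disp <- sqrt(rowSums(sweep(sub, 2L, sub[1L, ])^2))[-1L]
    excess_kurtosis(disp)
  }, numeric(1))
  mean(ks, na.rm = TRUE)
}

# Ensemble version of subtrack_kurtosis: per-walk mean excess kurtosis of
# the displacement-magnitude series over non-overlapping sub-tracks.
subtrack_kurtosis_ensemble <- function(axes, subtrack_len) {
  L <- nrow(axes[[1L]])
  n_sim <- ncol(axes[[1L]])
  n_sub <- max(L %/% subtrack_len, 1L)
  per_sub <- matrix(NA_real_, n_sub, n_sim)
  for (j in seq_len(n_sub)) {
    idx <- ((j - 1L) * subtrack_len + 1L):min(j * subtrack_len, L)
    sq <- Reduce(`+`, lapply(axes, function(m) {
      blk <- m[idx, , drop = FALSE]
      sweep(blk, 2L, blk[1L, ])^2
    }))
    disp <- sqrt(sq[-1L, , drop = FALSE])
    mu <- colMeans(disp)
    m2 <- colMeans(disp^2) - mu^2
    m4 <- colMeans(sweep(disp, 2L, mu)^4)
    k <- m4 / m2^2 - 3
    k[m2 == 0] <- NA_real_
    per_sub[j, ] <- k
  }
  colMeans(per_sub, na.rm = TRUE)
}

#' Random-walk baseline deltas
#'
#' Compares a track against matched isotropic random walks: each of the
#' `n_sim` simulated walks takes the same number of steps, with step lengths
#' resampled with replacement from the track's own observed step lengths and
#' uniformly random directions. The deltas are the observed statistic minus
#' the simulated mean: `rw_linearity` (linearity), `rw_netdist` (net
#' distance, um) and `rw_kurtosis` (excess kurtosis of the
#' displacement-magnitude series averaged over non-overlapping sub-tracks of
#' `subtrack_len` frames). Positive deltas mean more directed / dispersed
#' than a matched random walk. Deterministic given `seed`.
#'
#' @param t A `track` of length >= 3.
#' @param n_sim Number of simulated walks (>= 1).
#' @param seed Integer seed.
#' @param subtrack_len Sub-track length in frames for the kurtosis delta.
#' @return Named list `rw_linearity`, `rw_netdist`, `rw_kurtosis`.
#' @export
random_walk_deltas <- function(t, n_sim = 100L, seed = 99L,
                               subtrack_len = 20L) {
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (track_length(t) < 3L) stop("random_walk_deltas needs length >= 3")
  st <- track_steps(t)
  d <- track_dim(t)
  obs_lin <- linearity_metrics(t)$linearity
  obs_net <- path_metrics(t)$net_distance
  obs_kurt <- subtrack_kurtosis(t$positions, subtrack_len)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  axes <- resampled_walk_ensemble(st$lengths, d, n_sim)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  L <- nrow(axes[[1L]])
  if (d == 2L) {
    sim_lin <- colwise_linearity(axes[[1L]], axes[[2L]])
  } else {
    # match linearity_metrics: per walk, the two largest-variance axes
    vars <- vapply(axes, function(m) apply(m, 2L, stats::var),
                   numeric(n_sim))
    if (is.null(dim(vars))) vars <- matrix(vars, nrow = 1L)
    sim_lin <- vapply(seq_len(n_sim), function(s) {
      ord <- order(vars[s, ], decreasing = TRUE)[1:2]
      x <- axes[[ord[1L]]][, s]
      y <- axes[[ord[2L]]][, s]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(1)
      stats::cor(x, y)^2
    }, numeric(1))
  }
  sim_net <- sqrt(Reduce(`+`, lapply(axes, function(m)
    (m[L, ] - m[1L, ])^2)))
  sim_kurt <- subtrack_kurtosis_ensemble(axes, subtrack_len)
  list(rw_linearity = obs_lin - mean(sim_lin),
       rw_netdist = obs_net - mean(sim_net),
       rw_kurtosis = if (is.na(obs_kurt)) NA_real_
                     else obs_kurt - mean(sim_kurt, na.rm = TRUE))
}

#' Movement occupancy: time moving and speed while moving
#'
#' A step counts as "moving" when its speed exceeds the threshold. The track
#' is split into non-overlapping sub-tracks of `subtrack_len` frames (the
#' trailing remainder joins the last sub-track); for each threshold,
#' `time_moving` is the across-sub-track mean fraction of moving steps, and
#' `avg_moving_speed` the across-sub-track mean speed over moving steps
#' (defined as 0 in a sub-track with no moving step).
#'
#' @param t A `track`.
#' @param thresholds Speed thresholds, um/min.
#' @param subtrack_len Sub-track length, frames; must not exceed the track
#'   length.
#' @return List of two named numeric vectors, `time_moving` and
#'   `avg_moving_speed`, one element per threshold.
#' @export
movement_occupancy <- function(t, thresholds = c(0.5, 1, 2, 5),
                               subtrack_len = 20L) {
  L <- track_length(t)
  if (subtrack_len > L) stop("subtrack_len exceeds track length")
  if (subtrack_len < 2L) stop("subtrack_len must be >= 2")
  speeds <- track_steps(t)$speeds
  nstep_sub <- subtrack_len - 1L
  n_sub <- max(length(speeds) %/% nstep_sub, 1L)
  groups <- pmin((seq_along(speeds) - 1L) %/% nstep_sub + 1L, n_sub)
  tm <- am <- stats::setNames(numeric(length(thresholds)),
                              vapply(thresholds, format, character(1), trim = TRUE))
  for (k in seq_along(thresholds)) {
    thr <- thresholds[k]
    per_sub <- vapply(seq_len(n_sub), function(j) {
      sp <- speeds[groups == j]
      moving <- sp > thr
      c(frac = mean(moving),
        spd = if (any(moving)) mean(sp[moving]) else 0)
    }, numeric(2))
    tm[k] <- mean(per_sub["frac", ])
    am[k] <- mean(per_sub["spd", ])
  }
  list(time_moving = tm, avg_moving_speed = am)
}

#' Directional autocorrelation of the displacement series
#'
#' For each lag, the mean cosine between step vectors `lag` frames apart: 1
#' for constant-direction motion, -1 for strict direction reversal, near 0
#' for memoryless motion. Zero-length steps contribute no direction and are
#' dropped pairwise; if no valid pair remains the value is `NA`. A Pearson
#' autocorrelation of the step-magnitude series is returned alongside as a
#' diagnostic (`NA` when magnitudes have zero variance).
#'
#' @param t A gap-free `track` with length >= max(lags) + 2.
#' @param lags Frame lags.
#' @return List with `autocorr` (mean step-direction cosine per lag) and
#'   `autocorr_magnitude` (magnitude-series Pearson correlation per lag).
#' @export
displacement_autocorr <- function(t, lags = c(1L, 2L, 5L)) {
  if (!is_gap_free(t)) stop("displacement_autocorr needs a gap-free track")
  st <- track_steps(t)
  n <- nrow(st$vectors)
  if (n < max(lags) + 1L) stop("lag too large for track length")
  cosv <- magv <- stats::setNames(rep(NA_real_, length(lags)),
                                  paste0("lag", lags))
  for (k in seq_along(lags)) {
    g <- lags[k]
    a <- st$vectors[1L:(n - g), , drop = FALSE]
    b <- st$vectors[(1L + g):n, , drop = FALSE]
    na <- st$lengths[1L:(n - g)]
    nb <- st$lengths[(1L + g):n]
    ok <- na > 0 & nb > 0
    if (any(ok))
      cosv[k] <- mean(rowSums(a[ok, , drop = FALSE] *
                                b[ok, , drop = FALSE]) / (na[ok] * nb[ok]))
    if (stats::sd(na) > 0 && stats::sd(nb) > 0)
      magv[k] <- stats::cor(na, nb)
  }
  list(autocorr = cosv, autocorr_magnitude = magv)
}

#' TrackMate-style summary metrics
#'
#' The four per-track statistics reported by TrackMate's track tables:
#' total distance travelled, total displacement (net distance), mean
#' straight-line speed (net distance over track duration) and velocity
#' (mean of the per-step speeds).
#'
#' @param t A `track` of length >= 2.
#' @return Named list `total_distance`, `total_displacement` (um),
#'   `mean_straight_line_speed`, `velocity` (um/min).
#' @export
trackmate_summary <- function(t) {
  pm <- path_metrics(t)
  duration <- (t$frames[track_length(t)] - t$frames[1L]) * t$frame_interval
  list(total_distance = pm$total_distance,
       total_displacement = pm$net_distance,
       mean_straight_line_speed = pm$net_distance / duration,
       velocity = pm$avg_speed)
}

#' Compute the full motility feature table of a trackset
#'
#' One row per track, with the complete feature battery, the TrackMate-style
#' summary metrics (prefixed `tm_`) and the condition label. Tracks with
#' frame gaps of at most `params$max_gap` are linearly interpolated before
#' the lag-based statistics (MSD slope, Hurst, non-Gaussian parameter,
#' autocorrelation); tracks with larger gaps get `NA` for those features and
#' are counted in the `gap_excluded` attribute. Undefined features (e.g. on
#' stationary tracks) are `NA`, never silently zero; per-feature missing
#' counts are attached as the `missing_counts` attribute.
#'
#' @param ts A [trackset()], typically after [filter_tracks()].
#' @param params A [feature_params()].
#' @return A data frame of class `"feature_table"`, deterministic given
#'   `params$rw_seed`.
#' @export
feature_table <- function(ts, params = feature_params()) {
  if (!length(ts)) stop("empty trackset")
  rows <- lapply(seq_along(ts$tracks), function(i) {
    t <- ts$tracks[[i]]
    reg <- regularize_track(t, params$max_gap)
    pm <- path_metrics(t)
    lin <- if (track_length(t) >= 3L) linearity_metrics(t)
           else list(linearity = NA_real_, spearmanrsq = NA_real_)
    msd <- hur <- ng <- NA_real_
    ac <- stats::setNames(rep(NA_real_, length(params$autocorr_lags)),
                          paste0("lag", params$autocorr_lags))
    if (!is.null(reg)) {
      msd <- msd_profile(reg, params$msd_lag_max)$msd_slope
      if (track_length(reg) >= 16L)
        hur <- hurst_rs(reg, params$hurst_min_window)
      if (track_length(reg) >= 9L)
        ng <- nongauss_alpha2(reg, 1L)
      if (track_length(reg) >= max(params$autocorr_lags) + 2L)
        ac <- displacement_autocorr(reg, params$autocorr_lags)$autocorr
    }
    rw <- if (track_length(t) >= 3L)
      random_walk_deltas(t, params$rw_n_sim,
                         substream_seed(params$rw_seed, i),
                         params$subtrack_len)
    else list(rw_linearity = NA_real_, rw_netdist = NA_real_,
              rw_kurtosis = NA_real_)
    mo <- if (track_length(t) >= params$subtrack_len)
      movement_occupancy(t, params$move_thresholds, params$subtrack_len)
    else list(time_moving = stats::setNames(
                rep(NA_real_, length(params$move_thresholds)),
                vapply(params$move_thresholds, format, character(1), trim = TRUE)),
              avg_moving_speed = stats::setNames(
                rep(NA_real_, length(params$move_thresholds)),
                vapply(params$move_thresholds, format, character(1), trim = TRUE)))
    tm <- trackmate_summary(t)
    out <- data.frame(track_id = t$track_id, condition = t$condition,
                      total_distance = pm$total_distance,
                      net_distance = pm$net_distance,
                      progressivity = pm$progressivity,
                      linearity = lin$linearity,
                      spearmanrsq = lin$spearmanrsq,
                      max_speed = pm$max_speed, min_speed = pm$min_speed,
                      avg_speed = pm$avg_speed,
                      msd_slope = msd, hurst_rs = hur, nongauss = ng,
                      rw_linearity = rw$rw_linearity,
                      rw_netdist = rw$rw_netdist,
                      rw_kurtosis = rw$rw_kurtosis,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (nm in names(mo$time_moving))
      out[[paste0("time_moving_", nm)]] <- unname(mo$time_moving[nm])
    for (nm in names(mo$avg_moving_speed))
      out[[paste0("avg_moving_speed_", nm)]] <- unname(mo$avg_moving_speed[nm])
    for (nm in names(ac)) out[[paste0("autocorr_", nm)]] <- unname(ac[nm])
    out$tm_total_distance <- tm$total_distance
    out$tm_total_displacement <- tm$total_displacement
    out$tm_mean_straight_line_speed <- tm$mean_straight_line_speed
    out$tm_velocity <- tm$velocity
    out$gap_excluded <- is.null(reg)
    out
  })
  fm <- do.call(rbind, rows)
  rownames(fm) <- NULL
  num <- vapply(fm, is.numeric, logical(1))
  attr(fm, "missing_counts") <- colSums(is.na(fm[, num, drop = FALSE]))
  attr(fm, "gap_excluded") <- sum(fm$gap_excluded)
  class(fm) <- c("feature_table", "data.frame")
  fm
}

#' Names of the numeric feature columns of a feature table
#' @param fm A [feature_table()] result.
#' @return Character vector of feature column names (excludes identifiers).
#' @export
feature_columns <- function(fm) {
  setdiff(names(fm)[vapply(fm, is.numeric, logical(1))], "gap_excluded")
}
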