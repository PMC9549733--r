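# Hand-built fixture tracks and independent brute-force oracles used across
# the suite. The oracles deliberately use plain loops and first-principles
# formulas, not the package's code paths.

line_track <- function(n = 5L, interval = 1, dx = 1) {
  track("line", seq_len(n) - 1L, cbind((seq_len(n) - 1L) * dx, 0), interval)
}

square_loop_track <- function(interval = 1) {
  track("loop", 0:4,
        rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)), interval)
}

zigzag_track <- function(interval = 10) {
  track("zigzag", 0:3, rbind(c(0, 0), c(1, 1), c(2, 0), c(3, 1)), interval)
}

stationary_track <- function(n = 20L, interval = 10) {
  track("still", seq_len(n) - 1L, cbind(rep(1.5, n), rep(-2, n)), interval)
}

brownian_set <- function(n_tracks, n_frames = 72L, sigma = 1, seed = 1L,
                         interval = 10) {
  cfg <- simulation_config("brownian", n_tracks = n_tracks,
                           n_frames = n_frames, frame_interval = interval,
                           sigma = sigma, seed = seed)
  simulate_tracks(cfg, condition = "sim")$tracks
}

# --- brute-force oracles -------------------------------------------------

bf_step_lengths <- function(pos) {
  out <- numeric(nrow(pos) - 1L)
  for (i in seq_len(nrow(pos) - 1L)) {
    out[i] <- sqrt(sum((pos[i + 1L, ] - pos[i, ])^2))
  }
  out
}

bf_path_metrics <- function(pos, frames, interval) {
  lens <- bf_step_lengths(pos)
  total <- 0
  for (l in lens) total <- total + l
  net <- sqrt(sum((pos[nrow(pos), ] - pos[1L, ])^2))
  speeds <- lens / (diff(frames) * interval)
  list(total_distance = total, net_distance = net,
       progressivity = if (total > 0) net / total else 0,
       max_speed = max(speeds), min_speed = min(speeds),
       avg_speed = sum(speeds) / length(speeds))
}

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_linearity <- function(pos) {
  x <- pos[, 1L]
  y <- pos[, 2L]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(linearity = 1, spearmanrsq = 1))
  list(linearity = bf_pearson(x, y)^2,
       spearmanrsq = bf_pearson(rank(x), rank(y))^2)
}

bf_msd <- function(pos, lag) {
  n <- nrow(pos)
  acc <- 0
  for (i in seq_len(n - lag)) {
    acc <- acc + sum((pos[i + lag, ] - pos[i, ])^2)
  }
  acc / (n - lag)
}

bf_trackmate <- function(pos, frames, interval) {
  pm <- bf_path_metrics(pos, frames, interval)
  duration <- (frames[length(frames)] - frames[1L]) * interval
  list(total_distance = pm$total_distance,
       total_displacement = pm$net_distance,
       mean_straight_line_speed = pm$net_distance / duration,
       velocity = pm$avg_speed)
}

bf_autocorr_cos <- function(pos, lag) {
  n <- nrow(pos) - 1L
  steps <- pos[-1L, , drop = FALSE] - pos[-(n + 1L), , drop = FALSE]
  vals <- c()
  for (i in seq_len(n - lag)) {
    a <- steps[i, ]
    b <- steps[i + lag, ]
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na > 0 && nb > 0) vals <- c(vals, sum(a * b) / (na * nb))
  }
  if (length(vals)) sum(vals) / length(vals) else NA_real_
}

bf_nongauss <- function(pos, lag = 1L) {
  n <- nrow(pos)
  a2 <- numeric(ncol(pos))
  for (ax in seq_len(ncol(pos))) {
    dx <- pos[(1L + lag):n, ax] - pos[1L:(n - lag), ax]
    m2 <- sum(dx^2) / length(dx)
    m4 <- sum(dx^4) / length(dx)
    a2[ax] <- m4 / (3 * m2^2) - 1
  }
  sum(a2) / length(a2)
}

bf_movement <- function(pos, frames, interval, threshold, subtrack_len) {
  lens <- bf_step_lengths(pos)
  speeds <- lens / (diff(frames) * interval)
  per_sub <- subtrack_len - 1L
  n_sub <- max(length(speeds) %/% per_sub, 1L)
  fr <- sp <- numeric(n_sub)
  for (j in seq_len(n_sub)) {
    lo <- (j - 1L) * per_sub + 1L
    hi <- if (j == n_sub) length(speeds) else j * per_sub
    s <- speeds[lo:hi]
    fr[j] <- mean(s > threshold)
    sp[j] <- if (any(s > threshold)) mean(s[s > threshold]) else 0
  }
  list(time_moving = mean(fr), avg_moving_speed = mean(sp))
}

# Pearson chi-squared statistic from first principles.
bf_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - expected)^2 / expected)
}

rotate2d <- function(ts, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  tracks <- lapply(ts$tracks, function(t) {
    t$positions <- t$positions %*% R
    t
  })
  trackset(tracks)
}

translate_ts <- function(ts, shift) {
  trackset(lapply(ts$tracks, function(t) {
    t$positions <- sweep(t$positions, 2L, shift, `+`)
    t
  }), ts$field_bounds)
}
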