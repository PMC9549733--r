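#' Configuration for the synthetic trajectory generator
#'
#' Bundles the parameters of one simulated tracking experiment. The motion
#' models are:
#'
#' * `brownian` — i.i.d. Normal(0, `sigma`^2) displacement per axis per frame.
#' * `prw` — persistent random walk: Ornstein--Uhlenbeck velocity with
#'   relaxation time `persistence_time` (minutes) and per-axis stationary
#'   velocity SD `speed` (um/min). Position and velocity are advanced with
#'   the exact joint Gaussian update of the integrated OU process, so the
#'   ensemble MSD follows the Fuerth formula at any frame interval.
#' * `directed` — constant `velocity` (um/min per axis) plus Normal(0,
#'   `sigma`^2) per-axis step noise.
#' * `levy` — step lengths Pareto(`levy_alpha`, `min_step`), isotropic
#'   directions.
#' * `mixture` — each track draws its motion model from `mixture_spec`, a
#'   list of components `list(model =, params =, proportion =)` whose
#'   proportions sum to 1; the drawn component labels are returned as ground
#'   truth.
#'
#' @param model One of `"brownian"`, `"prw"`, `"directed"`, `"levy"`,
#'   `"mixture"`.
#' @param n_tracks Number of tracks.
#' @param n_frames Observed frames per track (>= 2).
#' @param frame_interval Minutes per frame.
#' @param dim Spatial dimensionality, 2 or 3.
#' @param seed Integer seed. Each track consumes its own RNG substream
#'   derived from this seed and the track index, so increasing `n_tracks`
#'   never reshuffles earlier tracks.
#' @param sigma Per-axis step SD (um) for `brownian` and the noise of
#'   `directed`.
#' @param speed Per-axis stationary velocity SD (um/min) for `prw`.
#' @param persistence_time Velocity relaxation time (minutes) for `prw`.
#' @param velocity Numeric drift velocity vector (um/min) for `directed`.
#' @param levy_alpha Pareto tail exponent (> 1) for `levy`.
#' @param min_step Pareto scale (minimum step length, um) for `levy`.
#' @param mixture_spec Component list for `mixture` (see above).
#' @param noise_sd Localisation noise SD (um) added to every coordinate
#'   after path generation; 0 disables.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(model = c("brownian", "prw", "directed",
                                        "levy", "mixture"),
                              n_tracks, n_frames, frame_interval, dim = 2L,
                              seed = 1L, sigma = 1, speed = 0.5,
                              persistence_time = 30, velocity = NULL,
                              levy_alpha = 2, min_step = 0.5,
                              mixture_spec = NULL, noise_sd = 0) {
  model <- match.arg(model)
  stopifnot(n_tracks >= 1, n_frames >= 2, frame_interval > 0,
            dim %in% c(2L, 3L), sigma >= 0, speed >= 0,
            persistence_time >= 0, noise_sd >= 0)
  if (model == "levy" && (levy_alpha <= 1 || min_step <= 0))
    stop("levy needs levy_alpha > 1 and min_step > 0")
  if (model == "directed") {
    if (is.null(velocity)) velocity <- c(1, rep(0, dim - 1L))
    if (length(velocity) != dim) stop("velocity must have length dim")
  }
  if (model == "mixture") {
    if (is.null(mixture_spec) || !length(mixture_spec))
      stop("mixture needs a mixture_spec")
    p <- vapply(mixture_spec, function(cm) cm$proportion, numeric(1))
    if (abs(sum(p) - 1) > 1e-8)
      stop("mixture proportions must sum to 1 (got ", sum(p), ")")
  }
  structure(list(model = model, n_tracks = as.integer(n_tracks),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, dim = as.integer(dim),
                 seed = as.integer(seed), sigma = sigma, speed = speed,
                 persistence_time = persistence_time, velocity = velocity,
                 levy_alpha = levy_alpha, min_step = min_step,
                 mixture_spec = mixture_spec, noise_sd = noise_sd),
            class = "simulation_config")
}

# Deterministic per-track substream seed; independent of total track count.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed %% 65011L) * 33029 + as.double(i) * 7919) %%
               2147483629)
}

unit_directions <- function(n, dim) {
  v <- matrix(stats::rnorm(n * dim), n, dim)
  v / sqrt(rowSums(v^2))
}

# One path, positions n_frames x dim starting at origin. RNG state is the
# caller's responsibility.
simulate_path <- function(model, cfg, n_frames) {
  d <- cfg$dim
  dt <- cfg$frame_interval
  nstep <- n_frames - 1L
  steps <- switch(model,
    brownian = matrix(stats::rnorm(nstep * d, 0, cfg$sigma), nstep, d),
    directed = matrix(rep(cfg$velocity * dt, each = nstep), nstep, d) +
      matrix(stats::rnorm(nstep * d, 0, cfg$sigma), nstep, d),
    levy = {
      len <- cfg$min_step * stats::runif(nstep)^(-1 / cfg$levy_alpha)
      unit_directions(nstep, d) * len
    },
    prw = prw_steps(nstep, d, dt, cfg$speed, cfg$persistence_time),
    stop("unknown model: ", model))
  rbind(rep(0, d), apply(steps, 2L, cumsum))
}

# Exact joint update of the integrated Ornstein-Uhlenbeck process:
# velocity v_{t+dt} = v_t e + N(0, s^2(1-e^2)), displacement conditionally
# Gaussian with mean v_t P (1-e) and the exact covariance, e = exp(-dt/P).
# Degenerate P = 0 falls back to uncorrelated Gaussian steps of matching
# per-step variance.
prw_steps <- function(nstep, d, dt, s, P) {
  if (P <= 0 || s == 0)
    return(matrix(stats::rnorm(nstep * d, 0, s * sqrt(2 * dt * max(P, 0))),
                  nstep, d))
  e <- exp(-dt / P)
  var_v <- s^2 * (1 - e^2)
  cov_xv <- s^2 * P * (1 - e)^2
  var_x <- 2 * s^2 * P * (dt - 2 * P * (1 - e) + (P / 2) * (1 - e^2))
  b2 <- max(var_x - cov_xv^2 / var_v, 0)
  v <- stats::rnorm(d, 0, s)
  steps <- matrix(0, nstep, d)
  for (i in seq_len(nstep)) {
    z1 <- stats::rnorm(d)
    z2 <- stats::rnorm(d)
    steps[i, ] <- v * P * (1 - e) + (cov_xv / sqrt(var_v)) * z1 +
      sqrt(b2) * z2
    v <- v * e + sqrt(var_v) * z1
  }
  steps
}

#' Ensemble mean-squared displacement of a persistent random walk
#'
#' The Fuerth closed form for the integrated Ornstein--Uhlenbeck model:
#' `MSD(t) = 2 d S^2 P (t - P (1 - exp(-t/P)))` with per-axis stationary
#' velocity SD `S` and persistence time `P`. Used as the analytic oracle for
#' the `prw` generator.
#'
#' @param t Time lag(s), minutes.
#' @param dim Spatial dimensionality.
#' @param speed Per-axis stationary velocity SD (um/min).
#' @param persistence_time Persistence time (minutes).
#' @return MSD in um^2 at each `t`.
#' @export
furth_msd <- function(t, dim, speed, persistence_time) {
  P <- persistence_time
  2 * dim * speed^2 * P * (t - P * (1 - exp(-t / P)))
}

#' Simulate a trackset under a motion model
#'
#' Generates `cfg$n_tracks` tracks of `cfg$n_frames` frames each. For the
#' `mixture` model each track first draws its component from the configured
#' proportions; the drawn labels are returned as ground truth for planted
#' recovery experiments. Localisation noise (`cfg$noise_sd`) is added after
#' path generation. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param condition Condition label stamped on every generated track.
#' @param id_prefix Prefix for generated track ids.
#' @return A list with `tracks` (a [trackset()]) and `labels` (data frame
#'   `track_id, condition, component`; component is the model name for
#'   non-mixture configs).
#' @examples
#' cfg <- simulation_config("brownian", n_tracks = 5, n_frames = 20,
#'                          frame_interval = 10, sigma = 1, seed = 7)
#' sim <- simulate_tracks(cfg, condition = "untreated")
#' sim$labels$component
#' @export
simulate_tracks <- function(cfg, condition = "unspecified",
                            id_prefix = condition) {
  stopifnot(inherits(cfg, "simulation_config"))
  tracks <- vector("list", cfg$n_tracks)
  comp <- character(cfg$n_tracks)
  frames <- seq_len(cfg$n_frames) - 1L
  for (i in seq_len(cfg$n_tracks)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(substream_seed(cfg$seed, i))
    if (cfg$model == "mixture") {
      p <- vapply(cfg$mixture_spec, function(cm) cm$proportion, numeric(1))
      j <- sample.int(length(p), 1L, prob = p)
      spec <- cfg$mixture_spec[[j]]
      sub <- utils::modifyList(cfg, as.list(spec$params))
      sub$dim <- cfg$dim
      comp[i] <- if (!is.null(spec$name)) spec$name else spec$model
      pos <- simulate_path(spec$model, sub, cfg$n_frames)
    } else {
      comp[i] <- cfg$model
      pos <- simulate_path(cfg$model, cfg, cfg$n_frames)
    }
    if (cfg$noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, cfg$noise_sd),
                          nrow(pos), ncol(pos))
    id <- sprintf("%s-%04d", id_prefix, i)
    tracks[[i]] <- track(id, frames, pos, cfg$frame_interval, condition)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  ts <- trackset(tracks)
  list(tracks = ts,
       labels = data.frame(track_id = names(ts$tracks),
                           condition = condition, component = comp,
                           stringsAsFactors = FALSE))
}

#' Add localisation noise to every coordinate of a trackset
#'
#' Adds i.i.d. Normal(0, `sd`^2) noise per coordinate, emulating centroid
#' localisation error of the segmentation step. `sd = 0` is the identity.
#'
#' @param ts A [trackset()].
#' @param sd Noise SD in micrometres (>= 0).
#' @param seed Integer seed.
#' @return A [trackset()] of the same shape.
#' @export
add_localization_noise <- function(ts, sd, seed = 1L) {
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(ts)
  tracks <- ts$tracks
  for (i in seq_along(tracks)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(substream_seed(seed, i))
    t <- tracks[[i]]
    t$positions <- t$positions +
      matrix(stats::rnorm(length(t$positions), 0, sd),
             nrow(t$positions), ncol(t$positions))
    tracks[[i]] <- t
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  trackset(tracks, ts$field_bounds)
}

#' Simulate a 3D tissue scene with shared rigid drift
#'
#' Builds the synthetic counterpart of a migrating-cell assay on a 3D tissue
#' construct: fiducial landmarks that follow a shared drift path (plus
#' localisation jitter), and cells whose own motion rides on the same drift.
#' The latent drift is stored so drift-correction accuracy can be measured.
#'
#' @param cfg A [simulation_config()] describing the cells' own motion
#'   (its `dim`, `n_frames`, `frame_interval` also set the scene geometry).
#' @param drift_spec List describing the drift path: `model` one of
#'   `"none"`, `"linear"`, `"sinusoidal"`; `velocity` (um/frame vector, for
#'   `linear`); `amplitude` (um) and optional `period` (frames, default the
#'   scene length) and `axis` (unit vector) for `sinusoidal`.
#' @param n_fiducials Number of fiducial tracks (>= 2).
#' @param fiducial_jitter_sd Localisation jitter SD of the fiducials (um).
#' @param condition Condition label for the cell tracks.
#' @return An object of class `"drift_scene"`: list with `cells`,
#'   `fiducials` (tracksets), `true_drift` (n_frames x dim cumulative drift,
#'   first row zero), `clean_cells` (cells without drift, the ground truth),
#'   `labels`, and `fiducial_jitter_sd`.
#' @export
make_drift_scene <- function(cfg, drift_spec, n_fiducials = 10L,
                             fiducial_jitter_sd = 0.2,
                             condition = "unspecified") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n_fiducials < 2L) stop("need at least 2 fiducials")
  nf <- cfg$n_frames
  d <- cfg$dim
  drift <- drift_path_matrix(drift_spec, nf, d)
  sim <- simulate_tracks(cfg, condition = condition, id_prefix = "cell")
  clean <- sim$tracks
  drifted <- clean
  for (i in seq_along(drifted$tracks)) {
    drifted$tracks[[i]]$positions <- drifted$tracks[[i]]$positions + drift
  }
  fid <- vector("list", n_fiducials)
  frames <- seq_len(nf) - 1L
  for (i in seq_len(n_fiducials)) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(substream_seed(cfg$seed + 104729L, i))
    base <- stats::runif(d, 0, 100)
    pos <- sweep(drift, 2L, base, `+`)
    if (fiducial_jitter_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, fiducial_jitter_sd),
                          nf, d)
    fid[[i]] <- track(sprintf("fid-%03d", i), frames, pos,
                      cfg$frame_interval, "fiducial")
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(cells = drifted, fiducials = trackset(fid),
                 true_drift = drift, clean_cells = clean,
                 labels = sim$labels,
                 fiducial_jitter_sd = fiducial_jitter_sd),
            class = "drift_scene")
}

drift_path_matrix <- function(drift_spec, n_frames, dim) {
  model <- drift_spec$model %||% "none"
  drift <- switch(model,
    none = matrix(0, n_frames, dim),
    linear = {
      v <- drift_spec$velocity
      if (length(v) != dim) stop("linear drift velocity must have length dim")
      outer(seq_len(n_frames) - 1L, v)
    },
    sinusoidal = {
      amp <- drift_spec$amplitude
      if (is.null(amp)) stop("sinusoidal drift needs an amplitude")
      period <- drift_spec$period %||% n_frames
      axis <- drift_spec$axis %||% c(1, rep(0, dim - 1L))
      axis <- axis / sqrt(sum(axis^2))
      phase <- sin(2 * pi * (seq_len(n_frames) - 1L) / period)
      outer(amp * phase, axis)
    },
    stop("unknown drift model: ", model))
  sweep(drift, 2L, drift[1L, ], `-`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default two-condition motility scenario
#'
#' The study conditions the generator emulates by default: 2D nuclei tracks
#' imaged every 10 minutes for 12 hours (72 frames), each condition a
#' mixture of a low-motility Brownian regime and a motile persistent-walk
#' regime, with motile fractions 1/24 in the untreated and 11/24 in the
#' treated condition, plus 0.3 um localisation noise.
#'
#' @param n_tracks Tracks per condition (default 216, i.e. 9 x 24 so the
#'   motile fractions are exact multiples).
#' @param seed Integer seed; the two conditions use disjoint substreams.
#' @return List of two [simulation_config()]s named `untreated`, `treated`.
#' @export
default_scenario <- function(n_tracks = 216L, seed = 1L) {
  comp <- function(frac_motile) list(
    list(name = "low_motility", model = "brownian",
         params = list(sigma = 0.5), proportion = 1 - frac_motile),
    list(name = "motile", model = "prw",
         params = list(speed = 0.35, persistence_time = 60),
         proportion = frac_motile))
  mk <- function(frac, seed) simulation_config(
    "mixture", n_tracks = n_tracks, n_frames = 72L, frame_interval = 10,
    dim = 2L, seed = seed, mixture_spec = comp(frac), noise_sd = 0.3)
  list(untreated = mk(1 / 24, seed),
       treated = mk(11 / 24, seed + 499979L))
}
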