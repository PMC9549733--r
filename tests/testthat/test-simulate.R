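test_that("generation is deterministic and substreams are stable", {
  cfg <- simulation_config("brownian", n_tracks = 10L, n_frames = 20L,
                           frame_interval = 10, sigma = 1, seed = 42L)
  a <- simulate_tracks(cfg, "u")
  b <- simulate_tracks(cfg, "u")
  expect_identical(a$tracks$tracks, b$tracks$tracks)
  # growing the track count must not reshuffle earlier tracks
  cfg5 <- simulation_config("brownian", n_tracks = 5L, n_frames = 20L,
                            frame_interval = 10, sigma = 1, seed = 42L)
  small <- simulate_tracks(cfg5, "u")
  expect_identical(small$tracks$tracks, a$tracks$tracks[1:5])
})

test_that("brownian step lengths follow the Rayleigh mean", {
  cfg <- simulation_config("brownian", n_tracks = 40L, n_frames = 51L,
                           frame_interval = 10, sigma = 1, seed = 7L)
  ts <- simulate_tracks(cfg, "u")$tracks
  lens <- unlist(lapply(ts$tracks, function(t) track_steps(t)$lengths))
  # 2D Gaussian steps: |step| is Rayleigh(sigma), mean sigma*sqrt(pi/2)
  expected <- sqrt(pi / 2)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 3 * se)
})

test_that("persistent random walk matches the Fuerth MSD closed form", {
  P <- 30
  s <- 0.4
  cfg <- simulation_config("prw", n_tracks = 500L, n_frames = 48L,
                           frame_interval = 10, speed = s,
                           persistence_time = P, seed = 3L)
  ts <- simulate_tracks(cfg, "u")$tracks
  for (lag in c(3L, 9L)) {  # t = P and 3P at 10 min/frame
    msd <- mean(vapply(ts$tracks, function(t) {
      L <- track_length(t)
      dd <- t$positions[(1 + lag):L, , drop = FALSE] -
        t$positions[1:(L - lag), , drop = FALSE]
      mean(rowSums(dd^2))
    }, numeric(1)))
    expect_lt(abs(msd / furth_msd(lag * 10, 2, s, P) - 1), 0.05)
  }
})

test_that("brownian ensemble MSD is linear and PRW slope falls with lag", {
  ts <- brownian_set(200L, n_frames = 72L, seed = 9L)
  slopes <- vapply(ts$tracks, function(t) msd_profile(t)$msd_slope,
                   numeric(1))
  expect_gt(mean(slopes), 0.9)
  expect_lt(mean(slopes), 1.1)

  cfg <- simulation_config("prw", n_tracks = 150L, n_frames = 100L,
                           frame_interval = 10, speed = 0.4,
                           persistence_time = 60, seed = 13L)
  prw <- simulate_tracks(cfg, "u")$tracks
  ens_msd <- function(lag) mean(vapply(prw$tracks, function(t) {
    L <- track_length(t)
    dd <- t$positions[(1 + lag):L, , drop = FALSE] -
      t$positions[1:(L - lag), , drop = FALSE]
    mean(rowSums(dd^2))
  }, numeric(1)))
  lags <- c(1, 2, 4, 8, 16)
  msds <- vapply(lags, ens_msd, numeric(1))
  local_slope <- diff(log(msds)) / diff(log(lags))
  # ballistic (~2) at lags << P decaying towards diffusive (~1) at lags >> P;
  # the Fuerth local slope at the largest window (t ~ 2P) is ~1.52
  expect_true(all(diff(local_slope) < 0))
  expect_gt(local_slope[1], 1.7)
  expect_lt(local_slope[length(local_slope)], 1.6)
})

test_that("levy steps follow the configured Pareto tail", {
  cfg <- simulation_config("levy", n_tracks = 30L, n_frames = 60L,
                           frame_interval = 10, levy_alpha = 2,
                           min_step = 0.5, seed = 21L)
  ts <- simulate_tracks(cfg, "u")$tracks
  lens <- unlist(lapply(ts$tracks, function(t) track_steps(t)$lengths))
  expect_gte(min(lens), 0.5)
  # Pareto(alpha=2, xm): median = xm * 2^(1/2)
  expect_lt(abs(median(lens) - 0.5 * sqrt(2)), 0.05)
})

test_that("mixture assigns components at configured proportions with labels", {
  spec <- list(
    list(name = "slow", model = "brownian", params = list(sigma = 0.3),
         proportion = 0.75),
    list(name = "fast", model = "prw",
         params = list(speed = 0.5, persistence_time = 30),
         proportion = 0.25))
  cfg <- simulation_config("mixture", n_tracks = 400L, n_frames = 20L,
                           frame_interval = 10, mixture_spec = spec,
                           seed = 5L)
  sim <- simulate_tracks(cfg, "u")
  expect_setequal(unique(sim$labels$component), c("slow", "fast"))
  p_hat <- mean(sim$labels$component == "fast")
  se <- sqrt(0.25 * 0.75 / 400)
  expect_lt(abs(p_hat - 0.25), 3 * se)
  # proportions must sum to one
  bad <- spec
  bad[[1]]$proportion <- 0.9
  expect_error(simulation_config("mixture", 10, 10, 10,
                                 mixture_spec = bad, seed = 1),
               "sum to 1")
})

test_that("localization noise has the configured SD and sd=0 is identity", {
  still <- trackset(lapply(1:20, function(i)
    track(paste0("s", i), 0:49, cbind(rep(0, 50), rep(0, 50)), 10)))
  expect_identical(add_localization_noise(still, 0, seed = 1L), still)
  noisy <- add_localization_noise(still, sd = 1, seed = 8L)
  coords <- unlist(lapply(noisy$tracks, function(t) t$positions))
  se <- 1 / sqrt(2 * length(coords))   # SE of a sample SD of N(0,1)
  expect_lt(abs(sd(coords) - 1), 3 * se)
  expect_identical(add_localization_noise(still, 1, seed = 8L),
                   noisy)
  expect_error(add_localization_noise(still, -1), ">= 0")
})

test_that("drift scenes embed the exact latent drift", {
  cfg <- simulation_config("brownian", n_tracks = 5L, n_frames = 40L,
                           frame_interval = 12, dim = 3L, sigma = 0.5,
                           seed = 31L)
  # zero drift, zero jitter: fiducials stationary, cells undrifted
  calm <- make_drift_scene(cfg, list(model = "none"), n_fiducials = 4L,
                           fiducial_jitter_sd = 0)
  for (f in calm$fiducials$tracks) {
    expect_equal(max(track_steps(f)$lengths), 0)
  }
  expect_equal(calm$cells$tracks[[1]]$positions,
               calm$clean_cells$tracks[[1]]$positions)

  # linear drift: every fiducial step is exactly the drift velocity
  lin <- make_drift_scene(cfg, list(model = "linear",
                                    velocity = c(1, 0, 0)),
                          n_fiducials = 3L, fiducial_jitter_sd = 0)
  for (f in lin$fiducials$tracks) {
    expect_equal(track_steps(f)$vectors,
                 matrix(rep(c(1, 0, 0), each = 39), 39, 3))
  }

  # sinusoidal drift + jitter: fiducial mean recovers the path within RMS
  n_fid <- 25L
  jit <- 0.2
  sine <- make_drift_scene(cfg, list(model = "sinusoidal", amplitude = 5),
                           n_fiducials = n_fid, fiducial_jitter_sd = jit)
  anchored <- lapply(sine$fiducials$tracks, function(f)
    sweep(f$positions, 2L, f$positions[1L, ]))
  mean_path <- Reduce(`+`, anchored) / n_fid
  rmse <- sqrt(mean((mean_path - sine$true_drift)^2))
  expect_lt(rmse, 3 * jit / sqrt(n_fid))
  expect_error(make_drift_scene(cfg, list(model = "none"),
                                n_fiducials = 1L), "at least 2")
})
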