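# Synthetic sessions with ground-truth labels: virtual-track runs with
# teleports, foraging arena trajectories, tuned rate functions (cue, grid,
# border, head direction), inhomogeneous Poisson spikes by thinning, and
# calcium traces derived from spikes.

#' Simulate a virtual-track trajectory with teleports
#'
#' Unidirectional runs along the track at an Ornstein-Uhlenbeck-modulated
#' speed with occasional pause epochs (speed below 1 cm/s, exercising the
#' velocity gate); the animal teleports back to the start at the track
#' end.
#'
#' @param track_length track length (cm), default 800 (8 m).
#' @param n_runs number of traversals.
#' @param mean_speed,speed_sd running-speed mean and spread (cm/s).
#' @param dt sampling interval (s), default 0.02 (50 Hz).
#' @param pause_rate_hz rate of entering a pause epoch (per second).
#' @param pause_mean_s mean pause duration (s).
#' @param seed optional RNG seed.
#' @return a [track_session()] with no spikes.
#' @export
simulate_track_trajectory <- function(track_length = 800, n_runs = 40,
                                      mean_speed = 15, speed_sd = 4,
                                      dt = 0.02, pause_rate_hz = 0.02,
                                      pause_mean_s = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- numeric(0); run <- integer(0)
  v <- mean_speed
  paused_left <- 0
  theta <- 1; sig <- speed_sd * sqrt(2 * theta)
  for (r in seq_len(n_runs)) {
    x <- 0
    while (x < track_length) {
      if (paused_left > 0) {
        step_v <- stats::runif(1, 0, 0.8)       # crawl below the gate
        paused_left <- paused_left - dt
      } else {
        if (stats::runif(1) < pause_rate_hz * dt)
          paused_left <- stats::rexp(1, 1 / pause_mean_s)
        v <- v + theta * (mean_speed - v) * dt + sig * sqrt(dt) * stats::rnorm(1)
        v <- max(v, 1.5)
        step_v <- v
      }
      x <- x + step_v * dt
      if (x >= track_length) break
      pos <- c(pos, x); run <- c(run, r - 1L)
    }
  }
  time <- seq_along(pos) * dt
  track_session(time, pos, track_length, run_id = run)
}

#' Simulate a foraging trajectory in a square arena
#'
#' Smooth bounded random walk: the movement heading diffuses, speed
#' follows an Ornstein-Uhlenbeck process, and walls reflect. Head
#' direction is the movement heading plus an independent slow
#' head-scanning offset (Ornstein-Uhlenbeck, ~45 degree spread, 2 s
#' timescale) plus fast jitter, as rodent head direction is not slaved to
#' the direction of travel.
#'
#' @param arena_size arena side (cm), default 50.
#' @param duration session length (s).
#' @param dt sampling interval (s).
#' @param mean_speed mean speed (cm/s).
#' @param seed optional RNG seed.
#' @return an [arena_session()] with no spikes.
#' @export
simulate_arena_trajectory <- function(arena_size = 50, duration = 1200,
                                      dt = 0.02, mean_speed = 15,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt)
  x <- numeric(n); y <- numeric(n); hd <- numeric(n)
  px <- arena_size / 2; py <- arena_size / 2
  phi <- stats::runif(1, 0, 2 * pi)
  v <- mean_speed
  scan <- 0                       # head-scanning offset (radians)
  scan_sd <- 45 * pi / 180; scan_tau <- 2
  for (i in seq_len(n)) {
    phi <- phi + 1.2 * sqrt(dt) * stats::rnorm(1)
    scan <- scan - scan / scan_tau * dt +
      scan_sd * sqrt(2 * dt / scan_tau) * stats::rnorm(1)
    v <- v + 2 * (mean_speed - v) * dt + 6 * sqrt(dt) * stats::rnorm(1)
    v <- min(max(v, 2), 40)
    px <- px + v * cos(phi) * dt
    py <- py + v * sin(phi) * dt
    if (px < 0) { px <- -px; phi <- pi - phi }
    if (px > arena_size) { px <- 2 * arena_size - px; phi <- pi - phi }
    if (py < 0) { py <- -py; phi <- -phi }
    if (py > arena_size) { py <- 2 * arena_size - py; phi <- -phi }
    x[i] <- px; y[i] <- py
    hd[i] <- ((phi + scan) * 180 / pi + 5 * stats::rnorm(1)) %% 360
  }
  arena_session(seq_len(n) * dt, x, y, hd, arena_size = arena_size)
}

#' Cue-locked firing rate function along the track
#'
#' `lambda(x) = baseline + sum_c a_c * peak * exp(-(x - (center_c +
#' shift))^2 / (2 fw^2))` with one Gaussian field per cue, all displaced by
#' the same shift; per-cue amplitude factors `a_c` are drawn once.
#'
#' @param template a [cue_template()].
#' @param shift_cm common displacement of the fields from the cue centers.
#' @param field_width Gaussian field width sigma (cm).
#' @param peak peak rate above baseline (Hz).
#' @param baseline baseline rate (Hz).
#' @param per_cue_jitter spread of the per-cue amplitude factors (0 for
#'   identical cues; factors are `max(0.2, 1 + jitter * z_c)`).
#' @return function mapping position (cm) to rate (Hz), with attribute
#'   `amplitudes`.
#' @export
cue_rate_function <- function(template, shift_cm = 0, field_width = 10,
                              peak = 10, baseline = 0.5,
                              per_cue_jitter = 0) {
  iv <- template_intervals(template)
  bs <- template$bin_size
  centers <- (iv$start + iv$end) / 2 * bs - bs / 2 + shift_cm
  a <- pmax(0.2, 1 + per_cue_jitter * stats::rnorm(nrow(iv)))
  f <- function(x) {
    r <- rep(baseline, length(x))
    for (k in seq_along(centers))
      r <- r + a[k] * peak * exp(-(x - centers[k])^2 / (2 * field_width^2))
    r
  }
  attr(f, "amplitudes") <- a
  f
}

#' Inhomogeneous Poisson spikes along a trajectory, by thinning
#'
#' The rate is evaluated at every trajectory sample; candidate events are
#' drawn from a homogeneous Poisson process at the maximal rate and
#' accepted with probability `lambda(t) / lambda_max` (rates are treated
#' as piecewise constant between samples).
#'
#' @param rate_fn for a `track_session`, `function(position)`; for an
#'   `arena_session`, `function(x, y, hd)`.
#' @param session a session object.
#' @param seed optional RNG seed.
#' @return sorted spike times (s).
#' @export
poisson_spikes <- function(rate_fn, session, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam <- if (inherits(session, "track_session")) rate_fn(session$position)
         else rate_fn(session$x, session$y, session$head_direction)
  stopifnot(all(lam >= 0))
  lmax <- max(lam)
  if (lmax == 0) return(numeric(0))
  t0 <- session$time[1]; t1 <- session$time[length(session$time)]
  n_cand <- stats::rpois(1, lmax * (t1 - t0))
  if (n_cand == 0) return(numeric(0))
  ts <- sort(stats::runif(n_cand, t0, t1))
  j <- pmax(1L, findInterval(ts, session$time))
  keep <- stats::runif(n_cand) < lam[j] / lmax
  ts[keep]
}

#' Grid-cell firing rate function over the arena
#'
#' Thresholded sum of three plane-wave cosines with wave vectors separated
#' by 60 degrees.
#'
#' @param spacing grid spacing (cm).
#' @param orientation_deg grid orientation (degrees).
#' @param phase 2-vector spatial phase offset (cm).
#' @param peak,baseline peak and baseline rates (Hz).
#' @return `function(x, y, hd)` returning rates.
#' @export
grid_rate_function <- function(spacing = 40, orientation_deg = 0,
                               phase = c(0, 0), peak = 12, baseline = 0.1) {
  kmag <- 4 * pi / (sqrt(3) * spacing)
  angs <- (orientation_deg + c(0, 60, 120)) * pi / 180
  function(x, y, hd = NULL) {
    g <- 0
    for (a in angs)
      g <- g + cos(kmag * (cos(a) * (x - phase[1]) + sin(a) * (y - phase[2])))
    baseline + peak * pmax(0, (g + 1.5) / 4.5)^1.5
  }
}

#' Border-cell firing rate function (decays with distance to one wall)
#'
#' @param wall one of `"left"`, `"right"`, `"bottom"`, `"top"` (walls at
#'   x = 0, x = arena, y = 0, y = arena).
#' @param arena_size arena side (cm).
#' @param peak,baseline rates (Hz).
#' @param length_scale decay scale (cm).
#' @return `function(x, y, hd)`.
#' @export
border_rate_function <- function(wall = "left", arena_size = 50, peak = 10,
                                 baseline = 0.1, length_scale = 6) {
  function(x, y, hd = NULL) {
    d <- switch(wall,
                left = x, right = arena_size - x,
                bottom = y, top = arena_size - y,
                stop("unknown wall: ", wall))
    baseline + peak * exp(-d / length_scale)
  }
}

#' Head-direction (von Mises) firing rate function
#'
#' `lambda(hd) = baseline + peak * exp(kappa (cos(hd - mu) - 1))`.
#'
#' @param mu_deg preferred direction (degrees).
#' @param kappa concentration.
#' @param peak,baseline rates (Hz).
#' @return `function(x, y, hd)`.
#' @export
hd_rate_function <- function(mu_deg = 0, kappa = 4, peak = 15,
                             baseline = 0.1) {
  mu <- mu_deg * pi / 180
  function(x, y, hd) {
    th <- hd * pi / 180
    baseline + peak * exp(kappa * (cos(th - mu) - 1))
  }
}

#' Synthesize a dF/F trace from a spike train
#'
#' Spikes are convolved with a difference-of-exponentials kernel (rise
#' 50 ms, decay 400 ms by default, peak-normalized) and Gaussian noise is
#' added.
#'
#' @param spike_times spike times (s).
#' @param duration trace duration (s).
#' @param frame_rate frames per second.
#' @param rise_s,decay_s kernel time constants (s).
#' @param amplitude single-spike peak dF/F.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed optional RNG seed.
#' @return a `dff_trace`.
#' @export
spikes_to_dff <- function(spike_times, duration, frame_rate = 30,
                          rise_s = 0.05, decay_s = 0.4, amplitude = 1,
                          noise_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration * frame_rate)
  tt <- (seq_len(n) - 1) / frame_rate
  kern_t <- seq(0, 5 * decay_s, by = 1 / frame_rate)
  kern <- exp(-kern_t / decay_s) - exp(-kern_t / rise_s)
  kern <- amplitude * kern / max(kern)
  x <- numeric(n)
  idx <- floor(spike_times * frame_rate) + 1
  idx <- idx[idx >= 1 & idx <= n]
  for (i in idx) {
    j <- i:min(n, i + length(kern) - 1)
    x[j] <- x[j] + kern[seq_along(j)]
  }
  dff_trace(x + noise_sd * stats::rnorm(n), frame_rate)
}

#' Simulate a mixed population on a track (and optionally an arena)
#'
#' Generates one shared track trajectory (and arena trajectory when
#' `with_arena`), then one unit per cell with class-specific tuning:
#' cue cells fire in Gaussian fields displaced from each cue by a
#' per-cell shift; grid/border/head-direction cells are tuned in the
#' arena (and fire homogeneously on the track); untuned cells fire
#' homogeneously everywhere.
#'
#' @param template a [cue_template()] for the track.
#' @param n_cells total number of cells.
#' @param proportions named numeric proportions for classes `cue`,
#'   `grid`, `border`, `hd`, `untuned` (defaults 0.3/0.2/0.1/0.2/0.2).
#' @param shift_range_cm cue-cell shifts are drawn uniformly (then snapped
#'   to whole bins) in this range.
#' @param track_minutes,arena_minutes session lengths.
#' @param cue_peak,cue_baseline cue-cell field peak and baseline (Hz).
#' @param untuned_rate homogeneous rate of untuned firing (Hz).
#' @param with_arena simulate the arena session too.
#' @param seed RNG seed.
#' @return list with `track` (a `track_session` holding all units'
#'   spikes), `arena` (or `NULL`), and `truth` (data frame: `cell`,
#'   `class`, `shift_cm`, and tuning parameters).
#' @export
simulate_population <- function(template, n_cells = 60,
                                proportions = c(cue = 0.3, grid = 0.2,
                                                border = 0.1, hd = 0.2,
                                                untuned = 0.2),
                                shift_range_cm = c(-20, 20),
                                track_minutes = 30, arena_minutes = 20,
                                cue_peak = 10, cue_baseline = 0.5,
                                untuned_rate = 2, with_arena = TRUE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- round(proportions * n_cells)
  counts[1] <- n_cells - sum(counts[-1])
  classes <- rep(names(counts), counts)
  track_len <- template$track_length
  mean_speed <- 15
  n_runs <- ceiling(track_minutes * 60 * mean_speed / track_len)
  track <- simulate_track_trajectory(track_len, n_runs = n_runs,
                                     mean_speed = mean_speed)
  arena <- if (with_arena)
    simulate_arena_trajectory(duration = arena_minutes * 60) else NULL
  bs <- template$bin_size
  truth <- data.frame(cell = sprintf("c%03d", seq_len(n_cells)),
                      class = classes, shift_cm = NA_real_,
                      stringsAsFactors = FALSE)
  track_spikes <- list(); arena_spikes <- list()
  for (i in seq_len(n_cells)) {
    id <- truth$cell[i]
    cls <- classes[i]
    if (cls == "cue") {
      shift <- round(stats::runif(1, shift_range_cm[1], shift_range_cm[2]) / bs) * bs
      truth$shift_cm[i] <- shift
      fn <- cue_rate_function(template, shift_cm = shift, peak = cue_peak,
                              baseline = cue_baseline, per_cue_jitter = 0.15)
      track_spikes[[id]] <- poisson_spikes(fn, track)
      if (with_arena)
        arena_spikes[[id]] <- poisson_spikes(function(x, y, hd)
          rep(untuned_rate, length(x)), arena)
    } else {
      track_spikes[[id]] <- poisson_spikes(function(x)
        rep(untuned_rate, length(x)), track)
      if (with_arena) {
        fn <- switch(cls,
          grid = grid_rate_function(spacing = stats::runif(1, 30, 40),
                                    orientation_deg = stats::runif(1, 0, 60),
                                    phase = stats::runif(2, 0, 50)),
          border = border_rate_function(
            wall = sample(c("left", "right", "bottom", "top"), 1)),
          hd = hd_rate_function(mu_deg = stats::runif(1, 0, 360), kappa = 4),
          untuned = function(x, y, hd) rep(untuned_rate, length(x)))
        arena_spikes[[id]] <- poisson_spikes(fn, arena)
      }
    }
  }
  track$spikes <- validate_spikes(track_spikes, track$time)
  if (with_arena) arena$spikes <- validate_spikes(arena_spikes, arena$time)
  list(track = track, arena = arena, truth = truth)
}
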