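# Deterministic session builders and standard fixtures used across tests.

# Constant-speed unidirectional track: n_runs identical traversals,
# sampled every dt, teleporting at the end.
make_uniform_track <- function(track_length = 400, n_runs = 4, speed = 20,
                               dt = 0.02, spikes = list()) {
  pos_run <- seq(0, track_length - speed * dt / 2, by = speed * dt)
  pos <- rep(pos_run, n_runs)
  run <- rep(seq_len(n_runs) - 1L, each = length(pos_run))
  time <- seq_along(pos) * dt
  track_session(time, pos, track_length, spikes = spikes, run_id = run)
}

# spike times at which the uniform track first passes position x on run r
uniform_track_spike_time <- function(session, x, run) {
  idx <- which(session$run_id == run)
  idx[which.min(abs(session$position[idx] - x))] * sample_dt(session)
}

std_cues <- function() {
  data.frame(start_cm = c(100, 250, 400, 550, 700),
             end_cm = c(125, 275, 425, 575, 725),
             side = "both")
}

std_template <- function(track_length = 800) {
  cue_template(std_cues(), track_length)
}

# rate vector exactly proportional to a displaced template (+ baseline)
template_rate <- function(template, shift_bins = 0, baseline = 0,
                          gain = 1) {
  n <- length(template$values)
  v <- integer(n)
  src <- seq_len(n) - shift_bins
  ok <- src >= 1 & src <= n
  v[ok] <- template$values[src[ok]]
  baseline + gain * v
}

null_track_rate <- function(session, rate_hz = 2, seed = 1) {
  s <- session
  s$spikes <- list(u = poisson_spikes(function(x) rep(rate_hz, length(x)),
                                      session, seed = seed))
  track_ratemap(s, "u")$rate
}
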