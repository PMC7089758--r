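test_that("track trajectories are reproducible, well-formed, and paced", {
  a <- simulate_track_trajectory(800, n_runs = 5, seed = 301)
  b <- simulate_track_trajectory(800, n_runs = 5, seed = 301)
  expect_identical(a$position, b$position)
  expect_identical(simulate_track_trajectory(800, n_runs = 0, seed = 1)$time,
                   numeric(0))
  # mean traversal duration ~ track_length / mean_speed (within 10%)
  s <- simulate_track_trajectory(800, n_runs = 20, mean_speed = 15,
                                 seed = 302)
  dur <- diff(c(0, vapply(split(s$time, s$run_id), max, numeric(1))))
  expect_equal(mean(dur), 800 / 15, tolerance = 0.1)
  # positions monotone within runs
  for (r in unique(s$run_id))
    expect_true(!is.unsorted(s$position[s$run_id == r]))
  # pauses exercise the velocity gate
  expect_gt(sum(!velocity_filter(s)$mask), 0)
})

test_that("arena trajectories stay inside and cover the arena", {
  a <- simulate_arena_trajectory(duration = 1200, seed = 311)
  b <- simulate_arena_trajectory(duration = 1200, seed = 311)
  expect_identical(a$x, b$x)
  expect_true(all(a$x >= 0 & a$x <= 50 & a$y >= 0 & a$y <= 50))
  expect_true(all(a$head_direction >= 0 & a$head_direction < 360))
  occ <- arena_ratemap(a, "none")$occupancy
  expect_gte(mean(occ >= 0.3), 0.95)
})

test_that("cue rate functions peak at shifted cue centers and integrate correctly", {
  tm <- std_template(800)
  fn <- cue_rate_function(tm, shift_cm = 0, field_width = 10, peak = 8,
                          baseline = 0.4)
  x <- seq(0, 800, by = 0.5)
  lam <- fn(x)
  expect_true(all(lam >= 0.4))
  iv <- template_intervals(tm)
  centers <- (iv$start + iv$end) / 2 * 5 - 2.5
  for (ctr in centers)
    expect_lt(abs(x[which.max(lam * (abs(x - ctr) < 60))] - ctr), 1)
  # quadrature vs closed form: 5 Gaussians of mass peak * sigma * sqrt(2pi)
  integral <- sum(lam - 0.4) * 0.5
  expect_equal(integral, 5 * 8 * 10 * sqrt(2 * pi), tolerance = 0.01)
})

test_that("poisson spike counts follow the rate integral and superpose", {
  s <- make_uniform_track(800, n_runs = 10, speed = 16)
  lam1 <- function(x) rep(3, length(x))
  lam2 <- function(x) 2 * exp(-(x - 400)^2 / 800)
  T <- diff(range(s$time))
  n1 <- length(poisson_spikes(lam1, s, seed = 321))
  expect_equal(n1, 3 * T, tolerance = 0.1)
  expect_identical(poisson_spikes(function(x) rep(0, length(x)), s, seed = 1),
                   numeric(0))
  # superposition: E[count(l1 + l2)] = E[count(l1)] + E[count(l2)]
  n12 <- mean(vapply(1:8, function(i)
    length(poisson_spikes(function(x) lam1(x) + lam2(x), s, seed = 400 + i)),
    numeric(1)))
  exp2 <- sum(lam2(s$position)) * sample_dt(s)
  expect_equal(n12, 3 * T + exp2, tolerance = 0.05)
})

test_that("arena rate functions have their defining geometry", {
  g <- grid_rate_function(spacing = 40, orientation_deg = 0, phase = c(0, 0))
  # 60-degree rotational symmetry about a node
  th <- seq(0, 300, by = 60) * pi / 180
  r0 <- g(20 * cos(th), 20 * sin(th))
  expect_equal(max(r0) - min(r0), 0, tolerance = 1e-9)
  b <- border_rate_function("left", peak = 10, baseline = 0.1)
  xs <- seq(0, 50, by = 1)
  expect_identical(which.max(b(xs, rep(25, 51))), 1L)
  h <- hd_rate_function(mu_deg = 90, kappa = 2, peak = 10, baseline = 0)
  tune <- h(0, 0, seq(1.5, 358.5, by = 3))
  expect_equal(unname(hd_score(tune)["score"]),
               besselI(2, 1) / besselI(2, 0), tolerance = 1e-3)
  expect_equal(unname(hd_score(tune)["angle_deg"]), 90, tolerance = 1.6)
})

test_that("synthetic dF/F recovers the kernel and is linear in spikes", {
  # zero spikes: pure noise at the requested sd
  tr0 <- spikes_to_dff(numeric(0), duration = 60, noise_sd = 0.05,
                       seed = 331)
  expect_equal(sd(tr0$dff), 0.05, tolerance = 0.05)
  # single spike, noise averaged out across seeds, recovers the kernel peak
  peaks <- vapply(1:30, function(i) {
    tr <- spikes_to_dff(5, duration = 20, noise_sd = 0.05, seed = 330 + i)
    max(tr$dff[140:170])
  }, numeric(1))
  expect_equal(mean(peaks), 1, tolerance = 0.1)
  # linearity: two coincident spikes double the response
  tr1 <- spikes_to_dff(5, duration = 20, noise_sd = 0, seed = 1)
  tr2 <- spikes_to_dff(c(5, 5), duration = 20, noise_sd = 0, seed = 1)
  expect_equal(tr2$dff, 2 * tr1$dff, tolerance = 1e-12)
})

test_that("mixed populations carry one ground-truth class per cell", {
  tm <- std_template(800)
  sim <- simulate_population(tm, n_cells = 10, track_minutes = 2,
                             with_arena = FALSE, seed = 341)
  expect_identical(nrow(sim$truth), 10L)
  expect_true(all(sim$truth$class %in%
                    c("cue", "grid", "border", "hd", "untuned")))
  expect_true(all(!is.na(sim$truth$shift_cm[sim$truth$class == "cue"])))
  expect_true(all(is.na(sim$truth$shift_cm[sim$truth$class != "cue"])))
  expect_length(sim$track$spikes, 10)
})
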