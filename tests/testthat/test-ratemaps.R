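test_that("smoothed speed matches hand-computed boxcar cases", {
  # constant 10 cm/s
  s <- track_session((1:100) * 0.02, (1:100) * 0.2, 100)
  expect_equal(smoothed_speed(s), rep(10, 100), tolerance = 1e-12)
  # stationary
  s0 <- arena_session((1:100) * 0.02, rep(25, 100), rep(25, 100),
                      rep(0, 100), 50)
  expect_equal(smoothed_speed(s0), rep(0, 100))
  expect_error(smoothed_speed(track_session(1, 0, 100)), "2 samples")

  # speed step 0 -> 20 at 50 Hz: 1 s boxcar produces a linear ramp
  n <- 200
  pos <- c(rep(0, n / 2), cumsum(rep(20 * 0.02, n / 2)))
  st <- track_session((1:n) * 0.02, pos, 1000)
  v_inst <- c(0, abs(diff(pos)) / 0.02)
  v_inst[1] <- v_inst[2]
  # oracle: mean of instantaneous speed over +-0.5 s window
  tgrid <- (1:n) * 0.02
  oracle <- sapply(tgrid, function(t) {
    w <- which(tgrid >= t - 0.5 & tgrid <= t + 0.5)
    mean(v_inst[w])
  })
  expect_equal(smoothed_speed(st), oracle, tolerance = 1e-12)
  ramp <- smoothed_speed(st)[(n / 2 - 20):(n / 2 + 20)]
  expect_true(all(diff(ramp) >= -1e-12))
})

test_that("velocity filter keeps fast samples and their spikes", {
  s <- make_uniform_track(400, n_runs = 2, speed = 20)
  f <- velocity_filter(s)
  expect_true(all(f$mask))
  f2 <- velocity_filter(s, speed = rep(0.5, length(s$time)))
  expect_false(any(f2$mask))
  # spike during a slow epoch is dropped
  sp <- list(u = c(1.0, 3.0))
  s3 <- make_uniform_track(400, n_runs = 2, speed = 20, spikes = sp)
  speed <- rep(10, length(s3$time))
  speed[seq_len(which(s3$time >= 2)[1])] <- 0.2
  f3 <- velocity_filter(s3, speed = speed)
  expect_identical(f3$spikes$u, 3.0)
})

test_that("track rate maps conserve occupancy, spikes, and match hand smoothing", {
  s <- make_uniform_track(400, n_runs = 4, speed = 20)
  st <- sapply(0:3, function(r) uniform_track_spike_time(s, 202, r))
  s$spikes <- list(u = st)
  m <- track_ratemap(s, "u")
  dt <- sample_dt(s)
  expect_equal(sum(m$occupancy), length(s$time) * dt, tolerance = 1e-9)
  expect_equal(sum(m$count), 4)
  expect_true(all(m$rate[m$valid] >= 0))
  # no spikes -> rate identically zero
  m0 <- track_ratemap(s, "absent")
  expect_equal(m0$rate, rep(0, 80))
  # occupancy-weighted mean of raw rate = total spikes / total time
  expect_equal(sum(m$count) / sum(m$occupancy),
               length(st) / (length(s$time) * dt))
  # hand convolution of the 3-point sigma = 1 kernel
  k <- exp(-c(1, 0, 1) / 2); k <- k / sum(k)
  occ_sm <- stats::filter(m$occupancy, k)
  cnt_sm <- stats::filter(m$count, k)
  interior <- 2:79
  expect_equal(m$rate[interior],
               as.numeric(cnt_sm[interior] / occ_sm[interior]),
               tolerance = 1e-12)
  # single-bin spike train: peak at the spike bin, neighbours e^{-1/2} down
  j <- position_to_bin(202, 5, 400)
  expect_equal(which.max(m$rate), j)
  expect_equal(m$count[j + 1] + m$count[j - 1], 0)
  expect_equal(cnt_sm[j + 1] / cnt_sm[j], exp(-0.5), tolerance = 1e-12)
})

test_that("track rate map is equivariant under joint translation", {
  s <- make_uniform_track(400, n_runs = 4, speed = 20)
  st <- sapply(0:3, function(r) uniform_track_spike_time(s, 120, r))
  s$spikes <- list(u = st)
  r1 <- track_ratemap(s, "u")$rate
  st2 <- sapply(0:3, function(r) uniform_track_spike_time(s, 120 + 50, r))
  s$spikes <- list(u = st2)
  r2 <- track_ratemap(s, "u")$rate
  interior <- 15:70
  expect_equal(r2[interior + 10], r1[interior], tolerance = 1e-9)
})

test_that("arena maps mask unvisited bins and match a 2D convolution oracle", {
  # trajectory confined to the left half: right bins are invalid
  n <- 3000
  set.seed(4)
  s <- arena_session((1:n) * 0.02, runif(n, 0, 24), runif(n, 0, 49),
                     runif(n, 0, 360), 50)
  s$spikes <- list(u = s$time[seq(10, n, by = 50)])
  m <- arena_ratemap(s, "u")
  expect_true(all(!m$valid[15:20, ]))
  expect_true(any(m$valid[1:9, ]))
  # no spikes -> zero where valid
  m0 <- arena_ratemap(s, "none")
  expect_equal(max(m0$rate, na.rm = TRUE), 0)
  # oracle: direct truncated-renormalized convolution
  k1 <- exp(-((-2):2)^2 / 2); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  conv_or <- function(X) {
    out <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      acc <- 0; wsum <- 0
      for (a in -2:2) for (b in -2:2) {
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= 20 && jj >= 1 && jj <= 20) {
          w <- K[a + 3, b + 3]
          acc <- acc + w * X[ii, jj]; wsum <- wsum + w
        }
      }
      out[i, j] <- acc / wsum
    }
    out
  }
  socc <- conv_or(m$occupancy)
  scnt <- conv_or(matrix(as.numeric(m$count), 20, 20))
  expected <- ifelse(m$valid, scnt / socc, NA_real_)
  expect_equal(m$rate, expected, tolerance = 1e-12)
})

test_that("hd tuning smooths circularly and is rotation-equivariant", {
  n <- 6000
  set.seed(5)
  hd <- runif(n, 0, 360)
  s <- arena_session((1:n) * 0.02, runif(n, 1, 49), runif(n, 1, 49), hd, 50)
  # no spikes -> zero tuning
  t0 <- hd_tuning(s, "none")
  expect_equal(max(t0$rate, na.rm = TRUE), 0)
  # all spikes while heading in one bin
  sel <- which(hd >= 90 & hd < 93)
  s$spikes <- list(u = s$time[sel])
  tu <- hd_tuning(s, "u")
  target <- position_to_bin(91, 3, 360)
  nz <- which(tu$rate > 0)
  expect_true(all(abs(((nz - target + 60) %% 120) - 60) <= 2))
  # rotating the data rotates the tuning curve
  s2 <- s; s2$head_direction <- (hd + 30) %% 360
  tu2 <- hd_tuning(s2, "u")
  expect_equal(tu2$rate, c(tail(tu$rate, -110), head(tu$rate, 110)),
               tolerance = 1e-9)
})
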