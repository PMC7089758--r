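ideal_hex_map <- function(spacing = 35, orientation = 10, phase = c(5, 5)) {
  ctr <- (1:20 - 0.5) * 2.5
  fn <- grid_rate_function(spacing, orientation, phase)
  outer(ctr, ctr, function(x, y) fn(x, y))
}

test_that("autocorrelogram has center 1, point symmetry, and matches the oracle", {
  set.seed(101)
  M <- matrix(abs(rnorm(64, 2, 1)), 8, 8)
  M[1, 1] <- NA
  ac <- autocorr2d(M, min_overlap = 5)
  n <- nrow(ac)
  expect_equal(ac[(n + 1) / 2, (n + 1) / 2], 1, tolerance = 1e-10)
  expect_equal(ac, ac[n:1, n:1], tolerance = 1e-10)
  expect_equal(ac, oracle_autocorr(M, min_overlap = 5), tolerance = 1e-10)
})

test_that("grid score separates hexagonal, radial, and striped maps", {
  hexm <- ideal_hex_map()
  gs_hex <- grid_score(hexm, bin_size = 2.5)
  expect_gt(gs_hex, 0.5)
  ctr <- (1:20 - 0.5) * 2.5
  radial <- outer(ctr - 25, ctr - 25, function(x, y) exp(-(x^2 + y^2) / 200))
  expect_lt(abs(grid_score(radial, bin_size = 2.5)), 0.05)
  stripes <- outer(ctr, ctr, function(x, y) cos(2 * pi * x / 20) + 1.1)
  expect_lt(grid_score(stripes, bin_size = 2.5), gs_hex - 0.3)
})

test_that("grid score matches the brute-force oracle", {
  maps <- list(ideal_hex_map(),
               ideal_hex_map(spacing = 30, orientation = 25, phase = c(20, 0)))
  set.seed(102)
  noisy <- ideal_hex_map() + matrix(abs(rnorm(400, 0, 0.5)), 20, 20)
  maps <- c(maps, list(noisy))
  for (M in maps)
    expect_equal(grid_score(M, bin_size = 2.5),
                 oracle_grid_score(M, bin_size = 2.5), tolerance = 1e-10)
})

test_that("grid score is invariant under 60-degree rotation of the field pattern", {
  a <- grid_score(ideal_hex_map(orientation = 10), bin_size = 2.5)
  b <- grid_score(ideal_hex_map(orientation = 70), bin_size = 2.5)
  expect_equal(a, b, tolerance = 0.05)
})

test_that("hd score has the closed-form von Mises value and rotation equivariance", {
  th <- ((1:120) - 0.5) * 3 * pi / 180
  # all rate in one bin
  one <- rep(0, 120); one[40] <- 5
  expect_equal(unname(hd_score(one)["score"]), 1, tolerance = 1e-12)
  # uniform tuning
  expect_equal(unname(hd_score(rep(2, 120))["score"]), 0, tolerance = 1e-12)
  expect_true(is.na(hd_score(rep(0, 120))["score"]))
  # von Mises kappa = 2: mean vector length I1(2)/I0(2)
  vm <- exp(2 * cos(th - pi / 3))
  got <- hd_score(vm)
  expect_equal(unname(got["score"]), besselI(2, 1) / besselI(2, 0),
               tolerance = 1e-3)
  expect_equal(unname(got["angle_deg"]), 60, tolerance = 1.6)
  # rotating the tuning rotates the angle, not the score
  vm2 <- exp(2 * cos(th - pi / 3 - pi / 2))
  got2 <- hd_score(vm2)
  expect_equal(unname(got2["score"]), unname(got["score"]), tolerance = 1e-9)
  expect_equal(unname(got2["angle_deg"]), 150, tolerance = 1.6)
})

test_that("border score rewards wall-hugging fields and penalizes central ones", {
  # thin field spanning an entire wall: cM = 1, dM small
  M <- matrix(0.01, 20, 20)
  M[1:2, ] <- 10
  s_wall <- border_score(M, bin_size = 2.5)
  # cM = 1; dM: row-1 bins at 1.25 cm, row-2 interior at 3.75 cm, the two
  # row-2 corner bins at 1.25 cm (side walls are closer), /25 cm
  dM <- (20 * 1.25 + 18 * 3.75 + 2 * 1.25) / 40 / 25
  expect_equal(s_wall, (1 - dM) / (1 + dM), tolerance = 1e-10)
  # compact central blob: negative
  ctr <- (1:20 - 0.5) * 2.5
  blob <- outer(ctr - 25, ctr - 25, function(x, y)
    10 * exp(-(x^2 + y^2) / 50)) + 0.01
  expect_lt(border_score(blob, bin_size = 2.5), 0)
  # nothing above threshold with enough area -> undefined
  tiny <- matrix(0.01, 20, 20); tiny[5, 5] <- 10
  expect_true(is.na(border_score(tiny, bin_size = 2.5)))
})

test_that("split-half stability is 1 for deterministic repeating activity", {
  s <- make_uniform_track(400, n_runs = 8, speed = 20)
  st <- unlist(lapply(0:7, function(r)
    sapply(c(100, 300), function(x) uniform_track_spike_time(s, x, r))))
  s$spikes <- list(u = sort(st))
  expect_equal(split_half_stability(s, "u", "spatial"), 1, tolerance = 1e-9)
})

test_that("stable tuned cells beat unstable null cells in split-half stability", {
  ar <- simulate_arena_trajectory(duration = 600, seed = 111)
  ar$spikes <- list(
    g = poisson_spikes(grid_rate_function(spacing = 35), ar, seed = 112),
    u = poisson_spikes(function(x, y, hd) rep(2, length(x)), ar, seed = 113))
  expect_gt(split_half_stability(ar, "g", "spatial"), 0.5)
  expect_lt(abs(split_half_stability(ar, "u", "spatial")), 0.35)
})

test_that("circular spike-time shuffles preserve counts and are reproducible", {
  st <- sort(runif(200, 0, 600))
  sh <- circular_shift_spikes(st, 0, 600, 321.5)
  expect_length(sh, 200)
  expect_true(all(sh >= 0 & sh <= 600))
  ar <- simulate_arena_trajectory(duration = 300, seed = 121)
  ar$spikes <- list(u = poisson_spikes(function(x, y, hd) rep(3, length(x)),
                                       ar, seed = 122))
  fn <- function(s, u) unname(hd_score(hd_tuning(s, u))["score"])
  t1 <- score_shuffle_threshold(ar, "u", fn, n_shuffles = 10, seed = 5)
  t2 <- score_shuffle_threshold(ar, "u", fn, n_shuffles = 10, seed = 5)
  expect_identical(t1$threshold, t2$threshold)
  expect_length(t1$values, 10)
})

test_that("duplicate removal applies the summed-score and cross-day rules", {
  set.seed(131)
  base_arena <- matrix(abs(rnorm(400, 2, 1)), 20, 20)
  base_track <- abs(rnorm(80, 2, 1))
  spikes <- sort(runif(500, 0, 600))
  mk <- function(id, day, arena, track, st)
    list(id = id, day = day, spikes = st, arena_map = arena,
         track_map = track)
  # identical cluster duplicated within a day: larger kept
  u1 <- mk("a", 1, base_arena, base_track, spikes)
  u2 <- mk("b", 1, base_arena, base_track, spikes[1:400])
  r <- deduplicate_units(list(u1, u2))
  expect_identical(r$kept, "a")
  expect_true(r$pairs$duplicate[1])
  # independent cells: both kept
  u3 <- mk("c", 1, matrix(abs(rnorm(400, 2, 1)), 20, 20),
           abs(rnorm(80, 2, 1)), sort(runif(400, 0, 600)))
  r2 <- deduplicate_units(list(u1, u3))
  expect_setequal(r2$kept, c("a", "c"))
  # cross-day arena correlation above 0.8: duplicate, higher peak kept
  noisy <- base_arena + matrix(rnorm(400, 0, 0.2), 20, 20)
  u4 <- mk("d", 2, noisy * 2, abs(rnorm(80, 2, 1)), sort(runif(400, 0, 600)))
  r3 <- deduplicate_units(list(u1, u4))
  expect_identical(r3$kept, "d")
  # inclusion gates: too few spikes, or out-of-range track rates
  u5 <- mk("e", 1, base_arena, base_track, spikes[1:50])
  u6 <- mk("f", 1, base_arena, base_track + 20, spikes)
  r4 <- deduplicate_units(list(u5, u6))
  expect_setequal(r4$excluded, c("e", "f"))
})
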