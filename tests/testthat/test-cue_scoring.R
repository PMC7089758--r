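test_that("a rate equal to the template scores 1 at zero shift", {
  tm <- std_template(800)
  res <- cue_shift_and_score(as.numeric(tm$values), tm)
  expect_equal(res$shift_cm, 0)
  expect_equal(res$score, 1)
  expect_true(all(res$per_cue_r == 1, na.rm = TRUE))
})

test_that("a displaced template recovers the imposed shift with score 1", {
  tm <- std_template(800)
  # rate = template moved 2 bins toward larger positions -> shift +10 cm
  res <- cue_shift_and_score(template_rate(tm, shift_bins = 2), tm)
  expect_equal(res$shift_cm, 10)
  expect_equal(res$score, 1)
  res_neg <- cue_shift_and_score(template_rate(tm, shift_bins = -3), tm)
  expect_equal(res_neg$shift_cm, -15)
  expect_equal(res_neg$score, 1)
})

test_that("degenerate rates have undefined scores", {
  tm <- std_template(800)
  res <- cue_shift_and_score(rep(2, 160), tm)
  expect_true(is.na(res$score))
})

test_that("cue score is invariant under positive affine rate transforms", {
  tm <- std_template(800)
  s <- simulate_track_trajectory(800, n_runs = 10, seed = 31)
  s$spikes <- list(u = poisson_spikes(cue_rate_function(tm, shift_cm = 5), s,
                                      seed = 32))
  r <- track_ratemap(s, "u")$rate
  a <- cue_shift_and_score(r, tm)
  b <- cue_shift_and_score(3.7 * r + 1.2, tm)
  expect_equal(a$score, b$score, tolerance = 1e-12)
  expect_equal(a$shift_cm, b$shift_cm)
})

test_that("cue score matches the exhaustive brute-force oracle", {
  set.seed(41)
  for (i in 1:8) {
    nb <- sample(30:50, 1)
    tl <- nb * 5
    k <- sample(2:3, 1)
    starts <- sort(sample(seq(0, tl - 40, by = 5), k))
    cues <- data.frame(start_cm = starts, end_cm = starts + sample(c(15, 25), k,
                                                                   replace = TRUE))
    cues <- cues[cues$end_cm <= tl, , drop = FALSE]
    tm <- cue_template(cues, tl)
    if (!nrow(template_intervals(tm))) next
    rate <- abs(rnorm(nb, 2, 1)) + 2 * template_rate(tm, sample(-2:2, 1))
    got <- cue_shift_and_score(rate, tm, max_shift_cm = 100)
    want <- oracle_cue_score(rate, tm, max_lag_bins = 20)
    expect_equal(got$shift_cm / 5, want$shift_bins)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("shuffled templates preserve cue count and widths, and detect infeasibility", {
  tm <- std_template(800)
  set.seed(51)
  widths0 <- sort(template_intervals(tm)$width)
  starts <- integer(0)
  for (i in 1:300) {
    st <- shuffled_template(tm)
    iv <- template_intervals(st)
    expect_identical(sort(iv$width), widths0)
    expect_true(all(iv$start >= 1 & iv$end <= 160))
    starts <- c(starts, iv$start)
  }
  # placements spread over the whole track
  expect_lt(min(starts), 10)
  expect_gt(max(starts), 150)
  full <- cue_template(data.frame(start_cm = 0, end_cm = 800), 800)
  expect_error(shuffled_template(full), "fit")
})

test_that("pooled threshold is an order statistic of the pooled scores", {
  tm <- std_template(800)
  s <- simulate_track_trajectory(800, n_runs = 10, seed = 61)
  rates <- lapply(1:3, function(i) null_track_rate(s, seed = 600 + i))
  th <- cue_threshold(rates, tm, n_shuffles_per_cell = 20, seed = 62)
  expect_length(th$values, 60)
  expect_gte(th$threshold, min(th$values))
  expect_lte(th$threshold, max(th$values))
  expect_equal(th$threshold,
               unname(quantile(th$values, 0.95, type = 7)))
})

test_that("classification is a strict inequality on the threshold", {
  expect_identical(classify_cue_cells(c(0.5, 0.3, 0.4, NA), 0.4),
                   c(TRUE, FALSE, FALSE, FALSE))
})

test_that("side classification follows the unique- and double-pass rules", {
  cues <- data.frame(start_cm = c(100, 300, 500, 700),
                     end_cm = c(125, 325, 525, 725),
                     side = c("left", "right", "left", "right"))
  lt <- cue_template(cues, 1000, side = "left")
  rt <- cue_template(cues, 1000, side = "right")
  left_rate <- template_rate(lt, 0, baseline = 0.2)
  right_rate <- template_rate(rt, 0, baseline = 0.2)
  # responds to every right cue but only the first left cue: passes both
  # thresholds with a higher right score (local correlation is
  # amplitude-blind, so equal-fidelity responses on both sides would tie)
  set.seed(72)
  one_left <- rep(0, 200); one_left[21:25] <- 1
  both_rate <- right_rate + one_left + runif(200, 0, 0.02)
  flat <- rep(1, 200)
  res <- suppressWarnings(
    side_classify(list(left_rate, right_rate, both_rate, flat), lt, rt,
                  left_threshold = 0.3, right_threshold = 0.3))
  expect_identical(res$side[1], "left")
  expect_identical(res$side[2], "right")
  expect_identical(res$side[3], "right")  # passes both, right score higher
  expect_true(is.na(res$side[4]))
})

test_that("bilateral score separates single-side responders", {
  cues <- data.frame(start_cm = c(100, 300, 500, 700),
                     end_cm = c(125, 325, 525, 725),
                     side = c("left", "right", "left", "right"))
  lt <- cue_template(cues, 1000, side = "left")
  rt <- cue_template(cues, 1000, side = "right")
  set.seed(71)
  noise <- abs(rnorm(200, 0.3, 0.05))
  pure_left <- noise + 5 * template_rate(lt, 0)
  bl <- bilateral_score(pure_left, lt, rt, "left")
  expect_gt(bl$bilateral, 0.5)
  # brute-force check: other-side score at the preferred shift
  pref <- cue_shift_and_score(pure_left, lt)
  other <- cue_shift_and_score(pure_left, rt, shift_cm = pref$shift_cm)
  expect_equal(bl$bilateral, pref$score - other$score, tolerance = 1e-12)
  # sign symmetry
  pure_right <- noise + 5 * template_rate(rt, 0)
  br <- bilateral_score(pure_right, lt, rt, "right")
  expect_lt(br$bilateral, -0.5)
})

test_that("imposed shifts are recovered within one bin for strong cue cells", {
  tm <- std_template(800)
  s <- simulate_track_trajectory(800, n_runs = 20, seed = 81)
  shifts <- seq(-20, 20, by = 5)
  rec <- vapply(seq_along(shifts), function(i) {
    fn <- cue_rate_function(tm, shift_cm = shifts[i], peak = 10,
                            baseline = 0.5)
    s$spikes <- list(u = poisson_spikes(fn, s, seed = 800 + i))
    cue_shift_and_score(track_ratemap(s, "u")$rate, tm)$shift_cm
  }, numeric(1))
  expect_gte(mean(abs(rec - shifts) <= 5), 0.9)
})

test_that("random-template control reduces to the real percentage at n_random = 0", {
  tm <- std_template(800)
  s <- simulate_track_trajectory(800, n_runs = 8, seed = 91)
  rates <- lapply(1:2, function(i) null_track_rate(s, seed = 900 + i))
  ctl <- random_template_percentage_control(rates, tm, n_random = 0,
                                            n_shuffles_per_cell = 15,
                                            seed = 92)
  expect_length(ctl$random_pct, 0)
  expect_true(ctl$real_pct >= 0 && ctl$real_pct <= 100)
})
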