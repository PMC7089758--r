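# Velocity gating and occupancy-normalized rate maps.
#
# All maps divide a smoothed spike-count histogram by a smoothed occupancy
# histogram; counts and occupancy are smoothed independently with the same
# kernel, truncated and renormalized at the edges of non-circular domains.

#' Boxcar-smoothed running speed
#'
#' Instantaneous speed from consecutive displacements, averaged with a
#' moving boxcar window (default 1 s). On tracks, displacements across a
#' teleport (run boundary) are ignored.
#'
#' @param session a `track_session` or `arena_session`.
#' @param window_s boxcar width in seconds.
#' @return numeric speed (cm/s), one value per sample.
#' @export
smoothed_speed <- function(session, window_s = 1) {
  n <- length(session$time)
  if (n < 2) stop("need at least 2 samples to estimate speed")
  dt <- diff(session$time)
  if (inherits(session, "track_session")) {
    disp <- diff(session$position)
    disp[diff(session$run_id) != 0] <- NA   # teleport: no real displacement
  } else {
    disp <- sqrt(diff(session$x)^2 + diff(session$y)^2)
  }
  v <- c(NA, abs(disp) / dt)
  v[1] <- v[2]
  half <- window_s / 2
  # boxcar over a time window, ignoring NA entries (teleports)
  ok <- !is.na(v)
  cs <- cumsum(ifelse(ok, v, 0))
  cn <- cumsum(as.integer(ok))
  lo <- pmax(1L, findInterval(session$time - half, session$time,
                              left.open = TRUE) + 1L)
  hi <- findInterval(session$time + half, session$time)
  prev <- pmax(lo - 1L, 1L)           # 0 would drop elements, not pad
  s <- cs[hi] - ifelse(lo > 1, cs[prev], 0)
  m <- cn[hi] - ifelse(lo > 1, cn[prev], 0)
  out <- ifelse(m > 0, s / m, 0)
  as.numeric(out)
}

#' Velocity-gate a session
#'
#' Keeps samples whose smoothed speed exceeds the threshold (default
#' 1 cm/s). Spikes are assigned to the nearest preceding trajectory sample
#' and inherit its mask.
#'
#' @param session a session object.
#' @param speed optional precomputed speed (from [smoothed_speed()]).
#' @param threshold speed threshold (cm/s); strictly greater is kept.
#' @return a list with `mask` (logical per sample) and `spikes` (filtered
#'   named list, each entry the retained spike times).
#' @export
velocity_filter <- function(session, speed = NULL, threshold = 1) {
  if (is.null(speed)) speed <- smoothed_speed(session)
  mask <- speed > threshold
  spikes <- lapply(session$spikes, function(st) {
    j <- spike_sample_index(st, session$time)
    st[mask[j]]
  })
  list(mask = mask, spikes = spikes)
}

# nearest preceding sample; spikes before the first sample go to sample 1
spike_sample_index <- function(spike_times, time) {
  pmax(1L, findInterval(spike_times, time))
}

# Truncated-and-renormalized kernel smoothing of columns of a matrix (or a
# vector). For circular domains the kernel wraps instead.
smooth_columns <- function(x, kernel, circular = FALSE) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  k <- length(kernel)
  half <- (k - 1L) %/% 2L
  if (circular) {
    idx <- outer(seq_len(n), seq(-half, half), function(i, o) ((i + o - 1L) %% n) + 1L)
    out <- matrix(0, n, ncol(X))
    for (j in seq_len(k)) out <- out + kernel[j] * X[idx[, j], , drop = FALSE]
  } else {
    out <- matrix(0, n, ncol(X))
    norm <- numeric(n)
    for (j in seq_len(k)) {
      o <- j - half - 1L
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, , drop = FALSE] + kernel[j] * X[src[ok], , drop = FALSE]
      norm[ok] <- norm[ok] + kernel[j]
    }
    out <- out / norm
  }
  if (vec) drop(out) else out
}

#' Discrete Gaussian kernel
#' @param n number of taps (odd).
#' @param sigma standard deviation in bins.
#' @return weights normalized to sum 1.
#' @export
gaussian_kernel <- function(n, sigma) {
  half <- (n - 1) / 2
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w / sum(w)
}

#' Track spatial firing rate map
#'
#' Velocity-gated spike counts and occupancy are binned at `bin_size`
#' (default 5 cm) and independently smoothed with a 3-point sigma = 1
#' Gaussian window; the rate is their ratio.
#'
#' @param session a `track_session`.
#' @param unit unit id (name in `session$spikes`).
#' @param bin_size spatial bin (cm).
#' @param filtered optional precomputed [velocity_filter()] result.
#' @return a [rate_map()] of kind `"track"`.
#' @export
track_ratemap <- function(session, unit, bin_size = 5, filtered = NULL) {
  if (is.null(filtered)) filtered <- velocity_filter(session)
  dt <- sample_dt(session)
  keep <- which(filtered$mask)
  if (!length(keep)) stop("zero occupancy after velocity filtering")
  n <- n_bins(session$track_length, bin_size)
  bins <- position_to_bin(session$position[keep], bin_size, session$track_length)
  occupancy <- tabulate(bins, n) * dt
  st <- filtered$spikes[[as.character(unit)]]
  if (is.null(st)) st <- numeric(0)
  sb <- position_to_bin(
    session$position[spike_sample_index(st, session$time)],
    bin_size, session$track_length)
  count <- tabulate(sb, n)
  kern <- gaussian_kernel(3, 1)
  socc <- smooth_columns(occupancy, kern)
  scnt <- smooth_columns(count, kern)
  rate <- ifelse(socc > 0, scnt / socc, NA_real_)
  rate_map("track", occupancy, count, rate, valid = socc > 0, bin_size)
}

#' Arena spatial firing rate map
#'
#' 2.5 cm square bins; counts and occupancy convolved with a 5 x 5,
#' sigma = 1 bin Gaussian (truncated and renormalized at the walls) before
#' division. Bins visited for less than `min_occupancy_s` (default 0.3 s)
#' of raw occupancy are marked invalid.
#'
#' @inheritParams track_ratemap
#' @param session an `arena_session`.
#' @param min_occupancy_s occupancy below which the rate is undefined.
#' @return a [rate_map()] of kind `"arena"`; matrix fields are
#'   `n x n` with x as rows and y as columns.
#' @export
arena_ratemap <- function(session, unit, bin_size = 2.5,
                          min_occupancy_s = 0.3, filtered = NULL) {
  if (is.null(filtered)) filtered <- velocity_filter(session)
  dt <- sample_dt(session)
  keep <- which(filtered$mask)
  if (!length(keep)) stop("zero occupancy after velocity filtering")
  n <- n_bins(session$arena_size, bin_size)
  bx <- position_to_bin(session$x[keep], bin_size, session$arena_size)
  by <- position_to_bin(session$y[keep], bin_size, session$arena_size)
  occupancy <- matrix(tabulate((by - 1L) * n + bx, n * n), n, n) * dt
  st <- filtered$spikes[[as.character(unit)]]
  if (is.null(st)) st <- numeric(0)
  j <- spike_sample_index(st, session$time)
  sx <- position_to_bin(session$x[j], bin_size, session$arena_size)
  sy <- position_to_bin(session$y[j], bin_size, session$arena_size)
  count <- matrix(tabulate((sy - 1L) * n + sx, n * n), n, n)
  kern <- gaussian_kernel(5, 1)
  K <- outer(kern, kern)
  socc <- conv2_renorm(occupancy, K)
  scnt <- conv2_renorm(count, K)
  rate <- ifelse(socc > 0, scnt / socc, NA_real_)
  valid <- occupancy >= min_occupancy_s & socc > 0
  rate[!valid] <- NA_real_
  rate_map("arena", occupancy, count, rate, valid, bin_size)
}

# 2D convolution with edge truncation + kernel renormalization
conv2_renorm <- function(X, K) {
  n <- nrow(X); m <- ncol(X)
  kr <- nrow(K); kc <- ncol(K)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  out <- matrix(0, n, m); norm <- matrix(0, n, m)
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    di <- a - hr - 1L; dj <- b - hc - 1L
    si <- seq_len(n) + di; sj <- seq_len(m) + dj
    oi <- si >= 1L & si <= n; oj <- sj >= 1L & sj <= m
    out[oi, oj] <- out[oi, oj] + K[a, b] * X[si[oi], sj[oj], drop = FALSE]
    norm[oi, oj] <- norm[oi, oj] + K[a, b]
  }
  out / norm
}

#' Head-direction tuning curve
#'
#' Head direction is binned at `bin_deg` (default 3 degrees); spike count
#' and occupancy are each circularly boxcar-smoothed over `boxcar_bins`
#' bins (default 5, i.e. 15 degrees) before division.
#'
#' @inheritParams arena_ratemap
#' @param bin_deg angular bin width (degrees).
#' @param boxcar_bins width of the circular boxcar (bins).
#' @return a [rate_map()] of kind `"angular"` with
#'   `360 / bin_deg` bins; bin i covers `[(i-1)*bin_deg, i*bin_deg)`.
#' @export
hd_tuning <- function(session, unit, bin_deg = 3, boxcar_bins = 5,
                      filtered = NULL) {
  stopifnot(inherits(session, "arena_session"))
  if (is.null(filtered)) filtered <- velocity_filter(session)
  dt <- sample_dt(session)
  keep <- which(filtered$mask)
  if (!length(keep)) stop("zero occupancy after velocity filtering")
  n <- as.integer(360 / bin_deg)
  hb <- position_to_bin(session$head_direction[keep] %% 360, bin_deg, 360)
  occupancy <- tabulate(hb, n) * dt
  st <- filtered$spikes[[as.character(unit)]]
  if (is.null(st)) st <- numeric(0)
  j <- spike_sample_index(st, session$time)
  sb <- position_to_bin(session$head_direction[j] %% 360, bin_deg, 360)
  count <- tabulate(sb, n)
  box <- rep(1 / boxcar_bins, boxcar_bins)
  socc <- smooth_columns(occupancy, box, circular = TRUE)
  scnt <- smooth_columns(count, box, circular = TRUE)
  rate <- ifelse(socc > 0, scnt / socc, NA_real_)
  rate_map("angular", occupancy, count, rate, valid = socc > 0, bin_deg)
}
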