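# Shuffle-based detection of spatial firing fields on the track.
#
# The test statistic is the smoothed spatial firing rate built from 100 ms
# time bins; the null is a circular rotation of the spike-count time series
# against the (fixed) position series, so occupancy is preserved exactly.

#' Detect spatial firing fields with a circular-permutation null
#'
#' The velocity-gated session is re-binned into `time_bin` (default 100 ms)
#' chunks carrying a spike count and the spatial bin of the mean position.
#' The spike-count series is circularly rotated by `n_shuffles` random
#' offsets drawn uniformly between 5% and 95% of its length (snapped to
#' whole time bins), the smoothed rate map is recomputed for each rotation,
#' and each spatial bin receives a p-value equal to the fraction of
#' rotations whose rate in that bin exceeds the actual rate (ties count as
#' not exceeding). Bins with p below `p_threshold` (default 0.3, strict)
#' form the firing fields.
#'
#' @param session a `track_session`.
#' @param unit unit id.
#' @param n_shuffles number of circular rotations (default 100).
#' @param bin_size spatial bin (cm).
#' @param time_bin temporal chunk (s).
#' @param p_threshold per-bin p-value below which a bin is a field bin.
#' @param seed optional RNG seed.
#' @param filtered optional precomputed [velocity_filter()] result.
#' @return an object of class `field_mask`: list with `is_field` (logical
#'   per bin), `p` (per-bin p-values), `rate` (actual smoothed rate) and
#'   `bin_size`. A unit with no spikes gets `p = 1` everywhere.
#' @export
detect_fields <- function(session, unit, n_shuffles = 100, bin_size = 5,
                          time_bin = 0.1, p_threshold = 0.3, seed = NULL,
                          filtered = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(filtered)) filtered <- velocity_filter(session)
  ser <- field_time_series(session, unit, filtered, time_bin, bin_size)
  n <- n_bins(session$track_length, bin_size)
  actual <- series_ratemap(ser$count, ser$bin, n, time_bin)
  if (sum(ser$count) == 0) {
    return(structure(list(is_field = rep(FALSE, n), p = rep(1, n),
                          rate = actual, bin_size = bin_size),
                     class = "field_mask"))
  }
  L <- length(ser$count)
  offsets <- pmin(pmax(floor(stats::runif(n_shuffles, 0.05 * L, 0.95 * L)), 1L),
                  L - 1L)
  exceed <- numeric(n)
  defined <- numeric(n)
  for (s in seq_len(n_shuffles)) {
    shifted <- circular_shift(ser$count, offsets[s])
    r <- series_ratemap(shifted, ser$bin, n, time_bin)
    cmp <- r > actual
    ok <- !is.na(cmp)
    exceed[ok] <- exceed[ok] + cmp[ok]
    defined[ok] <- defined[ok] + 1
  }
  p <- ifelse(defined > 0, exceed / defined, 1)
  p[is.na(actual)] <- 1
  structure(list(is_field = p < p_threshold, p = p, rate = actual,
                 bin_size = bin_size),
            class = "field_mask")
}

# 100 ms spike-count / spatial-bin time series from velocity-gated samples
field_time_series <- function(session, unit, filtered, time_bin, bin_size) {
  keep <- which(filtered$mask)
  if (!length(keep)) stop("zero occupancy after velocity filtering")
  dt <- sample_dt(session)
  per <- max(1L, round(time_bin / dt))
  nchunk <- length(keep) %/% per
  if (nchunk < 2) stop("session too short for field detection")
  use <- keep[seq_len(nchunk * per)]
  chunk <- rep(seq_len(nchunk), each = per)
  mean_pos <- as.numeric(tapply(session$position[use], chunk, mean))
  bin <- position_to_bin(mean_pos, bin_size, session$track_length)
  st <- filtered$spikes[[as.character(unit)]]
  if (is.null(st)) st <- numeric(0)
  j <- spike_sample_index(st, session$time)
  pos_in_use <- match(j, use)
  ch <- chunk[pos_in_use[!is.na(pos_in_use)]]
  count <- tabulate(ch, nchunk)
  list(count = count, bin = bin)
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

# smoothed rate map from (count, spatial bin) series; occupancy per chunk
# is time_bin seconds
series_ratemap <- function(count, bin, n, time_bin) {
  occ <- tabulate(bin, n) * time_bin
  cnt <- numeric(n)
  agg <- rowsum(count, bin)
  cnt[as.integer(rownames(agg))] <- agg[, 1]
  kern <- gaussian_kernel(3, 1)
  socc <- smooth_columns(occ, kern)
  scnt <- smooth_columns(cnt, kern)
  ifelse(socc > 0, scnt / socc, NA_real_)
}

#' Population field distribution
#'
#' Fraction of cells with a firing field in each spatial bin.
#'
#' @param masks list of [detect_fields()] results with identical binning.
#' @return numeric vector in `[0, 1]`, one value per bin.
#' @export
population_field_distribution <- function(masks) {
  if (!length(masks)) stop("empty list of field masks")
  lens <- vapply(masks, function(m) length(m$is_field), integer(1))
  if (length(unique(lens)) != 1) stop("field masks differ in length")
  Reduce(`+`, lapply(masks, function(m) as.numeric(m$is_field))) / length(masks)
}

#' In-cue versus out-of-cue field-fraction contrast
#'
#' Means of the population field distribution over template bins equal to
#' one (inside cues) and zero (outside cues).
#'
#' @param distribution output of [population_field_distribution()].
#' @param template a [cue_template()] with matching binning.
#' @return named numeric vector `c(in_cue = , out_cue = )`.
#' @export
cue_region_field_contrast <- function(distribution, template) {
  v <- template$values
  stopifnot(length(distribution) == length(v))
  if (all(v == 1) || all(v == 0))
    stop("template must contain both cue and non-cue bins")
  c(in_cue = mean(distribution[v == 1]),
    out_cue = mean(distribution[v == 0]))
}
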