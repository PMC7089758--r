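# Calcium-imaging branch: dF/F, significant transients, in/out-of-field
# periods, candidate-cell gating, and cross-environment identity analysis.
# The cue-score path for imaging reuses the cue_scoring operations on
# mean-dF/F-per-bin vectors unchanged.

#' Fractional fluorescence change (dF/F)
#'
#' `dff(t) = (F(t) - F0(t)) / F0(t)` where the baseline `F0` is a rolling
#' low-percentile (default 8th) of the raw fluorescence over
#' `baseline_window_s`.
#'
#' @param F raw fluorescence trace (positive).
#' @param frame_rate acquisition rate (Hz).
#' @param baseline_window_s rolling window (s) for the baseline.
#' @param baseline_percentile percentile (0-100) defining the baseline.
#' @return an object of class `dff_trace`: list with `dff`, `baseline`,
#'   `frame_rate`, `frame_times` and (initially all-`FALSE`)
#'   `transient_mask`.
#' @export
compute_dff <- function(F, frame_rate, baseline_window_s = 30,
                        baseline_percentile = 8) {
  stopifnot(all(F > 0), frame_rate > 0)
  w <- max(3L, round(baseline_window_s * frame_rate))
  if (w %% 2 == 0) w <- w + 1L
  baseline <- zoo::rollapply(zoo::zoo(F), width = w,
                             FUN = stats::quantile,
                             probs = baseline_percentile / 100, names = FALSE,
                             partial = TRUE, align = "center")
  baseline <- as.numeric(baseline)
  if (any(baseline <= 0)) stop("non-positive baseline fluorescence")
  dff <- (F - baseline) / baseline
  structure(list(dff = dff, baseline = baseline, frame_rate = frame_rate,
                 frame_times = (seq_along(F) - 1) / frame_rate,
                 transient_mask = rep(FALSE, length(F))),
            class = "dff_trace")
}

#' Wrap a precomputed dF/F vector as a trace object
#' @param dff dF/F values per frame.
#' @param frame_rate acquisition rate (Hz).
#' @return a `dff_trace`.
#' @export
dff_trace <- function(dff, frame_rate) {
  structure(list(dff = as.numeric(dff), baseline = NULL,
                 frame_rate = frame_rate,
                 frame_times = (seq_along(dff) - 1) / frame_rate,
                 transient_mask = rep(FALSE, length(dff))),
            class = "dff_trace")
}

# runs of consecutive TRUE at least len long
runs_at_least <- function(flag, len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect significant calcium transients
#'
#' Candidate events are excursions of dF/F above `k * sigma` lasting at
#' least `d` seconds. The (k, d) pair is chosen per cell, over the grid
#' `k in {2, 2.5, 3, 3.5, 4}` and `d in [0.2, 1] s`, as the least strict
#' combination for which matching negative-going excursions (below
#' `-k * sigma`, same duration) amount to at most `fp_target` (default 1%)
#' of the detected positive events. Sigma is a robust estimate
#' (median absolute deviation) of the trace noise.
#'
#' @param trace a `dff_trace`.
#' @param fp_target tolerated ratio of negative to positive events.
#' @param k_grid,d_grid_s searched thresholds and durations.
#' @return the trace with `transient_mask` filled in and attributes
#'   `k`, `d_s`, `n_events`, `n_negative` describing the chosen rule.
#' @export
detect_transients <- function(trace, fp_target = 0.01,
                              k_grid = c(2, 2.5, 3, 3.5, 4),
                              d_grid_s = seq(0.2, 1, by = 0.2)) {
  stopifnot(inherits(trace, "dff_trace"))
  x <- trace$dff
  sigma <- stats::mad(x)
  if (sigma == 0) stop("zero noise estimate; cannot calibrate transients")
  fr <- trace$frame_rate
  best <- NULL
  for (k in k_grid) {
    for (d in d_grid_s) {
      len <- max(1L, round(d * fr))
      pos <- runs_at_least(x > k * sigma, len)
      neg <- runs_at_least(x < -k * sigma, len)
      if (nrow(pos) == 0) next
      if (nrow(neg) <= fp_target * nrow(pos)) { best <- list(k = k, d = d, pos = pos, neg = neg); break }
    }
    if (!is.null(best)) break
  }
  mask <- rep(FALSE, length(x))
  if (is.null(best)) {
    attr(trace, "k") <- NA_real_; attr(trace, "d_s") <- NA_real_
    attr(trace, "n_events") <- 0L; attr(trace, "n_negative") <- 0L
    trace$transient_mask <- mask
    return(trace)
  }
  for (i in seq_len(nrow(best$pos)))
    mask[best$pos$start[i]:best$pos$end[i]] <- TRUE
  trace$transient_mask <- mask
  attr(trace, "k") <- best$k; attr(trace, "d_s") <- best$d
  attr(trace, "n_events") <- nrow(best$pos)
  attr(trace, "n_negative") <- nrow(best$neg)
  trace
}

#' In-field and out-of-field periods of a dF/F response
#'
#' The mean dF/F per 5 cm bin (velocity-gated at 1 cm/s) is compared to
#' `n_boot` surrogates obtained by circularly rotating the dF/F trace by
#' offsets uniform in `[0.05 N, 0.95 N]` samples. Each bin's p-value is
#' the fraction of rotations whose mean exceeds the real mean. In-field
#' periods are runs of >= 3 adjacent bins (2 suffice at the track ends)
#' with `p <= 0.2` in which at least 10% of the runs (traversals) contain
#' a significant transient; out-of-field periods are runs of >= 2 bins
#' with `p >= 0.75`.
#'
#' @param session a `track_session` whose `dff` list contains `cell`.
#' @param cell cell id.
#' @param transient_mask optional logical per sample (from
#'   [detect_transients()] on the cell's trace); when `NULL` the
#'   transient-participation gate is skipped.
#' @param n_boot number of rotations (default 1000).
#' @param bin_size spatial bin (cm).
#' @param seed optional RNG seed.
#' @param speed_threshold velocity gate (cm/s).
#' @return list with `p` (per bin), `mean_dff` (per bin), `in_field`
#'   (data frame of bin intervals), `out_field` (same), `is_in_field`
#'   (logical per bin).
#' @export
field_periods <- function(session, cell, transient_mask = NULL,
                          n_boot = 1000, bin_size = 5, seed = NULL,
                          speed_threshold = 1) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(session, "track_session"), !is.null(session$dff))
  x <- session$dff[[as.character(cell)]]
  if (is.null(x)) stop("no dF/F trace for cell ", cell)
  n <- n_bins(session$track_length, bin_size)
  if (n < 3) stop("track shorter than 3 bins")
  speed <- smoothed_speed(session)
  keep <- which(speed >= speed_threshold)
  if (!length(keep)) stop("no samples pass the velocity gate")
  bins <- position_to_bin(session$position[keep], bin_size, session$track_length)
  xk <- x[keep]
  N <- length(xk)
  bin_mean <- function(v) {
    s <- rowsum(v, bins)
    cnt <- rowsum(rep(1, N), bins)
    out <- rep(NA_real_, n)
    out[as.integer(rownames(s))] <- s[, 1] / cnt[, 1]
    out
  }
  real <- bin_mean(xk)
  offsets <- pmin(pmax(floor(stats::runif(n_boot, 0.05 * N, 0.95 * N)), 1L),
                  N - 1L)
  exceed <- numeric(n); defined <- numeric(n)
  for (s in seq_len(n_boot)) {
    m <- bin_mean(circular_shift(xk, offsets[s]))
    cmp <- m > real
    ok <- !is.na(cmp)
    exceed[ok] <- exceed[ok] + cmp[ok]
    defined[ok] <- defined[ok] + 1
  }
  p <- ifelse(defined > 0, exceed / defined, NA_real_)
  low <- !is.na(p) & p <= 0.2
  candidates <- runs_at_least(low, 2)
  if (nrow(candidates)) {
    interior_short <- candidates$end - candidates$start + 1 < 3 &
      candidates$start != 1 & candidates$end != n
    candidates <- candidates[!interior_short, , drop = FALSE]
  }
  if (nrow(candidates) && !is.null(transient_mask)) {
    run_ids <- sort(unique(session$run_id))
    frac_participating <- vapply(seq_len(nrow(candidates)), function(i) {
      sel <- bins >= candidates$start[i] & bins <= candidates$end[i]
      hit <- vapply(run_ids, function(rid) {
        in_run <- session$run_id[keep] == rid & sel
        any(transient_mask[keep][in_run])
      }, logical(1))
      mean(hit)
    }, numeric(1))
    candidates <- candidates[frac_participating >= 0.1, , drop = FALSE]
  }
  high <- !is.na(p) & p >= 0.75
  out_field <- runs_at_least(high, 2)
  is_in <- rep(FALSE, n)
  for (i in seq_len(nrow(candidates)))
    is_in[candidates$start[i]:candidates$end[i]] <- TRUE
  list(p = p, mean_dff = real, in_field = candidates, out_field = out_field,
       is_in_field = is_in)
}

#' Restrict to candidate cue cells
#'
#' Keeps cells with at least one in-field period and at least one
#' out-of-field period.
#'
#' @param periods named list of [field_periods()] results.
#' @return character vector of retained cell ids.
#' @export
candidate_cells <- function(periods) {
  keep <- vapply(periods, function(p)
    nrow(p$in_field) >= 1 && nrow(p$out_field) >= 1, logical(1))
  names(periods)[keep]
}

#' Cross-environment commonality of cue-cell identity
#'
#' Fraction of track-A cue cells that are also cue cells on track B (and
#' likewise for non-cue cells), against a null band from `n_random`
#' random reassignments of the class labels that preserve each track's
#' class counts.
#'
#' @param classA,classB named logical vectors (cue-cell flags) over the
#'   same cell ids.
#' @param n_random number of random reassignments (default 50).
#' @param seed optional RNG seed.
#' @return list with `common_cue`, `common_noncue` (fractions),
#'   `random_cue` / `random_noncue` (`mean`, `sd`, `values`).
#' @export
cross_env_commonality <- function(classA, classB, n_random = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- intersect(names(classA), names(classB))
  if (!length(ids)) stop("no common cell ids between the two tracks")
  a <- classA[ids]; b <- classB[ids]
  frac <- function(x, y) {
    if (!any(x)) return(NA_real_)
    mean(y[x])
  }
  common_cue <- frac(a, b)
  common_noncue <- frac(!a, !b)
  rand <- replicate(n_random, {
    rb <- stats::setNames(sample(b), ids)
    c(cue = frac(a, rb), noncue = frac(!a, !rb))
  })
  list(common_cue = common_cue, common_noncue = common_noncue,
       random_cue = list(mean = mean(rand["cue", ], na.rm = TRUE),
                         sd = stats::sd(rand["cue", ]),
                         values = rand["cue", ]),
       random_noncue = list(mean = mean(rand["noncue", ], na.rm = TRUE),
                            sd = stats::sd(rand["noncue", ]),
                            values = rand["noncue", ]))
}

#' Cross-environment consistency of spatial shifts
#'
#' Pairs the spatial shifts of common cue cells on two tracks and returns
#' their Pearson correlation.
#'
#' @param shiftsA,shiftsB named numeric shifts (cm) per cell.
#' @param cells optional cell ids to use (default: ids present in both).
#' @return list with `pairs` (data frame `cell`, `shift_a`, `shift_b`)
#'   and `correlation` (`NA` with fewer than 3 common cells).
#' @export
cross_env_shift_consistency <- function(shiftsA, shiftsB, cells = NULL) {
  if (is.null(cells)) cells <- intersect(names(shiftsA), names(shiftsB))
  pairs <- data.frame(cell = cells,
                      shift_a = as.numeric(shiftsA[cells]),
                      shift_b = as.numeric(shiftsB[cells]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[stats::complete.cases(pairs[, c("shift_a", "shift_b")]), ]
  corr <- if (nrow(pairs) >= 3 && stats::sd(pairs$shift_a) > 0 &&
              stats::sd(pairs$shift_b) > 0)
    stats::cor(pairs$shift_a, pairs$shift_b) else NA_real_
  list(pairs = pairs, correlation = corr)
}
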