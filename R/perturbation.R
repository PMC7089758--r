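# Cue-removal perturbation analysis: per-region template correlations and
# field fractions compared between a with-cues and a missing-cues track.

#' Region-restricted template correlation at the nearest-zero lag peak
#'
#' Rate and template are restricted to the region; the lagged Pearson
#' correlation (up to +/- `max_shift_cm`) is scanned and the value at the
#' local maximum nearest zero lag is returned.
#'
#' @param rate rate vector (or track rate map).
#' @param template a [cue_template()].
#' @param region integer bin interval `c(first, last)` (inclusive).
#' @param max_shift_cm maximal |lag| (cm).
#' @param min_bins minimal region length in bins.
#' @return correlation at the nearest-zero peak, or `NA` when undefined.
#' @export
region_template_correlation <- function(rate, template, region,
                                        max_shift_cm = 300, min_bins = 10) {
  if (inherits(rate, "rate_map")) rate <- rate$rate
  stopifnot(length(region) == 2, region[1] >= 1,
            region[2] <= length(rate), region[1] <= region[2])
  if (region[2] - region[1] + 1 < min_bins)
    stop("region shorter than ", min_bins, " bins")
  r <- rate[region[1]:region[2]]
  v <- template$values[region[1]:region[2]]
  if (all(v == v[1])) return(NA_real_)
  lc <- lag_correlation(r, v, max_lag_bins = round(max_shift_cm / template$bin_size),
                        min_overlap = min_bins)
  pk <- nearest_zero_peak(lc$lag, lc$r)
  if (is.null(pk)) NA_real_ else pk$r
}

#' Fraction of a region's bins inside firing fields
#'
#' @param mask a `field_mask` or logical vector.
#' @param region integer bin interval `c(first, last)`.
#' @return fraction in `[0, 1]`.
#' @export
region_field_fraction <- function(mask, region) {
  if (inherits(mask, "field_mask")) mask <- mask$is_field
  stopifnot(length(region) == 2, region[1] >= 1, region[2] <= length(mask))
  if (region[2] < region[1]) stop("empty region")
  mean(mask[region[1]:region[2]])
}

#' Equalize run counts between two track sessions
#'
#' Truncates the session with more runs to the first `n` runs, where `n`
#' is the smaller run count, so paired comparisons use equal numbers of
#' traversals.
#'
#' @param a,b `track_session` objects.
#' @return list with the truncated sessions `a` and `b`.
#' @export
equalize_runs <- function(a, b) {
  na <- length(unique(a$run_id)); nb <- length(unique(b$run_id))
  n <- min(na, nb)
  trim <- function(s) {
    runs <- sort(unique(s$run_id))[seq_len(n)]
    subset_session(s, which(s$run_id %in% runs))
  }
  list(a = trim(a), b = trim(b))
}

#' Paired per-region comparison between two tracks
#'
#' For each cell, computes the with-cues minus missing-cues difference of
#' a per-region measure and a one-tailed paired t-test of the hypothesis
#' that the with-cues values are larger.
#'
#' @param values_a,values_b numeric per-cell measures on track A
#'   (with cues) and track B (missing cues), paired by position.
#' @return list with `differences`, `t` (statistic), `p` (one-tailed,
#'   alternative: A greater than B), `mean_difference`.
#' @export
paired_region_comparison <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  ok <- !is.na(values_a) & !is.na(values_b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  d <- values_a[ok] - values_b[ok]
  if (stats::sd(d) == 0) {
    # degenerate: identical measures on both tracks
    return(list(differences = d, t = NA_real_,
                p = if (all(d > 0)) 0 else 1, mean_difference = mean(d)))
  }
  tt <- stats::t.test(values_a[ok], values_b[ok], paired = TRUE,
                      alternative = "greater")
  list(differences = d, t = unname(tt$statistic), p = tt$p.value,
       mean_difference = mean(d))
}
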