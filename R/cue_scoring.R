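# The cue score: template cross-correlation, nearest-zero peak alignment,
# per-cue local correlations, pooled shuffle thresholds, side-specific and
# bilateral variants, and the random-template control.
#
# Sign convention (applied uniformly): a positive shift displaces the cue
# template toward larger track positions to align it with the firing rate,
# i.e. a cell firing 10 cm beyond each cue has shift +10 cm.

#' Lagged Pearson correlation between a rate vector and a template
#'
#' At lag `k` bins (positive = template moved toward larger positions) the
#' correlation uses only the overlapping segment of the two vectors; lags
#' leaving fewer than `min_overlap` overlapping bins, or whose overlap has
#' zero variance, are `NA`.
#'
#' @param rate numeric rate per bin.
#' @param values numeric template values per bin.
#' @param max_lag_bins maximal |lag| in bins (default 60, i.e. 300 cm at
#'   5 cm bins).
#' @param min_overlap minimal overlapping bins for a defined correlation.
#' @return data frame with columns `lag` (bins) and `r`.
#' @export
lag_correlation <- function(rate, values, max_lag_bins = 60, min_overlap = 10) {
  n <- length(rate)
  stopifnot(length(values) == n)
  lags <- seq(-max_lag_bins, max_lag_bins)
  # Pearson from moment sums per lag; center both vectors globally first
  # (Pearson is shift-invariant) to keep the sums well conditioned.
  rate_c <- rate - mean(rate, na.rm = TRUE)
  val_c <- values - mean(values)
  r <- vapply(lags, function(k) {
    if (abs(k) >= n) return(NA_real_)
    if (k >= 0) { x <- rate_c[(1 + k):n]; y <- val_c[1:(n - k)] }
    else        { x <- rate_c[1:(n + k)]; y <- val_c[(1 - k):n] }
    if (anyNA(x)) { ok <- !is.na(x); x <- x[ok]; y <- y[ok] }
    m <- length(x)
    if (m < min_overlap) return(NA_real_)
    sx <- sum(x); sy <- sum(y)
    vx <- sum(x * x) - sx * sx / m
    vy <- sum(y * y) - sy * sy / m
    if (vx <= 1e-12 * max(1, sum(x * x)) ||
        vy <= 1e-12 * max(1, sum(y * y))) return(NA_real_)
    (sum(x * y) - sx * sy / m) / sqrt(vx * vy)
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

# Local maxima of the lag-correlation function; boundary points count when
# they exceed their single neighbour; plateaus contribute the plateau point
# nearest zero lag. Returns the peak with smallest |lag| (ties: higher r,
# then the more negative lag, deterministically).
nearest_zero_peak <- function(lags, r) {
  ok <- !is.na(r)
  lags <- lags[ok]; r <- r[ok]
  if (length(r) < 2) return(NULL)
  runs <- rle(r)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peak_lag <- numeric(0); peak_r <- numeric(0)
  for (i in seq_along(runs$values)) {
    left_ok <- i == 1 || runs$values[i] > runs$values[i - 1]
    right_ok <- i == length(runs$values) || runs$values[i] > runs$values[i + 1]
    if (left_ok && right_ok) {
      seg <- lags[starts[i]:ends[i]]
      peak_lag <- c(peak_lag, seg[which.min(abs(seg))])
      peak_r <- c(peak_r, runs$values[i])
    }
  }
  if (!length(peak_lag)) return(NULL)
  ord <- order(abs(peak_lag), -peak_r, peak_lag)
  list(lag = peak_lag[ord[1]], r = peak_r[ord[1]])
}

# Displace a template by `shift_bins` (positive toward larger positions),
# clipping cue bins that leave the track. Returns list(values, intervals)
# where intervals keep the original (unclipped) widths for window sizing.
displace_template <- function(template, shift_bins) {
  n <- length(template$values)
  iv <- template_intervals(template)
  values <- integer(n)
  if (nrow(iv)) {
    iv$start_d <- iv$start + shift_bins
    iv$end_d <- iv$end + shift_bins
    for (k in seq_len(nrow(iv))) {
      lo <- max(1L, iv$start_d[k]); hi <- min(n, iv$end_d[k])
      if (lo <= hi) values[lo:hi] <- 1L
    }
  }
  list(values = values, intervals = iv)
}

#' Cue score of a spatial firing rate against a cue template
#'
#' Steps: (1) lagged Pearson correlation between rate and template over
#' `+/- max_shift_cm`; (2) the local maximum nearest zero lag defines the
#' spatial shift; (3) the template is displaced by that shift; (4) for each
#' cue, rate and displaced template are correlated over a window spanning
#' the cue plus half the cue width on each side (clipped at the track
#' ends; windows shorter than `min_window_bins` are excluded, as are
#' windows where either vector is constant); (5) the cue score is the mean
#' of the per-cue correlations.
#'
#' @param rate numeric rate per bin, or a [rate_map()] of kind `"track"`.
#' @param template a [cue_template()].
#' @param max_shift_cm maximal |shift| (cm), default 300.
#' @param shift_cm optional fixed shift; when supplied the lag scan is
#'   skipped and the template is displaced by exactly this amount (used by
#'   the bilateral score).
#' @param min_overlap minimal overlapping bins per lag in the scan.
#' @param min_window_bins minimal local-window length after clipping.
#' @return an object of class `cue_score_result`: list with `score`,
#'   `shift_cm`, `per_cue_r`, `peak_r` (lag-scan correlation at the chosen
#'   peak) and `aligned` (FALSE when no peak was found).
#' @export
cue_shift_and_score <- function(rate, template, max_shift_cm = 300,
                                shift_cm = NULL, min_overlap = 10,
                                min_window_bins = 3) {
  if (inherits(rate, "rate_map")) rate <- rate$rate
  bs <- template$bin_size
  stopifnot(length(rate) == length(template$values))
  peak_r <- NA_real_
  if (is.null(shift_cm)) {
    lc <- lag_correlation(rate, template$values,
                          max_lag_bins = round(max_shift_cm / bs),
                          min_overlap = min_overlap)
    pk <- nearest_zero_peak(lc$lag, lc$r)
    if (is.null(pk)) {
      return(structure(list(score = NA_real_, shift_cm = NA_real_,
                            per_cue_r = numeric(0), peak_r = NA_real_,
                            aligned = FALSE),
                       class = "cue_score_result"))
    }
    shift_bins <- pk$lag
    peak_r <- pk$r
  } else {
    shift_bins <- round(shift_cm / bs)
  }
  disp <- displace_template(template, shift_bins)
  n <- length(rate)
  per_cue_r <- rep(NA_real_, nrow(disp$intervals))
  for (k in seq_len(nrow(disp$intervals))) {
    iv <- disp$intervals[k, ]
    ext <- ceiling(iv$width / 2)
    lo <- max(1L, iv$start_d - ext); hi <- min(n, iv$end_d + ext)
    if (lo > hi || (hi - lo + 1L) < min_window_bins) next
    x <- rate[lo:hi]; y <- disp$values[lo:hi]
    ok <- !is.na(x)
    if (sum(ok) < min_window_bins) next
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    per_cue_r[k] <- stats::cor(x, y)
  }
  score <- if (any(!is.na(per_cue_r))) mean(per_cue_r, na.rm = TRUE) else NA_real_
  structure(list(score = score, shift_cm = shift_bins * bs,
                 per_cue_r = per_cue_r, peak_r = peak_r, aligned = TRUE),
            class = "cue_score_result")
}

#' Randomly redistribute the cues of a template along the track
#'
#' Produces a template with the same number of cues and identical widths,
#' placed uniformly at random among all non-overlapping on-track
#' arrangements (cue order randomized). Cues are kept at least one bin
#' apart so that distinct cues never fuse into one template interval.
#'
#' @param template a [cue_template()].
#' @return a new `cue_template`.
#' @export
shuffled_template <- function(template) {
  n <- length(template$values)
  bs <- template$bin_size
  iv <- template_intervals(template)
  k <- nrow(iv)
  if (k == 0) stop("template has no cues")
  widths <- if (k > 1) sample(iv$width) else iv$width
  free <- n - sum(widths) - (k - 1L)    # bins left after 1-bin gaps
  if (free <= 0)
    stop("cues cannot fit on the track without overlap; nothing to shuffle")
  # uniform placement with >= 1 bin between cues: sorted-sample gap trick
  s <- sort(sample.int(free + k, k))
  gaps <- s - seq_len(k)
  starts_bin <- cumsum(c(0L, widths[-k] + 1L)) + gaps  # 0-based start bins
  cues <- data.frame(start_cm = starts_bin * bs,
                     end_cm = (starts_bin + widths) * bs,
                     side = rep("both", k))
  cue_template(cues, template$track_length, bin_size = bs)
}

#' Pooled shuffled-template cue-score threshold
#'
#' Every cell is scored against `n_shuffles_per_cell` location-shuffled
#' templates; all shuffled scores are pooled and the threshold is the
#' pooled `percentile`-th percentile (linear interpolation).
#'
#' @param rates list (or matrix with cells in rows) of rate vectors, all on
#'   the template's binning.
#' @param template a [cue_template()].
#' @param n_shuffles_per_cell shuffled templates per cell (100 for
#'   spike-rate data, 200 for imaging data in the reference workflow).
#' @param percentile pooled percentile defining the threshold.
#' @param seed optional RNG seed.
#' @return an object of class `shuffle_distribution`: list with `values`
#'   (pooled shuffled scores), `percentile` and `threshold`.
#' @export
cue_threshold <- function(rates, template, n_shuffles_per_cell = 100,
                          percentile = 95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- as_rate_list(rates)
  values <- numeric(0)
  for (rate in rates) {
    sc <- vapply(seq_len(n_shuffles_per_cell), function(i)
      cue_shift_and_score(rate, shuffled_template(template))$score,
      numeric(1))
    values <- c(values, sc)
  }
  values <- values[!is.na(values)]
  if (!length(values)) stop("all shuffled cue scores undefined")
  structure(list(values = values, percentile = percentile,
                 threshold = unname(stats::quantile(values, percentile / 100,
                                                    type = 7))),
            class = "shuffle_distribution")
}

as_rate_list <- function(rates) {
  if (is.matrix(rates)) rates <- lapply(seq_len(nrow(rates)), function(i) rates[i, ])
  if (!is.list(rates)) rates <- list(rates)
  lapply(rates, function(r) if (inherits(r, "rate_map")) r$rate else r)
}

#' Score a set of cells against one template
#'
#' @inheritParams cue_threshold
#' @param ... passed to [cue_shift_and_score()].
#' @return data frame with one row per cell: `cell`, `score`, `shift_cm`.
#' @export
score_cells <- function(rates, template, ...) {
  rates <- as_rate_list(rates)
  res <- lapply(rates, cue_shift_and_score, template = template, ...)
  data.frame(cell = if (is.null(names(rates))) seq_along(rates) else names(rates),
             score = vapply(res, `[[`, numeric(1), "score"),
             shift_cm = vapply(res, `[[`, numeric(1), "shift_cm"),
             stringsAsFactors = FALSE)
}

#' Classify cue cells against a shuffle threshold
#'
#' A cell is a cue cell when its cue score strictly exceeds the threshold;
#' an undefined score is never classified.
#'
#' @param scores numeric cue scores (e.g. column `score` of
#'   [score_cells()]).
#' @param threshold scalar threshold or a [cue_threshold()] result.
#' @return logical vector of class flags.
#' @export
classify_cue_cells <- function(scores, threshold) {
  if (inherits(threshold, "shuffle_distribution")) threshold <- threshold$threshold
  !is.na(scores) & scores > threshold
}

#' Side-specific cue-cell classification
#'
#' Cells passing only one side's threshold are assigned to that side;
#' cells passing both go to the side with the higher score (an exact tie
#' is left unassigned with a warning); cells passing neither are non-cue.
#'
#' @param rates list of rate vectors.
#' @param left_template,right_template side-specific [cue_template()]s on
#'   the same track.
#' @param left_threshold,right_threshold thresholds for the two templates
#'   (scalars or [cue_threshold()] results).
#' @return data frame with `cell`, `left_score`, `left_shift_cm`,
#'   `right_score`, `right_shift_cm`, `side` (`"left"`, `"right"` or
#'   `NA`).
#' @export
side_classify <- function(rates, left_template, right_template,
                          left_threshold, right_threshold) {
  L <- score_cells(rates, left_template)
  R <- score_cells(rates, right_template)
  pl <- classify_cue_cells(L$score, left_threshold)
  pr <- classify_cue_cells(R$score, right_threshold)
  side <- rep(NA_character_, nrow(L))
  side[pl & !pr] <- "left"
  side[pr & !pl] <- "right"
  both <- pl & pr
  if (any(both)) {
    hi_l <- both & L$score > R$score
    hi_r <- both & R$score > L$score
    side[hi_l] <- "left"; side[hi_r] <- "right"
    tie <- both & L$score == R$score
    if (any(tie)) warning(sum(tie), " cell(s) tie left and right scores; side left unassigned")
  }
  data.frame(cell = L$cell, left_score = L$score, left_shift_cm = L$shift_cm,
             right_score = R$score, right_shift_cm = R$shift_cm,
             side = side, stringsAsFactors = FALSE)
}

#' Bilateral score (left minus right cue score at the preferred shift)
#'
#' The cell is aligned to its preferred side's template at that template's
#' own best shift S; the other side's cue score is then evaluated with its
#' template displaced by the same S. The bilateral score is always
#' left score minus right score.
#'
#' @param rate rate vector (or track rate map).
#' @param left_template,right_template side templates.
#' @param preferred_side `"left"` or `"right"`.
#' @return list with `bilateral` (L - R), `preferred_score`,
#'   `other_score`, `shift_cm`.
#' @export
bilateral_score <- function(rate, left_template, right_template,
                            preferred_side = c("left", "right")) {
  preferred_side <- match.arg(preferred_side)
  pref_t <- if (preferred_side == "left") left_template else right_template
  other_t <- if (preferred_side == "left") right_template else left_template
  pref <- cue_shift_and_score(rate, pref_t)
  if (!pref$aligned || is.na(pref$score))
    return(list(bilateral = NA_real_, preferred_score = NA_real_,
                other_score = NA_real_, shift_cm = NA_real_))
  other <- cue_shift_and_score(rate, other_t, shift_cm = pref$shift_cm)
  bil <- if (preferred_side == "left") pref$score - other$score
         else other$score - pref$score
  list(bilateral = bil, preferred_score = pref$score,
       other_score = other$score, shift_cm = pref$shift_cm)
}

#' Random-template control for cue-cell percentages
#'
#' Re-runs the full classification (shuffle threshold plus thresholding)
#' with the real template and with `n_random` location-shuffled templates,
#' recomputing the threshold for every template.
#'
#' @inheritParams cue_threshold
#' @param n_random number of random templates.
#' @param n_shuffles_per_cell shuffled templates per cell for each
#'   threshold.
#' @return list with `real_pct` and `random_pct` (length `n_random`).
#' @export
random_template_percentage_control <- function(rates, template, n_random,
                                               n_shuffles_per_cell = 100,
                                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- as_rate_list(rates)
  pct_for <- function(tmpl) {
    thr <- cue_threshold(rates, tmpl, n_shuffles_per_cell)
    sc <- score_cells(rates, tmpl)
    100 * mean(classify_cue_cells(sc$score, thr))
  }
  real_pct <- pct_for(template)
  random_pct <- if (n_random > 0)
    vapply(seq_len(n_random), function(i) pct_for(shuffled_template(template)),
           numeric(1))
  else numeric(0)
  list(real_pct = real_pct, random_pct = random_pct)
}
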