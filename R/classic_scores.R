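# Grid, head-direction, border and split-half stability scores with
# circular spike-time shuffle thresholds, plus duplicate-unit removal.

#' Unbiased 2D spatial autocorrelogram
#'
#' Pearson correlation of the rate map with itself at every 2D offset,
#' computed over the mutually valid overlapping bins of each offset.
#' Offsets with fewer than `min_overlap` overlapping valid bins are `NA`.
#'
#' @param map a [rate_map()] of kind `"arena"`, or a numeric matrix with
#'   `NA` marking invalid bins.
#' @param min_overlap minimal overlapping bins per offset.
#' @return a `(2n-1) x (2m-1)` matrix of correlations; the center element
#'   is the zero-offset correlation (1).
#' @export
autocorr2d <- function(map, min_overlap = 20) {
  X <- if (inherits(map, "rate_map")) map$rate else map
  stopifnot(is.matrix(X))
  V <- ifelse(is.na(X), 0, 1)
  if (sum(V) < min_overlap) stop("fewer than min_overlap valid bins")
  X0 <- ifelse(is.na(X), 0, X)
  nn <- round(xcorr2(V, V))
  Sx <- xcorr2(X0, V); Sy <- xcorr2(V, X0)
  Sxy <- xcorr2(X0, X0)
  Sxx <- xcorr2(X0^2, V); Syy <- xcorr2(V, X0^2)
  num <- nn * Sxy - Sx * Sy
  d1 <- nn * Sxx - Sx^2
  d2 <- nn * Syy - Sy^2
  eps <- 1e-9 * max(abs(Sxx), 1)
  r <- ifelse(nn >= min_overlap & d1 > eps & d2 > eps,
              num / sqrt(pmax(d1, 0) * pmax(d2, 0)), NA_real_)
  pmin(pmax(r, -1), 1)
}

# linear 2D cross-correlation sums via FFT:
# out[di + n, dj + m] = sum_{i,j} A[i, j] * B[i + di, j + dj]
xcorr2 <- function(A, B) {
  n <- nrow(A); m <- ncol(A)
  P <- 2L * n - 1L; Q <- 2L * m - 1L
  pa <- matrix(0, P, Q); pa[1:n, 1:m] <- A
  pb <- matrix(0, P, Q); pb[1:n, 1:m] <- B
  cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE)) / (P * Q)
  cc[c((n + 1):P, 1:n), c((m + 1):Q, 1:m)]
}

# Bilinear rotation of a square matrix about its center; cells whose
# source falls outside the grid, or touches an NA neighbour, become NA.
# Interpolation geometry is cached per (size, angle).
.rot_cache <- new.env(parent = emptyenv())

rotate_matrix <- function(A, theta_deg) {
  n <- nrow(A)
  stopifnot(n == ncol(A))
  key <- sprintf("%d_%g", n, theta_deg)
  g <- .rot_cache[[key]]
  if (is.null(g)) {
    c0 <- (n + 1) / 2
    th <- theta_deg * pi / 180
    u <- rep(seq_len(n) - c0, times = n)
    v <- rep(seq_len(n) - c0, each = n)
    su <- cos(th) * u + sin(th) * v + c0
    sv <- -sin(th) * u + cos(th) * v + c0
    i0 <- floor(su); j0 <- floor(sv)
    fi <- su - i0; fj <- sv - j0
    inside <- i0 >= 1 & i0 + 1 <= n & j0 >= 1 & j0 + 1 <= n
    i0[!inside] <- 1L; j0[!inside] <- 1L
    g <- list(idx = cbind((j0 - 1L) * n + i0,
                          (j0 - 1L) * n + i0 + 1L,
                          j0 * n + i0,
                          j0 * n + i0 + 1L),
              w = cbind((1 - fi) * (1 - fj), fi * (1 - fj),
                        (1 - fi) * fj, fi * fj),
              inside = inside)
    .rot_cache[[key]] <- g
  }
  a <- as.vector(A)
  out <- g$w[, 1] * a[g$idx[, 1]] + g$w[, 2] * a[g$idx[, 2]] +
    g$w[, 3] * a[g$idx[, 3]] + g$w[, 4] * a[g$idx[, 4]]
  out[!g$inside] <- NA_real_
  matrix(out, n, n)
}

#' Grid score of an arena rate map
#'
#' From the autocorrelogram, an inner radius is taken as the smallest of
#' (i) the first local minimum of the radial mean profile, (ii) the first
#' radius at which the profile turns negative, and (iii) 10 cm. Annuli
#' between the inner radius and every outer radius from inner + 4 bins to
#' the autocorrelogram's maximal radius - 4 bins are correlated with their
#' rotations by 30..150 degrees in 30-degree steps; each annulus scores
#' max(r60, r120) - min(r30, r90, r150) and the grid score is the maximum
#' over annuli.
#'
#' @param map a [rate_map()] of kind `"arena"` or a matrix.
#' @param bin_size bin width (cm); taken from the map when available.
#' @param min_overlap passed to [autocorr2d()].
#' @return grid score (scalar), or `NA` when undefined.
#' @export
grid_score <- function(map, bin_size = NULL, min_overlap = 20) {
  if (inherits(map, "rate_map")) {
    if (is.null(bin_size)) bin_size <- map$bin_size
  }
  if (is.null(bin_size)) bin_size <- 2.5
  ac <- try(autocorr2d(map, min_overlap = min_overlap), silent = TRUE)
  if (inherits(ac, "try-error")) return(NA_real_)
  n <- nrow(ac)
  c0 <- (n + 1) / 2
  dist <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
  maxrad <- (n - 1) / 2
  ring <- round(dist)
  prof <- vapply(0:maxrad, function(k) mean(ac[ring == k], na.rm = TRUE),
                 numeric(1))
  first_min <- NA_integer_
  for (k in 2:(length(prof) - 1))
    if (!anyNA(prof[(k - 1):(k + 1)]) &&
        prof[k] < prof[k - 1] && prof[k] < prof[k + 1]) { first_min <- k - 1L; break }
  first_neg <- which(prof < 0)[1] - 1L
  inner <- min(c(first_min, first_neg, round(10 / bin_size)), na.rm = TRUE)
  if (inner + 4 > maxrad - 4) return(NA_real_)
  outers <- seq(inner + 4, maxrad - 4)
  rots <- lapply(c(30, 60, 90, 120, 150), function(th) rotate_matrix(ac, th))
  best <- NA_real_
  for (outer in outers) {
    ann <- dist > inner & dist <= outer
    v0 <- ac[ann]
    rr <- vapply(rots, function(R) {
      v1 <- R[ann]
      ok <- !is.na(v0) & !is.na(v1)
      if (sum(ok) < 3 || stats::sd(v0[ok]) == 0 || stats::sd(v1[ok]) == 0)
        return(NA_real_)
      stats::cor(v0[ok], v1[ok])
    }, numeric(1))
    if (anyNA(rr)) next
    val <- max(rr[c(2, 4)]) - min(rr[c(1, 3, 5)])
    if (is.na(best) || val > best) best <- val
  }
  best
}

#' Head-direction score (mean vector length) and preferred angle
#'
#' The score is the length of the rate-weighted mean vector of the tuning
#' curve, `|sum(r_k exp(i theta_k))| / sum(r_k)`; the preferred angle is
#' its orientation.
#'
#' @param tuning a [rate_map()] of kind `"angular"` or a numeric rate
#'   vector over equally spaced angular bins.
#' @param bin_deg angular bin width (degrees) when `tuning` is a vector.
#' @return named vector `c(score = , angle_deg = )`; `NA`s when the total
#'   rate is zero.
#' @export
hd_score <- function(tuning, bin_deg = 3) {
  if (inherits(tuning, "rate_map")) { bin_deg <- tuning$bin_size; tuning <- tuning$rate }
  r <- ifelse(is.na(tuning), 0, tuning)
  if (sum(r) == 0) return(c(score = NA_real_, angle_deg = NA_real_))
  theta <- (seq_along(r) - 0.5) * bin_deg * pi / 180
  mv <- sum(r * exp(1i * theta)) / sum(r)
  c(score = Mod(mv), angle_deg = (Arg(mv) * 180 / pi) %% 360)
}

#' Border score of an arena rate map
#'
#' Firing fields are 4-connected components of bins exceeding
#' `field_threshold` times the peak rate with an area of at least
#' `min_area_cm2`. cM is the maximal fraction of any single wall's bins
#' touched by a single field; dM is the rate-weighted mean distance of all
#' field bins to their nearest wall, normalized by half the arena width.
#' The score is (cM - dM) / (cM + dM).
#'
#' @param map a [rate_map()] of kind `"arena"` or a matrix.
#' @param bin_size bin width (cm).
#' @param field_threshold field threshold as a fraction of the peak rate.
#' @param min_area_cm2 minimal field area (cm^2).
#' @return border score, or `NA` when no field qualifies.
#' @export
border_score <- function(map, bin_size = NULL, field_threshold = 0.3,
                         min_area_cm2 = 200) {
  if (inherits(map, "rate_map")) {
    if (is.null(bin_size)) bin_size <- map$bin_size
    map <- map$rate
  }
  if (is.null(bin_size)) bin_size <- 2.5
  stopifnot(is.matrix(map))
  n <- nrow(map); m <- ncol(map)
  peak <- max(map, na.rm = TRUE)
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  mask <- !is.na(map) & map > field_threshold * peak
  if (!any(mask)) return(NA_real_)
  lab <- matrix(as.integer(EBImage::bwlabel(matrix(as.integer(mask), n, m))),
                n, m)
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas * bin_size^2 >= min_area_cm2])
  if (!length(keep)) return(NA_real_)
  wall_of <- function(l) {
    f <- lab == l
    max(sum(f[1, ]) / m, sum(f[n, ]) / m, sum(f[, 1]) / n, sum(f[, m]) / n)
  }
  cM <- max(vapply(keep, wall_of, numeric(1)))
  fb <- which(matrix(lab %in% keep, n, m), arr.ind = TRUE)
  d_wall <- (pmin(fb[, 1], n + 1 - fb[, 1], fb[, 2], m + 1 - fb[, 2]) - 0.5) *
    bin_size
  w <- map[fb]
  dM <- sum(w * d_wall) / sum(w) / (n * bin_size / 2)
  (cM - dM) / (cM + dM)
}

#' Split-half stability of spatial or head-direction firing
#'
#' The session is split at its temporal midpoint, the map is computed for
#' each half, and the stability is the Pearson correlation over bins valid
#' in both halves.
#'
#' @param session an `arena_session` (or `track_session` with
#'   `kind = "spatial"`, correlating track rate maps).
#' @param unit unit id.
#' @param kind `"spatial"` or `"hd"`.
#' @param min_bins minimal mutually valid bins (default 20).
#' @return Pearson correlation, or `NA` when undefined.
#' @export
split_half_stability <- function(session, unit, kind = c("spatial", "hd"),
                                 min_bins = 20) {
  kind <- match.arg(kind)
  tmid <- (session$time[1] + session$time[length(session$time)]) / 2
  h1 <- subset_session(session, which(session$time <= tmid))
  h2 <- subset_session(session, which(session$time > tmid))
  mapper <- if (kind == "hd") hd_tuning else
    if (inherits(session, "arena_session")) arena_ratemap else track_ratemap
  m1 <- try(mapper(h1, unit), silent = TRUE)
  m2 <- try(mapper(h2, unit), silent = TRUE)
  if (inherits(m1, "try-error") || inherits(m2, "try-error")) return(NA_real_)
  x <- as.vector(m1$rate); y <- as.vector(m2$rate)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_bins) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Circularly shift a unit's spike times
#'
#' Spike times are rotated by `offset` seconds around the recording
#' (modulo its length), preserving the spike count and the inter-spike
#' structure.
#'
#' @param spike_times numeric spike times (s).
#' @param t0,t1 recording start and end (s).
#' @param offset shift (s).
#' @return shifted, sorted spike times within `[t0, t1]`.
#' @export
circular_shift_spikes <- function(spike_times, t0, t1, offset) {
  L <- t1 - t0
  sort(((spike_times - t0 + offset) %% L) + t0)
}

#' Pooled circular spike-time shuffle threshold for a score
#'
#' For each unit, `n_shuffles` surrogate sessions are built by circularly
#' permuting that unit's spike times by offsets drawn uniformly between
#' 50% and 95% of the recording length; the score is recomputed on each
#' surrogate, all units' shuffled scores are pooled, and the threshold is
#' the pooled `percentile`-th percentile.
#'
#' @param session a session object carrying all units' spikes.
#' @param units character vector of unit ids.
#' @param score_fn function `(session, unit) -> scalar score` (e.g. a
#'   wrapper around [grid_score()]).
#' @param n_shuffles shuffles per unit (default 100).
#' @param percentile pooled percentile.
#' @param seed optional RNG seed.
#' @return a `shuffle_distribution` (see [cue_threshold()]).
#' @export
score_shuffle_threshold <- function(session, units, score_fn,
                                    n_shuffles = 100, percentile = 95,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- session$time[1]; t1 <- session$time[length(session$time)]
  L <- t1 - t0
  values <- numeric(0)
  for (u in units) {
    st <- session$spikes[[as.character(u)]]
    offs <- stats::runif(n_shuffles, 0.5 * L, 0.95 * L)
    sc <- vapply(offs, function(off) {
      surr <- session
      surr$spikes[[as.character(u)]] <- circular_shift_spikes(st, t0, t1, off)
      as.numeric(score_fn(surr, u)[1])
    }, numeric(1))
    values <- c(values, sc)
  }
  values <- values[!is.na(values)]
  if (!length(values)) stop("all shuffled scores undefined")
  structure(list(values = values, percentile = percentile,
                 threshold = unname(stats::quantile(values, percentile / 100,
                                                    type = 7))),
            class = "shuffle_distribution")
}

# log-binned inter-spike-interval histogram similarity used by the
# within-day duplicate rule: correlation of the merged train's ISI
# histogram with each cluster's own, averaged. Sub-refractory ISIs
# (duplicate detections of the same spike) are dropped first, so two cuts
# of the same cell merge to an ISI histogram matching each cut's own.
isi_similarity <- function(st1, st2, breaks = 10^seq(-3, 1, length.out = 31),
                           refractory_s = 0.0015) {
  isi_hist <- function(st) {
    isi <- diff(sort(st))
    isi <- isi[isi >= refractory_s]
    isi <- pmin(isi, breaks[length(breaks)])
    if (!length(isi)) return(numeric(length(breaks) - 1))
    h <- graphics::hist(isi, breaks = breaks, plot = FALSE)$counts
    h / max(sum(h), 1)
  }
  h1 <- isi_hist(st1); h2 <- isi_hist(st2)
  hm <- isi_hist(c(st1, st2))
  if (stats::sd(hm) == 0 || stats::sd(h1) == 0 || stats::sd(h2) == 0)
    return(NA_real_)
  mean(c(stats::cor(hm, h1), stats::cor(hm, h2)))
}

#' Remove duplicate units within and across recording days
#'
#' Units first pass inclusion gates (at least `min_spikes` spikes, track
#' rate minimum at most `max_min_rate` Hz and maximum at most
#' `max_max_rate` Hz). Within a day, a pair whose arena-map correlation
#' plus track-map correlation plus ISI-histogram similarity exceeds
#' `sum_threshold` is a duplicate; the cluster with more spikes is kept.
#' Across days, a pair whose arena-map correlation is at least
#' `arena_cor_min` or whose track-map correlation is at least
#' `track_cor_min` is a duplicate; the unit with the higher arena peak
#' rate is kept.
#'
#' @param units list of unit records, each a list with `id`, `day`,
#'   `spikes` (numeric spike times), `arena_map` (matrix or `rate_map`),
#'   `track_map` (numeric vector or `rate_map`).
#' @param sum_threshold within-day duplicate threshold on the summed
#'   scores (default 2.25).
#' @param arena_cor_min,track_cor_min cross-day correlation thresholds
#'   (defaults 0.8 and 0.75).
#' @param min_spikes,max_min_rate,max_max_rate inclusion gates.
#' @return list with `kept` (ids), `excluded` (ids failing gates) and
#'   `pairs` (data frame of examined pairs and decisions).
#' @export
deduplicate_units <- function(units, sum_threshold = 2.25,
                              arena_cor_min = 0.8, track_cor_min = 0.75,
                              min_spikes = 100, max_min_rate = 10,
                              max_max_rate = 50) {
  get_rate <- function(x) if (inherits(x, "rate_map")) x$rate else x
  info <- lapply(units, function(u) {
    tr <- get_rate(u$track_map)
    list(id = u$id, day = u$day, spikes = u$spikes,
         n_spikes = length(u$spikes),
         arena = as.vector(get_rate(u$arena_map)),
         arena_peak = suppressWarnings(max(get_rate(u$arena_map), na.rm = TRUE)),
         track = tr,
         track_min = min(tr, na.rm = TRUE), track_max = max(tr, na.rm = TRUE))
  })
  pass <- vapply(info, function(u)
    u$n_spikes >= min_spikes && u$track_min <= max_min_rate &&
      u$track_max <= max_max_rate, logical(1))
  excluded <- vapply(info[!pass], `[[`, character(1), "id")
  info <- info[pass]
  alive <- rep(TRUE, length(info))
  pair_rows <- list()
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  if (length(info) > 1) {
    for (i in seq_len(length(info) - 1)) for (j in (i + 1):length(info)) {
      if (!alive[i] || !alive[j]) next
      a <- info[[i]]; b <- info[[j]]
      ca <- safe_cor(a$arena, b$arena)
      ct <- safe_cor(a$track, b$track)
      if (is.na(ca) || is.na(ct)) {
        warning(sprintf("pair %s/%s skipped: undefined map correlation",
                        a$id, b$id))
        next
      }
      if (identical(a$day, b$day)) {
        s <- ca + ct + isi_similarity(a$spikes, b$spikes)
        dup <- !is.na(s) && s > sum_threshold
        if (dup) alive[if (a$n_spikes >= b$n_spikes) j else i] <- FALSE
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          id1 = a$id, id2 = b$id, type = "within_day", arena_cor = ca,
          track_cor = ct, total = s, duplicate = dup)
      } else {
        dup <- ca >= arena_cor_min || ct >= track_cor_min
        if (dup) alive[if (a$arena_peak >= b$arena_peak) j else i] <- FALSE
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          id1 = a$id, id2 = b$id, type = "cross_day", arena_cor = ca,
          track_cor = ct, total = NA_real_, duplicate = dup)
      }
    }
  }
  list(kept = vapply(info[alive], `[[`, character(1), "id"),
       excluded = excluded,
       pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
         data.frame(id1 = character(0), id2 = character(0),
                    type = character(0), arena_cor = numeric(0),
                    track_cor = numeric(0), total = numeric(0),
                    duplicate = logical(0)))
}
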