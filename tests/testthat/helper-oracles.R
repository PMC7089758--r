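# Brute-force reference implementations, written independently of the
# package internals (plain loops, stats::cor) and used to pin down the
# optimized code paths.

# exhaustive lagged-correlation cue score: scans every lag with cor(),
# picks the local maximum nearest zero, then averages per-cue local
# window correlations of the displaced template.
oracle_cue_score <- function(rate, template, max_lag_bins = 60,
                             min_overlap = 10, min_window = 3) {
  n <- length(rate)
  vals <- template$values
  lags <- seq(-max_lag_bins, max_lag_bins)
  r <- sapply(lags, function(k) {
    idx <- seq_len(n)
    src <- idx - k
    ok <- src >= 1 & src <= n & !is.na(rate)
    if (sum(ok) < min_overlap) return(NA)
    x <- rate[idx[ok]]; y <- vals[src[ok]]
    if (sd(x) == 0 || sd(y) == 0) return(NA)
    cor(x, y)
  })
  # local maxima incl. boundaries; plateau -> point nearest zero
  peaks <- data.frame(lag = integer(0), r = numeric(0))
  i <- 1
  good <- which(!is.na(r))
  lg <- lags[good]; rg <- r[good]
  m <- length(rg)
  while (i <= m) {
    j <- i
    while (j < m && rg[j + 1] == rg[i]) j <- j + 1
    left_up <- i == 1 || rg[i] > rg[i - 1]
    right_up <- j == m || rg[j] > rg[j + 1]
    if (left_up && right_up) {
      seg <- lg[i:j]
      peaks <- rbind(peaks,
                     data.frame(lag = seg[which.min(abs(seg))], r = rg[i]))
    }
    i <- j + 1
  }
  if (nrow(peaks) == 0) return(list(score = NA, shift_bins = NA))
  ord <- order(abs(peaks$lag), -peaks$r, peaks$lag)
  shift <- peaks$lag[ord[1]]
  # displaced template and merged cue intervals
  rl <- rle(vals)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
  cs <- starts[rl$values == 1]; ce <- ends[rl$values == 1]
  disp <- integer(n)
  for (k in seq_along(cs)) {
    lo <- max(1, cs[k] + shift); hi <- min(n, ce[k] + shift)
    if (lo <= hi) disp[lo:hi] <- 1L
  }
  rs <- c()
  for (k in seq_along(cs)) {
    w <- ce[k] - cs[k] + 1
    ext <- ceiling(w / 2)
    lo <- max(1, cs[k] + shift - ext); hi <- min(n, ce[k] + shift + ext)
    if (lo > hi) next
    x <- rate[lo:hi]; y <- disp[lo:hi]
    ok <- !is.na(x)
    if (sum(ok) < min_window) next
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    rs <- c(rs, cor(x[ok], y[ok]))
  }
  list(score = if (length(rs)) mean(rs) else NA,
       shift_bins = shift)
}

# direct-loop masked 2D autocorrelation
oracle_autocorr <- function(X, min_overlap = 20) {
  n <- nrow(X); m <- ncol(X)
  out <- matrix(NA_real_, 2 * n - 1, 2 * m - 1)
  for (di in -(n - 1):(n - 1)) for (dj in -(m - 1):(m - 1)) {
    xs <- c(); ys <- c()
    for (i in 1:n) for (j in 1:m) {
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= n && j2 >= 1 && j2 <= m &&
          !is.na(X[i, j]) && !is.na(X[i2, j2])) {
        xs <- c(xs, X[i, j]); ys <- c(ys, X[i2, j2])
      }
    }
    if (length(xs) >= min_overlap && sd(xs) > 0 && sd(ys) > 0)
      out[di + n, dj + m] <- cor(xs, ys)
  }
  out
}

# direct bilinear rotation (no caching)
oracle_rotate <- function(A, theta_deg) {
  n <- nrow(A)
  c0 <- (n + 1) / 2
  th <- theta_deg * pi / 180
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    u <- i - c0; v <- j - c0
    su <- cos(th) * u + sin(th) * v + c0
    sv <- -sin(th) * u + cos(th) * v + c0
    i0 <- floor(su); j0 <- floor(sv)
    if (i0 < 1 || i0 + 1 > n || j0 < 1 || j0 + 1 > n) next
    fi <- su - i0; fj <- sv - j0
    vals <- c(A[i0, j0], A[i0 + 1, j0], A[i0, j0 + 1], A[i0 + 1, j0 + 1])
    w <- c((1 - fi) * (1 - fj), fi * (1 - fj), (1 - fi) * fj, fi * fj)
    out[i, j] <- sum(w * vals)
  }
  out
}

# full brute-force grid score following the same definition
oracle_grid_score <- function(X, bin_size = 2.5, min_overlap = 20) {
  ac <- oracle_autocorr(X, min_overlap)
  n <- nrow(ac)
  c0 <- (n + 1) / 2
  dist <- sqrt(outer((1:n - c0)^2, (1:n - c0)^2, `+`))
  maxrad <- (n - 1) / 2
  prof <- sapply(0:maxrad, function(k) mean(ac[round(dist) == k], na.rm = TRUE))
  first_min <- NA
  for (k in 2:(length(prof) - 1))
    if (!anyNA(prof[(k - 1):(k + 1)]) && prof[k] < prof[k - 1] &&
        prof[k] < prof[k + 1]) { first_min <- k - 1; break }
  first_neg <- which(prof < 0)[1] - 1
  inner <- min(c(first_min, first_neg, round(10 / bin_size)), na.rm = TRUE)
  if (inner + 4 > maxrad - 4) return(NA)
  best <- NA
  for (outer in (inner + 4):(maxrad - 4)) {
    ann <- dist > inner & dist <= outer
    v0 <- ac[ann]
    rr <- sapply(c(30, 60, 90, 120, 150), function(th) {
      R <- oracle_rotate(ac, th)
      v1 <- R[ann]
      ok <- !is.na(v0) & !is.na(v1)
      if (sum(ok) < 3 || sd(v0[ok]) == 0 || sd(v1[ok]) == 0) return(NA)
      cor(v0[ok], v1[ok])
    })
    if (anyNA(rr)) next
    val <- max(rr[c(2, 4)]) - min(rr[c(1, 3, 5)])
    if (is.na(best) || val > best) best <- val
  }
  best
}

# direct ridge/background recomputation
oracle_ridge <- function(rate, template, shift_cm, ridge_bins = 5,
                         bg_from = 20, bg_to = 30) {
  bs <- template$bin_size
  n <- length(rate)
  shift <- round(shift_cm / bs)
  rl <- rle(template$values)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
  cs <- starts[rl$values == 1] + shift
  ce <- ends[rl$values == 1] + shift
  in_cue <- rep(FALSE, n)
  for (k in seq_along(cs)) {
    lo <- max(1, cs[k]); hi <- min(n, ce[k])
    if (lo <= hi) in_cue[lo:hi] <- TRUE
  }
  ratios <- c()
  for (k in seq_along(cs)) {
    ctr <- (cs[k] + ce[k]) %/% 2
    half <- (ridge_bins - 1) / 2
    ridge <- (ctr - half):(ctr + half)
    ridge <- ridge[ridge >= 1 & ridge <= n]
    if (!length(ridge)) next
    hw <- (ce[k] - cs[k] + 1) * bs / 2
    d <- abs(((1:n) - 0.5) * bs - (ctr - 0.5) * bs)
    bg <- which(d > hw + bg_from & d <= hw + bg_to & !in_cue)
    if (!length(bg)) next
    bm <- mean(rate[bg], na.rm = TRUE)
    if (!is.finite(bm) || bm == 0) next
    ratios <- c(ratios, mean(rate[ridge], na.rm = TRUE) / bm)
  }
  if (length(ratios)) mean(ratios) else NA
}

# direct region-restricted nearest-zero peak correlation
oracle_region_corr <- function(rate, template, region, max_lag_bins = 60,
                               min_overlap = 10) {
  r <- rate[region[1]:region[2]]
  v <- template$values[region[1]:region[2]]
  n <- length(r)
  lags <- seq(-max_lag_bins, max_lag_bins)
  cc <- sapply(lags, function(k) {
    idx <- seq_len(n); src <- idx - k
    ok <- src >= 1 & src <= n & !is.na(r)
    if (sum(ok) < min_overlap) return(NA)
    x <- r[idx[ok]]; y <- v[src[ok]]
    if (sd(x) == 0 || sd(y) == 0) return(NA)
    cor(x, y)
  })
  good <- which(!is.na(cc))
  lg <- lags[good]; rg <- cc[good]
  m <- length(rg)
  if (m < 2) return(NA)
  peaks <- data.frame(lag = integer(0), r = numeric(0))
  i <- 1
  while (i <= m) {
    j <- i
    while (j < m && rg[j + 1] == rg[i]) j <- j + 1
    if ((i == 1 || rg[i] > rg[i - 1]) && (j == m || rg[j] > rg[j + 1])) {
      seg <- lg[i:j]
      peaks <- rbind(peaks, data.frame(lag = seg[which.min(abs(seg))],
                                       r = rg[i]))
    }
    i <- j + 1
  }
  if (!nrow(peaks)) return(NA)
  peaks$r[order(abs(peaks$lag), -peaks$r, peaks$lag)][1]
}
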