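# Shared binning convention: bin i (1-based index) covers
# [(i-1)*bin_size, i*bin_size) cm, half-open; a position exactly at the far
# track end falls in the last bin.

#' Map positions to spatial bin indices
#'
#' Bins are half-open intervals `[(i-1)*bin_size, i*bin_size)`; a position
#' exactly equal to `extent` is assigned to the last bin.
#'
#' @param x numeric positions (cm).
#' @param bin_size bin width (cm).
#' @param extent total extent covered by the bins (cm).
#' @return integer bin indices in `1:ceiling(extent / bin_size)`.
#' @export
position_to_bin <- function(x, bin_size, extent) {
  n <- n_bins(extent, bin_size)
  i <- floor(x / bin_size) + 1L
  i[x >= extent] <- n
  i[x < 0] <- 1L
  as.integer(i)
}

#' @rdname position_to_bin
#' @export
n_bins <- function(extent, bin_size) as.integer(ceiling(extent / bin_size))

#' Construct a linear-track session
#'
#' A track session holds a time-aligned trajectory along a unidirectional
#' virtual track, run (traversal) labels, and the spike trains (and
#' optionally dF/F traces) observed during it.
#'
#' @param time sample times (s), strictly increasing.
#' @param position positions along the track (cm) in `[0, track_length]`.
#' @param track_length track length (cm).
#' @param spikes named list of numeric spike-time vectors, one per unit.
#' @param dff optional named list of dF/F vectors, one value per sample.
#' @param run_id optional integer run label per sample; inferred from
#'   teleports (backward jumps larger than half the track) when `NULL`.
#' @param position_tol tolerance (cm) for positions slightly out of bounds.
#' @return an object of class `track_session`.
#' @export
track_session <- function(time, position, track_length, spikes = list(),
                          dff = NULL, run_id = NULL, position_tol = 1) {
  time <- as.numeric(time); position <- as.numeric(position)
  stopifnot(length(time) == length(position), track_length > 0)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("sample times must be strictly increasing")
  bad <- which(position < -position_tol | position > track_length + position_tol)
  if (length(bad))
    stop(sprintf("position out of [0, %g] at row %d (%.2f cm)",
                 track_length, bad[1], position[bad[1]]))
  position <- pmin(pmax(position, 0), track_length)
  if (is.null(run_id)) {
    run_id <- if (length(position) == 0) integer(0) else
      cumsum(c(0L, as.integer(diff(position) < -track_length / 2)))
  }
  spikes <- validate_spikes(spikes, time)
  if (!is.null(dff)) {
    if (is.null(names(dff)) || !is.list(dff)) stop("dff must be a named list")
    for (nm in names(dff))
      if (length(dff[[nm]]) != length(time))
        stop(sprintf("dff trace '%s' length differs from trajectory", nm))
  }
  structure(list(time = time, position = position, run_id = as.integer(run_id),
                 track_length = as.numeric(track_length), spikes = spikes,
                 dff = dff),
            class = "track_session")
}

#' Construct an open-arena session
#'
#' @param time sample times (s), strictly increasing.
#' @param x,y positions (cm) inside `[0, arena_size]`.
#' @param head_direction head direction (degrees); wrapped into `[0, 360)`.
#' @param arena_size side of the square arena (cm).
#' @param spikes named list of spike-time vectors per unit.
#' @param position_tol tolerance (cm) for positions slightly out of bounds.
#' @return an object of class `arena_session`.
#' @export
arena_session <- function(time, x, y, head_direction, arena_size = 50,
                          spikes = list(), position_tol = 1) {
  time <- as.numeric(time)
  stopifnot(length(x) == length(time), length(y) == length(time),
            length(head_direction) == length(time))
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("sample times must be strictly increasing")
  for (v in list(x = x, y = y)) {
    bad <- which(v < -position_tol | v > arena_size + position_tol)
    if (length(bad))
      stop(sprintf("position outside [0, %g] arena at row %d (%.2f cm)",
                   arena_size, bad[1], v[bad[1]]))
  }
  structure(list(time = time,
                 x = pmin(pmax(as.numeric(x), 0), arena_size),
                 y = pmin(pmax(as.numeric(y), 0), arena_size),
                 head_direction = as.numeric(head_direction) %% 360,
                 arena_size = as.numeric(arena_size),
                 spikes = validate_spikes(spikes, time)),
            class = "arena_session")
}

validate_spikes <- function(spikes, time) {
  if (length(spikes) == 0) return(stats::setNames(list(), character(0)))
  if (is.null(names(spikes))) stop("spikes must be a named list")
  if (length(time)) {
    span <- range(time)
    for (nm in names(spikes)) {
      st <- as.numeric(spikes[[nm]])
      out <- which(st < span[1] | st > span[2])
      if (length(out))
        stop(sprintf("spike of unit '%s' at %.3f s outside trajectory span [%.3f, %.3f]",
                     nm, st[out[1]], span[1], span[2]))
      spikes[[nm]] <- sort(st)
    }
  }
  spikes
}

#' Median sampling interval of a session
#' @param session a `track_session` or `arena_session`.
#' @return the median inter-sample interval (s).
#' @export
sample_dt <- function(session) {
  if (length(session$time) < 2) stop("need at least 2 samples")
  stats::median(diff(session$time))
}

#' Read a linear-track session from TSV files
#'
#' The trajectory file is tab-separated with header columns `time_s` and
#' `pos_cm`; the spike file has `unit_id` and `time_s` (it may contain only
#' the header). Runs are split where the position jumps backward by more
#' than half the track length (a teleport back to the start).
#'
#' @param trajectory_path,spikes_path file paths.
#' @param track_length track length (cm).
#' @param dff_path optional TSV with columns `cell_id` plus one `dff` value
#'   per trajectory sample (long format: `cell_id`, `time_s`, `dff`).
#' @return a [track_session()].
#' @export
read_track_session <- function(trajectory_path, spikes_path, track_length,
                               dff_path = NULL) {
  traj <- read_tsv_checked(trajectory_path, c("time_s", "pos_cm"))
  if (is.unsorted(traj$time_s, strictly = TRUE))
    stop("non-monotonic time in ", trajectory_path)
  spk <- read_tsv_checked(spikes_path, c("unit_id", "time_s"))
  spikes <- split(spk$time_s, factor(spk$unit_id))
  dff <- NULL
  if (!is.null(dff_path)) {
    d <- read_tsv_checked(dff_path, c("cell_id", "time_s", "dff"))
    dff <- lapply(split(d, factor(d$cell_id)), function(g) g$dff[order(g$time_s)])
  }
  track_session(traj$time_s, traj$pos_cm, track_length, spikes = spikes,
                dff = dff)
}

#' Read an open-arena session from TSV files
#'
#' Trajectory columns: `time_s`, `x_cm`, `y_cm`, `hd_deg` (head direction is
#' wrapped into `[0, 360)`); spike columns as in [read_track_session()].
#'
#' @inheritParams read_track_session
#' @param arena_size arena side (cm).
#' @return an [arena_session()].
#' @export
read_arena_session <- function(trajectory_path, spikes_path, arena_size = 50) {
  traj <- read_tsv_checked(trajectory_path, c("time_s", "x_cm", "y_cm", "hd_deg"))
  if (is.unsorted(traj$time_s, strictly = TRUE))
    stop("non-monotonic time in ", trajectory_path)
  spk <- read_tsv_checked(spikes_path, c("unit_id", "time_s"))
  arena_session(traj$time_s, traj$x_cm, traj$y_cm, traj$hd_deg,
                arena_size = arena_size,
                spikes = split(spk$time_s, factor(spk$unit_id)))
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df
}

#' Construct a binary cue template over track bins
#'
#' A template has value 1 in every bin that overlaps the interval between
#' the front and back edge of some cue, and 0 elsewhere; a cue edge that
#' falls mid-bin marks the whole bin.
#'
#' @param cues data frame with columns `start_cm`, `end_cm` and optionally
#'   `side` (one of `"left"`, `"right"`, `"both"`; default `"both"`).
#' @param track_length track length (cm).
#' @param bin_size bin width (cm), default 5.
#' @param side restrict the template to cues on this side (`"both"` keeps
#'   all cues; `"left"`/`"right"` keep cues on that side plus bilateral
#'   cues labelled `"both"` are excluded).
#' @return an object of class `cue_template` with fields `values`
#'   (0/1 per bin), `cues`, `bin_size`, `track_length`.
#' @export
cue_template <- function(cues, track_length, bin_size = 5, side = "both") {
  stopifnot(is.data.frame(cues), all(c("start_cm", "end_cm") %in% names(cues)))
  if (!"side" %in% names(cues)) cues$side <- "both"
  if (side != "both") cues <- cues[cues$side == side, , drop = FALSE]
  if (nrow(cues) && any(cues$end_cm <= cues$start_cm))
    stop("cue end must exceed cue start")
  if (nrow(cues) && any(cues$start_cm < 0 | cues$end_cm > track_length))
    stop("cues must lie within the track")
  n <- n_bins(track_length, bin_size)
  values <- integer(n)
  for (k in seq_len(nrow(cues))) {
    lo <- floor(cues$start_cm[k] / bin_size) + 1
    hi <- ceiling(cues$end_cm[k] / bin_size)
    values[lo:min(hi, n)] <- 1L
  }
  structure(list(values = values, cues = cues, bin_size = bin_size,
                 track_length = track_length, side = side),
            class = "cue_template")
}

#' Merged cue intervals of a template, in bins
#'
#' Runs of 1s in the template; overlapping or bin-adjacent cues merge into
#' one interval.
#'
#' @param template a [cue_template()].
#' @return data frame with `start`, `end` (inclusive bin indices) and
#'   `width` (bins).
#' @export
template_intervals <- function(template) {
  r <- rle(template$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep],
             width = r$lengths[keep])
}

#' Read a cue table and build a template
#'
#' The cue TSV has columns `cue_id`, `start_cm`, `end_cm`, `side`.
#'
#' @inheritParams cue_template
#' @param path cue TSV path.
#' @return a [cue_template()].
#' @export
read_cue_template <- function(path, track_length, bin_size = 5, side = "both") {
  cues <- read_tsv_checked(path, c("start_cm", "end_cm"))
  cue_template(cues, track_length, bin_size = bin_size, side = side)
}

#' Construct a rate map object
#'
#' @param kind `"track"`, `"arena"` or `"angular"`.
#' @param occupancy raw occupancy per bin (s).
#' @param count raw spike count per bin.
#' @param rate smoothed rate per bin (Hz); `NA` where undefined.
#' @param valid logical validity mask.
#' @param bin_size bin width (cm or degrees).
#' @return an object of class `rate_map`.
#' @export
rate_map <- function(kind, occupancy, count, rate, valid, bin_size) {
  stopifnot(kind %in% c("track", "arena", "angular"))
  structure(list(kind = kind, occupancy = occupancy, count = count,
                 rate = rate, valid = valid, bin_size = bin_size),
            class = "rate_map")
}

#' Write / read a per-cell score table
#'
#' Tables are UTF-8 tab-separated with a header row; numeric values are
#' written with enough digits that a write/read round trip is bit-exact.
#'
#' @param panel data frame of per-cell scores, thresholds and class flags.
#' @param path output path.
#' @return `write_score_table` returns `path` invisibly;
#'   `read_score_table` returns the data frame.
#' @export
write_score_table <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  out <- panel
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      # keep a decimal point so the column reads back as double
      whole <- !grepl("[.eE]", s) & !is.na(out[[j]])
      s[whole] <- paste0(s[whole], ".0")
      s[is.na(out[[j]])] <- "NA"
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Restrict a session to a subset of samples
#'
#' Spikes are kept when they fall inside a retained inter-sample interval
#' (assigned to the nearest preceding sample).
#'
#' @param session a `track_session` or `arena_session`.
#' @param idx integer indices of samples to keep (must be contiguous for
#'   meaningful rate maps, e.g. a session half).
#' @return a session of the same class.
#' @export
subset_session <- function(session, idx) {
  idx <- sort(unique(as.integer(idx)))
  span <- range(session$time[idx])
  keep_spikes <- function(st) {
    j <- findInterval(st, session$time)
    # clamp spikes falling in the last retained inter-sample interval
    pmin(pmax(st[j %in% idx], span[1]), span[2])
  }
  spikes <- lapply(session$spikes, keep_spikes)
  if (inherits(session, "track_session")) {
    track_session(session$time[idx], session$position[idx],
                  session$track_length, spikes = spikes,
                  run_id = session$run_id[idx],
                  dff = if (!is.null(session$dff))
                    lapply(session$dff, `[`, idx))
  } else {
    arena_session(session$time[idx], session$x[idx], session$y[idx],
                  session$head_direction[idx], session$arena_size,
                  spikes = spikes)
  }
}
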