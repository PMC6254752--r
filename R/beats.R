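## beats: R-peak beat segmentation, systolic upstroke-onset detection by a
## backward linear-regression search, moving-window beat groups, and
## cycle-length matching of representative groups across runs.

#' Split a continuous waveform into beats at R-peaks
#'
#' Beat `i` spans the half-open column interval `[peak_i, peak_{i+1})`;
#' `n - 1` beats are produced from `n` peaks. The time axis is converted to
#' seconds from the opening R-peak using the waveform's time calibration.
#'
#' @param waveform a `raw_waveform`.
#' @param r_peaks ordered integer column indices of detected R-peaks.
#' @param run_id acquisition run label attached to each beat.
#' @return list of `waveform_beat` objects with fields `times` (s),
#'   `values`, `kind`, `onset_index` (NA until detected), `duration` (s),
#'   `run_id`, `beat_index`, `flag`.
#' @export
segment_beats <- function(waveform, r_peaks, run_id = 1L) {
  stopifnot(inherits(waveform, "raw_waveform"))
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 2L) {
    stop("segmentation error: need >= 2 R-peaks, got ", length(r_peaks),
         call. = FALSE)
  }
  if (is.unsorted(r_peaks, strictly = TRUE)) {
    stop("r_peaks must be strictly increasing", call. = FALSE)
  }
  nc <- length(waveform$values)
  if (r_peaks[1L] < 1L || r_peaks[length(r_peaks)] > nc) {
    stop("r_peaks outside the waveform", call. = FALSE)
  }
  dt <- waveform$time_cal / 1000   # s per column
  lapply(seq_len(length(r_peaks) - 1L), function(i) {
    cols <- seq.int(r_peaks[i], r_peaks[i + 1L] - 1L)
    structure(
      list(times = (cols - cols[1L]) * dt,
           values = waveform$values[cols],
           kind = waveform$kind,
           onset_index = NA_integer_,
           duration = (r_peaks[i + 1L] - r_peaks[i]) * dt,
           run_id = as.integer(run_id),
           beat_index = i,
           flag = NA_character_),
      class = "waveform_beat")
  })
}

#' Detect the onset of the systolic upstroke
#'
#' The onset is the data point after which the waveform begins its
#' quasi-linear early-systolic rise. Starting from the middle of the
#' systolic part — the temporal midpoint between the pre-peak minimum (the
#' foot search region) and the beat maximum — the search moves down point
#' by point; at each candidate the r-squared of the linear regression of
#' the segment from the candidate up to mid-systole is computed. The first
#' candidate where r-squared drops below `r2_min` stops the search and the
#' preceding point is the onset. If no candidate fails, the pre-peak
#' minimum itself is the onset.
#'
#' @param beat a `waveform_beat` with >= 10 samples.
#' @param r2_min r-squared threshold (default 0.985).
#' @return the beat with `onset_index` set (1-based sample index), plus
#'   attribute fields `onset_r2` and `mid_systole_index` for audit. A beat
#'   with no upstroke (maximum at the first sample) gets `flag = "no_upstroke"`.
#' @export
detect_upstroke_onset <- function(beat, r2_min = 0.985) {
  stopifnot(inherits(beat, "waveform_beat"))
  v <- beat$values
  n <- length(v)
  if (n < 10L) stop("beat has fewer than 10 samples", call. = FALSE)
  m <- which.max(v)
  if (m <= 2L) {
    beat$flag <- "no_upstroke"
    return(beat)
  }
  f <- which.min(v[seq_len(m)])
  s <- as.integer(floor((f + m) / 2))
  beat$mid_systole_index <- s
  if (s - f < 1L) {
    beat$flag <- "no_upstroke"
    return(beat)
  }
  # r2 of segments [k, s] for k = s-1 ... f via one reversed cumulative pass
  xs <- rev(beat$times[seq.int(f, s)])
  ys <- rev(v[seq.int(f, s)])
  r2 <- prefix_r2(xs, ys)          # r2[j] = segment of the last j points up to s
  onset <- f
  for (k in seq.int(s - 1L, f)) {
    j <- s - k + 1L
    if (!is.na(r2[j]) && r2[j] < r2_min) {
      onset <- k + 1L
      break
    }
  }
  beat$onset_index <- as.integer(onset)
  beat$onset_r2 <- if (onset > f) r2[s - onset + 1L] else r2[s - f + 1L]
  if (onset >= m) beat$flag <- "no_upstroke"
  beat
}

#' Form all six-beat moving-window groups
#'
#' @param beats list of consecutive `waveform_beat`s from one run
#'   (beat_index incrementing by 1, none flagged).
#' @param group_size beats per group (default 6).
#' @return list of `beat_group` objects (`beats`, `mean_duration`, `run_id`,
#'   `start_beat_index`), one per window position: `n - group_size + 1`.
#' @export
select_groups <- function(beats, group_size = 6L) {
  group_size <- as_count(group_size, "group_size")
  n <- length(beats)
  if (n < group_size) {
    stop("insufficient-beats error: ", n, " usable beats, need >= ",
         group_size, call. = FALSE)
  }
  idx <- vapply(beats, `[[`, integer(1), "beat_index")
  if (n > 1L && any(diff(idx) != 1L)) {
    stop("beats must be consecutive (beat_index incrementing by 1)",
         call. = FALSE)
  }
  durs <- vapply(beats, `[[`, numeric(1), "duration")
  lapply(seq_len(n - group_size + 1L), function(i) {
    w <- seq.int(i, i + group_size - 1L)
    structure(
      list(beats = beats[w],
           mean_duration = mean(durs[w]),
           run_id = beats[[i]]$run_id,
           start_beat_index = idx[i]),
      class = "beat_group")
  })
}

#' Longest run of consecutive unflagged beats
#'
#' Group selection operates on the longest stretch of beats that passed
#' onset detection, so one bad beat does not invalidate a whole run.
#'
#' @param beats list of `waveform_beat`s in beat order.
#' @return the sub-list forming the longest consecutive unflagged run.
#' @export
longest_unflagged_run <- function(beats) {
  ok <- vapply(beats, function(b) is.na(b$flag) && !is.na(b$onset_index),
               logical(1))
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which(r$values)[which.max(r$lengths[r$values])]
  beats[seq.int(starts[best], ends[best])]
}

#' Pick the representative group pair for a D/U run pair
#'
#' Of all candidate six-beat groups from one diameter run and one velocity
#' run, the pair whose mean cycle durations agree most closely (most similar
#' heart rate) is selected as representative. Ties are broken by the
#' earliest start beat in D, then in U.
#'
#' @param d_groups,u_groups lists of `beat_group`s from one run each.
#' @return list with elements `d` and `u`, the selected groups.
#' @export
match_groups <- function(d_groups, u_groups) {
  if (length(d_groups) == 0L || length(u_groups) == 0L) {
    stop("both group lists must be non-empty", call. = FALSE)
  }
  dd <- vapply(d_groups, `[[`, numeric(1), "mean_duration")
  du <- vapply(u_groups, `[[`, numeric(1), "mean_duration")
  ds <- vapply(d_groups, `[[`, integer(1), "start_beat_index")
  us <- vapply(u_groups, `[[`, integer(1), "start_beat_index")
  grid <- expand.grid(i = seq_along(d_groups), j = seq_along(u_groups))
  diff <- abs(dd[grid$i] - du[grid$j])
  ord <- order(diff, ds[grid$i], us[grid$j])
  pick <- grid[ord[1L], ]
  list(d = d_groups[[pick$i]], u = u_groups[[pick$j]])
}
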