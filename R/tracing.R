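## tracing: threshold-based wall tracing on M-mode images, maximum Doppler
## envelope extraction, spline smoothing / gap filling, diameter assembly.

#' Trace one arterial wall on an M-mode image
#'
#' Within a user-declared region of interest the wall position per column is
#' found by grayscale thresholding. The inner (lumen-facing) edge is kept:
#' the deepest suprathreshold pixel for the near (anterior) wall, the
#' shallowest for the far (posterior) wall. Columns with no suprathreshold
#' pixel, or inside declared artefact-exclusion intervals, are marked
#' missing and later filled by [smooth_trace()].
#'
#' An automatic artefact pass drops points more than 3 median absolute
#' deviations from a rolling median — a reproducible surrogate for the
#' manual artefact removal performed when tracing interactively.
#'
#' @param rec an M-mode [us_recording].
#' @param wall `"near"` or `"far"`.
#' @param roi half-open `[start, end)` row range to search.
#' @param threshold grayscale cutoff; pixels strictly above it are wall.
#' @param exclusions list of half-open `[start, end)` column intervals to
#'   discard as artefacts.
#' @param mad_k rolling-median outlier cutoff in MADs (default 3; `Inf`
#'   disables the automatic pass).
#' @return an object of class `wall_trace` with per-column `rows`
#'   (NA = missing), plus `wall`, `roi`, `threshold`, `exclusions`.
#' @export
trace_wall <- function(rec, wall = c("near", "far"), roi, threshold,
                       exclusions = list(), mad_k = 3) {
  stopifnot(inherits(rec, "us_recording"))
  if (rec$modality != "mmode") stop("trace_wall expects an mmode recording",
                                    call. = FALSE)
  wall <- match.arg(wall)
  rows <- range_idx(roi, nrow(rec$pixels), "roi")
  nc <- ncol(rec$pixels)
  sub <- rec$pixels[rows, , drop = FALSE]
  mask <- sub > threshold
  hit <- which(mask, arr.ind = TRUE)
  pos <- rep(NA_real_, nc)
  if (nrow(hit) > 0L) {
    agg <- if (wall == "near") max else min
    v <- tapply(hit[, "row"], hit[, "col"], agg)
    pos[as.integer(names(v))] <- rows[as.integer(v)]
  }
  for (ex in exclusions) pos[range_idx(ex, nc, "exclusion")] <- NA_real_
  pos <- drop_rolling_outliers(pos, mad_k, min_scale = 1)   # 1 pixel row
  missing_frac <- mean(is.na(pos))
  if (missing_frac > 0.6) {
    stop(sprintf(
      "tracing-quality error: %.0f%% of columns have no wall pixel; adjust the threshold (currently %g)",
      100 * missing_frac, threshold), call. = FALSE)
  }
  structure(
    list(rows = pos, wall = wall, roi = roi, threshold = threshold,
         exclusions = exclusions, smoothed = FALSE),
    class = "wall_trace")
}

#' Drop isolated artefact points that sit far off a rolling median.
#'
#' The robust scale is floored at `min_scale` (the quantization step of the
#' traced quantity, ~1 pixel): sub-pixel staircase wiggle on a steep
#' upstroke must never be treated as an artefact, or the systolic limb
#' would be systematically thinned and flattened by the gap-filling spline.
#' @noRd
drop_rolling_outliers <- function(pos, mad_k, half_window = 7L,
                                  min_scale = 1) {
  if (!is.finite(mad_k)) return(pos)
  ok <- which(!is.na(pos))
  if (length(ok) < 2L * half_window) return(pos)
  med <- stats::runmed(pos[ok], 2L * half_window + 1L, endrule = "median")
  dev <- abs(pos[ok] - med)
  s <- max(stats::mad(dev, center = 0), min_scale)
  pos[ok[dev > mad_k * s]] <- NA_real_
  pos
}

#' Smooth a wall trace and fill its gaps
#'
#' Fits a smoothing spline to the defined points of the trace and evaluates
#' it at every column, simultaneously smoothing the tracing and filling the
#' gaps left by thresholding and artefact exclusion. The smoothing parameter
#' follows the csaps convention on the pixel axis (`p = 0.001` by default):
#' `p = 1` interpolates, smaller `p` smooths harder.
#'
#' @param trace a `wall_trace` (or any list with a numeric `rows` field).
#' @param smoothing_parameter csaps-style p in (0, 1], default 0.001.
#' @return the trace with `rows` defined and finite at every column.
#' @export
smooth_trace <- function(trace, smoothing_parameter = 0.001) {
  pos <- trace$rows
  ok <- which(!is.na(pos))
  if (length(ok) < 4L) {
    stop("insufficient-data error: ", length(ok),
         " defined points (need >= 4) for spline smoothing", call. = FALSE)
  }
  trace$rows <- csaps_fit(ok, pos[ok], smoothing_parameter, seq_along(pos))
  trace$smoothed <- TRUE
  trace
}

#' Raw waveform container
#'
#' One continuous extracted waveform on the image's column grid.
#'
#' @param values numeric vector, cm (diameter) or m/s (velocity).
#' @param time_cal ms per column.
#' @param kind `"diameter"` or `"velocity"`.
#' @return an object of class `raw_waveform`.
#' @export
raw_waveform <- function(values, time_cal, kind = c("diameter", "velocity")) {
  kind <- match.arg(kind)
  if (any(!is.finite(values))) {
    stop("waveform contains non-finite values", call. = FALSE)
  }
  if (kind == "diameter" && any(values <= 0)) {
    stop("diameter values must be strictly positive (ln is taken later)",
         call. = FALSE)
  }
  structure(list(values = as.numeric(values), time_cal = as.numeric(time_cal),
                 kind = kind),
            class = "raw_waveform")
}

#' Diameter waveform from two smoothed wall traces
#'
#' The diameter is measured inner edge to inner edge: the far-wall row minus
#' the near-wall row, converted to centimetres by the depth calibration.
#'
#' @param near,far smoothed `wall_trace` objects (gap-free).
#' @param value_cal cm per pixel row.
#' @param time_cal ms per pixel column.
#' @return a `raw_waveform` of kind `"diameter"`.
#' @export
diameter_waveform <- function(near, far, value_cal, time_cal) {
  if (anyNA(near$rows) || anyNA(far$rows)) {
    stop("wall traces must be smoothed/gap-free; call smooth_trace() first",
         call. = FALSE)
  }
  if (length(near$rows) != length(far$rows)) {
    stop("wall traces have different column counts", call. = FALSE)
  }
  sep <- far$rows - near$rows
  if (any(sep <= 0)) {
    stop("anatomical-implausibility error: walls cross at column(s) ",
         paste(utils::head(which(sep <= 0), 5L), collapse = ", "),
         call. = FALSE)
  }
  raw_waveform(sep * value_cal, time_cal, "diameter")
}

#' Trace the maximum Doppler envelope
#'
#' Per column (from `start_column` on), the envelope is the suprathreshold
#' pixel farthest from the zero-velocity baseline on the forward-flow side;
#' its distance from the baseline times the velocity calibration gives the
#' maximum velocity. Missing and excluded columns are filled with the same
#' smoothing-spline procedure as the walls.
#'
#' @param rec a Doppler [us_recording] with `baseline_row` set.
#' @param threshold grayscale cutoff.
#' @param start_column first column to trace (earlier columns are treated as
#'   missing and filled).
#' @param exclusions list of half-open column intervals to discard.
#' @param flow_side side of the baseline carrying forward flow: `"above"`
#'   (smaller row indices, the usual display) or `"below"`.
#' @param smoothing_parameter csaps-style p for gap filling (default 0.001).
#' @param mad_k rolling-median outlier cutoff in MADs (default 3; `Inf`
#'   disables the automatic artefact pass).
#' @return a `raw_waveform` of kind `"velocity"`.
#' @export
trace_doppler_envelope <- function(rec, threshold, start_column = 1L,
                                   exclusions = list(),
                                   flow_side = c("above", "below"),
                                   smoothing_parameter = 0.001, mad_k = 3) {
  stopifnot(inherits(rec, "us_recording"))
  if (rec$modality != "doppler" || is.null(rec$baseline_row)) {
    stop("trace_doppler_envelope expects a doppler recording with a baseline",
         call. = FALSE)
  }
  flow_side <- match.arg(flow_side)
  start_column <- as_count(start_column, "start_column")
  nc <- ncol(rec$pixels)
  if (start_column < 1L || start_column > nc) {
    stop("start_column outside the image", call. = FALSE)
  }
  b <- rec$baseline_row
  rows <- if (flow_side == "above") seq_len(b) else seq.int(b, nrow(rec$pixels))
  sub <- rec$pixels[rows, , drop = FALSE]
  mask <- sub > threshold
  hit <- which(mask, arr.ind = TRUE)
  env_row <- rep(NA_real_, nc)
  if (nrow(hit) > 0L) {
    # farthest from baseline: minimal row above, maximal row below
    agg <- if (flow_side == "above") min else max
    v <- tapply(hit[, "row"], hit[, "col"], agg)
    env_row[as.integer(names(v))] <- rows[as.integer(v)]
  }
  if (start_column > 1L) env_row[seq_len(start_column - 1L)] <- NA_real_
  for (ex in exclusions) env_row[range_idx(ex, nc, "exclusion")] <- NA_real_
  vel <- if (flow_side == "above") (b - env_row) else (env_row - b)
  vel <- vel * rec$value_cal
  vel <- drop_rolling_outliers(vel, mad_k, min_scale = rec$value_cal)
  missing_frac <- mean(is.na(vel))
  if (missing_frac > 0.6) {
    stop(sprintf(
      "tracing-quality error: %.0f%% of columns below threshold %g",
      100 * missing_frac, threshold), call. = FALSE)
  }
  # the envelope is smoothed and gap-filled by the same spline procedure as
  # the walls ("a similar code"): thresholded envelope samples carry pixel
  # quantization plus spectral flicker, and the downstream regression rules
  # (upstroke onset 0.985, loop fit 0.98) are calibrated for traces of
  # wall-smoothing quality
  ok <- which(!is.na(vel))
  vel <- csaps_fit(ok, vel[ok], smoothing_parameter, seq_len(nc))
  raw_waveform(vel, rec$time_cal, "velocity")
}
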