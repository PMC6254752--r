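## ecg: extract the ECG strip rendered inside the image and detect R-peaks.

#' Extract the ECG trace from a recording's strip band
#'
#' Within the declared ECG band, the trace row for each column is the
#' intensity-weighted centroid of the pixels above the strip's intensity
#' floor (robust to a trace rendered 2-3 pixels thick). The amplitude is
#' expressed in pixels above the bottom row of the band. Columns with no
#' suprathreshold pixel are filled by linear interpolation from their
#' neighbours.
#'
#' @param rec an [us_recording] with a valid `ecg_band`.
#' @param floor_fraction fraction of the band's intensity range above its
#'   minimum used as the intensity floor (default 0.5).
#' @return an object of class `ecg_trace` with fields `amplitude` (per
#'   column, pixels), `time_cal` (ms per column), `threshold_fraction`
#'   (populated by [detect_r_peaks()]), and `r_peaks`.
#' @export
extract_ecg_trace <- function(rec, floor_fraction = 0.5) {
  stopifnot(inherits(rec, "us_recording"))
  if (is.null(rec$ecg_band)) {
    stop("extraction error: recording has no ecg_band", call. = FALSE)
  }
  rows <- range_idx(rec$ecg_band, nrow(rec$pixels), "ecg_band")
  if (length(rows) < 3L) {
    stop("extraction error: ecg_band must span >= 3 rows", call. = FALSE)
  }
  band <- rec$pixels[rows, , drop = FALSE]
  rng <- range(band)
  if (rng[2] <= rng[1]) {
    stop("extraction error: ECG strip has uniform intensity", call. = FALSE)
  }
  floor_int <- rng[1] + floor_fraction * (rng[2] - rng[1])
  mask <- band > floor_int
  hits <- colSums(mask)
  if (mean(hits == 0L) > 0.5) {
    stop("extraction error: no ECG signal in >50% of columns", call. = FALSE)
  }
  w <- (band - floor_int) * mask
  # centroid row (within band, 1-based from band top) per column
  rowidx <- matrix(seq_along(rows), nrow = length(rows), ncol = ncol(band))
  centroid <- colSums(w * rowidx) / colSums(w)
  centroid[hits == 0L] <- NA_real_
  amplitude <- length(rows) - centroid   # pixels above the band's bottom row
  amplitude <- fill_na_linear(amplitude)
  structure(
    list(amplitude = amplitude, time_cal = rec$time_cal,
         threshold_fraction = NA_real_, r_peaks = integer()),
    class = "ecg_trace")
}

#' Detect R-wave peaks by threshold crossing
#'
#' The threshold is height-relative: `min + threshold_fraction * (max - min)`
#' of the amplitude over the whole run. For every upward crossing, the column
#' of maximum amplitude before the next downward crossing is taken as the
#' R-peak. Crossings closer than `refractory_columns` to the previously
#' accepted peak are skipped, preventing double detection on noisy strips.
#'
#' @param trace an `ecg_trace` (or bare numeric amplitude vector).
#' @param threshold_fraction fraction of the ECG height (default 0.8).
#' @param refractory_columns minimum column separation between accepted
#'   peaks. The pipeline default corresponds to 200 ms.
#' @return integer vector of peak column indices (possibly empty).
#' @export
detect_r_peaks <- function(trace, threshold_fraction = 0.8,
                           refractory_columns = 57L) {
  amp <- if (inherits(trace, "ecg_trace")) trace$amplitude else as.numeric(trace)
  if (length(amp) < 2L) stop("trace must have >= 2 columns", call. = FALSE)
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  }
  refractory_columns <- as_count(refractory_columns, "refractory_columns")
  rng <- range(amp)
  thr <- rng[1] + threshold_fraction * (rng[2] - rng[1])
  above <- amp >= thr
  if (!any(above) || all(above)) return(integer())
  d <- diff(above)
  ups <- which(d == 1L) + 1L         # first column at/above threshold
  downs <- which(d == -1L) + 1L     # first column back below threshold
  if (above[1L]) ups <- c(1L, ups)
  peaks <- integer()
  last <- -Inf
  for (u in ups) {
    if (u - last < refractory_columns) next
    dn <- downs[downs > u]
    end <- if (length(dn)) dn[1L] - 1L else length(amp)
    seg <- seq.int(u, end)
    pk <- seg[which.max(amp[seg])]
    peaks <- c(peaks, pk)
    last <- pk
  }
  peaks
}
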