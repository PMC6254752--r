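## image_io: cine recordings as concatenated pixel matrices + calibrations.
##
## Supported cine dialect ("pwvloop-cine-1"): a recording is a directory of
## plain-text frame matrices plus a JSON sidecar carrying the calibrations.
## Frames contribute strictly ordered time columns; an optional integer
## overlap per frame pair is declared in the sidecar and removed
## deterministically, keeping the earlier frame's columns.

CINE_FORMAT <- "pwvloop-cine-1"

#' Ultrasound recording container
#'
#' Holds one acquisition run as a single concatenated grayscale image:
#' rows are depth (M-mode) or velocity (Doppler), columns are time.
#'
#' @param pixels numeric matrix, grayscale intensities (>= 0), rows x columns.
#' @param modality `"mmode"` or `"doppler"`.
#' @param time_cal milliseconds per pixel column (> 0).
#' @param value_cal cm per pixel row (M-mode) or m/s per pixel row (Doppler),
#'   (> 0).
#' @param baseline_row row index of zero velocity; required for Doppler,
#'   forbidden for M-mode.
#' @param ecg_band half-open `[start, end)` row range (1-based) containing the
#'   ECG strip, or `NULL` if the recording has none.
#' @param run_id acquisition run label (integer).
#' @param suggest optional list of tracing hints (ROIs, thresholds) carried in
#'   the sidecar; a reproducible surrogate for the interactive ROI clicks used
#'   when recordings are traced by hand.
#' @return an object of class `us_recording`.
#' @export
us_recording <- function(pixels, modality, time_cal, value_cal,
                         baseline_row = NULL, ecg_band = NULL, run_id = 1L,
                         suggest = NULL) {
  modality <- match.arg(modality, c("mmode", "doppler"))
  if (!is.matrix(pixels) || nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("pixels must be a matrix with >= 2 rows and >= 2 columns",
         call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixels must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(time_cal) || length(time_cal) != 1L || !is.finite(time_cal) ||
      time_cal <= 0) {
    stop("calibration error: time_cal must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(value_cal) || length(value_cal) != 1L ||
      !is.finite(value_cal) || value_cal <= 0) {
    stop("calibration error: value_cal must be a positive scalar", call. = FALSE)
  }
  if (modality == "doppler") {
    if (is.null(baseline_row)) {
      stop("calibration error: baseline_row is required for doppler",
           call. = FALSE)
    }
    baseline_row <- as_count(baseline_row, "baseline_row")
    if (baseline_row < 1L || baseline_row > nrow(pixels)) {
      stop("baseline_row outside the image", call. = FALSE)
    }
  } else if (!is.null(baseline_row)) {
    stop("baseline_row is only meaningful for doppler recordings",
         call. = FALSE)
  }
  if (!is.null(ecg_band)) {
    rows <- range_idx(ecg_band, nrow(pixels), "ecg_band")
    if (length(rows) < 3L) stop("ecg_band must span >= 3 rows", call. = FALSE)
    ecg_band <- c(as.integer(ecg_band[1]), as.integer(ecg_band[2]))
  }
  structure(
    list(pixels = pixels, modality = modality,
         time_cal = as.numeric(time_cal), value_cal = as.numeric(value_cal),
         baseline_row = baseline_row, ecg_band = ecg_band,
         run_id = as.integer(run_id), suggest = suggest),
    class = "us_recording")
}

#' @export
print.us_recording <- function(x, ...) {
  cat(sprintf(
    "<us_recording> %s run %d: %d rows x %d cols, %.4g ms/px, %.4g %s/px\n",
    x$modality, x$run_id, nrow(x$pixels), ncol(x$pixels),
    x$time_cal, x$value_cal, if (x$modality == "mmode") "cm" else "m/s"))
  invisible(x)
}

#' Concatenate cine frames into one continuous image
#'
#' Frames are spliced along the time (column) axis. When consecutive frames
#' overlap (the later frame repeats the last `k` columns of the earlier one),
#' the duplicated leading columns of the later frame are dropped, keeping the
#' earlier frame's columns.
#'
#' @param frames list of numeric matrices with identical row counts, in time
#'   order.
#' @param overlap integer overlap between each consecutive frame pair: a
#'   scalar recycled to all pairs or a vector of length `length(frames) - 1`.
#' @return one numeric matrix.
#' @export
concatenate_frames <- function(frames, overlap = 0L) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("frames must be a non-empty list of matrices", call. = FALSE)
  }
  heights <- vapply(frames, nrow, integer(1))
  if (length(unique(heights)) != 1L) {
    stop("shape error: frames have mismatched heights (",
         paste(unique(heights), collapse = ", "), ")", call. = FALSE)
  }
  nf <- length(frames)
  if (nf == 1L) return(frames[[1L]])
  overlap <- as.integer(overlap)
  if (length(overlap) == 1L) overlap <- rep(overlap, nf - 1L)
  if (length(overlap) != nf - 1L || any(overlap < 0L)) {
    stop("overlap must be a non-negative scalar or length(frames)-1 vector",
         call. = FALSE)
  }
  pieces <- vector("list", nf)
  pieces[[1L]] <- frames[[1L]]
  for (i in seq_len(nf - 1L)) {
    f <- frames[[i + 1L]]
    k <- overlap[i]
    if (k >= ncol(f)) {
      stop("overlap ", k, " swallows frame ", i + 1L, " entirely",
           call. = FALSE)
    }
    pieces[[i + 1L]] <- f[, seq.int(k + 1L, ncol(f)), drop = FALSE]
  }
  do.call(cbind, pieces)
}

#' Read a cine recording from disk
#'
#' Reads the supported cine dialect: a directory with a `meta.json` sidecar
#' (calibrations, ECG band, per-frame overlap) and one plain-text matrix per
#' frame. Frames are concatenated via [concatenate_frames()].
#'
#' @param path recording directory.
#' @param modality expected modality, `"mmode"` or `"doppler"`.
#' @return an [us_recording].
#' @export
read_recording <- function(path, modality = c("mmode", "doppler")) {
  modality <- match.arg(modality)
  meta_path <- file.path(path, "meta.json")
  if (!dir.exists(path) || !file.exists(meta_path)) {
    stop("parse error: '", path, "' is not a readable recording directory",
         call. = FALSE)
  }
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) {
                     stop("parse error reading ", meta_path, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (!identical(meta$format, CINE_FORMAT)) {
    stop("parse error: unsupported cine format '", meta$format %||% "<none>",
         "'", call. = FALSE)
  }
  for (field in c("modality", "time_cal_ms", "value_cal", "frame_files")) {
    if (is.null(meta[[field]])) {
      stop("calibration error: sidecar is missing required field '", field,
           "'", call. = FALSE)
    }
  }
  if (!identical(meta$modality, modality)) {
    stop("recording is '", meta$modality, "' but '", modality,
         "' was requested", call. = FALSE)
  }
  if (modality == "doppler" && is.null(meta$baseline_row)) {
    stop("calibration error: sidecar is missing required field 'baseline_row'",
         call. = FALSE)
  }
  frames <- lapply(file.path(path, meta$frame_files), function(f) {
    if (!file.exists(f)) stop("parse error: missing frame file ", f,
                              call. = FALSE)
    m <- unname(as.matrix(data.table::fread(f, header = FALSE, sep = "\t")))
    storage.mode(m) <- "double"
    m
  })
  pixels <- concatenate_frames(frames, overlap = meta$frame_overlap %||% 0L)
  us_recording(pixels, modality,
               time_cal = meta$time_cal_ms,
               value_cal = meta$value_cal,
               baseline_row = if (modality == "doppler") meta$baseline_row,
               ecg_band = if (!is.null(meta$ecg_band)) unlist(meta$ecg_band),
               run_id = meta$run_id %||% 1L,
               suggest = meta$suggest)
}

#' Write a recording as a cine fixture directory
#'
#' Splits the concatenated image back into frames (optionally with a declared
#' overlap that duplicates trailing columns) and writes the supported cine
#' dialect read by [read_recording()]. Pixel values are rounded to integers,
#' so a round trip of an integer-valued recording is bitwise exact.
#'
#' @param rec an [us_recording].
#' @param path output directory (created).
#' @param n_frames number of frames to split into.
#' @param overlap columns of the previous frame repeated at the start of each
#'   subsequent frame.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, n_frames = 1L, overlap = 0L) {
  stopifnot(inherits(rec, "us_recording"))
  n_frames <- as_count(n_frames, "n_frames")
  overlap <- as_count(overlap, "overlap")
  nc <- ncol(rec$pixels)
  if (n_frames < 1L || n_frames > nc) stop("invalid n_frames", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  # split the column range into n_frames contiguous chunks of new content
  bounds <- floor(seq(0L, nc, length.out = n_frames + 1L))
  files <- sprintf("frame_%03d.txt", seq_len(n_frames))
  px <- round(rec$pixels)
  for (i in seq_len(n_frames)) {
    lo <- bounds[i] + 1L
    if (i > 1L && overlap > 0L) lo <- max(1L, lo - overlap)
    cols <- seq.int(lo, bounds[i + 1L])
    data.table::fwrite(data.table::as.data.table(px[, cols, drop = FALSE]),
                       file.path(path, files[i]),
                       sep = "\t", col.names = FALSE)
  }
  meta <- list(
    format = CINE_FORMAT,
    modality = rec$modality,
    time_cal_ms = rec$time_cal,
    value_cal = rec$value_cal,
    baseline_row = rec$baseline_row,
    ecg_band = rec$ecg_band,
    run_id = rec$run_id,
    frame_files = files,
    frame_overlap = if (n_frames > 1L) rep(overlap, n_frames - 1L) else 0L,
    suggest = rec$suggest)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
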