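# Small in-code fixtures shared across test files. Everything is built at
# test time; nothing binary ships with the package.

# M-mode image with two flat horizontal wall bands (1-based rows).
# Near band occupies rows 41..45, far band rows 81..85, so the inner edges
# are 45 (near, deepest) and 81 (far, shallowest).
flat_band_recording <- function(ncol = 120, near_rows = 41:45,
                                far_rows = 81:85, nrow = 130,
                                intensity = 200, background = 10,
                                value_cal = 0.05, time_cal = 3.5) {
  px <- matrix(background, nrow = nrow, ncol = ncol)
  px[near_rows, ] <- intensity
  px[far_rows, ] <- intensity
  us_recording(px, "mmode", time_cal = time_cal, value_cal = value_cal)
}

# M-mode image whose near-wall inner edge follows a sinusoid.
sine_band_recording <- function(ncol = 400, center = 60, amp = 10,
                                period = 120, thickness = 4, nrow = 130,
                                value_cal = 0.05, time_cal = 3.5) {
  inner <- round(center + amp * sin(2 * pi * seq_len(ncol) / period))
  px <- matrix(10, nrow = nrow, ncol = ncol)
  for (k in 0:(thickness - 1)) {
    px[cbind(inner - k, seq_len(ncol))] <- 200
  }
  list(rec = us_recording(px, "mmode", time_cal = time_cal,
                          value_cal = value_cal),
       inner = inner)
}

# ECG strip recording rendering a known amplitude profile (pixels above the
# strip bottom). Rows 1..20 are a dummy body; the strip is rows 21..50.
ecg_strip_recording <- function(amplitude, strip_rows = 30, body_rows = 20) {
  nc <- length(amplitude)
  nr <- body_rows + strip_rows
  px <- matrix(5, nrow = nr, ncol = nc)
  bottom <- nr - 2
  row <- pmax(body_rows + 1, pmin(round(bottom - amplitude), bottom))
  px[cbind(row, seq_len(nc))] <- 220
  px[cbind(row + 1, seq_len(nc))] <- 220
  us_recording(px, "mmode", time_cal = 3.5, value_cal = 0.05,
               ecg_band = c(body_rows + 1, nr + 1))
}

# A waveform_beat built directly from a value vector (native dt in ms).
make_beat <- function(values, dt_ms = 3.5, kind = "diameter", run_id = 1L,
                      beat_index = 1L) {
  structure(
    list(times = (seq_along(values) - 1) * dt_ms / 1000,
         values = values, kind = kind, onset_index = NA_integer_,
         duration = length(values) * dt_ms / 1000,
         run_id = as.integer(run_id), beat_index = as.integer(beat_index),
         flag = NA_character_),
    class = "waveform_beat")
}

# Independent brute-force oracle for the upstroke-onset search: evaluates
# the r-squared of every contiguous segment ending at mid-systole with lm(),
# walking down exactly as the detector specifies.
oracle_onset <- function(values, times, r2_min = 0.985) {
  m <- which.max(values)
  if (m <= 2) return(NA_integer_)
  f <- which.min(values[1:m])
  s <- floor((f + m) / 2)
  if (s - f < 1) return(NA_integer_)
  for (k in seq(s - 1, f)) {
    seg <- k:s
    if (length(seg) == 2) {
      r2 <- 1                                   # two points: exact fit
    } else if (stats::var(values[seg]) == 0) {
      r2 <- 1                                   # constant y: a line fits it
    } else {
      fit <- stats::lm(values[seg] ~ times[seg])
      r2 <- suppressWarnings(summary(fit)$r.squared)
    }
    if (r2 < r2_min) return(k + 1L)
  }
  as.integer(f)
}

# Brute-force longest-prefix oracle for the loop-growth rule (fixed start).
oracle_prefix_stop <- function(x, y, r2_min = 0.98) {
  for (L in 3:length(x)) {
    if (stats::var(y[1:L]) == 0) {
      r2 <- 1
    } else if (stats::var(x[1:L]) == 0) {
      r2 <- 0
    } else {
      r2 <- suppressWarnings(summary(stats::lm(y[1:L] ~ x[1:L]))$r.squared)
    }
    if (r2 <= r2_min) return(L - 1L)
  }
  length(x)
}

# Sort-and-slice oracle for the trimmed mean.
oracle_trimmed <- function(values, trim_fraction) {
  n <- length(values)
  k <- floor(n * trim_fraction / 2)
  s <- sort(values)
  kept <- s[(k + 1):(n - k)]
  list(mean = mean(kept), n_retained = length(kept),
       sd = if (length(kept) > 1) stats::sd(kept) else 0)
}

# Quiet default subject for fast synthetic tests.
quiet_subject <- function(seed = 1L, ...) {
  synthetic_subject(seed = seed,
                    noise_sd = list(image = 0, speckle_rate = 0,
                                    wander_px = 0, waveform_d = 0,
                                    waveform_u = 0),
                    ...)
}
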