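## synthetic: ground-truth waveform generator and ultrasound-like renderers.
##
## The generator states a physiologic world and sticks to it: a diastolic
## diameter with a raised-cosine systolic upstroke and exponential diastolic
## decay, velocity tied to diameter through U = 2 c ln(D / D_d) during the
## reflection-free window, an additive delayed reflected component that
## breaks that linearity (dD up, dU down), beat-to-beat cycle-length and
## amplitude variability, and sequential acquisition (independent beat
## trains for the diameter and velocity runs).

#' Synthetic subject parameters
#'
#' Defaults describe a healthy young adult ascending aorta: wave speed
#' ~4.1 m/s, diastolic diameter 2.6 cm, 0.2 cm systolic distension, heart
#' rate 70 bpm with 3% beat-to-beat variability, reflections returning
#' 80 ms after the upstroke at 15% relative magnitude.
#'
#' @param seed RNG seed (integer); fixed seed gives bitwise-identical output.
#' @param c_true ground-truth wave speed, m/s.
#' @param D_d diastolic diameter, cm.
#' @param pulse_amplitude systolic diameter excursion, cm.
#' @param heart_rate_mean mean heart rate, bpm.
#' @param heart_rate_cv fractional beat-to-beat SD of cycle length.
#' @param amp_cv fractional beat-to-beat SD of pulse amplitude.
#' @param reflection_delay seconds after upstroke onset at which the
#'   reflected wave arrives.
#' @param reflection_magnitude reflected amplitude as a fraction of the
#'   forward amplitude, in `[0, 1)`.
#' @param reflection_rise rise time of the reflected wavefront, seconds.
#'   Shorter than the forward rise: the arriving reflection is a developed
#'   wavefront, so the loop turns away from its early-systolic line promptly
#'   at `reflection_delay` rather than drifting off it.
#' @param noise_sd list of noise scales: `waveform_d` (cm), `waveform_u`
#'   (m/s) added to exported waveform series, `image` (grayscale SD of the
#'   rendered background/band speckle), `speckle_rate` (fraction of pixels
#'   replaced by bright speckle), `wander_px` (SD, in pixel rows, of the
#'   slow AR(1) wander of each rendered interface — wall bands and Doppler
#'   envelope — emulating speckle-decorrelation jitter of the traced edge;
#'   correlated over `wander_corr_px` columns so it survives the tracing
#'   spline, as it does in clinical recordings).
#' @return an object of class `synthetic_subject`.
#' @export
synthetic_subject <- function(seed = 1L,
                              c_true = 4.1,
                              D_d = 2.6,
                              pulse_amplitude = 0.2,
                              heart_rate_mean = 70,
                              heart_rate_cv = 0.03,
                              amp_cv = 0.02,
                              reflection_delay = 0.12,
                              reflection_magnitude = 0.35,
                              reflection_rise = 0.02,
                              noise_sd = list()) {
  stopifnot(c_true > 0, D_d > 0, pulse_amplitude > 0,
            heart_rate_mean > 0, heart_rate_cv >= 0, amp_cv >= 0,
            reflection_delay > 0, reflection_rise > 0,
            reflection_magnitude >= 0, reflection_magnitude < 1)
  ns <- utils::modifyList(
    list(waveform_d = 0.004, waveform_u = 0.015, image = 10,
         speckle_rate = 5e-4, wander_px = 1.0, wander_corr_px = 5),
    noise_sd)
  structure(
    list(seed = as.integer(seed), c_true = c_true, D_d = D_d,
         pulse_amplitude = pulse_amplitude,
         heart_rate_mean = heart_rate_mean, heart_rate_cv = heart_rate_cv,
         amp_cv = amp_cv,
         reflection_delay = reflection_delay,
         reflection_magnitude = reflection_magnitude,
         reflection_rise = reflection_rise,
         noise_sd = ns,
         # waveform shape constants (seconds)
         onset_delay = 0.06, rise_time = 0.12, decay_tau = 0.22,
         lead_in = 0.30, tail = 0.25),
    class = "synthetic_subject")
}

#' Run code with a temporarily fixed RNG seed
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(round(seed) %% 2147483647))
  force(code)
}

#' Systolic pulse shape: quarter-sine upstroke (p(0) = 0 with positive
#' initial slope, so the waveform "begins to increase linearly" at the
#' onset, as at aortic valve opening), smooth peak at rise_time, then
#' exponential diastolic decay.
#' @noRd
pulse_shape <- function(tau, rise_time, decay_tau) {
  p <- numeric(length(tau))
  up <- tau >= 0 & tau <= rise_time
  dn <- tau > rise_time
  p[up] <- sin(0.5 * pi * tau[up] / rise_time)
  p[dn] <- exp(-(tau[dn] - rise_time) / decay_tau)
  p
}

#' One synthetic acquisition run (beat train + waveform + ECG)
#'
#' @param subject a [synthetic_subject].
#' @param kind `"diameter"` or `"velocity"` — which waveform this run records.
#' @param n_beats number of complete beats (n_beats + 1 R-peaks).
#' @param run_seed sub-seed for this run's beat train; distinct sub-seeds per
#'   run emulate sequential acquisition.
#' @param time_cal ms per sample/column (default 3.5).
#' @param run_id run label.
#' @return list with `time_ms`, `values`, `kind`, `time_cal`,
#'   `ecg_amplitude` (pixels), `r_peaks` (column indices), and `truth`
#'   (R-peak times, onset times/columns, reflection onsets, durations,
#'   per-beat amplitudes, `c_true`).
#' @export
synth_run <- function(subject, kind = c("diameter", "velocity"),
                      n_beats = 22L, run_seed = subject$seed,
                      time_cal = 3.5, run_id = 1L) {
  stopifnot(inherits(subject, "synthetic_subject"))
  kind <- match.arg(kind)
  n_beats <- as_count(n_beats, "n_beats")
  if (n_beats < 1L) stop("n_beats must be >= 1", call. = FALSE)
  s <- subject
  with_seed(run_seed, {
    t_mean <- 60 / s$heart_rate_mean
    durs <- t_mean * (1 + s$heart_rate_cv *
                        pmax(-3, pmin(3, stats::rnorm(n_beats))))
    durs <- pmax(durs, 0.4)
    amps <- s$pulse_amplitude * (1 + s$amp_cv *
                                   pmax(-3, pmin(3, stats::rnorm(n_beats))))
    amps <- pmax(amps, 0.02)
    r_times <- s$lead_in + c(0, cumsum(durs))       # n_beats + 1 R-peaks
    total_s <- r_times[length(r_times)] + s$tail
    dt <- time_cal / 1000
    t <- seq(0, total_s, by = dt)
    onset_times <- r_times[seq_len(n_beats)] + s$onset_delay
    # forward and reflected latent pulses (each beat contributes to its own
    # window and decays into the next one)
    fwd <- numeric(length(t))
    refl <- numeric(length(t))
    for (j in seq_len(n_beats)) {
      fwd <- fwd + amps[j] * pulse_shape(t - onset_times[j],
                                         s$rise_time, s$decay_tau)
      if (s$reflection_magnitude > 0) {
        refl <- refl + s$reflection_magnitude * amps[j] *
          pulse_shape(t - onset_times[j] - s$reflection_delay,
                      s$reflection_rise, s$decay_tau)
      }
    }
    if (kind == "diameter") {
      values <- s$D_d + fwd + refl
      values <- values + stats::rnorm(length(t), 0, s$noise_sd$waveform_d)
      values <- pmax(values, 0.1 * s$D_d)
    } else {
      values <- 2 * s$c_true * (log1p(fwd / s$D_d) - log1p(refl / s$D_d))
      values <- values + stats::rnorm(length(t), 0, s$noise_sd$waveform_u)
    }
    r_cols <- round(r_times / dt) + 1L
    ecg <- synth_ecg_amplitude(t, r_times)
    list(time_ms = t * 1000, values = values, kind = kind,
         time_cal = time_cal,
         ecg_amplitude = ecg, r_peaks = r_cols, run_id = as.integer(run_id),
         truth = list(c_true = s$c_true,
                      r_times_s = r_times,
                      durations_s = durs,
                      onset_times_s = onset_times,
                      onset_cols = round(onset_times / dt) + 1L,
                      reflection_onset_s = onset_times + s$reflection_delay,
                      amps = amps))
  })
}

#' Slow AR(1) interface wander in pixel rows
#' @noRd
ar1_wander <- function(n, sd, corr_px) {
  if (sd <= 0) return(numeric(n))
  rho <- exp(-1 / max(corr_px, 1e-6))
  as.numeric(stats::arima.sim(list(ar = rho), n = n,
                              sd = sd * sqrt(1 - rho^2)))
}

#' ECG amplitude (pixels above strip baseline) for a known beat train
#' @noRd
synth_ecg_amplitude <- function(t, r_times) {
  amp <- rep(2, length(t))
  for (rt in r_times) {
    # triangular R spike, 24 ms wide, 30 px tall
    d <- abs(t - rt)
    amp <- amp + pmax(0, 30 * (1 - d / 0.012)) * (d <= 0.012)
    # T wave: smooth bump 300 ms after R
    amp <- amp + 7 * exp(-((t - rt - 0.30) / 0.05)^2)
  }
  pmin(amp, 34)
}

#' Generate a sequential D/U waveform pair with ground truth
#'
#' The diameter and velocity series come from independently sampled beat
#' trains (distinct sub-seeds), as in sequential clinical acquisition, so
#' the cycle-length matching and truncation paths are genuinely exercised.
#'
#' @param subject a [synthetic_subject].
#' @param n_beats complete beats per series.
#' @param d_seed,u_seed sub-seeds (defaults derived from the subject seed).
#' @return list with `d` and `u` (each as returned by [synth_run()]) and
#'   `c_true`.
#' @export
generate_waveform_pair <- function(subject, n_beats = 22L,
                                   d_seed = as.numeric(subject$seed) * 131 + 1,
                                   u_seed = as.numeric(subject$seed) * 131 + 2) {
  d <- synth_run(subject, "diameter", n_beats, run_seed = d_seed)
  u <- synth_run(subject, "velocity", n_beats, run_seed = u_seed)
  list(d = d, u = u, c_true = subject$c_true)
}

#' Render an M-mode image from a diameter series
#'
#' Two bright wall bands whose inner-edge separation follows `D(t)` around a
#' configured centerline, over speckle-noise background, with the ECG strip
#' rendered at the bottom of the image. The sidecar `suggest` block carries
#' the ROIs/thresholds a user would otherwise click, derived from the known
#' geometry.
#'
#' @param run a diameter series from [synth_run()].
#' @param subject the [synthetic_subject] (noise scales, seed).
#' @param value_cal cm per pixel row (default 0.01).
#' @param n_rows image height (default 360).
#' @param center_row lumen centerline row (default 165).
#' @param wall_thickness band thickness, pixels (default 4).
#' @param render_seed sub-seed for pixel noise.
#' @return list with `recording` (an [us_recording]) and `truth`
#'   (per-column true inner-edge rows `near_rows`, `far_rows`, and the run
#'   truth record).
#' @export
render_mmode <- function(run, subject, value_cal = 0.01, n_rows = 380L,
                         center_row = 165, wall_thickness = 4L,
                         render_seed = as.numeric(subject$seed) * 131 + 11) {
  stopifnot(run$kind == "diameter", value_cal > 0)
  nc <- length(run$values)
  ecg_band <- c(n_rows - 39L, n_rows + 1L)          # bottom 40 rows
  sep <- run$values / value_cal
  ns <- subject$noise_sd
  with_seed(render_seed, {
    # each interface wanders independently (speckle decorrelation)
    near <- round(center_row - sep / 2 +
                    ar1_wander(nc, ns$wander_px, ns$wander_corr_px))
    far <- round(center_row + sep / 2 +
                   ar1_wander(nc, ns$wander_px, ns$wander_corr_px))
    if (min(near) - wall_thickness < 1L || max(far) + wall_thickness >
        ecg_band[1L] - 6L) {
      stop("geometry error: diameter range does not fit in the image",
           call. = FALSE)
    }
    px <- matrix(pmax(0, stats::rnorm(n_rows * nc, 30, ns$image)),
                 nrow = n_rows)
    for (k in 0:(wall_thickness - 1L)) {
      px[cbind(near - k, seq_len(nc))] <-
        pmin(255, pmax(150, 220 + stats::rnorm(nc, 0, ns$image)))
      px[cbind(far + k, seq_len(nc))] <-
        pmin(255, pmax(150, 220 + stats::rnorm(nc, 0, ns$image)))
    }
    if (ns$speckle_rate > 0) {
      body_rows <- seq_len(ecg_band[1L] - 1L)
      n_sp <- stats::rpois(1, ns$speckle_rate * length(body_rows) * nc)
      if (n_sp > 0) {
        px[cbind(sample(body_rows, n_sp, replace = TRUE),
                 sample.int(nc, n_sp, replace = TRUE))] <-
          stats::runif(n_sp, 140, 255)
      }
    }
    px <- render_ecg_strip(px, ecg_band, run$ecg_amplitude, ns$image)
    px <- round(pmin(px, 255))
    pad <- wall_thickness + 8L
    suggest <- list(
      near_roi = c(max(1L, min(near) - pad), max(near) + 9L),
      far_roi = c(max(1L, min(far) - 8L), min(ecg_band[1L] - 1L,
                                              max(far) + pad)),
      near_threshold = 128, far_threshold = 128)
    rec <- us_recording(px, "mmode", time_cal = run$time_cal,
                        value_cal = value_cal, ecg_band = ecg_band,
                        run_id = run$run_id, suggest = suggest)
    list(recording = rec,
         truth = c(run$truth, list(near_rows = near, far_rows = far,
                                   r_peaks = run$r_peaks)))
  })
}

#' Render a PW-Doppler spectrogram image from a velocity series
#'
#' A filled spectral band from the zero-velocity baseline up to the envelope
#' row for `U(t)`, intensity decaying toward the envelope edge, over a noise
#' floor; a thin near-baseline band persists through diastole (spectral
#' clutter), as on clinical spectrograms. Forward flow is rendered above the
#' baseline.
#'
#' @param run a velocity series from [synth_run()].
#' @param subject the [synthetic_subject].
#' @param value_cal m/s per pixel row (default 0.01).
#' @param n_rows image height (default 360).
#' @param baseline_row zero-velocity row (default 300).
#' @param render_seed sub-seed for pixel noise.
#' @return list with `recording` and `truth` (per-column true envelope rows).
#' @export
render_doppler <- function(run, subject, value_cal = 0.01, n_rows = 360L,
                           baseline_row = 300L,
                           render_seed = as.numeric(subject$seed) * 131 + 12) {
  stopifnot(run$kind == "velocity", value_cal > 0)
  nc <- length(run$values)
  ecg_band <- c(n_rows - 39L, n_rows + 1L)
  if (baseline_row >= ecg_band[1L]) {
    stop("geometry error: baseline inside the ECG band", call. = FALSE)
  }
  ns <- subject$noise_sd
  with_seed(render_seed, {
    env <- baseline_row -
      round(pmax(run$values, 0) / value_cal +
              ar1_wander(nc, ns$wander_px, ns$wander_corr_px))
    if (min(env) < 2L) {
      stop("geometry error: envelope exceeds the top of the image",
           call. = FALSE)
    }
    env <- pmin(env, baseline_row - 1L)   # idle clutter band, >= 1 px
    px <- matrix(pmax(0, stats::rnorm(n_rows * nc, 20, ns$image)),
                 nrow = n_rows)
    rows <- seq_len(baseline_row)
    rowm <- matrix(rows, nrow = baseline_row, ncol = nc)
    envm <- matrix(env, nrow = baseline_row, ncol = nc, byrow = TRUE)
    inside <- rowm >= envm
    depth <- (rowm - envm) / pmax(baseline_row - envm, 1)   # 0 edge -> 1 base
    band <- (80 + 120 * depth + matrix(stats::rnorm(baseline_row * nc, 0,
                                                    ns$image),
                                       nrow = baseline_row)) * inside
    px[rows, ] <- pmax(px[rows, ], pmin(band, 255))
    if (ns$speckle_rate > 0) {
      body_rows <- seq_len(ecg_band[1L] - 1L)
      n_sp <- stats::rpois(1, ns$speckle_rate * length(body_rows) * nc)
      if (n_sp > 0) {
        px[cbind(sample(body_rows, n_sp, replace = TRUE),
                 sample.int(nc, n_sp, replace = TRUE))] <-
          stats::runif(n_sp, 120, 255)
      }
    }
    px <- render_ecg_strip(px, ecg_band, run$ecg_amplitude, ns$image)
    px <- round(pmin(px, 255))
    rec <- us_recording(px, "doppler", time_cal = run$time_cal,
                        value_cal = value_cal, baseline_row = baseline_row,
                        ecg_band = ecg_band, run_id = run$run_id,
                        suggest = list(doppler_threshold = 60,
                                       flow_side = "above"))
    list(recording = rec,
         truth = c(run$truth, list(envelope_rows = env,
                                   r_peaks = run$r_peaks)))
  })
}

#' Draw the ECG trace into the strip band of an image
#' @noRd
render_ecg_strip <- function(px, ecg_band, amplitude, noise_sd) {
  rows <- seq.int(ecg_band[1L], ecg_band[2L] - 1L)
  nc <- ncol(px)
  px[rows, ] <- pmax(0, stats::rnorm(length(rows) * nc, 12, noise_sd / 2))
  bottom <- rows[length(rows)] - 2L
  trace_row <- round(bottom - amplitude)
  trace_row <- pmax(rows[1L], pmin(trace_row, bottom))
  for (k in 0:1) {
    px[cbind(trace_row + k, seq_len(nc))] <- 230
  }
  px
}

#' Write a full synthetic subject as cine fixture directories
#'
#' Generates `n_runs` independent M-mode runs and `n_runs` independent
#' Doppler runs, renders them, splits each into frames of the supported cine
#' dialect, and writes a `truth.json`. All filenames are prefixed
#' `synth_` — these are synthetic stand-ins, not clinical recordings.
#'
#' @param subject a [synthetic_subject].
#' @param dir output directory.
#' @param n_runs runs per modality (default 3).
#' @param n_beats complete beats per run (default 22, ~20 s at 70 bpm).
#' @param n_frames cine frames per recording (default 6).
#' @param overlap duplicated columns between consecutive frames (default 0).
#' @return the input manifest for [run_pipeline()]: list with `d_runs`,
#'   `u_runs` (paths) and `truth_file`.
#' @export
write_synthetic_subject <- function(subject, dir, n_runs = 3L, n_beats = 22L,
                                    n_frames = 6L, overlap = 0L) {
  stopifnot(inherits(subject, "synthetic_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d_paths <- character(n_runs)
  u_paths <- character(n_runs)
  truth <- list(c_true = subject$c_true, d = list(), u = list())
  for (i in seq_len(n_runs)) {
    dr <- synth_run(subject, "diameter", n_beats,
                    run_seed = as.numeric(subject$seed) * 131 + 10 * i + 1,
                    run_id = i)
    ur <- synth_run(subject, "velocity", n_beats,
                    run_seed = as.numeric(subject$seed) * 131 + 10 * i + 2,
                    run_id = i)
    dm <- render_mmode(dr, subject,
                       render_seed = as.numeric(subject$seed) * 131 + 10 * i + 3)
    um <- render_doppler(ur, subject,
                         render_seed = as.numeric(subject$seed) * 131 + 10 * i + 4)
    d_paths[i] <- file.path(dir, sprintf("synth_mmode_%d", i))
    u_paths[i] <- file.path(dir, sprintf("synth_doppler_%d", i))
    write_recording(dm$recording, d_paths[i], n_frames = n_frames,
                    overlap = overlap)
    write_recording(um$recording, u_paths[i], n_frames = n_frames,
                    overlap = overlap)
    truth$d[[i]] <- dm$truth[c("r_times_s", "onset_times_s", "durations_s",
                               "c_true")]
    truth$u[[i]] <- um$truth[c("r_times_s", "onset_times_s", "durations_s",
                               "c_true")]
  }
  truth_file <- file.path(dir, "synth_truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA)
  list(d_runs = d_paths, u_runs = u_paths, truth_file = truth_file)
}
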