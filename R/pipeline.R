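## cli/pipeline: configuration with per-module defaults, end-to-end
## orchestration (images -> waveforms -> beats -> groups -> loops -> PWV),
## structured JSONL logging, and deterministic CSV/JSON reports.

#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()], with the
#' per-module defaults. Unknown keys are rejected rather than silently
#' ignored. Tracing ROIs/thresholds default to `NULL`, meaning "use the
#' hints embedded in the recording sidecar" (the reproducible surrogate for
#' clicking ROIs on screen); recordings without hints then raise an error
#' naming the missing key.
#'
#' @param ... overrides as named nested lists, e.g.
#'   `ecg = list(threshold_fraction = 0.8)`,
#'   `tracing = list(near_threshold = 128)`.
#' @return a `pipeline_config` list with entries `ecg`, `tracing`, `beats`,
#'   `loop`, `ensemble`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    ecg = list(threshold_fraction = 0.8, refractory_ms = 200),
    tracing = list(near_roi = NULL, far_roi = NULL,
                   near_threshold = NULL, far_threshold = NULL,
                   doppler_threshold = NULL, doppler_start_column = 1,
                   exclusions = list(), smoothing_parameter = 0.001,
                   flow_side = NULL),
    beats = list(group_size = 6, upstroke_r2 = 0.985),
    loop = list(dt_ms = 1.0, fit_r2 = 0.98, min_fit_ms = 10),
    ensemble = list(trim_fraction = 0.10, per_tail = FALSE))
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  for (section in names(overrides)) {
    if (!section %in% names(defaults)) {
      stop("unknown config section '", section, "'", call. = FALSE)
    }
    for (key in names(overrides[[section]])) {
      if (!key %in% names(defaults[[section]])) {
        stop("unknown config key '", section, ".", key, "'", call. = FALSE)
      }
      defaults[[section]][key] <- list(overrides[[section]][[key]])
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with the same nesting as [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @noRd
cfg_or_suggest <- function(cfg_val, suggest, key) {
  if (!is.null(cfg_val)) return(cfg_val)
  if (!is.null(suggest[[key]])) return(suggest[[key]])
  stop("config error: 'tracing.", key, "' not set and the recording ",
       "carries no suggestion for it", call. = FALSE)
}

#' @noRd
jsonl_logger <- function(path) {
  if (is.null(path)) return(function(...) invisible(NULL))
  con <- file(path, open = "w", encoding = "UTF-8")
  function(stage = NULL, ..., close = FALSE) {
    if (close) { base::close(con); return(invisible(NULL)) }
    writeLines(jsonlite::toJSON(c(list(stage = stage), list(...)),
                                auto_unbox = TRUE, digits = NA, null = "null"),
               con)
    invisible(NULL)
  }
}

#' Extract one run: recording -> waveform + R-peaks + grouped beats
#' @noRd
process_run <- function(rec, modality, config, log) {
  trace <- extract_ecg_trace(rec)
  refr <- max(1L, as.integer(round(config$ecg$refractory_ms / rec$time_cal)))
  peaks <- detect_r_peaks(trace, config$ecg$threshold_fraction, refr)
  if (length(peaks) < 2L) {
    stop("segmentation error: run ", rec$run_id, " (", modality,
         ") has ", length(peaks), " R-peaks", call. = FALSE)
  }
  tcfg <- config$tracing
  sug <- rec$suggest
  if (modality == "mmode") {
    near <- trace_wall(rec, "near",
                       roi = cfg_or_suggest(tcfg$near_roi, sug, "near_roi"),
                       threshold = cfg_or_suggest(tcfg$near_threshold, sug,
                                                  "near_threshold"),
                       exclusions = tcfg$exclusions)
    far <- trace_wall(rec, "far",
                      roi = cfg_or_suggest(tcfg$far_roi, sug, "far_roi"),
                      threshold = cfg_or_suggest(tcfg$far_threshold, sug,
                                                 "far_threshold"),
                      exclusions = tcfg$exclusions)
    near <- smooth_trace(near, tcfg$smoothing_parameter)
    far <- smooth_trace(far, tcfg$smoothing_parameter)
    wf <- diameter_waveform(near, far, rec$value_cal, rec$time_cal)
  } else {
    wf <- trace_doppler_envelope(
      rec,
      threshold = cfg_or_suggest(tcfg$doppler_threshold, sug,
                                 "doppler_threshold"),
      start_column = tcfg$doppler_start_column,
      exclusions = tcfg$exclusions,
      flow_side = cfg_or_suggest(tcfg$flow_side, sug, "flow_side"),
      smoothing_parameter = tcfg$smoothing_parameter)
  }
  beats <- segment_beats(wf, peaks, run_id = rec$run_id)
  beats <- lapply(beats, detect_upstroke_onset, r2_min = config$beats$upstroke_r2)
  usable <- longest_unflagged_run(beats)
  log("beats", modality = modality, run = rec$run_id,
      n_peaks = length(peaks), n_beats = length(beats),
      n_usable = length(usable),
      onsets = vapply(beats, function(b) as.integer(b$onset_index %||% NA),
                      integer(1)),
      flags = vapply(beats, function(b) b$flag %||% NA_character_,
                     character(1)))
  groups <- select_groups(usable, config$beats$group_size)
  list(waveform = wf, peaks = peaks, beats = beats, groups = groups,
       run_id = rec$run_id)
}

#' Run the full PWV pipeline
#'
#' Executes read -> ECG -> trace -> beats -> groups -> match -> pairings ->
#' loop fits -> trimmed-mean ensemble for one subject, and (optionally)
#' writes waveform CSVs, a per-loop CSV, a subject JSON report, and a JSONL
#' decision log to `out_dir`. Deterministic given inputs and config: the
#' reports carry no timestamps and no randomness.
#'
#' @param manifest input manifest. For image input: `list(d_runs =, u_runs =)`
#'   with paths to cine recording directories. For waveform input:
#'   `list(d_waveforms =, u_waveforms =)` with paths to CSVs written by a
#'   previous image run (each `<name>.csv` accompanied by
#'   `<name>_peaks.json`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` for no file output.
#' @return the subject report: list with `estimate` (a `pwv_estimate`),
#'   `fits`, `n_runs_d`, `n_runs_u`, `selected` (per run pair, the chosen
#'   group start indices and durations).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  from_images <- !is.null(manifest$d_runs) || !is.null(manifest$u_runs)
  dkey <- if (from_images) "d_runs" else "d_waveforms"
  ukey <- if (from_images) "u_runs" else "u_waveforms"
  if (length(manifest[[dkey]]) < 1L || length(manifest[[ukey]]) < 1L) {
    stop("manifest error: need >= 1 D run and >= 1 U run (got ",
         length(manifest[[dkey]]), " D, ", length(manifest[[ukey]]), " U)",
         call. = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "waveforms"), recursive = TRUE,
               showWarnings = FALSE)
  }
  log <- jsonl_logger(if (!is.null(out_dir)) file.path(out_dir, "log.jsonl"))
  on.exit(log(close = TRUE))

  load_runs <- function(paths, modality) {
    lapply(seq_along(paths), function(i) {
      if (from_images) {
        rec <- read_recording(paths[i], modality)
        run <- process_run(rec, modality, config, log)
      } else {
        run <- read_waveform_run(paths[i], config, log)
      }
      if (!is.null(out_dir) && from_images) {
        write_waveform_run(run, file.path(
          out_dir, "waveforms",
          sprintf("%s_run%d", if (modality == "mmode") "diameter" else
            "velocity", run$run_id)))
      }
      run
    })
  }
  d_runs <- load_runs(manifest[[dkey]], "mmode")
  u_runs <- load_runs(manifest[[ukey]], "doppler")

  n_pairs <- min(length(d_runs), length(u_runs))
  if (length(d_runs) != length(u_runs)) {
    log("match", note = "unequal run counts; pairing index-wise",
        n_d = length(d_runs), n_u = length(u_runs))
  }
  selected_d <- vector("list", n_pairs)
  selected_u <- vector("list", n_pairs)
  selected <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    m <- match_groups(d_runs[[i]]$groups, u_runs[[i]]$groups)
    selected_d[[i]] <- m$d
    selected_u[[i]] <- m$u
    selected[[i]] <- list(
      run_pair = i,
      d_start_beat = m$d$start_beat_index, d_mean_duration = m$d$mean_duration,
      u_start_beat = m$u$start_beat_index, u_mean_duration = m$u$mean_duration)
    log("match", run_pair = i,
        d_start_beat = m$d$start_beat_index,
        u_start_beat = m$u$start_beat_index,
        d_mean_duration = m$d$mean_duration,
        u_mean_duration = m$u$mean_duration)
  }
  fits <- all_pairings(selected_d, selected_u,
                       dt = config$loop$dt_ms / 1000,
                       r2_min = config$loop$fit_r2,
                       min_fit_ms = config$loop$min_fit_ms)
  estimate <- trimmed_mean_pwv(fits, config$ensemble$trim_fraction,
                               config$ensemble$per_tail)
  log("ensemble", n_loops = length(fits), n_total = estimate$n_total,
      n_retained = estimate$n_retained, n_flagged = estimate$n_flagged,
      trimmed_mean = estimate$trimmed_mean, wsd = estimate$wsd)
  report <- list(estimate = estimate, fits = fits,
                 n_runs_d = length(d_runs), n_runs_u = length(u_runs),
                 selected = selected)
  if (!is.null(out_dir)) write_subject_report(report, out_dir)
  report
}

#' @noRd
write_waveform_run <- function(run, stem) {
  data.table::fwrite(
    data.table::data.table(
      time_ms = (seq_along(run$waveform$values) - 1L) * run$waveform$time_cal,
      value = run$waveform$values),
    paste0(stem, ".csv"))
  jsonlite::write_json(
    list(r_peaks = run$peaks, time_cal_ms = run$waveform$time_cal,
         kind = run$waveform$kind, run_id = run$run_id),
    paste0(stem, "_peaks.json"), auto_unbox = TRUE, digits = NA)
}

#' @noRd
read_waveform_run <- function(csv_path, config, log) {
  peaks_path <- sub("\\.csv$", "_peaks.json", csv_path)
  if (!file.exists(csv_path) || !file.exists(peaks_path)) {
    stop("manifest error: missing waveform CSV or its _peaks.json sidecar: ",
         csv_path, call. = FALSE)
  }
  tab <- data.table::fread(csv_path)
  meta <- jsonlite::read_json(peaks_path, simplifyVector = TRUE)
  wf <- raw_waveform(tab$value, meta$time_cal_ms, meta$kind)
  beats <- segment_beats(wf, meta$r_peaks, run_id = meta$run_id %||% 1L)
  beats <- lapply(beats, detect_upstroke_onset, r2_min = config$beats$upstroke_r2)
  usable <- longest_unflagged_run(beats)
  log("beats", modality = meta$kind, run = meta$run_id %||% 1L,
      n_peaks = length(meta$r_peaks), n_beats = length(beats),
      n_usable = length(usable))
  groups <- select_groups(usable, config$beats$group_size)
  list(waveform = wf, peaks = meta$r_peaks, beats = beats, groups = groups,
       run_id = as.integer(meta$run_id %||% 1L))
}

#' @noRd
write_subject_report <- function(report, out_dir) {
  fits <- report$fits
  loops <- data.table::data.table(
    d_run = vapply(fits, function(f) f$d_source$run_id, integer(1)),
    d_beat = vapply(fits, function(f) f$d_source$beat_index, integer(1)),
    u_run = vapply(fits, function(f) f$u_source$run_id, integer(1)),
    u_beat = vapply(fits, function(f) f$u_source$beat_index, integer(1)),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    n_fit = vapply(fits, `[[`, integer(1), "n_fit"),
    pwv = vapply(fits, `[[`, numeric(1), "pwv"),
    flags = vapply(fits, function(f) paste(f$flags, collapse = ";"),
                   character(1)))
  data.table::fwrite(loops, file.path(out_dir, "loops.csv"))
  est <- report$estimate
  jsonlite::write_json(
    list(n_loops = length(fits),
         n_total = est$n_total, n_retained = est$n_retained,
         trimmed_mean = est$trimmed_mean, wsd = est$wsd,
         trim_fraction = est$trim_fraction,
         n_flagged = est$n_flagged,
         flag_counts = as.list(est$flag_counts),
         n_runs_d = report$n_runs_d, n_runs_u = report$n_runs_u,
         selected = report$selected),
    file.path(out_dir, "subject.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Pipeline from rendered/clinical images
#' @param d_runs,u_runs cine recording directories.
#' @inheritParams run_pipeline
#' @return see [run_pipeline()].
#' @export
pwv_from_images <- function(d_runs, u_runs, config = pipeline_config(),
                            out_dir = NULL) {
  run_pipeline(list(d_runs = d_runs, u_runs = u_runs), config, out_dir)
}

#' Pipeline from pre-extracted waveform CSVs
#' @param d_waveforms,u_waveforms waveform CSV paths (`time_ms,value`), each
#'   with a `<name>_peaks.json` sidecar.
#' @inheritParams run_pipeline
#' @return see [run_pipeline()].
#' @export
pwv_from_waveforms <- function(d_waveforms, u_waveforms,
                               config = pipeline_config(), out_dir = NULL) {
  run_pipeline(list(d_waveforms = d_waveforms, u_waveforms = u_waveforms),
               config, out_dir)
}
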