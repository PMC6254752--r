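## loop: align a diameter beat and a velocity beat at their upstroke onsets,
## truncate to common length, build the ln(D)U-loop, fit its early-systolic
## slope while r2 stays above threshold, and convert the slope to PWV.

#' Align a D beat with a U beat and truncate to common length
#'
#' Each beat is linearly interpolated onto a uniform grid of step `dt`
#' running from its own upstroke onset to its closing R-peak. Because the
#' two acquisitions are sequential, the spans differ; the longer series is
#' truncated at the tail (late diastole) so the pair has equal length,
#' preserving the systolic portion on which the slope depends. Sample 0 of
#' the pair is the upstroke onset of both beats.
#'
#' @param d_beat diameter `waveform_beat` with `onset_index` set.
#' @param u_beat velocity `waveform_beat` with `onset_index` set.
#' @param dt common sample interval in seconds (default 0.001).
#' @return an object of class `loop_pair`: `lnD`, `U`, `dt`, `n`,
#'   `d_source`, `u_source`.
#' @export
align_and_truncate <- function(d_beat, u_beat, dt = 0.001) {
  stopifnot(inherits(d_beat, "waveform_beat"), inherits(u_beat, "waveform_beat"))
  if (d_beat$kind != "diameter" || u_beat$kind != "velocity") {
    stop("expected a diameter beat and a velocity beat (in that order)",
         call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  grids <- lapply(list(d_beat, u_beat), function(b) {
    if (is.na(b$onset_index)) {
      stop("beat has no detected upstroke onset", call. = FALSE)
    }
    t0 <- b$times[b$onset_index]
    span <- b$times[length(b$times)] - t0
    if (span < 10 * dt) {
      stop("degenerate-beat error: onset-to-R span ", signif(span, 3),
           " s is shorter than 10 samples at dt = ", dt, " s", call. = FALSE)
    }
    tau <- seq(0, span, by = dt)
    list(tau = tau,
         v = stats::approx(b$times - t0, b$values, xout = tau, rule = 2)$y)
  })
  n <- min(lengths(lapply(grids, `[[`, "tau")))
  d <- grids[[1L]]$v[seq_len(n)]
  u <- grids[[2L]]$v[seq_len(n)]
  if (any(d <= 0)) {
    stop("diameter must stay strictly positive for ln", call. = FALSE)
  }
  structure(
    list(lnD = log(d), U = u, dt = dt, n = n,
         d_source = list(run_id = d_beat$run_id, beat_index = d_beat$beat_index),
         u_source = list(run_id = u_beat$run_id, beat_index = u_beat$beat_index)),
    class = "loop_pair")
}

#' Fit the early-systolic limb of a ln(D)U-loop
#'
#' Starting from the common upstroke onset with the first 3 samples, points
#' are added one at a time in time order; after each addition the
#' least-squares line of U against ln(D) and its r-squared are evaluated.
#' Growth stops the first time r-squared drops to `r2_min` or below, and
#' the reported fit is the last one with r-squared above `r2_min` — the
#' longest initial stretch over which the loop is acceptably linear, i.e.
#' the reflection-free early-systolic limb.
#'
#' A fitted stretch shorter than `min_fit_ms` cannot be the early-systolic
#' limb (which lasts tens of milliseconds). Such stunted fits arise when
#' the detected onset sits a few samples inside the preceding diastolic
#' tail, putting a hook at the start of the loop; when fitted
#' interactively these are corrected by eye (both the onset and the linear
#' fit). The automated stand-in: if growth from the common onset cannot
#' sustain `min_fit_ms`, the start is advanced one sample at a time — at
#' most `max_start_ms` — to the first sample from which the same growth
#' rule sustains it, i.e. the point after which the loop genuinely rises
#' linearly. If no start works the loop is flagged `short_fit` and
#' excluded from the ensemble.
#'
#' @param pair a `loop_pair`.
#' @param r2_min r-squared threshold (default 0.98).
#' @param min_fit_ms minimum physiologically meaningful fit span in
#'   milliseconds (default 10).
#' @param max_start_ms furthest the fit start may be advanced past the
#'   detected common onset, milliseconds (default 30).
#' @return an object of class `loop_fit`: `slope` (dU/dlnD), `r2`, `n_fit`,
#'   `start_index` (1 = the common onset), `pwv` (m/s, NA when flagged),
#'   `flags` (character vector), and the pair's provenance.
#' @export
fit_loop <- function(pair, r2_min = 0.98, min_fit_ms = 10, max_start_ms = 30) {
  stopifnot(inherits(pair, "loop_pair"))
  x <- pair$lnD; y <- pair$U
  min_n <- max(3L, as.integer(ceiling(min_fit_ms / 1000 / pair$dt)) + 1L)
  max_start <- 1L + max(0L, as.integer(floor(max_start_ms / 1000 / pair$dt)))
  best <- NULL
  for (j0 in seq_len(max_start)) {
    if (pair$n - j0 + 1L < 3L) break
    r2 <- prefix_r2(x[j0:pair$n], y[j0:pair$n])
    lens <- seq_len(pair$n - j0 + 1L)
    cand <- which(lens >= 3L & !is.na(r2) & r2 <= r2_min)
    n_fit <- if (length(cand) == 0L) pair$n - j0 + 1L else cand[1L] - 1L
    if (is.null(best) || n_fit > best$n_fit) best <- list(j0 = j0, n_fit = n_fit)
    if (n_fit >= min_n) { best <- list(j0 = j0, n_fit = n_fit); break }
  }
  flags <- character()
  if (is.null(best) || best$n_fit < 3L) {
    return(structure(
      list(slope = NA_real_, r2 = NA_real_, n_fit = 0L, start_index = 1L,
           pwv = NA_real_, flags = "unfittable_loop",
           d_source = pair$d_source, u_source = pair$u_source),
      class = "loop_fit"))
  }
  idx <- seq.int(best$j0, best$j0 + best$n_fit - 1L)
  line <- ols_line(x[idx], y[idx])
  if (!is.finite(line$slope)) {
    flags <- "unfittable_loop"
    pwv <- NA_real_
  } else if (best$n_fit < min_n) {
    flags <- "short_fit"
    pwv <- NA_real_
  } else if (line$slope <= 0) {
    flags <- "negative_slope"
    pwv <- NA_real_
  } else {
    pwv <- pwv_from_slope(line$slope)
  }
  structure(
    list(slope = line$slope, r2 = line$r2, n_fit = as.integer(best$n_fit),
         start_index = as.integer(best$j0), pwv = pwv, flags = flags,
         d_source = pair$d_source, u_source = pair$u_source),
    class = "loop_fit")
}

#' Pulse wave velocity from a ln(D)U-loop slope
#'
#' In the absence of reflected waves in early systole the loop is linear
#' with slope `dU/dlnD = 2 * PWV`, so `PWV = slope / 2`. Forward flow is
#' taken as positive; non-positive slopes have no physical wave speed and
#' yield `NA` (callers flag them).
#'
#' @param slope fitted dU/dlnD in m/s.
#' @return PWV in m/s, or `NA_real_` for non-positive slopes.
#' @export
pwv_from_slope <- function(slope) {
  if (length(slope) != 1L || !is.finite(slope)) {
    stop("slope must be a finite scalar", call. = FALSE)
  }
  if (slope <= 0) return(NA_real_)
  slope / 2
}

#' @export
print.loop_fit <- function(x, ...) {
  cat(sprintf(
    "<loop_fit> slope %.3f, r2 %.4f, n_fit %d, PWV %s m/s%s\n",
    x$slope, x$r2, x$n_fit,
    if (is.na(x$pwv)) "NA" else sprintf("%.2f", x$pwv),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}
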