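## ensemble: cross all selected D beats with all selected U beats, aggregate
## the pairing-level PWV values into a trimmed mean with a within-subject SD.

#' Fit a ln(D)U-loop for every D/U beat pairing
#'
#' Every beat of every selected diameter group is paired with every beat of
#' every selected velocity group (the beats being representative six-beat
#' windows, one group per run), so three 20-s runs per modality yield
#' 6x3 x 6x3 = 324 loops.
#'
#' @param d_selection list of selected diameter `beat_group`s (one per run).
#' @param u_selection list of selected velocity `beat_group`s (one per run).
#' @param dt common sample interval in seconds (default 0.001).
#' @param r2_min loop-fit r-squared threshold (default 0.98).
#' @param min_fit_ms minimum fit span passed to [fit_loop()] (default 10).
#' @return list of `loop_fit`s of length
#'   `(sum of D beats) * (sum of U beats)`.
#' @export
all_pairings <- function(d_selection, u_selection, dt = 0.001, r2_min = 0.98,
                         min_fit_ms = 10) {
  if (length(d_selection) == 0L || length(u_selection) == 0L) {
    stop("empty group selection", call. = FALSE)
  }
  d_beats <- unlist(lapply(d_selection, `[[`, "beats"), recursive = FALSE)
  u_beats <- unlist(lapply(u_selection, `[[`, "beats"), recursive = FALSE)
  if (length(d_beats) == 0L || length(u_beats) == 0L) {
    stop("empty group selection", call. = FALSE)
  }
  grid <- expand.grid(d = seq_along(d_beats), u = seq_along(u_beats))
  lapply(seq_len(nrow(grid)), function(i) {
    pair <- align_and_truncate(d_beats[[grid$d[i]]], u_beats[[grid$u[i]]],
                               dt = dt)
    fit_loop(pair, r2_min = r2_min, min_fit_ms = min_fit_ms)
  })
}

#' Trimmed-mean PWV over the pairing ensemble
#'
#' Flagged loops are removed first and counted; the surviving PWV values
#' are sorted and the most extreme 10% (by default) excluded — half from
#' each tail, `k = floor(n * trim_fraction / 2)` per tail — before taking
#' the mean. The SD of the retained values is the within-subject SD.
#'
#' @param fits list of `loop_fit`s, or a bare numeric vector of PWV values.
#' @param trim_fraction total fraction of extreme values excluded
#'   (default 0.10). With `per_tail = TRUE` the fraction is instead applied
#'   to each tail.
#' @param per_tail logical; see above.
#' @return an object of class `pwv_estimate`: `values`, `n_total`,
#'   `n_retained`, `trimmed_mean`, `wsd`, `trim_fraction`, `n_flagged`,
#'   `flag_counts`, `retained` (logical over `values`).
#' @export
trimmed_mean_pwv <- function(fits, trim_fraction = 0.10, per_tail = FALSE) {
  if (!(trim_fraction >= 0 && trim_fraction < 1)) {
    stop("trim_fraction must be in [0, 1)", call. = FALSE)
  }
  if (is.numeric(fits)) {
    values <- fits
    flag_counts <- integer()
    n_flagged <- 0L
  } else {
    flags <- lapply(fits, `[[`, "flags")
    flagged <- lengths(flags) > 0L
    n_flagged <- sum(flagged)
    flag_counts <- table(unlist(flags))
    values <- vapply(fits[!flagged], `[[`, numeric(1), "pwv")
  }
  n <- length(values)
  if (n == 0L) {
    stop("no-estimate error: every loop was flagged; nothing to aggregate",
         call. = FALSE)
  }
  k <- if (per_tail) floor(n * trim_fraction) else floor(n * trim_fraction / 2)
  if (n - 2L * k < 1L) {
    stop("trim_fraction leaves no values", call. = FALSE)
  }
  ord <- order(values)
  keep_sorted <- ord[seq.int(k + 1L, n - k)]
  retained <- logical(n)
  retained[keep_sorted] <- TRUE
  vals_kept <- values[retained]
  wsd <- if (length(vals_kept) > 1L) stats::sd(vals_kept) else 0
  structure(
    list(values = values, n_total = n, n_retained = length(vals_kept),
         trimmed_mean = mean(vals_kept), wsd = wsd,
         trim_fraction = trim_fraction, per_tail = per_tail,
         n_flagged = n_flagged, flag_counts = flag_counts,
         retained = retained),
    class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf(
    "<pwv_estimate> %.2f +/- %.2f m/s (trimmed mean +/- wsd), %d/%d loops retained%s\n",
    x$trimmed_mean, x$wsd, x$n_retained, x$n_total,
    if (x$n_flagged > 0L) sprintf(", %d flagged", x$n_flagged) else ""))
  invisible(x)
}

#' Cohort summary across subjects
#'
#' @param estimates list of `pwv_estimate`s (or a named list mapping subject
#'   id to estimate).
#' @return list with `mean`, `sd` (0 with a flag when n = 1), and `table`,
#'   a data.frame (subject_id, pwv, wsd, n_retained) mirroring a
#'   per-volunteer results table.
#' @export
cohort_summary <- function(estimates) {
  if (length(estimates) < 1L) stop("need >= 1 estimate", call. = FALSE)
  ids <- names(estimates) %||% as.character(seq_along(estimates))
  if (is.null(names(estimates))) names(estimates) <- ids
  pwv <- vapply(estimates, `[[`, numeric(1), "trimmed_mean")
  wsd <- vapply(estimates, `[[`, numeric(1), "wsd")
  nr <- vapply(estimates, `[[`, integer(1), "n_retained")
  single <- length(pwv) == 1L
  list(mean = mean(pwv),
       sd = if (single) 0 else stats::sd(pwv),
       n_subjects = length(pwv),
       single_subject = single,
       table = data.frame(subject_id = ids, pwv = unname(pwv),
                          wsd = unname(wsd), n_retained = unname(nr),
                          row.names = NULL))
}
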