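make_fit <- function(pwv, flags = character()) {
  structure(list(slope = 2 * pwv, r2 = 0.999, n_fit = 50L, start_index = 1L,
                 pwv = if (length(flags)) NA_real_ else pwv, flags = flags,
                 d_source = list(run_id = 1L, beat_index = 1L),
                 u_source = list(run_id = 1L, beat_index = 1L)),
            class = "loop_fit")
}

# a beat pair that produces a clean linear loop
linear_beats <- function(c_true = 4, n_beats = 1, run_id = 1L) {
  d_vals <- 2.6 + 0.2 * sin(0.5 * pi * (0:100) / 100)
  u_vals <- 2 * c_true * log(d_vals / 2.6)
  list(
    d = lapply(seq_len(n_beats), function(i) {
      b <- make_beat(d_vals, kind = "diameter", run_id = run_id,
                     beat_index = i)
      b$onset_index <- 1L
      b
    }),
    u = lapply(seq_len(n_beats), function(i) {
      b <- make_beat(u_vals, kind = "velocity", run_id = run_id,
                     beat_index = i)
      b$onset_index <- 1L
      b
    }))
}

as_group <- function(beats, run_id = 1L) {
  structure(list(beats = beats,
                 mean_duration = mean(vapply(beats, `[[`, numeric(1),
                                             "duration")),
                 run_id = run_id, start_beat_index = beats[[1]]$beat_index),
            class = "beat_group")
}

test_that("all_pairings crosses every D beat with every U beat", {
  lb <- linear_beats(n_beats = 6)
  # 3 runs x 6 beats per side -> 324 loops
  d_sel <- lapply(1:3, function(r) as_group(lb$d, r))
  u_sel <- lapply(1:3, function(r) as_group(lb$u, r))
  fits <- all_pairings(d_sel, u_sel)
  expect_length(fits, 324)

  # 2 runs x 6 -> 144; 1 x 1 beat -> 1
  expect_length(all_pairings(d_sel[1:2], u_sel[1:2]), 144)
  one <- linear_beats(n_beats = 1)
  expect_length(all_pairings(list(as_group(one$d)), list(as_group(one$u))), 1)

  expect_error(all_pairings(list(), u_sel), "empty")
})

test_that("pairing count law holds over run/group configurations", {
  set.seed(5)
  for (i in 1:8) {
    nd <- sample(1:3, 1); nu <- sample(1:3, 1)
    sd_ <- sample(2:5, 1); su <- sample(2:5, 1)
    d_sel <- lapply(seq_len(nd), function(r)
      as_group(linear_beats(n_beats = sd_)$d, r))
    u_sel <- lapply(seq_len(nu), function(r)
      as_group(linear_beats(n_beats = su)$u, r))
    expect_length(all_pairings(d_sel, u_sel), nd * sd_ * nu * su)
  }
})

test_that("trimmed mean matches the sort-and-slice oracle on random sets", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(7:500, 1)
    trim <- runif(1, 0, 0.4)
    vals <- rnorm(n, 4, 1.5)
    est <- trimmed_mean_pwv(vals, trim)
    want <- oracle_trimmed(vals, trim)
    expect_equal(est$trimmed_mean, want$mean)
    expect_identical(est$n_retained, want$n_retained)
    expect_equal(est$wsd, want$sd)
    expect_identical(est$n_retained,
                     est$n_total - 2L * as.integer(floor(n * trim / 2)))
  }
})

test_that("trimming behaves on the documented examples", {
  set.seed(8)
  v324 <- rnorm(324, 4, 0.5)
  est <- trimmed_mean_pwv(v324, 0.10)
  expect_identical(est$n_retained, 292L)      # 324 - 2 * floor(324 * 0.05)

  same <- trimmed_mean_pwv(rep(4, 50), 0.10)
  expect_identical(same$trimmed_mean, 4)
  expect_identical(same$wsd, 0)

  est0 <- trimmed_mean_pwv(v324, 0)
  expect_identical(est0$trimmed_mean, mean(v324))

  # per-tail variant removes trim_fraction from each tail
  pt <- trimmed_mean_pwv(v324, 0.10, per_tail = TRUE)
  expect_identical(pt$n_retained, 324L - 2L * 32L)
})

test_that("flagged loops are excluded before trimming", {
  fits <- c(lapply(rep(4, 30), make_fit),
            list(make_fit(NA, "negative_slope"),
                 make_fit(NA, "unfittable_loop"),
                 make_fit(NA, "short_fit")))
  est <- trimmed_mean_pwv(fits, 0.10)
  expect_identical(est$n_total, 30L)
  expect_identical(est$n_flagged, 3L)
  expect_identical(est$trimmed_mean, 4)

  all_bad <- lapply(rep(NA, 3), function(x) make_fit(x, "unfittable_loop"))
  expect_error(trimmed_mean_pwv(all_bad), "no-estimate")
})

test_that("symmetric extreme contamination leaves the trimmed mean fixed", {
  set.seed(11)
  core <- rnorm(100, 4, 0.3)
  est1 <- trimmed_mean_pwv(core, 0.10)
  contaminated <- c(core, rep(0.1, 3), rep(12, 3))
  est2 <- trimmed_mean_pwv(contaminated, 0.20)
  # both tails of the contamination fall inside the trimmed region
  expect_equal(est2$trimmed_mean, mean(sort(core)[8:93]))
  expect_lt(abs(est2$trimmed_mean - est1$trimmed_mean), 0.05)
})

test_that("cohort summary mirrors a per-volunteer table", {
  mk_est <- function(pwv) trimmed_mean_pwv(rep(pwv, 20), 0.10)
  single <- cohort_summary(list(a = mk_est(3.9)))
  expect_equal(single$mean, 3.9)
  expect_identical(single$sd, 0)
  expect_true(single$single_subject)

  two <- cohort_summary(list(a = mk_est(3), b = mk_est(5)))
  expect_equal(two$mean, 4)
  expect_equal(two$table$pwv, c(3, 5))
  expect_named(two$table, c("subject_id", "pwv", "wsd", "n_retained"))
})
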