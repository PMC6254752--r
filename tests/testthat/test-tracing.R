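test_that("inner edges of flat bands are traced exactly", {
  rec <- flat_band_recording()
  near <- trace_wall(rec, "near", roi = c(30, 60), threshold = 128)
  far <- trace_wall(rec, "far", roi = c(70, 100), threshold = 128)
  # near inner edge = deepest suprathreshold row; far = shallowest
  expect_true(all(near$rows == 45))
  expect_true(all(far$rows == 81))

  # exclusion intervals are honored (half-open)
  ex <- trace_wall(rec, "near", roi = c(30, 60), threshold = 128,
                   exclusions = list(c(100, 121)))
  expect_true(all(is.na(ex$rows[100:120])))
  expect_false(anyNA(ex$rows[-(100:120)]))
})

test_that("a sinusoidal band is traced within 1 pixel of truth", {
  sb <- sine_band_recording()
  tr <- trace_wall(sb$rec, "near", roi = c(40, 80), threshold = 128)
  ok <- !is.na(tr$rows)
  expect_gt(mean(ok), 0.9)
  expect_true(all(abs(tr$rows[ok] - sb$inner[ok]) <= 1))
})

test_that("tracing-quality error names the threshold", {
  rec <- flat_band_recording()
  expect_error(trace_wall(rec, "near", roi = c(30, 60), threshold = 250),
               "tracing-quality")
})

test_that("smoothing reproduces a line and bridges gaps in a sinusoid", {
  line <- structure(list(rows = 10 + 0.05 * (1:200)), class = "wall_trace")
  sm <- smooth_trace(line, 0.001)
  expect_lt(max(abs(sm$rows - (10 + 0.05 * (1:200)))), 0.1)

  sine <- 60 + 10 * sin(2 * pi * (1:400) / 150)
  gap <- sine
  gap[200:219] <- NA                        # 20-column gap
  sm2 <- smooth_trace(structure(list(rows = gap), class = "wall_trace"))
  expect_true(all(is.finite(sm2$rows)))
  expect_lt(max(abs(sm2$rows[200:219] - sine[200:219])), 1)

  expect_error(
    smooth_trace(structure(list(rows = c(1, NA, NA, 2, NA)),
                           class = "wall_trace")),
    "insufficient-data")
})

test_that("diameter is far minus near times the depth calibration", {
  rec <- flat_band_recording()
  near <- smooth_trace(trace_wall(rec, "near", c(30, 60), 128))
  far <- smooth_trace(trace_wall(rec, "far", c(70, 100), 128))
  d <- diameter_waveform(near, far, value_cal = 0.05, time_cal = 3.5)
  expect_true(all(abs(d$values - (81 - 45) * 0.05) < 1e-9))
  expect_identical(d$kind, "diameter")

  # crossing walls are anatomically implausible
  bad <- far
  bad$rows[5] <- near$rows[5] - 1
  expect_error(diameter_waveform(near, bad, 0.05, 3.5),
               "anatomical-implausibility")
})

test_that("rendered diameter waveform round-trips within 2 calibrations", {
  # smooth raised-cosine pulse: the documented contract fixture; sharper
  # corners than the prescribed spline can follow are a known limitation
  sub <- quiet_subject(seed = 12)
  run <- synth_run(sub, "diameter", n_beats = 5, run_seed = 120)
  tt <- (seq_along(run$values) - 1) * 3.5 / 1000
  run$values <- 2.6 + 0.2 * (1 - cos(2 * pi * tt / 0.857)) / 2
  rm <- render_mmode(run, sub, render_seed = 121)
  rec <- rm$recording
  near <- smooth_trace(trace_wall(rec, "near", rec$suggest$near_roi,
                                  rec$suggest$near_threshold))
  far <- smooth_trace(trace_wall(rec, "far", rec$suggest$far_roi,
                                 rec$suggest$far_threshold))
  d <- diameter_waveform(near, far, rec$value_cal, rec$time_cal)
  expect_lt(max(abs(d$values - run$values)), 2 * rec$value_cal)
  expect_true(all(is.finite(log(d$values))))
})

test_that("the maximum Doppler envelope is traced within 2 calibrations", {
  sub <- quiet_subject(seed = 13)
  run <- synth_run(sub, "velocity", n_beats = 5, run_seed = 130)
  tt <- (seq_along(run$values) - 1) * 3.5 / 1000
  run$values <- 0.5 + 0.45 * sin(2 * pi * tt / 0.857)   # smooth, positive
  rd <- render_doppler(run, sub, render_seed = 131)
  rec <- rd$recording
  u <- trace_doppler_envelope(rec, rec$suggest$doppler_threshold)
  expect_lt(max(abs(u$values - pmax(run$values, 0))), 2.5 * rec$value_cal)
})

test_that("an envelope exactly at the baseline maps to zero velocity", {
  px <- matrix(10, 80, 60)
  px[60, ] <- 200                       # band only at the baseline row
  rec <- us_recording(px, "doppler", 3.5, 0.01, baseline_row = 60)
  u <- trace_doppler_envelope(rec, threshold = 100)
  expect_true(all(u$values == 0))
})

test_that("silent-diastole columns are spline-filled near zero", {
  px <- matrix(10, 80, 200)
  burst <- c(30 * sin(pi * (1:55) / 55)^2, rep(0, 45))
  tri <- rep_len(burst, 200)
  env_row <- 60 - round(tri)
  for (c in seq_len(200)) px[env_row[c]:60, c] <- 200
  # mid-diastole dropouts: those columns have no suprathreshold pixel
  silent <- c(80:94, 180:194)
  px[, silent] <- 10
  rec <- us_recording(px, "doppler", 3.5, 0.01, baseline_row = 60)
  u <- trace_doppler_envelope(rec, threshold = 100)
  expect_true(all(is.finite(u$values)))
  expect_lt(max(abs(u$values[silent])), 2 * 0.01)
})

test_that("envelope tracing ignores uniform background below threshold", {
  sub <- quiet_subject(seed = 14)
  run <- synth_run(sub, "velocity", n_beats = 3, run_seed = 140)
  rd <- render_doppler(run, sub, render_seed = 141)
  rec <- rd$recording
  u1 <- trace_doppler_envelope(rec, 60)
  rec2 <- rec
  set.seed(99)
  noise <- matrix(runif(length(rec2$pixels), 0, 40), nrow = nrow(rec2$pixels))
  rec2$pixels <- pmax(rec2$pixels, noise)   # uniform noise strictly below 60
  u2 <- trace_doppler_envelope(rec2, 60)
  expect_equal(u1$values, u2$values)
})

test_that("artefacts inside declared exclusions do not move the diameter", {
  sub <- quiet_subject(seed = 15)
  run <- synth_run(sub, "diameter", n_beats = 4, run_seed = 150)
  rm <- render_mmode(run, sub, render_seed = 151)
  rec <- rm$recording
  extract <- function(r, excl = list()) {
    near <- smooth_trace(trace_wall(r, "near", r$suggest$near_roi, 128,
                                    exclusions = excl))
    far <- smooth_trace(trace_wall(r, "far", r$suggest$far_roi, 128,
                                   exclusions = excl))
    diameter_waveform(near, far, r$value_cal, r$time_cal)$values
  }
  clean <- extract(rec)
  rec$pixels[seq(rec$suggest$near_roi[1] + 1, rec$suggest$near_roi[2] - 1),
             300:320] <- 255           # bright artefact inside the near ROI
  dirty <- extract(rec, excl = list(c(295, 326)))
  expect_lt(max(abs(clean - dirty)), 1.5 * rec$value_cal)
})
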