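Package: pwvloop
Title: Local Pulse Wave Velocity from Ultrasound Diameter and Velocity
    Waveforms via the ln(D)U-Loop
Version: 0.1.0
Authors@R:
    person("pwvloop", "developers", email = "pwvloop@example.org",
           role = c("aut", "cre"))
Description: Estimates local pulse wave velocity (PWV) in the ascending
    aorta from sequentially acquired ultrasound recordings: M-mode images
    for the diameter waveform D and pulsed-wave Doppler spectrograms for
    the velocity waveform U. Walls and the maximum Doppler envelope are
    traced by grayscale thresholding, smoothed with a smoothing spline,
    segmented into beats at ECG R-peaks, aligned at the systolic upstroke
    onset, and combined into ln(D)U-loops whose early-systolic slope
    equals twice the local wave speed. All cross-run beat pairings are
    aggregated into a trimmed-mean PWV with a within-subject standard
    deviation. A synthetic-data generator renders ultrasound-like images
    with known ground-truth wave speed so the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
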