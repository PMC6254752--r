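{
  "ecg": { "threshold_fraction": 0.8, "refractory_ms": 200 },
  "tracing": { "smoothing_parameter": 0.001 },
  "beats": { "group_size": 6, "upstroke_r2": 0.985 },
  "loop": { "dt_ms": 1.0, "fit_r2": 0.98, "min_fit_ms": 10 },
  "ensemble": { "trim_fraction": 0.1, "per_tail": false }
}
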