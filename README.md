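# fmdetect

Passive detection of fetal movement (FM) from dual 3-axis abdominal
accelerometer recordings.

Counting fetal movements is a routine, low-cost indicator of fetal
well-being, but maternal counting is subjective and tiring. A wearable
alternative straps two 3-axis accelerometers to the abdomen (six channels
at 100 Hz) and detects movement bursts automatically. The hard part is
that the signal of interest — transients of 0.015–0.06 g lasting under
three seconds — sits between maternal respiration (below 0.015 g),
wideband sensor noise, and large maternal body-movement artifacts (above
0.1 g) that mimic fetal activity.

`fmdetect` implements the full detection chain:

* **Preprocessing** — per-window baseline removal and scalar Kalman
  denoising of each axis;
* **Amplitude gating** — the empirical bands A1 = 0.015 g, A2 = 0.06 g,
  A3 = 0.1 g: any axis above A3 vetoes the window as a maternal artifact,
  and only axes with peaks strictly inside (A1, A2) reach the classifier;
* **Dictionary classification** — K-SVD-trained complete dictionaries
  (256 atoms of length 256) for the FM and non-FM classes; a candidate
  window is labelled by comparing its reconstruction errors,

  minimise ‖Y − DX‖²_F subject to ‖x_i‖₀ ≤ T₀,

  coded by orthogonal matching pursuit (OMP, default sparsity T₀ = 3), or
  alternatively by an LMS adaptive filter (ŕ(n) = Σ_m w_m(n) r(n−m),
  e(n) = d(n) − ŕ(n), w_m(n+1) = w_m(n) + 2μ e(n) r(n−m)) matched against
  every atom;
* **Mask fusion** — the six per-axis bits M(1:6) are OR-combined into the
  window label;
* **Evaluation** — consecutive FM windows merge into events, scored
  against maternal-perception annotations as TDR = 100·DME/TMF and
  PPV = 100·DME/(DME+FD);
* **Synthetic data** — a seeded generator of annotated recordings and
  training corpora reproducing the amplitude taxonomy above, so the whole
  system trains and evaluates with no external data.

The methods vignette (`vignettes/fm-detection-methods.Rmd`) documents the
models, every tunable parameter, and the design choices in detail.

## Worked example

Train the dictionary pair on a synthetic corpus, generate an annotated
hour-long recording, and run detection:

```r
library(fmdetect)

dicts <- train_dictionaries(synth_config(seed = 1), n_per_class = 1000)
print(dicts$D1)
#> K-SVD feature dictionary (FM): 256 x 256, T0 = 3
#>   24 iteration(s), final ||Y - DX||_F = 6.492 (converged)

rec <- make_recording(synth_config(duration_s = 3600, seed = 2001))
print(rec)
#> fm_recording: 360000 samples x 6 channels @ 100 Hz (3600.0 s)
#>   annotations: 7 event interval(s)

det <- run_detection(rec, pipeline_config(), dicts$D1, dicts$D2, verbose = TRUE)
#> run_detection [OMP]: 1406 windows (22 artifact, 14 candidate-bearing), 7 event(s) detected
print(det)
#> fm_detection [OMP]: 1406 windows, 7 detected FM event(s)
#>   gate: 22 ARTIFACT window(s), 14 window(s) with candidates
#> FM detection metrics
#>   TMF = 7, DME = 7, FD = 0
#>   TDR = 100.00%, PPV = 100.00%

head(det$events, 3)
#>   start_s   end_s
#> 1  215.04  217.60
#> 2 1031.68 1034.24
#> 3 1886.72 1889.28
```

Reading the output: the hour splits into 1406 non-overlapping 2.56 s
windows; 22 were vetoed by the artifact gate (injected maternal
movements), 14 carried candidate axes, and the classifier confirmed the
windows covering all 7 annotated movements with no false detections —
TDR and PPV of 100% on this clean synthetic hour. `det$decisions` holds
the per-window log (gate flag, 6-bit mask, fused label);
`sweep_sparsity()` tabulates TDR/PPV across OMP sparsities.

A thin command-line front end over the same functions ships at
`inst/cli/fmdetect` with subcommands `synth`, `train`, `detect`,
`evaluate` and `sweep`, all accepting `--config` (flat `key = value`
file) and `--seed`.

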