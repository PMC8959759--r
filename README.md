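# respiradar

Contactless respiration monitoring for up to two subjects, combining
impulse-radio ultra-wideband (IR-UWB) radars with a depth-camera skeleton
tracker — implemented as a fully simulatable R pipeline, no hardware
required.

## The problem and the method

Clinically interesting breathing patterns — eupnea (normal breathing),
Cheyne-Stokes respiration, Kussmaul respiration, apnea — can be read from
the chest's millimetric micro-motion, which an IR-UWB radar sees as an
amplitude modulation of the range bin at the chest's distance. A radar
alone, however, does not know where people are, whether they are moving,
or which of several radars sees a subject's chest squarely. respiradar
implements the fused pipeline:

1. **Localization** — skeleton joints (chest, shoulders) arrive in a
   tilted camera frame and are corrected by the rotation
   `p0 = Rx(A) · prot` (tilt `A = −30°` by default). A subject is *moving*
   when the average shoulder-midpoint speed exceeds 0.7 m/s.
2. **Radar selection** — a radar covers a subject inside its 60° beam and
   under 5 m. Among covering radars, the one with orientation angle
   `∠RMD = arccos[(RM² + MD² − RD²) / (2·RM·MD)]` closest to 90° (squarely
   facing) wins; when two subjects sit within 6 range bins (≈ 30 cm) of
   the same distance to one radar, that radar's bins carry both echoes and
   the affected subject falls back to its next-best radar.
3. **Extraction** — after truncated-SVD clutter removal and background
   subtraction, the bin with maximal slow-time variance among
   `round(d / 0.0522 m) ± 3` is the respiratory signal.
4. **Classification** — a random forest (100 trees) on 13 statistical
   features (peak amplitudes, Hilbert instantaneous frequency, short-term
   energy) labels each 15-s chunk with one of five patterns; a
   morphological discriminator (signal quality index + crescendo-
   decrescendo test) confirms or overrides the label.
5. **Rate estimation** — for quality-passing eupnea only, a 0.1–0.5 Hz
   (6–30 breaths/min) zero-phase Butterworth bandpass and the mean
   peak-to-peak interval give `RR = 60 / Δt`.

A stream orchestrator slides 15-s windows at a 3-s stride (12-s overlap)
over a recording, each window containing 255 samples at 17 Hz. A built-in
simulator generates respiratory waveforms for all five patterns, radar
matrices with clutter and noise, and skeleton streams, and is the basis of
the whole test suite.

## Worked example

A subject 2.09 m in front of a wall radar, breathing normally at
15 breaths/min, recorded for 30 s:

```r
library(respiradar)

scene <- scene_config(radars = list(
  radar_pose(1, c(0, 0.5, 0), c(0, 1)),      # front wall, boresight +z
  radar_pose(2, c(-2.5, 0.5, 2.5), c(1, 0))))
subject <- subject_script(
  1, data.frame(time_s = 0, x = 0, y = 0.5, z = 2.09), facing_deg = 180,
  pattern_schedule = list(list(start_s = 0, end_s = 30,
    params = pattern_params("eupnea", rate_bpm = 15, seed = 1))))

m <- gen_radar_matrix(scene, 1, list(subject), duration_s = 30, seed = 2)
m
#> radar_matrix: radar 1, 510 slow-time samples x 180 range bins (30.0 s at 17 Hz)

chunk <- extract_respiratory_signal(preprocess_radar_matrix(m),
                                    chest_distance_m = 2.09)
chunk
#> resp_chunk: 510 samples at 17 Hz (30.0 s), subject NA, radar 1, bin 40

evaluate_signal_quality(chunk)
#> quality_report: 6 valid breaths, interval NSD 0.038 -> pass

estimate_rr(bandpass_filter(chunk))
#> rr_estimate: 15.00 breaths/min (7 peaks, mean interval 4.00 s)

model <- train_classifier(gen_training_database(seed = 1), seed = 1)
discriminate(classify(model, chunk), chunk)
#> pattern_label: eupnea (classifier)
```

The extractor lands on range bin 40 — `round(2.09 / 0.0522)`, the bin the
simulator modulated — the quality index counts 6 regular breaths, and the
interval estimator recovers the scripted 15 breaths/min exactly (mean
peak-to-peak interval 4.00 s).

For file-based sessions there is a command-line driver (installed under
`exec/`):

```sh
respiradar train    --seed 1 --out model.rds
respiradar simulate --config scene.yaml --duration 60 --seed 2 --out simdata
respiradar run      --config scene.yaml --input simdata \
                    --model model.rds --out results.csv
respiradar evaluate --model model.rds --seed 99
```

`run` writes one audit row per (window, subject): motion status, selected
radar and why, range bin, classifier and final labels, quality flag, and
the rate when the workflow gate allows one.

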