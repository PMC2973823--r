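# rgcdecode

Decoding **what** (stimulus colour) and **when** (stimulus onset time)
from retinal ganglion cell (RGC) spike trains.

## The scientific problem

Most analyses of the neural code clock everything from stimulus onset:
first-spike latencies, trial-aligned filters, peri-stimulus histograms.
But a brain has no external trigger line — onset time must itself be
decoded from the spikes. In the archer fish, a behaving animal that
reports two-alternative colour decisions by shooting at a target, the
retina faces exactly this split problem: brief 66 ms red/green flashes at
unpredictable times and intensities must be both *detected* and
*discriminated*.

`rgcdecode` implements the full decoding pipeline for this setting:

* **Synthetic populations** — inhomogeneous-Poisson RGCs with the
  response statistics of flash-stimulated archer-fish retina: baselines of
  6–10 Hz, stronger/earlier responses to green than red, a ~70 ms
  red–green latency shift in the ~5% of strongly tuned (OFF) cells, a
  small green-only subgroup, ~60% colour-blind cells, and
  intensity-dependent gain and latency.
* **"What" readouts** (single cell, onset given) — a linear–nonlinear
  (LN) estimator $\hat s = \sum_\tau h(\tau)x(\tau) + C$ fitted by least
  squares on 25 ms / 50%-overlap spike-count windows (375 ms filter)
  followed by an optimal threshold $\theta \approx 1.5$; and a
  first-spike-latency maximum-likelihood classifier.
* **"When" readout** (population) — a multi-cell LN detector
  $\hat s_t = \sum_i \sum_\tau h_i(\tau)\, x_i(t+\tau) + C$ reconstructing
  the binary flash indicator with 250 ms (or 125 ms) filters; onsets are
  first threshold crossings, scored with a ±125 ms criterion (false
  negatives per true event, false positives per detected event), with
  timing split into RMS error and the red–green bias. Naive total-count
  and weighted-count rate detectors are included as baselines, plus a
  population-size sweep averaging 50 random subgroups per size.
* **Two-stage causal readout** — detect onset from ~100 cells with 125 ms
  filters, then classify colour from a single cell using only spikes after
  the detection interval (parallel or serial learning).
* **ISI Bayesian readout** — joint/conditional/posterior tables of
  interspike intervals vs stimulus, ML and MAP classifiers, and the
  closed-form false-alarm interval $1000/(r\,f)$ ms for a baseline rate
  $r$ with confusable ISI fraction $f$.
* **Cell typing and geometry** — spike-triggered averages under Gaussian
  full-field flicker with ON/OFF classification, and pinhole-eye estimates
  of retinal image size and the photoreceptor / ganglion-cell counts that
  set the scale of the encoding population.

## Worked example

```r
library(rgcdecode)

stim <- generate_stimulus(500, seed = 1)      # 66 ms flashes, 1.1-2.1 s gaps
rec  <- generate_population(population_spec(100, seed = 2), stim)

halves   <- split_recording(rec)              # train on one half, test on the other
detector <- fit_onset_ln(halves$train, filter_length = 250)
ev       <- evaluate_detector(detector, halves$test)
print(ev$detection)
print(ev$timing)

cls  <- vapply(rec$cell_params, function(p) p$selectivity_class, "")
best <- rec$cell_ids[cls == "tuned"][1]
acc  <- colour_accuracy(rec$trains[[best]], stim, method = "ln")
cat(sprintf("best-cell colour accuracy (held out): %.1f%%\n", 100 * acc$accuracy))

print(run_two_stage(rec, readout_cell = best))
```

Output:

```
Detection: FN 0.0% (of 250 true), FP 0.0% (of 250 detected), +/-125 ms
Timing: RMS 17.3 ms, red-green bias 7.3 ms (n=250)
best-cell colour accuracy (held out): 94.0%
Two-stage (parallel learning, ln colour readout)
  accuracy with estimated onset: 93.2%
  accuracy with exact onset:     94.8%
  matched 250 flashes, missed 0
```

Reading this: the 100-cell LN detector finds every held-out flash within
±125 ms with no false alarms, places onsets with 17 ms RMS error, and
over-delays red relative to green by ~7 ms (the colour-dependent bias no
uniform delay line could fix). A single tuned cell then reads colour at
94% given true onsets — and loses only ~1.6 percentage points when it must
rely on the population's *estimated* onsets, using only spikes fired after
the causal detection interval. Single cells cannot do the detection part:
none reaches both error rates below 5%.

A thin CLI covers the same pipeline from the shell
(`inst/cli/rgcdecode`): `simulate`, `train-what`, `eval-what`,
`train-when`, `detect`, `sweep`, `two-stage`, `isi-decode`, `sta`,
`geometry`, reading/writing delimited-text spike tables and stimulus
logs, YAML configs and JSON reports.

## The methods vignette

`vignettes/decoding-what-and-when.Rmd` documents the simulation model and
its calibration, every decoder definition, the numerical conventions
(window edges, threshold search, tie-breaks, degenerate inputs), and what
the synthetic tests do and do not establish about real retinas.
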