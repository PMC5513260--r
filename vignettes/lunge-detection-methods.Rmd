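---
title: "Decision-tree detection of rorqual lunges: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree detection of rorqual lunges: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungedetect)
```

## The problem and the signal model

A lunge is a discrete, energetically extreme feeding event: the whale
accelerates toward a prey patch, opens its jaws to engulf a volume of water
comparable to its own body, and stalls. On a suction-cup archival tag this
produces three roughly synchronous signatures:

* **flow noise** — band-limited (66–94 Hz) RMS level of the tag hydrophone,
  a monotone proxy for swim speed. It ramps up over ~10 s to a maximum at
  the moment of peak speed, then collapses 8–12 s later as the opened mouth
  brakes the animal. The drop is large: ≥ 15 dB in deep lunges, ≥ 10 dB near
  the surface where ambient noise is higher.
* **jerk** — `fs · ‖Δa‖₂`, the rate-scaled norm of successive triaxial
  accelerometer differences. The engulfment transient produces a burst,
  followed by a low-jerk interval while the water is filtered. Differencing
  cancels the slowly varying gravity/orientation component, so jerk isolates
  fast kinematics. The `fs` scaling puts all tags (50–500 Hz here) on the
  m/s³ scale, though higher-rate tags still resolve intrinsically larger
  jerk, which is why they discriminate surface noise better.
* **roll** — shallow lunges usually involve a sustained (> 3 s) body roll
  beyond 20°, which deep lunges often lack; the detector therefore uses roll
  only in its shallow branch.

Absolute signal amplitude is *not* comparable across deployments: tag
placement on a free-swimming whale is uncontrolled, and the farther the tag
sits from the head the weaker every signature. All thresholds are therefore
quantiles of each record's own distribution ("top 16 %/22 %", "bottom
32 %/66 %") rather than physical units.

## The decision tree

The series are reduced to 1 s bins (`bin_features()`): modes of quantized
jerk, flow and roll, the sample SD of raw roll, and mean depth. Each branch
(shallow/deep) then runs, over the whole record:

1. **Peak finding** (`find_top_peaks()`): bins strictly above the
   `1 − top_fraction` quantile form maximal runs; each run's argmax is one
   peak. The strict inequality makes a constant series peak-free. In the
   shallow branch, jerk and flow peaks from runs shorter than 2 bins are
   discarded (`filter_short_runs()`) — surfacing impacts spike for a single
   second, real lunges stay elevated longer.
2. **Roll screening** (shallow only, `roll_criterion_filter()`): a roll-SD
   peak survives only if ≥ 3 consecutive bins with |roll mode| > 20° lie
   wholly within ±3 s of it.
3. **Pairing and exclusions** (`pair_and_filter()`): a flow peak survives if
   a jerk peak lies within 5 s; (shallow) a surviving roll-SD peak lies
   within 10 s; the binned flow mode falls by the branch's drop (10/15 dB)
   somewhere in the +8..+12 s window; and a jerk-drop time — the first bin
   of a bottom-quantile jerk run — follows the paired jerk peak within 15 s.
   Jerk drops with *any* jerk peak within ±4 s are removed first: a
   spike-then-silence that fast is the tag breaking the surface, not
   engulfment.
4. **Depth gating and deduplication**: shallow candidates are kept where the
   interpolated depth at the candidate time is < 30 m, deep candidates at
   ≥ 30 m; the union is clustered transitively at 15 s and the last member
   of each cluster kept (a whale needs tens of seconds to process a
   mouthful, so nearer detections are one event).

Running both branches over the full record and gating afterwards (rather
than segmenting the record at 30 m first) avoids truncating signatures that
straddle the boundary. Candidates whose +8..+12 s window runs off the record
end cannot be evaluated and are discarded rather than padded.

## Numerical choices

* **Quantile definition**: linear-interpolation empirical quantile
  (`stats::quantile` type 7). The oracle tests pin this, so any equivalent
  definition could be substituted consistently.
* **Mode on continuous data**: continuous series are quantized before
  voting — 0.5 dB for flow, 1° for roll, and for jerk 1 % of the record's
  99th-percentile jerk (relative, so the step follows the tag's rate-
  dependent jerk scale). Ties break to the smallest value, the convention of
  common statistical mode implementations. `quant_jerk_step` can fix an
  absolute step instead; this matters for nearly noiseless records, see
  below.
* **Flow-drop test**: uses the *minimum* of the binned flow mode over the
  +8..+12 s window against the flow mode at the peak. (An endpoint test
  would be more fragile to the exact drop delay.)
* **Dedup window**: 15 s by default; a 20 s variant is in circulation for
  this decision table and is available via `dedup_window_s`.
* **Flow level reference**: unity (arbitrary). Only quantiles and relative
  drops are used, never absolute level, so no hydrophone calibration or
  speed calibration is attempted.
* **Band filtering**: 4th-order Butterworth applied forward-backward
  (zero-phase), RMS over non-overlapping 0.2 s windows, floor-clipped at
  −120 dB so silence stays finite.

## The synthetic generator

Real tag archives from the validation cohort are not redistributable, so the
package carries a generator (`synthetic_spec()` / `generate_record()`) whose
defaults emulate the study conditions: 10 lunges per record, interlunge
gaps ~ N(44.5, 19.1²) s floored at 30 s (the floor keeps canonical
signatures disjoint and outside the dedup window; the unfloored sampler,
`draw_interlunge_gaps()`, reproduces the 44.5 s mean), mixed shallow
(12–20 m) and deep (45–75 m) lunges, a monotone dive profile interpolated
through the lunge depths with surface intervals at the record ends, AR(1)
accelerometer noise (SD 0.05 m/s², ρ = 0.6) plus a 0.25 Hz fluking
oscillation on the longitudinal axis, background flow noise at 90 dB with
SD 2.5 dB — half the 5 dB margin between the injected 20 dB flow drop and
the 15 dB deep criterion, so the binding criterion is genuinely exercised —
roll noise of 2°, and a surfacing artifact (accelerometer spike, brief flow
bump, 2 s quiet interval) at every surface interval. Flow noise is
synthesized directly as a 5 Hz dB series, since that is all the detector
consumes; `compute_flow_noise()` is exercised separately on synthesized
audio.

What the generator does **not** emulate: realistic ocean-noise spectra,
wind-dependence of ambient level near the surface, tag-placement variability
(the dominant source of inter-whale performance differences in real
cohorts), fluking harmonics, prey-driven behavioral correlation between
successive lunges, and partial or aborted lunges. Passing the synthetic
recovery experiment therefore demonstrates that the decision tree is
implemented correctly and is robust at the stated noise levels — not that it
would attain the same rates on an arbitrary new deployment.

## Problem sizes and the validation experiments

The package validates itself three ways:

1. **Evaluation arithmetic**: every published per-whale TP/FP rate of the
   19-whale fin whale cohort is recomputed from the corresponding count
   tables (`whale_lunge_counts()` → `compute_rates()`), and the cohort
   averages from `cohort_summary()`. The "adjusted" FP convention — drop
   whales whose 100 % FP rate arises from a record with no true feeding in
   the category — reproduces the published cohort means and SDs. Two printed
   cohort means (the low-frequency-band adjusted FP and the secondary-review
   deep adjusted FP) are inconsistent with their own printed SDs; in both
   cases the recomputed SD matches exactly, so the tests pin the SDs.
2. **Operation oracles**: the quantile/run/peak/matching primitives are
   pinned against independent brute-force re-implementations on seeded
   random series, and the detector against constructed single-candidate
   scenes where each rule is violated one at a time.
3. **Synthetic recovery**: 20 seeded records of 10 lunges each (~500 s,
   50 Hz — about 1.5 h of tag time in total, sized to run in seconds) are
   generated, detected and scored; the cohort mean TP must reach the
   published overall 92.8 % and the mean FP stay within 9.5 %. At the
   default conditions the detector recovers every injected lunge with no
   false positives, so both bounds hold with a wide margin.

## Known limitations

* **The noiseless limit and relative quantization.** As sensor noise → 0
  the background jerk approaches the fluking signal alone (~0.5 m/s³),
  which is *below* the default relative jerk quantization step (1 % of the
  p99 jerk, set by the lunge bursts to ~1.7 m/s³). The whole background
  then quantizes to zero and the jerk-minimum rule loses its contrast, so
  recovery collapses — not a bug but a property of relative quantization.
  With a step that resolves the background (e.g. `quant_jerk_frac = 0.001`
  or an absolute `quant_jerk_step`), recovery in the noiseless limit is
  100 % TP / 0 % FP, which the test suite asserts. Practically: for very
  clean records, set the jerk quantization to resolve the background
  process, not the bursts.
* Detections inherit 1 s bin resolution; sub-second lunge timing is out of
  scope (the evaluation tolerance is 10 s).
* The depth split is a hard 30 m boundary at the detection time; animals
  feeding exactly at the boundary can flip category with depth-sensor noise.
* The evaluation's totals are sums of the per-category scores; a detection
  can only match truth within its own depth category.
* Thresholds are global per record. Records mixing long non-feeding
  transits with short feeding bouts shift the quantiles and may need
  per-segment runs.
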