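---
title: "Classifying eye movements from two temporal EEG channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying eye movements from two temporal EEG channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eogbci)
```

## The signal and the problem

Electrodes behind the ears record a mixture of cortical EEG and the much
larger, slower electrooculogram (EOG) generated by the corneo-retinal dipole.
A horizontal saccade drives the left and right temporal sites with opposite
polarity; vertical movements and eyelid closure drive them with the same
polarity. Two derived signals therefore carry almost all the usable
information:

* `Y1 = X_L − X_R` — the channel difference. Horizontal saccades add
  constructively here; common-mode activity (blinks, vertical movements,
  mains interference) cancels.
* `Y2 = smoothed(X_L + X_R)` — the channel sum. Vertical movements and
  blinks add constructively; horizontal saccades cancel. Vertical
  information survives in the sum only because the two eyes do **not** move
  at perfectly mirrored angles about the midline, so the two electrodes see
  slightly different vertical EOG; the sum amplifies that shared component.

The package classifies each 1-s block of a 256 Hz recording into one of six
classes — `up`, `down`, `left`, `right`, `center`, `blink` — using wavelet
detection plus a fixed-threshold decision tree, and maps the decision stream
onto continuous control of a 2D obstacle-evasion game. Everything is causal:
the system is modeled as a real-time loop that only ever holds one 1-s
buffer plus carried filter state, so zero-phase (forward–backward) filtering
is deliberately not used, and the constant group delay this costs is shared
by all classes.

## Processing chain and its assumptions

1. **Front-end.** 8th-order Butterworth band-pass 0.5–100 Hz followed by a
   4th-order 48–52 Hz band-stop notch against 50 Hz mains. Designed with
   `signal::butter` (an order-4 band design yields the 8th-order band-pass
   transfer function); pole moduli are checked at construction. Filtering
   runs in Direct Form I with the trailing input/output samples carried
   between blocks, which makes block-streamed output *exactly* equal to
   whole-record output — the property the tests assert at 1e-6 µV.
2. **Band split at 10 Hz** (4th-order pair). Only the low band, 0.5–10 Hz,
   feeds detection: saccades, vertical movements and blinks are all
   sub-10 Hz events, while alpha and higher cortical rhythms live above.
   The high band is computed and exposed for inspection but unused.
3. **Baseline correction**, block-local: the slow baseline is estimated as a
   centered 1-s moving average (edge-truncated at the block borders) and
   subtracted, then the residual mean is removed so each block is exactly
   zero-mean. Subtracting the *smoothed signal* — rather than outputting it —
   is the reading of "baseline correction" that preserves the events: a
   fast biphasic transient has near-zero net area, so its moving average is
   close to zero and the transient passes through the correction intact,
   while drift slower than the window is removed. The alternative reading
   (output the smoothed, demeaned signal itself) would annihilate any
   zero-net-area transient shorter than the window and leave drift mostly
   untouched, which defeats the detector it feeds.
4. **Derived pair.** `Y1` is the raw difference; `Y2` smooths the sum with a
   100-ms moving average. `Y1` is left unsmoothed — horizontal saccades are
   the sharpest, best-conditioned events and smoothing would only blunt
   their velocity feature. Both operations are block-local, matching a
   per-block real-time loop.

### Detection: Haar scalogram

The Haar continuous wavelet transform is computed on each derived signal:
`C(a,b) = a^{-1/2} Σ_t x(t) ψ((t−b)/a)`, Haar mother (+1 on the first half
support, −1 on the second), on eight dyadic scales with supports of
8–64 samples (31–250 ms at 256 Hz). The grid spans saccadic transients
(30–150 ms) through blink pulses (100–300 ms). Scales must be even sample
counts so the two half-supports balance and a constant signal yields exactly
zero coefficients — that zero-mean property is what makes total scalogram
energy `E = Σ C²` a pure *event* energy. Events are timing-free: detection
does not assume a cue grid, only that `E` clears a per-signal threshold; the
event is then located at the maximum-|coefficient| position (reported at the
wavelet's transition point, i.e. the event center). The implementation uses
cumulative sums — each coefficient is a difference of two box sums — and is
tested against a brute-force double-loop oracle at 1e-6 relative error.

Two streaming refinements deal with the block boundaries the 1-s contract
creates: each block is analysed with the previous block's final 250 ms
prepended (detections whose center falls in that context belong to the
previous block and are dropped), and a 500-ms per-signal refractory period
prevents one biphasic transient from being counted in two consecutive
blocks. Energies are accumulated only over coefficients centered in the
block proper, so thresholds calibrated on bare blocks transfer unchanged.

### Features and the decision tree

Over a 51-sample window (200 ms at 256 Hz is 51.2 samples; 25 samples each
side of the event gives an odd, symmetric window) the classifier measures:
maximum wavelet coefficient; trapezoidal areas of the positive and the
negative part (µV·s, `pracma::trapz`); peak-to-peak amplitude (µV); maximum
first-difference velocity (µV/s); and the sign of the first excursion beyond
25% of the window's absolute maximum (`lead_sign` — the 25% fraction rejects
noise-induced early crossings). A net-to-total area ratio
`|auc_pos + auc_neg| / (auc_pos − auc_neg)` summarises pulse shape: 0 for a
perfectly balanced biphasic transient, 1 for a one-sided pulse.

The tree, evaluated once per block:

1. no supra-threshold event on either signal → `center`;
2. `Y2` event with amplitude ≥ `blink_amp_min`, area ratio ≤ `blink_sym_max`
   and `E_y2 ≥ ratio_hv · E_y1` → `blink`;
3. `Y1` event with `E_y1 ≥ ratio_hv · E_y2` (or no `Y2` event) → `left` if
   the leading lobe is positive, `right` if negative;
4. otherwise a `Y2` event → `up` (positive lead) or `down` (negative);
5. any feature of the winning event below its floor → `center`.

A point worth recording: before filtering, a blink is monophasic (a
Gaussian-like pulse) and a saccade biphasic, which suggests blinks should
have the ratio near 1. After the causal zero-DC front-end the opposite
holds — the filter balances the blink's hump with an undershoot, so within
the 200-ms window the blink is the most area-balanced event (ratio
≈ 0.02–0.1), while the up/down window catches an unbalanced slice of a
longer transient (ratio ≈ 0.2–0.35). The `≤ blink_sym_max` direction of the
test reflects the processed, not the raw, morphology. Amplitude remains the
stronger blink discriminator; the ratio and energy-dominance conditions
mop up.

The polarity convention (leftward gaze → positive `Y1` leading lobe; upward
gaze and blink → positive `Y2` leading lobe) is a single config constant
(`classify$polarity`), and flipping it exactly swaps left/right and up/down —
a property the tests exercise. Swapped electrode leads are therefore a
one-flag fix, not a recalibration.

### Calibration

`calibrate_thresholds()` needs a labeled feature table with at least five
examples per class, including `center`:

* detection energy thresholds: noise-block mean + 4 SD per signal (a
  conservative gate; scalogram energy of stationary noise concentrates well
  below it);
* the four feature floors: midpoint between the event population's
  (mean − 2 SD) on each class's active signal and the noise population's
  (mean + 2 SD), floored at zero — for identical populations this degrades
  gracefully to the common mean and the classifier falls back to `center`;
* blink amplitude floor and symmetry ceiling: midpoints of the *class means*
  of the blink and up/down populations. These separate two event classes
  rather than events from noise; the ±2 SD-edge rule is asymmetric there (it
  hugs whichever population is tighter), while the midpoint of means is the
  natural symmetric boundary;
* `ratio_hv` = 1.5 is a fixed default, not calibrated: channel
  antisymmetry/symmetry puts horizontal and vertical events orders of
  magnitude apart on the `E_y1/E_y2` ratio, so any modest constant works and
  a calibrated one would add a data dependence with no discriminative gain.

## The synthetic generator

No recordings accompany the study design this package operationalises, so
`synth_trial()`/`synth_dataset()` generate labeled data with the morphology
the pipeline assumes:

* **saccades** (`left`/`right`): antisymmetric biphasic transients, one
  80-ms raised-cosine lobe per phase, 60 µV, opposite polarity on the two
  channels. Generating the post-filter *transient* directly (rather than a
  sustained gaze step that the 0.5 Hz high-pass would differentiate anyway)
  keeps the noiseless limit interpretable;
* **vertical movements** (`up`/`down`): the same biphasic shape, common mode,
  with channel gains 1.3 : 1 (`vertical_asymmetry`) standing in for the
  non-mirrored eye geometry; `Y2` carries the signature and `Y1` keeps a
  small residue;
* **blink**: a Gaussian pulse (SD = blink duration/4 = 62.5 ms, 120 µV) on
  both channels equally;
* **background**: band-limited pink (1/f) noise (8 µV SD), 10 Hz alpha
  bursts at ~20% duty cycle, common-mode 50 Hz mains (5 µV), and < 0.3 Hz
  drift (20 µV). Amplitudes are order-of-magnitude EOG/EEG values at
  temporal sites; the true scale for this montage is not established, so all
  are config-exposed — but the defaults are fixed once and are the study
  conditions for every test in the package.

The 60-s `synth_trial()` follows the cued protocol: 10 s fixation, four
directional events in randomised order at 15/25/35/45 s ± 1 s, and three
blinks in the final 10 s (54/55.5/57 s ± 0.5 s — one deliberate triple-blink
toggle gesture, which the decision-log utility `blink_toggles()` recognises
within a 5-s span). `synth_dataset()` yields a balanced design of `n`
segments per class (five event classes plus noise-only `center`). Segments
are 3 s with the event centered in the middle 1-s block: the causal filters
need settle time, and calibration and scoring read the middle block only.
Per-segment seeds derive deterministically from the master seed.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: inter-subject and inter-session variability,
electrode impedance drift and motion artifacts, overshoot/glissades in real
saccades, the strong within-class amplitude variability of natural blinks,
and any correlation between eye kinematics and the background EEG. The
generator's clean class separation at default settings yields held-out
accuracies well above what human recordings produce; the package's accuracy
numbers characterise the implementation, not human performance.

## Game control

Decisions map to the command vocabulary: `left`/`right` → move commands, all
other classes → stop; two successive same-direction decisions add a
speed-up, two successive opposite decisions a speed-down. The base command is
a majority vote over the last 3 mapped directions — the smallest window with
a strict majority — which absorbs the gaze's return to center after a
saccade (the return would otherwise read as an opposite command; the tests
assert the canonical left-then-misread-right sequence shifts net velocity by
at most one 0.1 increment). Stop is exempt from the vote and acts
immediately. The character's velocity integrates ±0.1 per command, clamped
at ±0.5 (5 increments; unspecified by the design, chosen for stability,
configurable). Meteors fall with 0.01/step acceleration capped at 0.1/step;
five release points draw exponential inter-release delays ("semirandomised"
is unspecified; memoryless is the simplest seed-controlled choice) with the
rate set so all points together release on average 3 per repetition, one
repetition being the 15 steps a meteor needs to cross the stage. A release
attempted while five meteors are airborne is deferred, not dropped, so the
long-run release rate is preserved; the concurrency cap is asserted at every
step.

## Numerical choices and degenerate inputs

* Moving averages truncate (shrink) their window at signal edges — causal
  friendly and deterministic; no reflection padding.
* Wavelet coefficients are computed only where the support lies fully inside
  the signal; argmax ties resolve to the first (smallest-scale, earliest)
  position, making decisions fully deterministic.
* A recording shorter than one block streams to zero blocks with a warning;
  a trailing partial second is dropped, never padded — the real-time loop
  only ever sees whole buffers.
* Flat windows give all-zero features with `lead_sign` 0, which the tree
  sends to `center`.
* The area-ratio denominator guards against zero total area (flat window →
  ratio 0).
* EDF input honours the physical-dimension field and converts mV/V to µV;
  16-bit quantisation bounds the round-trip error.

## Problem sizes

The test suite and the acceptance script run at desk scale: calibration and
held-out evaluation use 10 segments per class (60 blocks scored), the noise
robustness sweep uses 30 segments per class at four noise levels, chance
levels are Monte-Carlo checked at n = 100,000 draws, and the meteor
schedule is averaged over 1000 repetitions. These sizes keep every
statistical check's sampling error well inside its decision margin while the
whole suite completes in about a minute.

## Known limitations

* Fixed thresholds assume the calibration and deployment distributions
  match; there is no adaptation or drift tracking.
* The 5-class closed-eyes mode is represented only as a label merge
  (blink → up); auditory cueing and closed-lid signal changes are not
  modeled.
* One decision per second bounds the command rate by design; faster control
  would need overlapping blocks and a revised refractory rule.
* The Haar scale grid tops out at 250 ms; pathologically slow eye movements
  (smooth pursuit) are out of scope, as are head/body motion artifacts.
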