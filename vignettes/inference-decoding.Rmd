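---
title: "Inference decoding of illusory-contour representations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference decoding of illusory-contour representations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdecode)
```

## The scientific problem

When aligned "pac-man" inducers are arranged so that their cut-outs line
up, observers perceive an illusory contour (IC): an edge with no physical
luminance contrast.  A population of visual cortical neurons that
represents this *inference* — rather than the raw pixels — should
respond to the illusory bar as if it were a real bar.  `icdecode`
implements a complete analysis chain for asking that question of
trial-aligned population recordings, and a synthetic-population
simulator that plants the structure the analyses are designed to detect,
so every stage can be validated against ground truth.

The chain has five stages:

1. **Stimulus battery** (`stimulus_spec()`, `render_battery()`).  Four
   white circles (30° diameter, diagonal centers 46° apart, leaving a
   16° central gap) carry black bar segments 16° long.  `I_C1` and
   `I_C2` place the bars so a 135° or 45° illusory bar spans the gap
   (orientations are measured clockwise from vertical).  The controls
   `L_C1`/`L_C2` recombine the top and bottom halves of the two I_C
   images: every local segment is preserved but no illusory bar forms.
   With bars 16° long and a 16° gap the illusory bar's support ratio is
   2·16/(2·16+16) = 2/3.  Real-edge probes complete the battery:
   `T_REk` contains the inducer segment shared by `I_Ck` and `L_Ck`
   plus an outlined real edge spanning the gap; `X_REk` is a
   full-length outlined real bar at the position and orientation of the
   illusory bar in `I_Ck`; `In_q`/`Out_q` show single inward or
   outward inducer segments per quadrant; `blank_circles` shows the
   circles alone (they persist through the inter-trial interval and are
   excluded from all ink-overlap computations).

2. **Simulator** (`make_neurons()`, `simulate_population()`): see below.

3. **Functional classification** (`find_ic_encoders()` and relatives).
   *IC-encoders* respond to exactly one I_C image and to neither L_C
   image (Kruskal–Wallis omnibus over blank/I_C1/L_C1/L_C2/I_C2
   followed by a Tukey–Kramer comparison on mean ranks).  *Segment
   responders* respond more to the inward than the outward segment of
   one quadrant (one-sided rank-sum).  *LC-encoders* mirror the IC rule
   with roles swapped.

4. **Decoding** (`train_cv_decoder()`, `probe()`, `tre_inference()`,
   `xre_inference()`).  A linear SVM in a one-vs-one scheme is trained
   to classify I_C1/L_C1/L_C2/I_C2 trials under stratified 10-fold
   cross-validation; each fold z-scores every neuron by its *training*
   trials.  "Inference decoding" probes the trained decoder with
   held-out real-edge trials: if the population represents the
   inference, `T_REk` trials are classified as `I_Ck` more often than
   as `L_Ck` (score = fraction(I_C) − fraction(L_C), chance 0), and
   I_C trials probe a binary X_RE1-vs-X_RE2 decoder above the 0.5
   chance level.  `zero_out()` and `train_subset()` attribute the
   inference signal to neuron subsets.

5. **Circuit readouts**: `holo_cross_decode()` asks whether
   holography-evoked activity in non-photoactivated neurons (>50 µm
   from every target; >25 µm in mesoscope mode) is classified as the
   targeted ensemble's visual image — the decodable signature of
   pattern completion; `compute_ccg()`/`call_connection()` infer
   putative excitatory connections from slow-rate-corrected spike-train
   cross-correlograms.

## The generative model

Each neuron's response on a visual trial of stimulus $s$ is

$$ r_i = b_i + \gamma_t\,\big[g_i\,B_i(s)\,O_i(s) + c_i\,T_i(s)\big] + \varepsilon_{it}, \qquad
\varepsilon_{it} \sim \mathcal N(0, \sigma_i^2),\ \ \gamma_t \sim \mathcal N(1, \sigma_\gamma^2). $$

- $B_i(s)$: **bottom-up drive** — the Gaussian-receptive-field-weighted
  mean of $|\text{pixel} - \text{background}|$.  Units: dimensionless
  contrast energy in $[0, 0.5]$.
- $O_i(s)$: **orientation factor** — a von Mises tuning factor
  $\exp\{\kappa[\cos 2(\theta_s - \theta_i) - 1]\}$ evaluated at the
  dominant local edge orientation inside the RF, computed from
  orientation-binned (15° bins) luminance-gradient energy; $O_i = 1$
  when the RF contains no oriented ink.
- $T_i(s)$: **emergent indicator** — 1 iff $s$ carries the neuron's
  planted feature.  For an IC1-encoder this set is
  $\{I_{C1}, T_{RE1}, X_{RE1}, I_{RE}(135°)\}$ when
  `emergent_drives_real_edges = TRUE` — the generative hypothesis under
  which inference decoding is positive, because the emergent response
  links the illusory image to its real-edge counterparts.  Switching it
  off makes the emergent response specific to the illusory image and
  provides the matching null.
- $\gamma_t$: a trial-wide multiplicative gain shared by the whole
  population — the dominant mode of trial-to-trial covariability in
  cortical recordings.

### Parameter choices and why

| parameter | default | units | rationale |
|---|---|---|---|
| trial noise $\sigma$ | 1 | response units | sets the scale; all other amplitudes are in s.d. units |
| emergent amplitude $c$ | 3 | response units | a large, unambiguous emergent signal (3 trial-s.d.), the planted effect size used by the recovery analyses |
| evoked gain $g$ | 2 | units per unit drive | gives a segment responder ≈1 s.d. single-trial drive; decoding accuracy then falls in the range seen in real populations rather than saturating at 1.0 |
| shared gain s.d. $\sigma_\gamma$ | 0.3 | — | typical cortical shared-gain variability; also places realistic variance along response directions outside the trained manifold, which keeps probe classification unbiased |
| RF σ | 5° (3° for planted encoders) | deg | mouse V1 receptive fields; encoders get gap-confined RFs (1° placement jitter) per the classical definition, so their I_C selectivity is purely emergent |
| tuning κ | 2 | — | moderate orientation selectivity |
| population | 200 neurons; 10+10 IC-encoders, 12/quadrant segment responders | — | desk-scale session; planted fractions are enlarged relative to real cortex so subset analyses have ≥10 neurons |
| trials | 400 per training image, 100 per probe image | — | the repeat counts of the experimental design this package models |
| holography | direct drive 5, recurrent gain 0.4, feedforward gain 0.4, suppression 0.5, 50 reps/ensemble | response units | strong direct activation of targets; aggregate routed drive 0.4·5 = 2 units to responsive recipients; mild global suppression of everyone else |

The connectivity object embodies the circuit hypothesis under study:
IC-encoders broadcast *like-to-like recurrent* weights to local V1
neurons responsive to their illusory image; segment responders send
*feedforward* weights to higher-area neurons responsive to the image
containing their quadrant.  Weights are normalized so that
photoactivating a full ensemble delivers `recurrent_gain * direct_drive`
to each recipient, making the planted expectations closed-form.

## What the simulator does and does not emulate

It emulates: trial-aligned response matrices with label structure
produced by RF geometry, orientation tuning and planted emergent
signals; shared-gain trial noise; holography trial tables with direct,
routed and suppressive drive; millisecond Poisson spike trains with
planted monosynaptic connections and slow rate comodulation; pupil
traces with planted fixation breaks.

It does not emulate: calcium-indicator kinetics or imaging noise,
non-Gaussian/correlated private noise, adaptation or temporal dynamics
within trials, realistic cell-type proportions, or biophysical network
dynamics (holography responses are a single linear step, not a
recurrent simulation).  Passing tests therefore demonstrate that the
*analysis chain* recovers planted structure at realistic signal-to-noise
— not that real cortex contains that structure.

## Numerical and procedural choices

- **Probe drawing.**  Only the overlap *audits* constrain the real-edge
  probe drawings, so the outlines are placed where the audits hold by
  construction: T_RE outlines flank the gap span only (no end caps), and
  X_RE/I_RE outlines are drawn outside the bar region, giving exactly
  zero ink overlap with the inducer fills.  The bar width (8°) is a free
  drawing parameter.
- **Raster.**  4 px/deg on a 96°×96° canvas; pixel centers at
  half-integer offsets make the grid mirror-symmetric, so the
  T_RE-balance and L_C-recombination audits hold exactly, not just to
  quantization.
- **Tukey–Kramer on ranks.**  Studentized-range comparison of group mean
  ranks with tie-corrected pooled variance, gated on the
  Kruskal–Wallis omnibus at the same α.
- **One-vs-one votes.**  Majority vote over the 6 pairwise linear SVMs;
  vote ties are broken by summed decision-function margins, then by the
  lowest class index.  Regularization C = 1 (configurable).
- **Zero-variance neurons.**  Per-fold standard deviations are floored
  at `sqrt(.Machine$double.eps)`, so a constant neuron becomes an
  uninformative constant feature instead of a division by zero.
- **Zeroing-out** happens *after* standardization: a zeroed neuron is
  clamped at its training mean, the natural "remove information"
  reading.  (Zero-then-standardize is the alternative; it additionally
  shifts the decoder input by the neuron's mean.)
- **Holography normalization.**  The holography response matrix is
  normalized per neuron across *all* holography trials and fed directly
  to each fold's classifier; this across-trial normalization replaces
  the visual-train z-scoring for probe input.  Normalizing within a
  single ensemble's trials would subtract away exactly the
  ensemble-specific pattern being tested.
- **CCG.**  1-ms bins, lags to ±100 ms, sum over
  $t = 1+\tau_{max} \dots L-\tau_{max}$, normalization by
  $\sqrt{\lambda_1 \lambda_2}$ with λ the full-train spike counts.  The
  rate correction subtracts the CCG of 25-ms-boxcar-smoothed trains; a
  putative excitatory connection requires the corrected peak in the
  1–10 ms window to exceed 7× the flank s.d. (lags 50–100 ms).  The
  production path works from spike times (pair-difference histograms
  plus a triangle-kernel convolution, with exact handling of window-edge
  pairs) and equals the literal dense evaluation to machine precision;
  the equality is asserted in the tests.  Because the summation window
  is fixed to the reference train, lag antisymmetry
  $ccg_{12}(\tau) = ccg_{21}(-\tau)$ is exact whenever the trim margins
  hold no spikes and holds to $O(\text{rate} \cdot \tau_{max}/L)$
  otherwise.
- **Pupil mode.**  The resting position is the mode on a 1°-binned 2D
  histogram (ties to the earliest occupied bin); trial windows are
  half-open $[t_{on}, t_{off})$.
- **Degenerate inputs.**  Zero-variance z-score blocks, empty baselines,
  windows without samples, zero-spike trains, unknown target ids and
  mismatched rasters all raise explicit errors.

## Problem sizes used by the validation suite

The packaged analyses run at desk scale: 200-neuron sessions; 20-seed
chance calibrations with 100 trials per class; 10-seed
planted-recovery runs at 400 training / 100 probe repeats; 6-seed
holography runs with 4 ensembles × 50 trials; CCG calibration on
72-minute 10-Hz spike-train pairs (30 planted, 1,000 independent).
These sizes were chosen so each property is measured with comfortable
statistical margin while a full run stays in the minutes range on one
CPU.

## Known limitations

- The linear readout is the only decoder implemented; kernel decoders
  are a configuration extension, not included.
- Holography responses are generated (and analyzed) as one linear step;
  true recurrent dynamics, multi-synaptic routing and
  suppression-activation interplay are out of scope.
- The segment-responder inference-score control is unbiased but noisy at
  finite probe counts (binomial floor ≈ 0.07 s.d. per session at 100
  probe trials/image); conclusions about near-zero scores should always
  be drawn across sessions or seeds, as the session-level statistics in
  the package do.
- The CCG connection caller evaluates excitatory (peak) connections
  only; troughs (putative inhibition) are not called.
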