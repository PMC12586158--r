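# icdecode

Inference decoding of illusory-contour representations in neural
populations.

## What this package is for

When the cut-outs of four "pac-man"-style inducers line up, observers —
mice included — perceive an illusory contour (IC): an edge with no
physical luminance contrast. A cortical population that merely relays
pixels should treat an IC-containing image and a pixel-matched control
identically; a population that represents the *inference* should respond
to the illusory bar as if it were a real bar. `icdecode` implements the
analysis framework for testing this with trial-aligned population
recordings (two-photon calcium imaging or high-density
electrophysiology), together with a synthetic-population simulator that
plants the hypothesized structure so every analysis can be validated
against ground truth. It is aimed at systems neuroscientists analyzing
visual-cortex population data and at methodologists who want a tested,
self-contained reference implementation of the procedure.

## The core procedure

**Stimuli.** Two illusory images `I_C1`/`I_C2` (30° circles, 46°
diagonal center spacing leaving a 16° gap; 16° inducer bars, so the
illusory bar's support ratio is 2L/(2L+gap) = 2/3) and two recombined
controls `L_C1`/`L_C2` that preserve every local segment while
destroying the global alignment. Real-edge probes: `T_REk` (the segment
shared by `I_Ck` and `L_Ck` plus an outlined real edge across the gap,
with equal ink overlap with both training images) and `X_REk` (a
full-length outlined bar at the illusory bar's position/orientation,
with equal ink overlap with both I_C images).

**Decoding.** A linear SVM (one-vs-one, majority vote; ties by summed
margins) classifies I_C1/L_C1/L_C2/I_C2 trials under stratified 10-fold
cross-validation; each fold z-scores every neuron by its training trials
only. **Inference decoding** then probes the trained decoder with the
held-out real-edge trials:

- T_RE score = P(T_REk → I_Ck) − P(T_REk → L_Ck), averaged over the
  two image sets; chance 0.
- X_RE score = ½[P(I_C1 → X_RE1) + P(I_C2 → X_RE2)] from a binary
  X_RE1-vs-X_RE2 decoder; chance 0.5.

A positive score means the population's real-edge response resembles its
illusory-image response beyond what pixel overlap predicts.
`zero_out()` (clamp a subset at its training mean after
standardization) and `train_subset()` attribute the score to functional
ensembles — IC-encoders (neurons responding to exactly one I_C image and
neither L_C, by Kruskal–Wallis + Tukey–Kramer on ranks) versus segment
responders (inward > outward segment, rank-sum). `holo_cross_decode()`
classifies holography-evoked activity of non-photoactivated neurons
(>50 µm from all targets) with the visually trained decoder — the
readout of recurrent pattern completion — and
`compute_ccg()`/`call_connection()` infer putative excitatory
connections from slow-rate-corrected spike-train cross-correlograms
(corrected 1–10 ms peak > 7× the 50–100 ms flank s.d.).

## Worked example

```r
library(icdecode)

battery <- render_battery(stimulus_spec())
neurons <- make_neurons(n = 200, seed = 42)   # plants 10+10 IC-encoders
trials  <- make_trial_table(c(I_C1 = 400, L_C1 = 400, L_C2 = 400,
                              I_C2 = 400, T_RE1 = 100, T_RE2 = 100,
                              blank_circles = 50), seed = 42)
session <- simulate_population(neurons, battery, trials, seed = 42)

X <- build_response_matrix(session)
y <- session$trials$stimulus
core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")

decoder <- train_cv_decoder(X[core, ], y[core], seed = 42)
decoder
#> 10-fold linear decoder on 200 neurons, classes {I_C1, I_C2, L_C1, L_C2}
#>   CV accuracy 0.979 (chance 0.250)

tre <- tre_inference(decoder, X[y == "T_RE1", ], X[y == "T_RE2", ])
#> T_RE decoded as I_C: 0.966, as L_C: 0.033, inference score: 0.933

ic <- which(neurons$emergent_class %in% c("IC1", "IC2"))
tre_inference(decoder, X[y == "T_RE1", ], X[y == "T_RE2", ],
              zero_idx = ic)$score
#> after zeroing the 20 planted IC-encoders: score -0.191

sum(find_ic_encoders(X, y) != "none")
#> rank-test classification recovers 24 IC-encoders (20 planted)
```

Reading the numbers: the four images are decodable at 0.979 accuracy
(chance 0.25), and the ambiguous real-edge probes are classified as the
corresponding illusory image 0.966 of the time versus 0.033 for the
pixel-matched control — an inference score of 0.933, far above the 0
expected from a pixel-faithful population. Zeroing the 20 planted
IC-encoders in the decoder input destroys the positive score entirely,
attributing the inference signal to that small ensemble, and the
rank-test classifier recovers the planted encoders (plus a few
noise-level extras) from the responses alone.

`run_pipeline(default_config(), seed)` chains all stages (simulation,
classification, decoding with controls, optional holography and CCG
scans) into one deterministic run summarized as a tidy data frame.

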