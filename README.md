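# uvalley

Psychometrics, choice modeling, and ROI time-course statistics for
uncanny-valley experiments, driven by a synthetic-data generator with known
ground truth.

## The problem

The uncanny-valley (UV) hypothesis predicts that likability increases with
an artificial agent's humanlikeness but drops selectively for highly
humanlike artificial agents. Testing it quantitatively requires a chain of
analyses: psychometric quantification of the valley from rating data, a
decision-variable account of preference choices, response models linking
regional neural signals to the humanlikeness continuum, and time-course
statistics that avoid circular inference. `uvalley` implements that chain
for researchers in social/decision neuroscience and human–robot
interaction, and validates every stage by parameter recovery against its
own generator.

## The core quantities

* **UV depth** — OLS fit of likability on humanlikeness over per-stimulus
  means of all non-target stimuli; depth = predicted − observed likability
  of the target (artificial-human) category. Positive depth = valley.
  A leave-one-category-out residual profile provides the converging
  measure, and a cubic fit describes the overall nonlinearity.
* **Decision variable (DV)** — per-subject logistic regression
  `P(choice = second) = logistic(β0 + β1·ΔLikability + β2·ΔFamiliarity +
  β3·ΔHumanlikeness)` (Δ = first − second); the DV is the weighted delta
  sum without the constant. Choice UV depth = observed − predicted mean
  |DV| for the human vs artificial-human contrast, relative to a
  humanlikeness-continuum fit over the other contrasts.
* **Linear–nonlinear (LNL) region models** — TPJ linear in humanlikeness;
  FFG inverse-linear for nonhumans with a constant human response; DMPFC
  human-detection step; VMPFC = m + k·TPJ·FFG (multiplicative
  integration). `reconstruct_vmpfc()` recovers the VMPFC pattern from the
  measured TPJ and FFG patterns.
* **ROI time-course machinery** — canonical double-gamma HRF; 128 s
  discrete-cosine high-pass; z-normalization; ×10 sinc oversampling;
  per-timepoint GLMs without orthogonalization with VIF diagnostics;
  Gaussian-AIC inclusion test for a human-detection regressor;
  leave-one-subject-out (LOSO) peak extraction; Pearson + Huber-robust
  across-subject association with context-specific Bonferroni thresholds
  (0.0125 / 0.0167); simplified convolution-domain PPI.

## Worked example

The `analysis/` scripts run the full chain on a simulated 21-subject study
(seed 1) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_uv_quantification.R
Rscript analysis/03_choice_model.R
Rscript analysis/04_lnl_model.R
Rscript analysis/05_roi_timecourse.R
```

Step 2 prints, for a cohort whose sampled ground-truth dip is 0.683:

```
Group UV depth: 0.710 rating units, t(20) = 9.70, p = 5.2e-09
Per-subject valley significant in 21 of 21 subjects
Estimated vs generating dip correlation: r = 0.912
Most negative residual: artificial_human
```

The estimated group depth (0.710) matches the cohort's true mean dip to
within 0.03 rating units, and the residual method concurs on the target
category. Step 3 prints the choice-model fit quality

```
Mean classification accuracy: 87.0% (SEM 0.94)
Mean McFadden pseudo-R^2: 0.55 (SEM 0.02)
Choice UV depth: mean 1.470, t(20) = 5.05, p = 6.1e-05
```

showing that the refit decision variable classifies choices well and that
the preference gap for artificial humans exceeds the humanlikeness
continuum (the choice-task valley). Step 4 reconstructs the VMPFC pattern
multiplicatively (`r = 0.999`, minimum computed amplitude at
`artificial_human`), and step 5 runs the BOLD chain end to end (AIC model
selection, LOSO extraction, PPI positive control).

Equivalent calls are available programmatically: `simulate_study()`,
`uv_depth()`, `fit_choice_logistic()`, `choice_uv_depth()`, `fit_lnl()`,
`timepoint_glm()`, and friends — see the package help and the methods
vignette (`vignettes/uncanny-valley-methods.Rmd`).

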