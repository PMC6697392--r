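---
title: "Modeling the uncanny valley: psychometrics, choices, and regional response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the uncanny valley}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvalley)
```

## The scientific problem

The uncanny-valley hypothesis holds that likability rises with an artificial
agent's humanlikeness but drops selectively for agents that are almost — yet
not quite — human. `uvalley` implements the full quantitative chain used to
study this effect with ratings, two-alternative preference choices, and
region-of-interest (ROI) fMRI time courses: a synthetic-data generator with
known ground truth, psychometric uncanny-valley (UV) quantification, a
logistic decision-variable model of choices, linear–nonlinear (LNL) models of
regional responses, and the ROI time-course statistical machinery. Because no
raw cohort data are available, every statistical claim in this package is
validated by parameter recovery and error-rate simulations against the
generator's ground truth.

## The experimental design being emulated

Six stimulus categories span the humanlikeness continuum: mechanoid robots,
humanoid robots, androids, artificial (synthetic) humans, humans with
physical impairments, and humans without. Six exemplars per category are each
rated twice on continuous 1–5 scales (likability, familiarity,
humanlikeness), giving 72 rating trials. Choices are organized in nine
contrasts — the unimpaired-human category against each of the other five, and
the android category against each remaining category except the unimpaired
humans — with 12 trials per contrast pairing distinct exemplars, half
starting with each category (108 choice trials). Event-related sessions use
TR = 2 s with inter-trial intervals jittered uniformly on 2–6 s.

## The generative model

For subject $s$ and trial $t$ with stimulus latent humanlikeness $h$:

* humanlikeness percept $h^* = h + \varepsilon_h$, reported directly as the
  humanlikeness rating;
* likability $= a_s + b_s h^* - d_s\,[\text{artificial human}] +
  \varepsilon_l$, where $d_s \ge 0$ is the subject's UV dip
  (population mean 0.8 rating units, SD 0.3, truncated at zero — $d_s = 0$
  defines the null subject);
* familiarity $= \mu_f + w_s (\text{signal} - \overline{\text{signal}}) +
  \varepsilon_f$, a convex mixture of the likability-generating signal and
  fresh noise.

All noise terms are Gaussian with SD 0.35 (the rating-noise default) and all
ratings are clipped to $[1, 5]$. Latent category humanlikeness values
(1.6–4.35) are placed well inside the scale so clipping is rare and the null
linear model stays well-specified; exemplars within a category receive small
fixed offsets (±0.12) so per-stimulus regressions have within-category
spread.

The mixture weight $w$ is not free: it is solved in closed form
(`calibrate_familiarity_coupling()`) so that the population trial-level
likability–familiarity shared variance equals $R^2 = 0.39$, the level this
design is known to produce. With the package defaults the solution is
$w \approx 0.56$.

Choices follow
$P(\text{choice} = \text{second}) = \operatorname{logit}^{-1}(\beta_0 +
\beta_1 \Delta L + \beta_2 \Delta F + \beta_3 \Delta H)$
with each $\Delta$ the first-minus-second difference in per-stimulus mean
ratings. Because the deltas are oriented first-minus-second while $y = 1$
codes the second stimulus, a subject who prefers the more likable agent has
a *negative* $\beta_1$; the defaults
($\beta = (0, -1.9, -0.7, -0.55)$, between-subject SDs 0.15–0.35) were scaled
so the refit model's classification accuracy and McFadden pseudo-$R^2$ land
near the levels this paradigm is known to produce (≈86%, ≈0.53). The decision
variable (DV) is the weighted delta sum *without* the constant; an option
includes it for sensitivity analyses. Confidence is a monotone increasing
function of $|DV|$ plus noise — the quantitative link between confidence and
the DV is a modeling choice, as no empirical generative account exists.

### Regional response models

The LNL stage ties regional amplitudes to the same latent humanlikeness:

* TPJ: linear, $a + b h$ (defaults 0.3, 0.5);
* FFG: human constant $c = 1.4$; for nonhumans $d - e h$ with $d = 3.2$ and
  the slope coupled to the subject's dip, $e = 1.0 \times d_s$ (so a dip-free
  subject has a flat FFG and no neural valley, and the neural and behavioral
  valleys co-vary across subjects);
* DMPFC: baseline 0.8 plus a human-detection step of 1.2; an optional
  nonhuman slope (default 0) is available because the data pattern could
  support either reading;
* VMPFC: $m + k \cdot \text{TPJ} \cdot \text{FFG}$ with $k = 1$,
  $m = 0.5$. The affine wrapper is needed because amplitudes are unit-free;
  the offset default is nonzero so every parameter has a well-defined
  relative recovery error;
* amygdala: a pure negative-gain code of the centered stimulus value, with
  no confidence component.

At the population mean dip, the TPJ×FFG product is concave over the nonhuman
range with its minimum at the artificial-human category — the multiplicative
origin of the valley — while the human constant keeps human responses high.
Amplitude noise SD defaults to 0.3.

Fitting (`fit_lnl`, `reconstruct_vmpfc`) uses the category-mean *rated*
humanlikeness as the x-variable, since a real analysis would not possess the
latent values. Exact parameter recovery holds for category-level noiseless
patterns; with within-category exemplar spread the category mean of products
differs from the product of means by a small Jensen gap, which is why the
exactness contract is stated at the category level.

## UV quantification

`uv_depth()` fits OLS of likability on humanlikeness over the per-stimulus
means of all non-target stimuli (30 points by default — per-stimulus rather
than per-category fitting was chosen for statistical efficiency) and defines
UV depth as predicted-minus-observed likability for the target category
(artificial humans; an option adds androids). The depth is invariant to
likability shifts and equivariant under scaling, and the target's own data
never influence its predicted value.

`uv_depth_residuals()` re-fits six regressions, each leaving out one
category, and records each left-out category's mean residual. Note an
asymmetry that follows from the procedure's definition: only the
artificial-human fit excludes the dipped data, so under a dip the other five
residuals are small and positive rather than exactly zero — the target is
identified as the strictly most negative entry.

`group_uv_tests()` runs the two-stage random-effects scheme: a two-sided
one-sample t test of per-subject depths, and per-subject t tests of
per-presentation deviations (predicted minus observed at each target
presentation; presentations rather than stimuli were chosen as the
observation unit, flagged for sensitivity analysis). All tests in the
package are two-sided.

## Choice-task UV

Per contrast, the Δ-decision-variable is the mean unsigned DV; clearer
preferences give larger values. A line of Δ-DV on the absolute
category-mean humanlikeness gap over the four non-target human-referenced
contrasts predicts the human-vs-artificial-human gap; the choice UV depth is
observed minus predicted (positive = valley). The psychometric curve bins
the DV into equally populated bins (default 8; counts differ by at most one,
ties broken by trial order) and fits a two-parameter logit by maximum
likelihood on trial-level data (bin-level fitting is offered as an option,
since either reading of the original procedure is defensible).

Logistic fits use `stats::glm`; complete separation is detected (divergent
coefficients) and handled by a small ridge penalty (`1e-3`, intercept
unpenalized) with a warning flag rather than failure. Pseudo-$R^2$ is
McFadden's $1 - \ell/\ell_0$ — the variant is a package choice, as "pseudo-
$R^2$" alone does not identify one.

## ROI time-course machinery

The canonical HRF is the double-gamma difference (peak delay 6 s, undershoot
delay 16 s, unit dispersions, undershoot ratio 1/6, peak normalized to 1).
Preprocessing applies, in order: a discrete-cosine high-pass projection at a
128 s cutoff period (the DCT family matches the convention of the ecosystem
this pipeline mirrors; the cutoff is the stated value), z-normalization of
the session series (filter first, then normalize — the stated order),
sinc oversampling ×10 (Hann-windowed kernel, half-width 16 samples,
reflective edge padding; edge samples are excluded from oracle comparisons),
and epoching into a trials × time matrix (window −2 to 12 s). The
normalization constant is stored on the object so epoch-level coefficients
can be returned to the acquisition scale, on which the whole chain is linear
— the property the recovery tests exploit.

`timepoint_glm()` fits OLS across trials at every oversampled timepoint with
all regressors competing (no orthogonalization), reports raw and
standardized coefficients, and computes VIFs once on the trial-level design;
exactly collinear regressors are refused by name. The group stage is the
standard random-effects scheme (per-timepoint one-sample t tests).
`model_select_aic()` accepts the binary human-detection regressor only when
it both lowers the summed Gaussian AIC ($n \log(\mathrm{RSS}/n) + 2k$ over
the 2–8 s analysis window — the window is configurable and reported, since
the original analysis window is not stated) and is significant in the group
test. HRF time derivatives are available as optional nuisance regressors in
principle but are off by default at the ROI level.

`loso_extract()` implements leave-one-subject-out peak selection: with $n$
subjects it performs exactly $n$ refits, computing the selection statistic
without the left-out subject and reading that subject's effect at the
selected locus. The package also ships `naive_peak_extract()` — circular
selection on the full group — precisely to document the bias LOSO removes:
under a global null the naive mean effect is positively biased while the
LOSO mean is centered on zero.

`across_subject_association()` pairs Pearson correlation with a Huber IRLS
robust regression (robust p from the coefficient t with $n-2$ df) and
applies the multiple-comparison context: α = 0.0125 for tests involving the
rating-task UV depth, α = 0.0167 for the choice-task UV depth, α = 0.05
otherwise.

The PPI is a declared simplification: instead of deconvolving the seed
series, the interaction regressor is the HRF-convolved psychological
contrast multiplied elementwise with the seed series (plus seed and
psychological main effects). Because the package operates on simulated data
where neural event amplitudes are known, an exact-neural mode builds the
interaction from psych × neural amplitudes before convolution. A constant
psychological vector is refused as collinear.

## What the generator does and does not emulate

It reproduces the design combinatorics, rating scale behavior,
inter-rating shared variance, logistic choice behavior with realistic fit
quality, dip-coupled regional patterns, and event-related BOLD structure
with drift and white noise. It does **not** model stimulus images, gender,
reaction times, temporally autocorrelated (AR) noise, motion artifacts, or
spatial structure — so passing tests certify the statistical machinery and
its error rates on data satisfying the model's assumptions, not robustness
to every property of real fMRI data.

## Problem sizes and numerical choices

Recovery and error-rate suites use 21-subject populations with 500
replicates (1000 for type-I rates), chosen to put Monte-Carlo error well
below the tolerances being asserted while keeping the default test run
short. Degenerate inputs are handled explicitly: zero-variance outcomes
report $R^2 = 0$ with a flag, zero-variance test inputs return degenerate
results rather than p-values, constant series skip z-normalization with a
warning (and projection dust is not z-amplified), and singular fits raise
errors naming the cause. Seeds propagate from a single integer so every
pipeline stage is bitwise reproducible.

## Known limitations

Per-timepoint OLS on smooth oversampled series inflates naive single-series
p-values (no AR modeling); inference in the package is therefore anchored at
the across-subject random-effects stage, as in the two-stage scheme it
mirrors. The ridge fallback for separated logistic fits biases coefficients
toward zero by construction — it is flagged, and at the default trial counts
separation is rare. The Jensen gap discussed above bounds the meaning of
"exact" LNL recovery to category-level patterns.
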