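Package: uvalley
Title: Uncanny-Valley Psychometrics, Choice Modeling, and ROI Time-Course Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis chain for uncanny-valley experiments with
    human and artificial-agent stimuli. Provides a synthetic-data generator with
    known ground truth (rating, choice, and event-related BOLD data for a
    six-category humanlikeness continuum), quantification of the uncanny valley
    from likability ratings (linear-continuum UV depth, leave-one-category-out
    residuals, cubic fits, group tests), a logistic decision-variable model of
    two-alternative preference choices (psychometric curve, delta-decision-variable
    choice UV), linear-nonlinear multiplicative models of regional neural
    responses, and region-of-interest time-course statistics (canonical HRF,
    discrete-cosine high-pass, sinc oversampling, per-timepoint GLMs without
    orthogonalization, AIC model selection, leave-one-subject-out effect
    extraction, robust across-subject association, and a simplified
    psychophysiological-interaction analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
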