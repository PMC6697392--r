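#' Simulate rating-task data for one subject
#'
#' Fills the rating columns of a trial table. On each trial the subject forms
#' a humanlikeness percept (latent value plus Gaussian noise); the
#' humanlikeness rating reports that percept, the likability rating is affine
#' in the percept minus the subject's uncanny-valley dip for artificial
#' humans (plus fresh noise), and the familiarity rating is a weighted
#' mixture of the likability-generating signal and fresh noise. All three
#' ratings are clipped to the 1--5 scale.
#'
#' @param params Subject parameters from \code{\link{sample_population}}.
#' @param trials Trial table from \code{\link{build_rating_trials}}.
#' @param seed Integer seed.
#' @return The trial table with \code{likability}, \code{familiarity},
#'   \code{humanlikeness} filled.
#' @export
simulate_ratings <- function(params, trials, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- nrow(trials)
  sd <- params$rating_noise_sd
  percept <- trials$latent_humanlikeness + stats::rnorm(n, 0, sd)
  signal <- params$intercept_likability +
    params$slope_likability * percept -
    params$uv_dip * (trials$category == "artificial_human")
  lik <- signal + stats::rnorm(n, 0, sd)
  fam <- params$familiarity_mean +
    params$familiarity_coupling * (signal - mean(signal)) +
    stats::rnorm(n, 0, sd)
  clip <- function(x) pmin(5, pmax(1, x))
  trials$humanlikeness <- clip(percept)
  trials$likability <- clip(lik)
  trials$familiarity <- clip(fam)
  trials
}

#' Per-stimulus mean ratings
#'
#' Averages each rating scale over the presentations of every stimulus,
#' mirroring the stimulus-specific ratings that feed the choice model and
#' the UV-depth fits.
#'
#' @param rated_trials Rating trials with filled rating columns.
#' @return Data frame with one row per stimulus: \code{stimulus},
#'   \code{category}, \code{is_human}, \code{likability},
#'   \code{familiarity}, \code{humanlikeness}.
#' @export
stimulus_rating_means <- function(rated_trials) {
  f <- factor(rated_trials$stimulus)
  n <- tabulate(f)
  sums <- rowsum(cbind(rated_trials$likability, rated_trials$familiarity,
                       rated_trials$humanlikeness),
                 f, reorder = TRUE)
  first <- match(levels(f), rated_trials$stimulus)
  out <- data.frame(
    stimulus = levels(f),
    category = rated_trials$category[first],
    is_human = rated_trials$is_human[first],
    likability = sums[, 1] / n,
    familiarity = sums[, 2] / n,
    humanlikeness = sums[, 3] / n,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-category mean ratings
#'
#' @param rated_trials Rating trials with filled rating columns.
#' @return Data frame with one row per category in continuum order.
#' @export
category_rating_means <- function(rated_trials) {
  means <- stimulus_rating_means(rated_trials)
  cats <- uv_categories()
  out <- do.call(rbind, lapply(cats$name, function(cn) {
    d <- means[means$category == cn, ]
    data.frame(category = cn, is_human = cats$is_human[cats$name == cn],
               likability = mean(d$likability),
               familiarity = mean(d$familiarity),
               humanlikeness = mean(d$humanlikeness),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate choice-task data for one subject
#'
#' Choices follow the logistic model
#' \code{P(choice = second) = plogis(b0 + b1*dLik + b2*dFam + b3*dHum)}
#' where each delta is the first-stimulus minus second-stimulus mean rating.
#' Confidence is a monotone increasing function of the unsigned decision
#' variable (the weighted delta sum without the constant) plus noise,
#' clipped to the 1--5 scale.
#'
#' @param params Subject parameters.
#' @param choice_trials Trial table from \code{\link{build_choice_design}}.
#' @param rating_means Per-stimulus means from
#'   \code{\link{stimulus_rating_means}}.
#' @param seed Integer seed.
#' @return The trial table with \code{choice} (0 = first, 1 = second) and
#'   \code{confidence} filled, plus the delta columns \code{d_likability},
#'   \code{d_familiarity}, \code{d_humanlikeness} and the generating
#'   probability \code{p_second}.
#' @export
simulate_choices <- function(params, choice_trials, rating_means, seed = 1) {
  trials <- relative_attributes(choice_trials, rating_means)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  b <- params$betas
  dv <- b[2] * trials$d_likability + b[3] * trials$d_familiarity +
    b[4] * trials$d_humanlikeness
  eta <- b[1] + dv
  p <- stats::plogis(eta)
  trials$choice <- stats::rbinom(nrow(trials), 1, p)
  conf <- 2.2 + params$confidence_gain * abs(dv) +
    stats::rnorm(nrow(trials), 0, params$confidence_noise_sd)
  trials$confidence <- pmin(5, pmax(1, conf))
  trials$p_second <- p
  trials
}

#' Simulate per-trial ROI amplitudes for one subject
#'
#' Region amplitudes follow the linear-nonlinear response models
#' (\code{\link{lnl_predict}}) evaluated at the trial stimulus' latent
#' humanlikeness, plus Gaussian noise. The amygdala carries a pure
#' negative-gain code of the stimulus value (the centered
#' likability-generating signal), without a confidence component.
#'
#' @param params Subject parameters.
#' @param trials Rating-trial table (one amplitude set per trial).
#' @param seed Integer seed.
#' @return Data frame with columns \code{trial}, \code{stimulus},
#'   \code{category}, \code{is_human}, and amplitudes \code{tpj},
#'   \code{ffg}, \code{dmpfc}, \code{vmpfc}, \code{amygdala}.
#' @export
simulate_roi_amplitudes <- function(params, trials, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  h <- trials$latent_humanlikeness
  hum <- trials$is_human
  lp <- subject_lnl_params(params)
  n <- nrow(trials)
  sd <- params$amplitude_noise_sd
  value <- params$intercept_likability + params$slope_likability * h -
    params$uv_dip * (trials$category == "artificial_human")
  out <- data.frame(
    trial = trials$trial,
    stimulus = trials$stimulus,
    category = trials$category,
    is_human = hum,
    tpj = lnl_predict(lp, "TPJ", h, hum) + stats::rnorm(n, 0, sd),
    ffg = lnl_predict(lp, "FFG", h, hum) + stats::rnorm(n, 0, sd),
    dmpfc = lnl_predict(lp, "DMPFC", h, hum) + stats::rnorm(n, 0, sd),
    vmpfc = lnl_predict(lp, "VMPFC", h, hum) + stats::rnorm(n, 0, sd),
    amygdala = -params$lnl$amygdala$gain * (value - mean(value)) +
      stats::rnorm(n, 0, sd),
    stringsAsFactors = FALSE
  )
  out
}

#' Resolve a subject's concrete region parameters
#'
#' Expands the population-level region model (with the FFG slope expressed
#' per unit of uncanny-valley dip) into the subject's concrete parameter set
#' accepted by \code{\link{lnl_predict}}.
#'
#' @param params Subject parameters.
#' @return List with \code{tpj}, \code{ffg} (fields \code{d}, \code{e},
#'   \code{c}), \code{dmpfc}, \code{vmpfc}.
#' @export
subject_lnl_params <- function(params) {
  lp <- params$lnl
  list(
    tpj = lp$tpj,
    ffg = list(d = lp$ffg$d, e = lp$ffg$e_per_dip * params$uv_dip,
               c = lp$ffg$c),
    dmpfc = lp$dmpfc,
    vmpfc = lp$vmpfc
  )
}

#' Simulate an event-related BOLD series
#'
#' Each event contributes its amplitude times the hemodynamic response
#' function shifted to the event onset; the series is sampled at the
#' repetition time, with optional slow cosine drift and white noise. The
#' noiseless series is exactly linear in the amplitudes.
#'
#' @param amplitudes Per-event response amplitudes.
#' @param onsets Event onsets in seconds, sorted, within the session.
#' @param tr Repetition time in seconds (default 2).
#' @param duration Session length in seconds.
#' @param hrf HRF object from \code{\link{canonical_hrf}}.
#' @param noise_sd White-noise SD (default 0).
#' @param drift_amplitude Amplitude of a slow cosine drift with period equal
#'   to the session length (default 0).
#' @param seed Integer seed.
#' @return List of class \code{"bold_series"} with \code{series},
#'   \code{time}, \code{tr}, \code{onsets}, \code{duration}.
#' @export
simulate_bold <- function(amplitudes, onsets, tr = 2, duration, hrf,
                          noise_sd = 0, drift_amplitude = 0, seed = 1) {
  if (tr <= 0) stop("`tr` must be positive")
  if (length(onsets) != length(amplitudes))
    stop("`amplitudes` and `onsets` lengths differ")
  if (is.unsorted(onsets)) stop("`onsets` must be sorted")
  if (any(onsets < 0) || any(onsets >= duration))
    stop("`onsets` must lie within [0, duration)")
  n <- floor(duration / tr)
  t <- (seq_len(n) - 1) * tr
  series <- numeric(n)
  for (i in seq_along(onsets)) {
    if (amplitudes[i] == 0) next
    series <- series + amplitudes[i] *
      hrf_value(hrf, t - onsets[i])
  }
  if (drift_amplitude != 0)
    series <- series + drift_amplitude * cos(2 * pi * t / duration)
  if (noise_sd > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    series <- series + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(series = series, time = t, tr = tr, onsets = onsets,
                 duration = duration),
            class = "bold_series")
}

#' Simulate one subject end to end
#'
#' Convenience wrapper: ratings, per-stimulus means, choices, and ROI
#' amplitudes for one subject under a shared design.
#'
#' @param params Subject parameters.
#' @param design List with \code{stimuli}, \code{rating_trials},
#'   \code{choice_design} (see \code{\link{build_study_design}}).
#' @param seed Integer seed.
#' @return List with \code{ratings}, \code{rating_means}, \code{choices},
#'   \code{amplitudes}, \code{params}.
#' @export
simulate_subject <- function(params, design, seed = 1) {
  seed <- as.integer(seed) %% .Machine$integer.max
  ratings <- simulate_ratings(params, design$rating_trials, seed = seed)
  means <- stimulus_rating_means(ratings)
  choices <- simulate_choices(params, design$choice_design$trials, means,
                              seed = seed + 1L)
  amps <- simulate_roi_amplitudes(params, ratings, seed = seed + 2L)
  list(ratings = ratings, rating_means = means, choices = choices,
       amplitudes = amps, params = params)
}

#' Build the default study design
#'
#' @param n_per_category Exemplars per category (default 6).
#' @param repetitions Rating presentations per stimulus (default 2).
#' @param trials_per_contrast Choice trials per contrast (default 12).
#' @param seed Integer seed.
#' @return List with \code{stimuli}, \code{rating_trials},
#'   \code{choice_design}.
#' @export
build_study_design <- function(n_per_category = 6, repetitions = 2,
                               trials_per_contrast = 12, seed = 1) {
  seed <- as.integer(seed) %% .Machine$integer.max
  stimuli <- build_stimulus_set(n_per_category)
  list(
    stimuli = stimuli,
    rating_trials = build_rating_trials(stimuli, repetitions, seed = seed),
    choice_design = build_choice_design(stimuli, trials_per_contrast,
                                        seed = seed + 1L)
  )
}

#' Simulate a full study
#'
#' Draws a subject population and simulates every subject under a common
#' design.
#'
#' @param config Population configuration.
#' @param seed Integer seed controlling design, population, and all
#'   subject-level noise.
#' @return List with \code{design}, \code{population} (parameter list), and
#'   \code{subjects} (list of per-subject data from
#'   \code{\link{simulate_subject}}).
#' @export
simulate_study <- function(config = population_config(), seed = 1) {
  seed <- as.integer(seed) %% .Machine$integer.max
  design <- build_study_design(seed = seed)
  pop <- sample_population(config, seed = seed + 100L)
  subjects <- lapply(seq_along(pop), function(i) {
    simulate_subject(pop[[i]], design, seed = seed + 1000L + 10L * i)
  })
  list(design = design, population = pop, subjects = subjects,
       config = config)
}
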