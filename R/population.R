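#' Default linear-nonlinear region parameters
#'
#' Ground-truth parameters of the regional response models used by the
#' generator (see \code{\link{lnl_predict}}). TPJ responds linearly to
#' humanlikeness; FFG responds with a negative humanlikeness slope for
#' nonhuman agents and a constant level for humans; DMPFC adds a step for
#' human agents; VMPFC is an affine wrapper around the TPJ x FFG product.
#' The FFG nonhuman slope is coupled to the subject's uncanny-valley dip
#' (\code{ffg$e_per_dip * uv_dip}), so a dip-free subject has a flat FFG and
#' hence a linear (valley-free) VMPFC pattern.
#'
#' @return Nested list of region parameters.
#' @export
lnl_default_params <- function() {
  list(
    tpj = list(a = 0.3, b = 0.5),
    ffg = list(d = 3.2, e_per_dip = 1.0, c = 1.4),
    dmpfc = list(baseline = 0.8, step = 1.2, nonhuman_slope = 0),
    vmpfc = list(k = 1.0, m = 0.5),
    amygdala = list(gain = 0.5)
  )
}

#' Population configuration for the synthetic-data generator
#'
#' Means and between-subject standard deviations for every subject-level
#' parameter. Defaults define the study conditions emulated throughout the
#' package: 21 subjects; likability affine in humanlikeness with a selective
#' dip (mean 0.8 rating units, SD 0.3) for artificial humans; rating noise
#' 0.35; choice betas on the log-odds scale for the model
#' P(choice = second) = logistic(b0 + b1*dLik + b2*dFam + b3*dHum) with
#' deltas defined first minus second (hence negative slopes: subjects prefer
#' the relatively more likable/familiar/humanlike agent); familiarity
#' coupling calibrated so the within-subject likability-familiarity shared
#' variance matches R^2 = 0.39 (see
#' \code{\link{calibrate_familiarity_coupling}}).
#'
#' @param n_subjects Number of subjects (default 21).
#' @param ... Named overrides of any default entry.
#' @return List of class \code{"uv_population_config"}.
#' @export
population_config <- function(n_subjects = 21, ...) {
  cfg <- list(
    n_subjects = n_subjects,
    slope_likability = c(mean = 0.6, sd = 0.08),
    intercept_likability = c(mean = 1.0, sd = 0.15),
    uv_dip = c(mean = 0.8, sd = 0.3),
    rating_noise_sd = c(mean = 0.35, sd = 0.04),
    familiarity_coupling = c(mean = NA_real_, sd = 0.05),  # NA: calibrated
    familiarity_mean = 3.0,
    beta0 = c(mean = 0.0, sd = 0.15),
    beta1 = c(mean = -1.9, sd = 0.35),
    beta2 = c(mean = -0.7, sd = 0.2),
    beta3 = c(mean = -0.55, sd = 0.2),
    confidence_gain = 0.8,
    confidence_noise_sd = 0.4,
    amplitude_noise_sd = 0.3,
    lnl = lnl_default_params(),
    target_r2_lik_fam = 0.39
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  if (is.na(cfg$familiarity_coupling["mean"])) {
    cfg$familiarity_coupling["mean"] <-
      calibrate_familiarity_coupling(cfg$target_r2_lik_fam, cfg)
  }
  sds <- c("slope_likability", "intercept_likability", "uv_dip",
           "rating_noise_sd", "familiarity_coupling",
           "beta0", "beta1", "beta2", "beta3")
  for (nm in sds) {
    if (cfg[[nm]]["sd"] < 0) stop("negative SD for ", nm)
  }
  class(cfg) <- "uv_population_config"
  cfg
}

#' Calibrate the familiarity-coupling weight
#'
#' Familiarity is generated as
#' \code{fam = fam_mean + w * (s - mean(s)) + noise}, where \code{s} is the
#' likability-generating signal (affine humanlikeness plus the dip) and the
#' noise SD equals the rating noise. The weight \code{w} is solved in closed
#' form so that the population trial-level squared correlation between
#' likability and familiarity equals \code{target_r2}:
#' \deqn{R^2 = w^2 \sigma_s^4 / ((\sigma_s^2+\sigma^2)(w^2\sigma_s^2+\sigma^2))}
#' with \eqn{\sigma_s^2} the signal variance over the default stimulus set
#' and \eqn{\sigma^2} the rating-noise variance.
#'
#' @param target_r2 Target shared variance (default 0.39).
#' @param cfg A population configuration supplying the mean slope, dip, and
#'   rating noise (defaults used when omitted).
#' @return The coupling weight in (0, 1].
#' @export
calibrate_familiarity_coupling <- function(target_r2 = 0.39, cfg = NULL) {
  slope <- if (is.null(cfg)) 0.6 else unname(cfg$slope_likability["mean"])
  dip <- if (is.null(cfg)) 0.8 else unname(cfg$uv_dip["mean"])
  sigma <- if (is.null(cfg)) 0.35 else unname(cfg$rating_noise_sd["mean"])
  stim <- build_stimulus_set()
  s <- slope * stim$latent_humanlikeness -
    dip * (stim$category == "artificial_human")
  # the likability-generating signal also carries the humanlikeness-percept
  # noise (slope^2 * sigma^2), shared between likability and familiarity
  vs <- stats::var(s) * (length(s) - 1) / length(s) + slope^2 * sigma^2
  vn <- sigma^2
  # solve target = w^2 vs^2 / ((vs+vn)(w^2 vs + vn))
  denom <- vs * (vs - target_r2 * (vs + vn))
  if (denom <= 0) stop("target R^2 unattainable at these variances")
  w2 <- target_r2 * (vs + vn) * vn / denom
  min(1, sqrt(w2))
}

#' Draw a population of subject parameters
#'
#' Samples \code{n_subjects} parameter sets from the population
#' configuration: independent normal draws per parameter, with the
#' uncanny-valley dip truncated at 0 (a dip of 0 defines the null,
#' valley-free subject) and noise SDs and the coupling weight truncated to
#' positive values / [0,1]. With all between-subject SDs zero every subject
#' equals the population mean.
#'
#' @param config From \code{\link{population_config}}.
#' @param seed Integer seed.
#' @return List of subject parameter lists, each of class
#'   \code{"uv_subject_params"} with fields \code{slope_likability},
#'   \code{intercept_likability}, \code{uv_dip}, \code{rating_noise_sd},
#'   \code{familiarity_coupling}, \code{familiarity_mean}, \code{betas}
#'   (length-4), confidence and amplitude noise settings, and \code{lnl}.
#' @export
sample_population <- function(config = population_config(), seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- config$n_subjects
  draw <- function(ms) stats::rnorm(n, ms["mean"], ms["sd"])
  slope <- draw(config$slope_likability)
  icept <- draw(config$intercept_likability)
  dip <- pmax(0, draw(config$uv_dip))
  noise <- pmax(0.05, draw(config$rating_noise_sd))
  coup <- pmin(1, pmax(0, draw(config$familiarity_coupling)))
  b0 <- draw(config$beta0); b1 <- draw(config$beta1)
  b2 <- draw(config$beta2); b3 <- draw(config$beta3)
  lapply(seq_len(n), function(i) {
    p <- list(
      subject = i,
      slope_likability = slope[i],
      intercept_likability = icept[i],
      uv_dip = dip[i],
      rating_noise_sd = noise[i],
      familiarity_coupling = coup[i],
      familiarity_mean = config$familiarity_mean,
      betas = c(beta0 = b0[i], beta1 = b1[i], beta2 = b2[i], beta3 = b3[i]),
      confidence_gain = config$confidence_gain,
      confidence_noise_sd = config$confidence_noise_sd,
      amplitude_noise_sd = config$amplitude_noise_sd,
      lnl = config$lnl
    )
    class(p) <- "uv_subject_params"
    p
  })
}
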