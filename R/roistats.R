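#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF is the difference of two gamma densities: a positive
#' response peaking around 5 s and a smaller, later undershoot. Defaults use
#' the conventional parameterization (peak delay 6 s, undershoot delay 16 s,
#' unit dispersions, undershoot ratio 1/6); the peak amplitude is normalized
#' to 1. The value at t = 0 is exactly 0.
#'
#' @param resolution Grid step in seconds (default 0.1).
#' @param duration Support length in seconds (default 32).
#' @param peak_delay,undershoot_delay Gamma delays in seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions in
#'   seconds.
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @return Object of class \code{"hrf"}: \code{grid} (seconds),
#'   \code{values} (peak-normalized), \code{parameters}.
#' @export
canonical_hrf <- function(resolution = 0.1, duration = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6) {
  if (resolution <= 0) stop("`resolution` must be positive")
  grid <- seq(0, duration, by = resolution)
  v <- stats::dgamma(grid, shape = peak_delay / peak_dispersion,
                     scale = peak_dispersion) -
    undershoot_ratio *
    stats::dgamma(grid, shape = undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion)
  v <- v / max(v)
  structure(list(grid = grid, values = v,
                 parameters = list(peak_delay = peak_delay,
                                   undershoot_delay = undershoot_delay,
                                   peak_dispersion = peak_dispersion,
                                   undershoot_dispersion = undershoot_dispersion,
                                   undershoot_ratio = undershoot_ratio,
                                   resolution = resolution,
                                   duration = duration)),
            class = "hrf")
}

#' Evaluate an HRF at arbitrary times
#'
#' Linear interpolation on the HRF grid; zero outside the support.
#'
#' @param hrf From \code{\link{canonical_hrf}}.
#' @param t Times in seconds (may be negative).
#' @return Numeric values.
#' @export
hrf_value <- function(hrf, t) {
  out <- numeric(length(t))
  inside <- t >= 0 & t <= max(hrf$grid)
  if (any(inside))
    out[inside] <- stats::approx(hrf$grid, hrf$values, xout = t[inside])$y
  out
}

#' Discrete-cosine high-pass filter
#'
#' Projects out the low-frequency discrete-cosine basis (periods longer than
#' \code{cutoff} seconds) plus the constant, the standard drift model for
#' event-related series.
#'
#' @param series Numeric series sampled at \code{tr}.
#' @param tr Sampling interval in seconds.
#' @param cutoff Cutoff period in seconds (default 128).
#' @return Filtered series (mean zero).
#' @export
dct_highpass <- function(series, tr, cutoff = 128) {
  n <- length(series)
  if (cutoff <= 2 * tr) stop("`cutoff` must exceed 2 * tr")
  K <- floor(2 * n * tr / cutoff)
  i <- seq_len(n) - 1
  X <- cbind(1, vapply(seq_len(K), function(k)
    cos(pi * (2 * i + 1) * k / (2 * n)), numeric(n)))
  series - drop(X %*% qr.coef(qr(X), series))
}

#' Windowed-sinc oversampling
#'
#' Interpolates a series onto a grid \code{oversample} times finer with a
#' Hann-windowed sinc kernel and reflective edge padding. Edge samples
#' (within the kernel half-width) are approximate; interior accuracy for
#' band-limited input is well below 1e-3.
#'
#' @param series Numeric series.
#' @param oversample Integer factor >= 1.
#' @param half_width Kernel half-width in input samples (default 16).
#' @return Numeric series of length \code{length(series) * oversample};
#'   element \code{1 + (i-1)*oversample} coincides with input sample i.
#' @export
sinc_oversample <- function(series, oversample = 10, half_width = 16) {
  if (oversample < 1 || oversample != round(oversample))
    stop("`oversample` must be a positive integer")
  if (oversample == 1) return(series)
  n <- length(series)
  L <- half_width
  pad <- c(rev(series[2:(L + 1)]), series, rev(series[(n - L):(n - 1)]))
  n_out <- n * oversample
  frac <- (seq_len(n_out) - 1) / oversample       # position in input samples
  base <- floor(frac)
  out <- numeric(n_out)
  wsum <- numeric(n_out)
  for (m in (-L + 1):L) {
    k <- base + m                                  # input sample index
    u <- frac - k                                  # offset in samples
    w <- sinc_hann(u, L)
    out <- out + w * pad[k + L + 1]
    wsum <- wsum + w
  }
  out / wsum
}

sinc_hann <- function(u, L) {
  s <- ifelse(u == 0, 1, sin(pi * u) / (pi * u))
  w <- ifelse(abs(u) < L, 0.5 * (1 + cos(pi * u / L)), 0)
  s * w
}

#' Preprocess an ROI series and epoch it into trials
#'
#' Applies, in order: discrete-cosine high-pass at the cutoff period,
#' z-normalization of the session series, sinc oversampling, and epoching
#' around event onsets, producing a trials x time matrix on the oversampled
#' grid.
#'
#' @param series Raw session series sampled at \code{tr} (or a
#'   \code{"bold_series"} object).
#' @param tr Sampling interval in seconds (taken from the object when one
#'   is supplied).
#' @param onsets Event onsets in seconds.
#' @param cutoff High-pass cutoff period in seconds (default 128).
#' @param oversample Sinc oversampling factor (default 10).
#' @param epoch_window Two-element window in seconds relative to onset
#'   (default \code{c(-2, 12)}).
#' @return Object of class \code{"roi_timecourse"}: \code{epochs}
#'   (trials x time), \code{time} (epoch grid, seconds),
#'   \code{tr_effective}, \code{series} (preprocessed, oversampled),
#'   \code{scale} (the session SD divided out by z-normalization;
#'   multiplying epoch-level coefficients by it returns them to the
#'   acquisition scale), \code{degenerate} (constant input flag).
#' @export
preprocess_timecourse <- function(series, tr = NULL, onsets,
                                  cutoff = 128, oversample = 10,
                                  epoch_window = c(-2, 12)) {
  if (inherits(series, "bold_series")) {
    tr <- series$tr
    series <- series$series
  }
  if (is.null(tr)) stop("`tr` required")
  n <- length(series)
  session_len <- n * tr
  if (any(onsets < 0) || any(onsets >= session_len))
    stop("onsets outside session")
  filtered <- dct_highpass(series, tr, cutoff)
  s <- stats::sd(filtered)
  # numerical dust left by the basis projection must not be z-amplified
  degenerate <- s < 1e-10 * max(1, abs(mean(series)))
  if (degenerate) {
    warning("constant series after filtering: z-normalization skipped")
    z <- numeric(n)
  } else {
    z <- (filtered - mean(filtered)) / s
  }
  norm_scale <- if (degenerate) 1 else s
  os <- sinc_oversample(z, oversample)
  dt <- tr / oversample
  tgrid <- seq(epoch_window[1], epoch_window[2], by = dt)
  idx0 <- round(onsets / dt)                 # oversampled index of each onset
  rel <- round(tgrid / dt)
  epochs <- t(vapply(idx0, function(i0) {
    ii <- i0 + rel + 1
    if (any(ii < 1) || any(ii > length(os)))
      stop("epoch window extends outside session for some onset")
    os[ii]
  }, numeric(length(tgrid))))
  structure(list(epochs = epochs, time = tgrid, tr_effective = dt,
                 series = os, onsets = onsets, oversample = oversample,
                 scale = norm_scale, degenerate = degenerate),
            class = "roi_timecourse")
}

#' Variance inflation factors of a trial-level design
#'
#' @param X Numeric matrix of regressors (no intercept column).
#' @return Named vector of VIFs; infinite entries indicate exact
#'   collinearity.
#' @export
design_vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 1) return(stats::setNames(1, colnames(X)))
  vif <- vapply(seq_len(p), function(j) {
    xj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    # lm.fit pivots, so rank-deficient predictor sets still give residuals
    res <- stats::lm.fit(others, xj)$residuals
    sst <- sum((xj - mean(xj))^2)
    sse <- sum(res^2)
    if (sse / max(sst, .Machine$double.eps) < 1e-12) return(Inf)
    sst / sse
  }, numeric(1))
  stats::setNames(vif, colnames(X))
}

#' Per-timepoint GLM across trials
#'
#' Fits, at every timepoint of the epoch grid, an OLS regression of the
#' trial amplitudes on the (mean-centered) trial-level regressors, with all
#' regressors competing for variance (no orthogonalization). Reports raw
#' and standardized coefficients per timepoint and the design's variance
#' inflation factors. Exactly collinear regressors are refused by name.
#'
#' @param epochs A \code{"roi_timecourse"} or a trials x time matrix.
#' @param regressors Data frame or matrix of per-trial regressor values
#'   (centered internally).
#' @param standardize Report standardized coefficients
#'   (\code{b * sd(x) / sd(y_t)}) alongside raw ones (default TRUE).
#' @return Object of class \code{"effect_timecourse"}: \code{coefficients}
#'   and \code{standardized} (time x regressor matrices), \code{time},
#'   \code{vif}, \code{n_trials}.
#' @export
timepoint_glm <- function(epochs, regressors, standardize = TRUE) {
  time <- NULL
  if (inherits(epochs, "roi_timecourse")) {
    time <- epochs$time
    epochs <- epochs$epochs
  }
  Y <- as.matrix(epochs)
  X0 <- as.matrix(regressors)
  if (is.null(colnames(X0)))
    colnames(X0) <- paste0("x", seq_len(ncol(X0)))
  if (nrow(X0) != nrow(Y)) stop("trials mismatch between epochs and regressors")
  X0 <- scale(X0, center = TRUE, scale = FALSE)
  vif <- design_vif(X0)
  if (any(!is.finite(vif)))
    stop("exactly collinear regressor(s): ",
         paste(names(vif)[!is.finite(vif)], collapse = ", "))
  X <- cbind(`(intercept)` = 1, X0)
  B <- qr.coef(qr(X), Y)                      # (p+1) x T
  coefs <- t(B[-1, , drop = FALSE])           # T x p
  colnames(coefs) <- colnames(X0)
  std <- NULL
  if (standardize) {
    sdx <- apply(X0, 2, stats::sd)
    sdy <- apply(Y, 2, stats::sd)
    std <- coefs * rep(sdx, each = nrow(coefs))
    std <- sweep(std, 1, ifelse(sdy > 0, sdy, Inf), "/")
  }
  structure(list(coefficients = coefs, standardized = std,
                 time = if (is.null(time)) seq_len(nrow(coefs)) else time,
                 vif = vif, n_trials = nrow(Y)),
            class = "effect_timecourse")
}

#' Group-level effect-size time courses
#'
#' Random-effects stage: per-timepoint, per-regressor one-sample t tests of
#' the subject coefficients against zero, with group means and standard
#' errors.
#'
#' @param subject_effects List of \code{"effect_timecourse"} objects (or
#'   time x regressor matrices) with identical layout.
#' @param use Which coefficients to test: \code{"standardized"} (default)
#'   or \code{"raw"}.
#' @return List of class \code{"group_effect_timecourse"} with matrices
#'   \code{mean}, \code{se}, \code{t}, \code{p} (time x regressor) and
#'   \code{time}.
#' @export
group_effect_timecourse <- function(subject_effects,
                                    use = c("standardized", "raw")) {
  use <- match.arg(use)
  mats <- lapply(subject_effects, function(e) {
    if (inherits(e, "effect_timecourse"))
      (if (use == "standardized" && !is.null(e$standardized))
        e$standardized else e$coefficients)
    else as.matrix(e)
  })
  n <- length(mats)
  if (n < 2) stop("need at least two subjects")
  arr <- simplify2array(mats)                 # time x reg x subj
  m <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(n)
  tmat <- m / se
  pmat <- 2 * stats::pt(-abs(tmat), df = n - 1)
  time <- if (inherits(subject_effects[[1]], "effect_timecourse"))
    subject_effects[[1]]$time else seq_len(nrow(m))
  structure(list(mean = m, se = se, t = tmat, p = pmat, time = time,
                 n_subjects = n),
            class = "group_effect_timecourse")
}

#' Gaussian-likelihood AIC for an OLS fit
#'
#' \code{AIC = n * log(RSS / n) + 2k}, the form obtained from the profiled
#' Gaussian likelihood up to an additive constant shared by models on the
#' same data.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of estimated regression parameters.
#' @return AIC value.
#' @export
aic_gaussian <- function(rss, n, k) n * log(rss / n) + 2 * k

#' AIC-guided inclusion of the human-detection regressor
#'
#' Compares, across subjects, a base per-timepoint GLM (parametric
#' likability, humanlikeness, familiarity) with an extended GLM that adds
#' the binary, mean-centered human-detection contrast. Per subject, the
#' Gaussian AIC is summed over the timepoints of the analysis window and
#' both models' totals accumulate across subjects. The extended model is
#' accepted only if it lowers total AIC \emph{and} the human-detection
#' regressor is significant in the group-level random-effects t test over
#' the window.
#'
#' @param subjects List; each element a list with \code{epochs} (trials x
#'   time matrix or \code{"roi_timecourse"}) and \code{regressors} (data
#'   frame containing the base columns and the candidate column).
#' @param base Character vector of base regressor names.
#' @param candidate Candidate regressor name (default
#'   \code{"human_detection"}).
#' @param window Analysis window in seconds (default \code{c(2, 8)}).
#' @param time Epoch time grid (taken from the first subject's
#'   \code{"roi_timecourse"} when available).
#' @param alpha Group-test level (default 0.05).
#' @return List of class \code{"aic_selection"}: \code{selected}
#'   (\code{"base"} or \code{"extended"}), \code{aic_base},
#'   \code{aic_extended}, \code{candidate_t}, \code{candidate_p},
#'   \code{window}.
#' @export
model_select_aic <- function(subjects, base = c("likability",
                                                "humanlikeness",
                                                "familiarity"),
                             candidate = "human_detection",
                             window = c(2, 8), time = NULL, alpha = 0.05) {
  get_epochs <- function(s)
    if (inherits(s$epochs, "roi_timecourse")) s$epochs$epochs else
      as.matrix(s$epochs)
  if (is.null(time)) {
    e1 <- subjects[[1]]$epochs
    time <- if (inherits(e1, "roi_timecourse")) e1$time else
      seq_len(ncol(get_epochs(subjects[[1]])))
  }
  in_win <- time >= window[1] & time <= window[2]
  if (!any(in_win)) stop("empty analysis window")
  aic_b <- 0; aic_e <- 0
  cand_eff <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    Y <- get_epochs(subjects[[i]])[, in_win, drop = FALSE]
    R <- as.data.frame(subjects[[i]]$regressors)
    n <- nrow(Y)
    fit_rss <- function(cols) {
      X <- cbind(1, scale(as.matrix(R[cols]), center = TRUE, scale = FALSE))
      res <- Y - X %*% qr.coef(qr(X), Y)
      colSums(res^2)
    }
    rss_b <- fit_rss(base)
    rss_e <- fit_rss(c(base, candidate))
    aic_b <- aic_b + sum(aic_gaussian(rss_b, n, length(base) + 1))
    aic_e <- aic_e + sum(aic_gaussian(rss_e, n, length(base) + 2))
    eff <- timepoint_glm(Y, R[c(base, candidate)], standardize = TRUE)
    cand_eff[i] <- mean(eff$standardized[, candidate])
  }
  tt <- stats::t.test(cand_eff, mu = 0)
  selected <- if (aic_e < aic_b && tt$p.value < alpha) "extended" else "base"
  structure(list(selected = selected, aic_base = aic_b, aic_extended = aic_e,
                 candidate_t = unname(tt$statistic),
                 candidate_p = tt$p.value, candidate_effects = cand_eff,
                 window = window, alpha = alpha),
            class = "aic_selection")
}

#' Leave-one-subject-out effect extraction
#'
#' For each subject, the selection statistic (group mean, or group mean
#' absolute value) is computed over candidate loci from \emph{all other}
#' subjects; the winning locus' effect is then read from the left-out
#' subject's own map. With n subjects this performs exactly n leave-one-out
#' refits, making each extracted effect statistically independent of the
#' selection and eliminating circularity bias.
#'
#' @param effect_maps Subjects x loci matrix of effect estimates.
#' @param select \code{"max"} (default) or \code{"absmax"} selection
#'   statistic on the group mean.
#' @return Data frame with per-subject \code{subject}, \code{locus},
#'   \code{effect}.
#' @export
loso_extract <- function(effect_maps, select = c("max", "absmax")) {
  select <- match.arg(select)
  M <- as.matrix(effect_maps)
  n <- nrow(M)
  if (n < 3) stop("need at least 3 subjects")
  out <- do.call(rbind, lapply(seq_len(n), function(s) {
    stat <- colMeans(M[-s, , drop = FALSE])
    if (select == "absmax") stat <- abs(stat)
    loc <- which.max(stat)
    data.frame(subject = s, locus = loc, effect = M[s, loc])
  }))
  rownames(out) <- NULL
  out
}

#' Circular (non-cross-validated) peak extraction
#'
#' Selects the peak locus from the full group (including every subject) and
#' reads all subjects' effects there. Provided as the biased contrast to
#' \code{\link{loso_extract}}: under a global null its mean effect is
#' positively biased.
#'
#' @inheritParams loso_extract
#' @return Data frame with \code{subject}, \code{locus}, \code{effect}.
#' @export
naive_peak_extract <- function(effect_maps, select = c("max", "absmax")) {
  select <- match.arg(select)
  M <- as.matrix(effect_maps)
  stat <- colMeans(M)
  if (select == "absmax") stat <- abs(stat)
  loc <- which.max(stat)
  data.frame(subject = seq_len(nrow(M)), locus = loc, effect = M[, loc])
}

#' Across-subject brain-behavior association
#'
#' Pearson correlation plus Huber robust linear regression (IRLS) between a
#' per-subject behavioral scalar and a per-subject neural scalar. The
#' significance level follows the multiple-comparison context: tests
#' involving the rating-task UV depth use alpha = 0.0125, tests involving
#' the choice-task UV depth use alpha = 0.0167, otherwise 0.05.
#'
#' @param behavioral,neural Numeric vectors, one value per subject.
#' @param context \code{"other"}, \code{"rating_uv"}, or
#'   \code{"choice_uv"}.
#' @return Object of class \code{"uv_association"}: \code{pearson_r},
#'   \code{p}, \code{robust_slope}, \code{robust_p},
#'   \code{alpha_threshold}, \code{significant}, \code{degenerate}.
#' @export
across_subject_association <- function(behavioral, neural,
                                       context = c("other", "rating_uv",
                                                   "choice_uv")) {
  context <- match.arg(context)
  if (length(behavioral) != length(neural)) stop("length mismatch")
  n <- length(behavioral)
  if (n < 3) stop("need at least 3 subjects")
  alpha <- switch(context, rating_uv = 0.0125, choice_uv = 0.0167, 0.05)
  if (stats::sd(behavioral) == 0 || stats::sd(neural) == 0) {
    warning("zero variance: association undefined")
    return(structure(list(pearson_r = NA_real_, p = NA_real_,
                          robust_slope = NA_real_, robust_p = NA_real_,
                          alpha_threshold = alpha, significant = NA,
                          degenerate = TRUE, n = n),
                     class = "uv_association"))
  }
  ct <- stats::cor.test(behavioral, neural)
  rfit <- MASS::rlm(neural ~ behavioral, psi = MASS::psi.huber, maxit = 50)
  cf <- summary(rfit)$coefficients
  rt <- cf["behavioral", "Value"] / cf["behavioral", "Std. Error"]
  rp <- 2 * stats::pt(-abs(rt), df = n - 2)
  structure(list(pearson_r = unname(ct$estimate), p = ct$p.value,
                 robust_slope = cf["behavioral", "Value"], robust_p = rp,
                 alpha_threshold = alpha,
                 significant = ct$p.value < alpha,
                 degenerate = FALSE, n = n),
            class = "uv_association")
}

#' @export
print.uv_association <- function(x, ...) {
  cat(sprintf("Across-subject association (n = %d): r = %.3f, p = %.4g\n",
              x$n, x$pearson_r, x$p))
  cat(sprintf("  robust slope %.4f (p = %.4g); alpha = %g -> %s\n",
              x$robust_slope, x$robust_p, x$alpha_threshold,
              if (isTRUE(x$significant)) "significant" else
                "not significant"))
  invisible(x)
}

#' Simplified psychophysiological-interaction analysis
#'
#' Convolution-domain PPI: the psychological contrast (per-trial values,
#' mean-centered) is expanded to event amplitudes and convolved with the
#' HRF; the interaction regressor is its elementwise product with the seed
#' series. The target series is regressed on the interaction, the seed, and
#' the convolved psychological regressor, and the interaction coefficient
#' with its t statistic is reported. When the generating neural event
#' amplitudes of the seed are known (simulation), an exact-neural mode
#' builds the interaction from psych x neural amplitudes before
#' convolution.
#'
#' @param seed_series Seed ROI series sampled at \code{tr}.
#' @param target_series Target ROI series, same length.
#' @param psych Per-trial psychological contrast values.
#' @param onsets Event onsets in seconds.
#' @param tr Sampling interval in seconds.
#' @param hrf From \code{\link{canonical_hrf}}.
#' @param seed_neural Optional per-trial neural amplitudes of the seed; when
#'   supplied, the interaction is the convolution of
#'   \code{psych * seed_neural} (exact-neural mode).
#' @return Object of class \code{"ppi_result"}: \code{coefficient},
#'   \code{se}, \code{t}, \code{p}, \code{mode}.
#' @export
ppi_analysis <- function(seed_series, target_series, psych, onsets, tr, hrf,
                         seed_neural = NULL) {
  if (length(seed_series) != length(target_series))
    stop("seed and target series lengths differ")
  if (length(psych) != length(onsets)) stop("psych/onsets length mismatch")
  psych <- psych - mean(psych)
  if (stats::sd(psych) == 0)
    stop("constant psychological vector: interaction collinear with seed")
  dur <- length(seed_series) * tr
  conv_events <- function(a)
    simulate_bold(a, onsets, tr = tr, duration = dur, hrf = hrf)$series
  psych_conv <- conv_events(psych)
  if (is.null(seed_neural)) {
    interaction <- psych_conv * seed_series
    mode <- "convolution"
  } else {
    if (length(seed_neural) != length(psych))
      stop("seed_neural/psych length mismatch")
    interaction <- conv_events(psych * seed_neural)
    mode <- "exact_neural"
  }
  X <- cbind(interaction = interaction, seed = seed_series,
             psych = psych_conv)
  if (any(apply(X, 2, stats::sd) == 0) ||
      qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("collinear PPI design")
  fit <- stats::lm(target_series ~ X)
  cf <- summary(fit)$coefficients
  structure(list(coefficient = cf["Xinteraction", "Estimate"],
                 se = cf["Xinteraction", "Std. Error"],
                 t = cf["Xinteraction", "t value"],
                 p = cf["Xinteraction", "Pr(>|t|)"],
                 mode = mode),
            class = "ppi_result")
}
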