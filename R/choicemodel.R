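#' Relative rating attributes for choice trials
#'
#' Attaches the trial-wise rating differences (first-presented minus
#' second-presented stimulus) for likability, familiarity, and
#' humanlikeness, computed from each stimulus' mean ratings.
#'
#' @param choice_trials Choice-trial table with \code{first}/\code{second}
#'   stimulus ids.
#' @param rating_means Per-stimulus means from
#'   \code{\link{stimulus_rating_means}}.
#' @return The trial table with columns \code{d_likability},
#'   \code{d_familiarity}, \code{d_humanlikeness} appended.
#' @export
relative_attributes <- function(choice_trials, rating_means) {
  i1 <- match(choice_trials$first, rating_means$stimulus)
  i2 <- match(choice_trials$second, rating_means$stimulus)
  if (anyNA(i1) || anyNA(i2)) {
    missing <- unique(c(choice_trials$first[is.na(i1)],
                        choice_trials$second[is.na(i2)]))
    stop("no rating means for stimulus: ", paste(missing, collapse = ", "))
  }
  choice_trials$d_likability <-
    rating_means$likability[i1] - rating_means$likability[i2]
  choice_trials$d_familiarity <-
    rating_means$familiarity[i1] - rating_means$familiarity[i2]
  choice_trials$d_humanlikeness <-
    rating_means$humanlikeness[i1] - rating_means$humanlikeness[i2]
  choice_trials
}

#' Subject-wise logistic choice model
#'
#' Maximum-likelihood logistic regression of the observed choice (0 = first
#' stimulus, 1 = second stimulus) on the three relative rating attributes
#' plus a constant. Reports classification accuracy at a 0.5 threshold and
#' McFadden's pseudo-R-squared (1 minus the ratio of the fitted to the
#' intercept-only log-likelihood). Complete or quasi-complete separation is
#' handled by a small ridge penalty with a warning flag instead of failure.
#'
#' @param trials Choice trials with delta columns (see
#'   \code{\link{relative_attributes}}) and \code{choice}.
#' @param ridge Ridge penalty used when separation is detected (default
#'   1e-3).
#' @return Object of class \code{"decision_model"}: \code{betas} (beta0..
#'   beta3), \code{vcov}, \code{accuracy}, \code{pseudo_r2},
#'   \code{loglik}, \code{loglik_null}, \code{separation}.
#' @export
fit_choice_logistic <- function(trials, ridge = 1e-3) {
  y <- trials$choice
  if (anyNA(y)) stop("`choice` contains NA")
  X <- cbind(1, trials$d_likability, trials$d_familiarity,
             trials$d_humanlikeness)
  colnames(X) <- c("beta0", "beta1", "beta2", "beta3")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  separation <- !fit$converged || max(abs(fit$coefficients)) > 15
  if (separation) {
    warning("separation detected: ridge-stabilized logistic fit used")
    co <- ridge_logistic(X, y, lambda = ridge)
    betas <- co$beta
    V <- co$vcov
  } else {
    betas <- fit$coefficients
    w <- fit$weights
    V <- solve(crossprod(X * sqrt(w)))
  }
  eta <- drop(X %*% betas)
  p <- stats::plogis(eta)
  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  p0 <- mean(y)
  ll0 <- if (p0 %in% c(0, 1)) 0 else
    sum(y * log(p0) + (1 - y) * log(1 - p0))
  pseudo_r2 <- if (ll0 == 0) NA_real_ else 1 - ll / ll0
  acc <- mean((p >= 0.5) == (y == 1))
  structure(list(betas = stats::setNames(betas, colnames(X)),
                 vcov = V, accuracy = acc, pseudo_r2 = pseudo_r2,
                 loglik = ll, loglik_null = ll0, n = length(y),
                 separation = separation),
            class = "decision_model")
}

# penalized IRLS for logistic regression (intercept unpenalized)
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  P <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * sqrt(w)) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = stats::setNames(drop(beta), colnames(X)), vcov = solve(H))
}

#' @export
print.decision_model <- function(x, ...) {
  cat("Logistic choice model (", x$n, " trials)\n", sep = "")
  print(round(x$betas, 4))
  cat(sprintf("  accuracy %.3f, McFadden pseudo-R2 %.3f%s\n", x$accuracy,
              x$pseudo_r2,
              if (x$separation) " [ridge-stabilized]" else ""))
  invisible(x)
}

#' Per-trial decision variable
#'
#' The decision variable is the weighted sum of the relative rating
#' attributes using the fitted subject weights, excluding the constant term
#' by default. Its sign predicts the choice (positive favors the second
#' stimulus on the model's scale) and its magnitude the choice strength.
#'
#' @param trials Choice trials with delta columns.
#' @param model A \code{"decision_model"}.
#' @param include_intercept Include beta0 in the sum (default \code{FALSE}).
#' @return Data frame with per-trial \code{dv} and \code{abs_dv}.
#' @export
decision_variable <- function(trials, model, include_intercept = FALSE) {
  b <- model$betas
  dv <- b["beta1"] * trials$d_likability +
    b["beta2"] * trials$d_familiarity +
    b["beta3"] * trials$d_humanlikeness
  if (include_intercept) dv <- dv + b["beta0"]
  data.frame(dv = unname(dv), abs_dv = abs(unname(dv)))
}

#' Psychometric curve over decision-variable bins
#'
#' Bins the decision variable into equally populated bins (bin counts differ
#' by at most one; ties broken by trial order) and computes the choice
#' probability per bin. A two-parameter logit curve
#' \code{P(choice = second) = plogis(bias + slope * dv)} is fitted by
#' maximum likelihood, on trial-level data by default or on bin-level
#' proportions as an option.
#'
#' @param dv Numeric decision variable per trial.
#' @param y Binary choices (1 = second stimulus).
#' @param n_bins Number of bins (default 8).
#' @param fit_on \code{"trials"} (default) or \code{"bins"}.
#' @return Object of class \code{"psychometric_fit"}: \code{bins} (data
#'   frame with \code{mid_dv}, \code{choice_prob}, \code{n}),
#'   \code{logit_bias}, \code{logit_slope}.
#' @export
psychometric_curve <- function(dv, y, n_bins = 8, fit_on = c("trials", "bins")) {
  fit_on <- match.arg(fit_on)
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  if (length(dv) < n_bins) stop("fewer trials than bins")
  if (length(unique(dv)) == 1)
    stop("binning error: decision variable is constant")
  ord <- order(dv)
  bin <- integer(length(dv))
  bin[ord] <- rep(seq_len(n_bins),
                  times = diff(floor(seq(0, length(dv), length.out = n_bins + 1))))
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    data.frame(bin = b, mid_dv = mean(dv[sel]),
               choice_prob = mean(y[sel]), n = sum(sel))
  }))
  if (fit_on == "trials") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, dv), y, family = stats::binomial()))
    cf <- fit$coefficients
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, bins$mid_dv), bins$choice_prob,
                     family = stats::binomial(), weights = bins$n))
    cf <- fit$coefficients
  }
  structure(list(bins = bins, logit_bias = unname(cf[1]),
                 logit_slope = unname(cf[2]), fit_on = fit_on),
            class = "psychometric_fit")
}

#' Choice-task uncanny-valley depth from the decision variable
#'
#' Within each human-referenced choice contrast, the delta decision variable
#' is the mean unsigned decision variable; larger values indicate clearer
#' preference between the two categories. An OLS line of delta-DV on the
#' absolute category-mean humanlikeness difference is fitted over the four
#' non-target contrasts, and the choice UV depth is the observed minus the
#' predicted delta-DV for the human versus artificial-human contrast
#' (positive = valley: the preference gap is larger than the continuum
#' predicts).
#'
#' @param trials Choice trials with \code{contrast} labels and the
#'   \code{dv} column appended (see \code{\link{decision_variable}}).
#' @param category_means Per-category humanlikeness means (from
#'   \code{\link{category_rating_means}}).
#' @param reference Reference category (default \code{"human_no_impair"}).
#' @param target_other The target contrast's other category (default
#'   \code{"artificial_human"}).
#' @return Object of class \code{"choice_uv_result"}: \code{contrast_table}
#'   (per-contrast \code{delta_dv} and humanlikeness difference),
#'   \code{slope}, \code{intercept}, \code{predicted}, \code{observed},
#'   \code{choice_uv_depth}.
#' @export
choice_uv_depth <- function(trials, category_means,
                            reference = "human_no_impair",
                            target_other = "artificial_human") {
  if (!"dv" %in% names(trials))
    stop("`trials` must carry a `dv` column")
  others <- setdiff(uv_categories()$name, reference)
  wanted <- paste(reference, "vs", others)
  present <- intersect(wanted, unique(trials$contrast))
  if (!paste(reference, "vs", target_other) %in% present)
    stop("target contrast missing from `trials`")
  if (length(present) < 3)
    stop("need the reference-based contrasts to fit the continuum")
  h_ref <- category_means$humanlikeness[category_means$category == reference]
  tab <- do.call(rbind, lapply(present, function(cn) {
    oth <- sub(paste0("^", reference, " vs "), "", cn)
    h_oth <- category_means$humanlikeness[category_means$category == oth]
    data.frame(contrast = cn, other_category = oth,
               delta_dv = mean(abs(trials$dv[trials$contrast == cn])),
               d_humanlikeness = abs(h_ref - h_oth),
               stringsAsFactors = FALSE)
  }))
  is_target <- tab$other_category == target_other
  x <- tab$d_humanlikeness[!is_target]
  y <- tab$delta_dv[!is_target]
  if (stats::var(x) == 0) stop("singular fit: constant humanlikeness gaps")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  predicted <- intercept + slope * tab$d_humanlikeness[is_target]
  observed <- tab$delta_dv[is_target]
  structure(list(contrast_table = tab, slope = slope, intercept = intercept,
                 predicted = predicted, observed = observed,
                 choice_uv_depth = observed - predicted,
                 reference = reference, target_other = target_other),
            class = "choice_uv_result")
}

#' @export
print.choice_uv_result <- function(x, ...) {
  cat(sprintf("Choice UV depth (%s vs %s): %.4f\n", x$reference,
              x$target_other, x$choice_uv_depth))
  print(x$contrast_table, row.names = FALSE)
  invisible(x)
}

#' Group tests of choice-model coefficients
#'
#' Random-effects stage: one-sample two-sided t tests of each per-subject
#' logistic coefficient across subjects.
#'
#' @param beta_matrix Subjects x coefficients matrix.
#' @return Data frame with per-coefficient \code{mean}, \code{t}, \code{df},
#'   \code{p}.
#' @export
choice_group_tests <- function(beta_matrix) {
  out <- do.call(rbind, lapply(colnames(beta_matrix), function(cn) {
    v <- beta_matrix[, cn]
    tt <- stats::t.test(v, mu = 0)
    data.frame(coefficient = cn, mean = mean(v),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
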