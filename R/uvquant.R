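#' Uncanny-valley depth from a linear humanlikeness continuum
#'
#' Fits ordinary least squares of an outcome (likability by default) on
#' humanlikeness over the per-stimulus means of every non-target stimulus,
#' then defines the UV depth as the likability predicted at the target
#' category's mean humanlikeness minus the target's observed mean likability.
#' Positive depth means the target falls below the continuum, i.e. in the
#' valley.
#'
#' @param means Per-stimulus (or per-category) means with columns
#'   \code{category}, \code{humanlikeness}, and the outcome column.
#' @param target_category Category whose deviation is measured (default
#'   \code{"artificial_human"}).
#' @param include_androids If \code{TRUE}, androids join the target set and
#'   are excluded from the fit as well.
#' @param outcome Outcome column (default \code{"likability"}; amplitudes or
#'   other scales may be supplied).
#' @return Object of class \code{"uv_result"}: \code{slope},
#'   \code{intercept}, \code{predicted}, \code{observed}, \code{uv_depth},
#'   \code{target_category}, \code{n_fit}.
#' @export
#' @examples
#' d <- data.frame(category = c("a", "b", "c", "e", "t"),
#'                 humanlikeness = c(1, 2, 3, 5, 4),
#'                 likability = c(1, 2, 3, 5, 2))
#' uv_depth(d, target_category = "t")$uv_depth  # 2
uv_depth <- function(means, target_category = "artificial_human",
                     include_androids = FALSE, outcome = "likability") {
  targets <- target_category
  if (include_androids) targets <- union(targets, "android")
  in_target <- means$category %in% targets
  if (!any(in_target)) stop("target category absent from `means`")
  fit_d <- means[!in_target, ]
  x <- fit_d$humanlikeness
  y <- fit_d[[outcome]]
  if (length(unique(x)) < 2 || stats::var(x) == 0)
    stop("singular fit: humanlikeness has no variance outside the target")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  x_t <- mean(means$humanlikeness[in_target])
  observed <- mean(means[[outcome]][in_target])
  predicted <- intercept + slope * x_t
  structure(list(slope = slope, intercept = intercept,
                 predicted = predicted, observed = observed,
                 uv_depth = predicted - observed,
                 target_category = targets, outcome = outcome,
                 target_humanlikeness = x_t, n_fit = length(x)),
            class = "uv_result")
}

#' @export
print.uv_result <- function(x, ...) {
  cat(sprintf("UV depth (%s, target %s): %.4f\n", x$outcome,
              paste(x$target_category, collapse = "+"), x$uv_depth))
  cat(sprintf("  continuum fit: intercept %.4f, slope %.4f (n = %d)\n",
              x$intercept, x$slope, x$n_fit))
  cat(sprintf("  predicted %.4f vs observed %.4f at humanlikeness %.3f\n",
              x$predicted, x$observed, x$target_humanlikeness))
  invisible(x)
}

#' Leave-one-category-out residual profile
#'
#' For each category, fits the likability-on-humanlikeness regression on all
#' other categories' data and records the category's mean regression
#' residual (observed minus predicted). On valley data the
#' artificial-human residual is the most negative entry; residuals are the
#' sign-flip of \code{\link{uv_depth}}-style deviations.
#'
#' @inheritParams uv_depth
#' @return Object of class \code{"uv_residual_profile"}: data frame
#'   \code{profile} with per-category \code{residual}, \code{slope},
#'   \code{intercept}.
#' @export
uv_depth_residuals <- function(means, outcome = "likability") {
  cats <- intersect(uv_categories()$name, unique(means$category))
  if (length(cats) < 2) stop("need at least two categories")
  rows <- lapply(cats, function(cn) {
    held <- means$category == cn
    x <- means$humanlikeness[!held]
    y <- means[[outcome]][!held]
    if (length(unique(x)) < 2 || stats::var(x) == 0)
      stop("singular fit leaving out ", cn)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    pred <- intercept + slope * means$humanlikeness[held]
    data.frame(category = cn,
               residual = mean(means[[outcome]][held] - pred),
               slope = slope, intercept = intercept,
               stringsAsFactors = FALSE)
  })
  structure(list(profile = do.call(rbind, rows), outcome = outcome),
            class = "uv_residual_profile")
}

#' @export
print.uv_residual_profile <- function(x, ...) {
  cat("Leave-one-category-out residuals (", x$outcome, "):\n", sep = "")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Cubic fit of likability on humanlikeness
#'
#' Least-squares third-order polynomial with the coefficient of
#' determination computed as one minus the residual over total sum of
#' squares. A constant outcome (zero total sum of squares) yields
#' \code{r_squared = 0} with \code{degenerate = TRUE}.
#'
#' @param humanlikeness,likability Numeric vectors of equal length.
#' @return Object of class \code{"uv_cubic_fit"}: \code{coefficients}
#'   (c0..c3), \code{r_squared}, \code{fitted}, \code{degenerate}.
#' @export
cubic_uv_fit <- function(humanlikeness, likability) {
  if (length(humanlikeness) != length(likability))
    stop("input lengths differ")
  if (length(unique(humanlikeness)) < 4)
    stop("singular fit: need at least 4 distinct humanlikeness values")
  X <- cbind(1, humanlikeness, humanlikeness^2, humanlikeness^3)
  qrX <- qr(X)
  if (qrX$rank < 4) stop("singular fit: rank-deficient cubic design")
  cf <- qr.coef(qrX, likability)
  fitted <- drop(X %*% cf)
  sse <- sum((likability - fitted)^2)
  sst <- sum((likability - mean(likability))^2)
  degenerate <- sst == 0
  r2 <- if (degenerate) {
    warning("constant outcome: r_squared reported as 0")
    0
  } else 1 - sse / sst
  structure(list(coefficients = stats::setNames(cf, paste0("c", 0:3)),
                 r_squared = r2, fitted = fitted, degenerate = degenerate),
            class = "uv_cubic_fit")
}

#' Per-presentation deviations from the continuum fit
#'
#' For every rating trial of the target category, the deviation is the
#' likability predicted by the subject's non-target continuum fit at the
#' trial's own humanlikeness rating minus the observed likability
#' (predicted minus observed, so positive deviations indicate the valley).
#' These per-presentation deviations feed the within-subject significance
#' test in \code{\link{group_uv_tests}}.
#'
#' @param rated_trials A subject's rating trials with ratings filled.
#' @param fit A \code{"uv_result"} for the same subject.
#' @return Numeric vector of deviations, one per target presentation.
#' @export
uv_trial_deviations <- function(rated_trials, fit) {
  held <- rated_trials$category %in% fit$target_category
  pred <- fit$intercept + fit$slope * rated_trials$humanlikeness[held]
  pred - rated_trials[[fit$outcome]][held]
}

#' Group and per-subject uncanny-valley tests
#'
#' Group stage: two-sided one-sample t test of per-subject UV depths against
#' zero. Subject stage: for each subject, a two-sided one-sample t test of
#' that subject's per-presentation deviations (predicted minus observed)
#' against zero, with the count of subjects significant at \code{alpha}.
#' Zero-variance inputs are flagged degenerate rather than tested.
#'
#' @param depths Numeric vector of per-subject UV depths.
#' @param per_trial_deviations Optional list (one numeric vector per
#'   subject) of per-presentation deviations.
#' @param alpha Per-subject significance level (default 0.05).
#' @return Object of class \code{"uv_group_tests"}: group \code{t},
#'   \code{df}, \code{p}, \code{mean_depth}, \code{degenerate}; and, when
#'   deviations are given, \code{subject_p}, \code{n_significant}.
#' @export
group_uv_tests <- function(depths, per_trial_deviations = NULL,
                           alpha = 0.05) {
  if (length(depths) < 2) stop("need at least two subjects")
  out <- list(mean_depth = mean(depths), n = length(depths), alpha = alpha)
  if (stats::sd(depths) == 0) {
    out$degenerate <- TRUE
    out$t <- if (mean(depths) == 0) 0 else NA_real_
    out$df <- length(depths) - 1
    out$p <- NA_real_
  } else {
    tt <- stats::t.test(depths, mu = 0)
    out$degenerate <- FALSE
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
  }
  if (!is.null(per_trial_deviations)) {
    ps <- vapply(per_trial_deviations, function(d) {
      if (length(d) < 2 || stats::sd(d) == 0) return(NA_real_)
      stats::t.test(d, mu = 0)$p.value
    }, numeric(1))
    out$subject_p <- ps
    out$n_significant <- sum(ps < alpha, na.rm = TRUE)
  }
  class(out) <- "uv_group_tests"
  out
}

#' @export
print.uv_group_tests <- function(x, ...) {
  cat(sprintf("Group UV test: mean depth %.4f, t(%g) = %.3f, p = %.3g%s\n",
              x$mean_depth, x$df, x$t, x$p,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  if (!is.null(x$n_significant))
    cat(sprintf("  %d of %d subjects significant at alpha = %g\n",
                x$n_significant, x$n, x$alpha))
  invisible(x)
}
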