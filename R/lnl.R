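#' Linear-nonlinear region response prediction
#'
#' Evaluates the regional response models at a humanlikeness value:
#' \itemize{
#'   \item TPJ: linear, \code{a + b * h}.
#'   \item FFG: constant \code{c} for human agents; inverse linear
#'     \code{d - e * h} for nonhuman agents (\code{e >= 0}).
#'   \item DMPFC: \code{baseline + step} for humans;
#'     \code{baseline + nonhuman_slope * h} for nonhumans (slope 0 by
#'     default, giving a pure human-detection step).
#'   \item VMPFC: affine multiplicative combination
#'     \code{m + k * TPJ(h) * FFG(h)}.
#' }
#'
#' @param params Region parameter list (see \code{\link{lnl_default_params}}
#'   and \code{\link{subject_lnl_params}}; \code{ffg} must carry a concrete
#'   slope \code{e}).
#' @param region One of \code{"TPJ"}, \code{"FFG"}, \code{"DMPFC"},
#'   \code{"VMPFC"}.
#' @param humanlikeness Numeric vector.
#' @param is_human Logical vector (recycled if length 1).
#' @return Numeric amplitudes.
#' @export
lnl_predict <- function(params, region, humanlikeness, is_human) {
  if (length(is_human) == 1) is_human <- rep(is_human, length(humanlikeness))
  ffg_e <- if (!is.null(params$ffg$e)) params$ffg$e else
    stop("`params$ffg$e` missing: resolve subject parameters first")
  if (ffg_e < 0) stop("FFG nonhuman slope `e` must be >= 0")
  switch(toupper(region),
    TPJ = params$tpj$a + params$tpj$b * humanlikeness,
    FFG = ifelse(is_human, params$ffg$c, params$ffg$d - ffg_e * humanlikeness),
    DMPFC = {
      if (params$dmpfc$step < 0) stop("DMPFC step height must be >= 0")
      params$dmpfc$baseline + params$dmpfc$step * is_human +
        ifelse(is_human, 0, params$dmpfc$nonhuman_slope * humanlikeness)
    },
    VMPFC = params$vmpfc$m + params$vmpfc$k *
      lnl_predict(params, "TPJ", humanlikeness, is_human) *
      lnl_predict(params, "FFG", humanlikeness, is_human),
    stop("unknown region: ", region)
  )
}

#' Per-category region patterns from trial amplitudes
#'
#' @param amplitudes Trial amplitude table from
#'   \code{\link{simulate_roi_amplitudes}} (or same-shaped data).
#' @param regions Amplitude columns to average.
#' @return Data frame: one row per category in continuum order with
#'   \code{is_human} and the mean amplitude per region.
#' @export
region_patterns <- function(amplitudes,
                            regions = c("tpj", "ffg", "dmpfc", "vmpfc",
                                        "amygdala")) {
  regions <- intersect(regions, names(amplitudes))
  cats <- uv_categories()
  out <- do.call(rbind, lapply(cats$name, function(cn) {
    d <- amplitudes[amplitudes$category == cn, , drop = FALSE]
    row <- data.frame(category = cn,
                      is_human = cats$is_human[cats$name == cn],
                      stringsAsFactors = FALSE)
    for (r in regions) row[[r]] <- mean(d[[r]])
    row
  }))
  rownames(out) <- NULL
  out
}

#' Fit the linear-nonlinear region models to category patterns
#'
#' Least-squares fits of each region model to its six-category pattern:
#' TPJ linear over all categories; FFG piecewise (line over nonhumans, mean
#' over humans); DMPFC step model (nonhuman mean or optional nonhuman line,
#' plus human step); VMPFC gain and offset by regressing the measured
#' pattern on the product of the measured TPJ and FFG patterns.
#'
#' @param patterns Data frame from \code{\link{region_patterns}} with
#'   columns \code{tpj}, \code{ffg}, \code{dmpfc}, \code{vmpfc}.
#' @param humanlikeness Per-category humanlikeness means, aligned with
#'   \code{patterns} (by default the category-mean rated humanlikeness; the
#'   latent values are not assumed available).
#' @param is_human Logical per category (taken from \code{patterns} when
#'   present).
#' @param dmpfc_nonhuman_slope Fit a nonhuman slope in the DMPFC model
#'   (default \code{FALSE}: pure step).
#' @return Object of class \code{"lnl_fit"} with the same structure as
#'   \code{\link{lnl_default_params}} (concrete \code{e}), plus per-region
#'   fitted patterns.
#' @export
fit_lnl <- function(patterns, humanlikeness, is_human = patterns$is_human,
                    dmpfc_nonhuman_slope = FALSE) {
  h <- humanlikeness
  stopifnot(length(h) == nrow(patterns))
  nh <- !is_human
  if (sum(nh) < 2 || sum(is_human) < 1)
    stop("need at least two nonhuman and one human category")
  ols2 <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) stop("singular fit: constant predictor")
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    c(intercept = mean(y) - b * mean(x), slope = b)
  }
  tpj_cf <- ols2(h, patterns$tpj)
  ffg_cf <- ols2(h[nh], patterns$ffg[nh])
  ffg_c <- mean(patterns$ffg[is_human])
  if (dmpfc_nonhuman_slope) {
    dm_cf <- ols2(h[nh], patterns$dmpfc[nh])
    dm_baseline <- unname(dm_cf["intercept"])
    dm_slope <- unname(dm_cf["slope"])
    dm_pred_nh_at_h <- dm_baseline + dm_slope * h
  } else {
    dm_baseline <- mean(patterns$dmpfc[nh])
    dm_slope <- 0
    dm_pred_nh_at_h <- rep(dm_baseline, length(h))
  }
  dm_step <- mean(patterns$dmpfc[is_human]) -
    mean(dm_pred_nh_at_h[is_human])
  prod_meas <- patterns$tpj * patterns$ffg
  vm_cf <- ols2(prod_meas, patterns$vmpfc)
  fit <- list(
    tpj = list(a = unname(tpj_cf["intercept"]), b = unname(tpj_cf["slope"])),
    ffg = list(d = unname(ffg_cf["intercept"]),
               e = -unname(ffg_cf["slope"]), c = ffg_c),
    dmpfc = list(baseline = dm_baseline, step = dm_step,
                 nonhuman_slope = dm_slope),
    vmpfc = list(k = unname(vm_cf["slope"]), m = unname(vm_cf["intercept"]))
  )
  fitted <- data.frame(
    category = patterns$category,
    tpj = fit$tpj$a + fit$tpj$b * h,
    ffg = ifelse(is_human, fit$ffg$c, fit$ffg$d - fit$ffg$e * h),
    dmpfc = dm_pred_nh_at_h + dm_step * is_human,
    vmpfc = fit$vmpfc$m + fit$vmpfc$k * prod_meas,
    stringsAsFactors = FALSE
  )
  structure(c(fit, list(fitted = fitted)), class = "lnl_fit")
}

#' Reconstruct the VMPFC pattern from TPJ and FFG signals
#'
#' Regresses the measured VMPFC category pattern on the product of the
#' measured TPJ and FFG patterns (affine rescaling: gain and offset), and
#' reports the computed pattern with its Pearson correlation to the
#' measured one.
#'
#' @param tpj_pattern,ffg_pattern,vmpfc_measured Aligned per-category
#'   amplitude vectors.
#' @return Object of class \code{"vmpfc_reconstruction"}: \code{computed},
#'   \code{k}, \code{m}, \code{r}, \code{degenerate}.
#' @export
reconstruct_vmpfc <- function(tpj_pattern, ffg_pattern, vmpfc_measured) {
  stopifnot(length(tpj_pattern) == length(ffg_pattern),
            length(tpj_pattern) == length(vmpfc_measured))
  prod <- tpj_pattern * ffg_pattern
  if (stats::var(prod) == 0) stop("singular fit: constant TPJ x FFG product")
  slope <- sum((prod - mean(prod)) * (vmpfc_measured - mean(vmpfc_measured))) /
    sum((prod - mean(prod))^2)
  intercept <- mean(vmpfc_measured) - slope * mean(prod)
  computed <- intercept + slope * prod
  degenerate <- stats::var(vmpfc_measured) == 0
  r <- if (degenerate) {
    warning("constant measured pattern: correlation undefined")
    NA_real_
  } else stats::cor(computed, vmpfc_measured)
  structure(list(computed = computed, k = slope, m = intercept, r = r,
                 degenerate = degenerate),
            class = "vmpfc_reconstruction")
}

#' Neural uncanny-valley depth for a region pattern
#'
#' Applies the continuum UV-depth contract (\code{\link{uv_depth}}) to a
#' per-category amplitude pattern instead of likability ratings.
#'
#' @param pattern Per-category amplitudes (vector aligned with
#'   \code{categories}, or a \code{region_patterns} data frame plus a
#'   region column name in \code{outcome}).
#' @param humanlikeness Per-category humanlikeness means.
#' @param categories Category names aligned with \code{pattern} (default:
#'   the six categories in continuum order).
#' @param target_category Target category (default artificial humans).
#' @return A \code{"uv_result"} on the amplitude scale.
#' @export
neural_uv_depth <- function(pattern, humanlikeness,
                            categories = uv_categories()$name,
                            target_category = "artificial_human") {
  d <- data.frame(category = categories, humanlikeness = humanlikeness,
                  amplitude = pattern, stringsAsFactors = FALSE)
  uv_depth(d, target_category = target_category, outcome = "amplitude")
}
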