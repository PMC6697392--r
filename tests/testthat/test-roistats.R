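test_that("canonical HRF starts at zero and peaks at the gamma mode", {
  h <- canonical_hrf(0.01)
  expect_equal(h$values[1], 0)
  expect_equal(max(h$values), 1)
  # analytic mode of the dominant gamma: (shape - 1) * scale = 5 s;
  # the undershoot term is ~1e-5 there and cannot move the argmax by a step
  expect_lt(abs(h$grid[which.max(h$values)] - 5), 0.01 + 1e-9)
  # refinement consistency: coarse and fine grids agree within a coarse step
  hc <- canonical_hrf(0.1)
  expect_lt(abs(hc$grid[which.max(hc$values)] -
                  h$grid[which.max(h$values)]), 0.1 + 1e-9)
  # single positive peak then a smaller undershoot
  expect_lt(min(h$values), 0)
  expect_gt(max(h$values), abs(min(h$values)) * 3)
})

test_that("discrete-cosine high-pass removes slow drift, keeps fast signal", {
  tr <- 2; n <- 256
  t <- (0:(n - 1)) * tr
  expect_equal(dct_highpass(rep(3, n), tr), rep(0, n), tolerance = 1e-10)
  slow <- cos(2 * pi * t / 400)           # period 400 s > 128 s cutoff
  expect_lt(sd(dct_highpass(slow, tr)), 0.1 * sd(slow))
  fast <- sin(2 * pi * t / 40)            # period 40 s, well inside passband
  expect_gt(sd(dct_highpass(fast, tr)), 0.9 * sd(fast))
  expect_error(dct_highpass(rep(1, 10), tr = 2, cutoff = 3), "exceed")
})

test_that("sinc oversampling reproduces a band-limited oracle", {
  tr <- 2; n <- 300
  t <- (0:(n - 1)) * tr
  x <- sin(2 * pi * 0.05 * t + 0.3) + 0.5 * cos(2 * pi * 0.11 * t)
  os <- sinc_oversample(x, 10)
  expect_equal(length(os), n * 10)
  td <- (0:(n * 10 - 1)) * tr / 10
  truth <- sin(2 * pi * 0.05 * td + 0.3) + 0.5 * cos(2 * pi * 0.11 * td)
  interior <- 200:(length(os) - 200)      # kernel half-width off each edge
  expect_lt(max(abs(os - truth)[interior]), 1e-3)
  # on-grid samples pass through
  expect_equal(os[1 + (0:(n - 1)) * 10], x, tolerance = 1e-6)
})

test_that("preprocessing flags constant input and scales the time axis", {
  hrf <- canonical_hrf(0.1)
  ses <- build_session_onsets(10, seed = 2)
  b <- simulate_bold(rep(1, 10), ses$onsets, tr = 2, duration = ses$duration,
                     hrf = hrf, noise_sd = 0.2, seed = 1)
  tc <- preprocess_timecourse(b, onsets = ses$onsets, oversample = 10)
  expect_equal(length(tc$series), length(b$series) * 10)
  expect_equal(tc$tr_effective, 0.2)
  expect_equal(nrow(tc$epochs), 10)
  expect_equal(ncol(tc$epochs), length(tc$time))
  # full-session series is z-normalized before epoching
  expect_equal(mean(tc$series[seq(1, length(tc$series), by = 10)]), 0,
               tolerance = 0.05)
  expect_warning(
    tc0 <- preprocess_timecourse(rep(2, 200), tr = 2, onsets = c(30, 100)),
    "constant")
  expect_true(tc0$degenerate)
  expect_true(all(tc0$epochs == 0))
  expect_error(preprocess_timecourse(rnorm(100), tr = 2, onsets = 500),
               "outside session")
})

test_that("per-timepoint GLM matches simple fits for orthogonal designs", {
  set.seed(3)
  n <- 32
  x1 <- scale(rnorm(n), scale = FALSE)        # mean-centered
  x2 <- residuals(lm(rnorm(n) ~ x1))          # centered, orthogonal to x1
  X <- cbind(r1 = drop(x1), r2 = drop(x2))
  Y <- outer(X[, 1], c(1, 2, 3)) + outer(X[, 2], c(-1, 0, 1)) +
    matrix(rnorm(n * 3, 0, 0.1), n, 3)
  eff <- timepoint_glm(Y, X, standardize = FALSE)
  expect_equal(unname(eff$vif), c(1, 1), tolerance = 1e-10)
  for (j in 1:2) for (tt in 1:3) {
    simple <- coef(lm(Y[, tt] ~ X[, j]))[2]
    expect_equal(unname(eff$coefficients[tt, j]), unname(simple),
                 tolerance = 1e-8)
  }
})

test_that("per-timepoint GLM equals a hand normal-equations solve", {
  set.seed(8)
  X <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y <- matrix(rnorm(6 * 4), 6, 4)
  eff <- timepoint_glm(Y, X, standardize = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  for (tt in 1:4) {
    cf <- ols_normal_equations(cbind(1, Xc), Y[, tt])
    expect_equal(unname(eff$coefficients[tt, ]), unname(cf[-1]),
                 tolerance = 1e-8)
  }
})

test_that("exactly collinear regressors are refused by name", {
  X <- cbind(a = rnorm(10), b = 1:10)
  X <- cbind(X, c = X[, "a"] * 2)
  Y <- matrix(rnorm(20), 10, 2)
  expect_error(timepoint_glm(Y, X), "collinear.*a.*c|collinear.*c")
})

test_that("group effect time courses run one-sample t tests per timepoint", {
  set.seed(12)
  subj <- lapply(1:15, function(i)
    matrix(rnorm(20 * 2, mean = rep(c(1.2, 0), each = 20)), 20, 2,
           dimnames = list(NULL, c("x", "y"))))
  g <- group_effect_timecourse(subj)
  expect_equal(dim(g$mean), c(20, 2))
  v <- sapply(subj, function(m) m[3, 1])
  expect_equal(unname(g$t[3, 1]), mean(v) / (sd(v) / sqrt(15)),
               tolerance = 1e-12)
  expect_true(mean(g$p[, 1] < 0.05) > 0.5)  # real effect detected
})

test_that("Gaussian AIC matches the hand formula on a toy OLS fit", {
  set.seed(5)
  x <- rnorm(20); y <- 1 + 0.5 * x + rnorm(20, 0, 0.3)
  fit <- lm(y ~ x)
  rss <- sum(resid(fit)^2)
  expect_equal(aic_gaussian(rss, 20, 2), 20 * log(rss / 20) + 2 * 2)
})

test_that("AIC selection accepts the step regressor only when it is real", {
  # amplitude-level epochs: trial amplitude times an HRF-like course
  course <- exp(-((seq(0, 10, by = 1) - 5)^2) / 4)
  make_subjects <- function(step_weight, seed) {
    set.seed(seed)
    lapply(1:8, function(i) {
      R <- data.frame(likability = rnorm(36), humanlikeness = rnorm(36),
                      familiarity = rnorm(36),
                      human_detection = rep(c(-0.5, 0.5), 18))
      amp <- 0.8 * R$likability + 0.5 * R$humanlikeness +
        step_weight * R$human_detection
      epochs <- outer(amp, course) + matrix(rnorm(36 * 11, 0, 0.5), 36, 11)
      list(epochs = epochs, regressors = R)
    })
  }
  time <- seq(0, 10, by = 1)
  n_base <- 0; n_ext <- 0
  for (r in 1:60) {
    s0 <- model_select_aic(make_subjects(0, 1000 + r), time = time,
                           window = c(2, 8))
    if (s0$selected == "base") n_base <- n_base + 1
    s1 <- model_select_aic(make_subjects(1.5, 2000 + r), time = time,
                           window = c(2, 8))
    if (s1$selected == "extended") n_ext <- n_ext + 1
  }
  expect_gte(n_base / 60, 0.9)
  expect_gte(n_ext / 60, 0.9)
})

test_that("LOSO performs one refit per subject and respects agreement", {
  M <- matrix(rep(c(0.1, 0.9, 0.3), each = 21), 21, 3)
  res <- loso_extract(M)
  expect_equal(nrow(res), 21)
  expect_true(all(res$locus == 2))
  expect_error(loso_extract(M[1:2, ]), "at least 3")
})

test_that("across-subject association matches the closed-form Pearson r", {
  b <- c(0.2, 0.5, 0.9, 1.4)
  n4 <- c(1.1, 1.9, 3.1, 4.2)
  res <- across_subject_association(b, n4)
  r_hand <- sum((b - mean(b)) * (n4 - mean(n4))) /
    sqrt(sum((b - mean(b))^2) * sum((n4 - mean(n4))^2))
  expect_equal(res$pearson_r, r_hand, tolerance = 1e-12)
  # exact proportionality: r = 1
  res2 <- across_subject_association(b, 2 * b)
  expect_equal(res2$pearson_r, 1, tolerance = 1e-12)
  # Bonferroni context thresholds
  expect_equal(across_subject_association(b, n4,
                                          "rating_uv")$alpha_threshold,
               0.0125)
  expect_equal(across_subject_association(b, n4,
                                          "choice_uv")$alpha_threshold,
               0.0167)
  expect_warning(
    resz <- across_subject_association(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(resz$degenerate)
})

test_that("robust regression slope survives one gross outlier", {
  set.seed(14)
  b <- rnorm(20); nn <- 1.5 * b + rnorm(20, 0, 0.1)
  nn[1] <- nn[1] + 25
  res <- across_subject_association(b, nn)
  expect_lt(abs(res$robust_slope - 1.5), 0.3)
})

test_that("PPI detects context-dependent coupling and rejects degenerate input", {
  hrf <- canonical_hrf(0.1)
  ses <- build_session_onsets(36, seed = 6)
  psych <- rep(c(1, -1), 18)
  set.seed(10)
  amp_seed <- rnorm(36)
  seedb <- simulate_bold(amp_seed, ses$onsets, 2, ses$duration, hrf,
                         noise_sd = 0.2, seed = 21)
  tgt <- simulate_bold(psych * amp_seed, ses$onsets, 2, ses$duration, hrf,
                       noise_sd = 0.2, seed = 22)
  res <- ppi_analysis(seedb$series, tgt$series, psych, ses$onsets, 2, hrf)
  expect_lt(res$p, 0.001)
  # exact-neural mode uses the known event amplitudes
  res2 <- ppi_analysis(seedb$series, tgt$series, psych, ses$onsets, 2, hrf,
                       seed_neural = amp_seed)
  expect_lt(res2$p, res$p * 1.01)
  expect_equal(res2$mode, "exact_neural")
  # independent seed/target pairs: the interaction coefficient is unbiased
  # at zero (replicate mean within 2 SE)
  coefs <- vapply(1:60, function(r) {
    set.seed(300 + r)
    sb <- simulate_bold(rnorm(36), ses$onsets, 2, ses$duration, hrf,
                        noise_sd = 0.2, seed = 600 + r)
    t0 <- simulate_bold(rnorm(36), ses$onsets, 2, ses$duration, hrf,
                        noise_sd = 0.2, seed = 700 + r)
    ppi_analysis(sb$series, t0$series, psych, ses$onsets, 2,
                 hrf)$coefficient
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 2 * sd(coefs) / sqrt(60))
  expect_error(ppi_analysis(seedb$series, tgt$series, rep(0, 36),
                            ses$onsets, 2, hrf), "constant psych")
})
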