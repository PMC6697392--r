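# Shared fixtures, built in code at test time.

default_design <- build_study_design(seed = 7)

# a deterministic subject: no noise, known dip
noiseless_params <- function(uv_dip = 0) {
  p <- list(
    subject = 1,
    slope_likability = 0.6,
    intercept_likability = 1.0,
    uv_dip = uv_dip,
    rating_noise_sd = 0,
    familiarity_coupling = 0.6,
    familiarity_mean = 3.0,
    betas = c(beta0 = 0, beta1 = -1.9, beta2 = -0.7, beta3 = -0.55),
    confidence_gain = 0.8,
    confidence_noise_sd = 0,
    amplitude_noise_sd = 0,
    lnl = lnl_default_params()
  )
  class(p) <- "uv_subject_params"
  p
}

# fast per-subject rating simulation -> per-stimulus means
sim_subject_means <- function(params, seed) {
  stimulus_rating_means(
    simulate_ratings(params, default_design$rating_trials, seed = seed))
}

# brute-force OLS via normal equations, the independent linear-algebra oracle
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}
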