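test_that("relative attributes are first-minus-second and antisymmetric", {
  means <- data.frame(stimulus = c("s1", "s2"),
                      category = c("a", "b"), is_human = c(FALSE, TRUE),
                      likability = c(4.2, 3.0), familiarity = c(2.0, 2.0),
                      humanlikeness = c(3.5, 4.5))
  tr <- data.frame(first = "s1", second = "s2")
  d <- relative_attributes(tr, means)
  expect_equal(d$d_likability, 1.2)
  expect_equal(d$d_familiarity, 0)
  expect_equal(d$d_humanlikeness, -1)
  swapped <- relative_attributes(data.frame(first = "s2", second = "s1"),
                                 means)
  expect_equal(swapped$d_likability, -d$d_likability)
  expect_equal(swapped$d_humanlikeness, -d$d_humanlikeness)
  expect_error(relative_attributes(data.frame(first = "s1", second = "zz"),
                                   means), "no rating means")
})

test_that("logistic fit classifies separable data perfectly", {
  p <- noiseless_params()
  rt <- simulate_ratings(p, default_design$rating_trials, seed = 1)
  means <- stimulus_rating_means(rt)
  tr <- relative_attributes(default_design$choice_design$trials, means)
  tr$choice <- as.integer(tr$d_likability < 0)
  expect_warning(fit <- fit_choice_logistic(tr), "separation")
  expect_true(fit$separation)
  expect_equal(fit$accuracy, 1.0)
})

test_that("fitted log-likelihood dominates a brute-force beta grid", {
  set.seed(21)
  n <- 40
  tr <- data.frame(d_likability = rnorm(n), d_familiarity = rnorm(n),
                   d_humanlikeness = rnorm(n))
  eta <- 0.2 - 1.1 * tr$d_likability - 0.4 * tr$d_familiarity
  tr$choice <- rbinom(n, 1, plogis(eta))
  fit <- fit_choice_logistic(tr)
  X <- cbind(1, tr$d_likability, tr$d_familiarity, tr$d_humanlikeness)
  ll <- function(b) {
    p <- plogis(drop(X %*% b))
    sum(tr$choice * log(p) + (1 - tr$choice) * log(1 - p))
  }
  grid <- as.matrix(expand.grid(b0 = seq(-1, 1, 0.5),
                                b1 = seq(-3, 1, 0.5),
                                b2 = seq(-2, 2, 0.5),
                                b3 = seq(-1, 1, 0.5)))
  grid_ll <- apply(grid, 1, ll)
  expect_gte(fit$loglik, max(grid_ll) - 1e-8)
  # McFadden pseudo-R2 by definition
  expect_equal(fit$pseudo_r2, 1 - fit$loglik / fit$loglik_null,
               tolerance = 1e-12)
})

test_that("decision variable is the weighted delta sum without intercept", {
  model <- structure(list(betas = c(beta0 = 5, beta1 = 1, beta2 = 1,
                                    beta3 = 1)), class = "decision_model")
  tr <- data.frame(d_likability = 0.5, d_familiarity = -0.2,
                   d_humanlikeness = 0.1)
  expect_equal(decision_variable(tr, model)$dv, 0.4)
  expect_equal(decision_variable(tr, model, include_intercept = TRUE)$dv,
               5.4)
  tr0 <- data.frame(d_likability = 0, d_familiarity = 0,
                    d_humanlikeness = 0)
  expect_equal(decision_variable(tr0, model)$dv, 0)

  # antisymmetry under order swap
  trs <- data.frame(d_likability = c(0.7, -0.7),
                    d_familiarity = c(-0.3, 0.3),
                    d_humanlikeness = c(0.2, -0.2))
  dv <- decision_variable(trs, model)$dv
  expect_equal(dv[1], -dv[2])
})

test_that("psychometric binning is equally populated and the curve fits", {
  set.seed(77)
  dv <- rnorm(100)
  y <- rbinom(100, 1, plogis(2 * dv))
  fit <- psychometric_curve(dv, y, n_bins = 5)
  expect_equal(fit$bins$n, rep(20, 5))
  expect_true(all(fit$bins$choice_prob >= 0 & fit$bins$choice_prob <= 1))
  # value of the fitted curve at dv = 0 is plogis(bias), by definition
  expect_equal(plogis(fit$logit_bias + fit$logit_slope * 0),
               plogis(fit$logit_bias))
  # counts differ by at most one when trials do not divide evenly
  fit7 <- psychometric_curve(rnorm(101), rbinom(101, 1, 0.5), n_bins = 8)
  expect_lte(diff(range(fit7$bins$n)), 1)
  expect_error(psychometric_curve(rep(1, 50), rbinom(50, 1, 0.5), 5),
               "constant")
})

test_that("psychometric slope is recovered at large n", {
  set.seed(31)
  dv <- rnorm(5000, 0, 1.2)
  y <- rbinom(5000, 1, plogis(0.1 + 2 * dv))
  fit <- psychometric_curve(dv, y, n_bins = 8)
  expect_lt(abs(fit$logit_slope - 2), 0.3)
  # bin-level option agrees roughly with trial-level
  fitb <- psychometric_curve(dv, y, n_bins = 8, fit_on = "bins")
  expect_lt(abs(fitb$logit_slope - fit$logit_slope), 0.4)
})

test_that("choice UV depth vanishes for an exactly affine delta-DV profile", {
  cm <- data.frame(category = uv_categories()$name,
                   humanlikeness = c(1.5, 2.2, 3.0, 3.6, 4.1, 4.4))
  others <- setdiff(cm$category, "human_no_impair")
  gaps <- abs(cm$humanlikeness[match(others, cm$category)] -
                cm$humanlikeness[cm$category == "human_no_impair"])
  tr <- data.frame(contrast = paste("human_no_impair vs", others),
                   dv = 0.2 + 0.5 * gaps)
  res <- choice_uv_depth(tr, cm)
  expect_equal(res$choice_uv_depth, 0, tolerance = 1e-10)
  expect_error(choice_uv_depth(tr[-4, ], cm), "target contrast")
})

test_that("refit accuracy never falls below the majority-class rate", {
  pop <- sample_population(population_config(n_subjects = 10), seed = 12)
  for (i in seq_along(pop)) {
    s <- simulate_subject(pop[[i]], default_design, seed = 900 + i)
    fit <- suppressWarnings(fit_choice_logistic(s$choices))
    maj <- max(mean(s$choices$choice), 1 - mean(s$choices$choice))
    expect_gte(fit$accuracy, maj - 1e-12)
  }
})

test_that("group tests on per-subject betas report each coefficient", {
  set.seed(4)
  B <- cbind(beta0 = rnorm(21, 0, 0.2), beta1 = rnorm(21, -2, 0.4),
             beta2 = rnorm(21, -0.7, 0.3), beta3 = rnorm(21, -0.5, 0.3))
  g <- choice_group_tests(B)
  expect_equal(g$coefficient, colnames(B))
  expect_true(all(g$p[2:4] < 0.001))
  # closed-form t for one column
  expect_equal(g$t[1], mean(B[, 1]) / (sd(B[, 1]) / sqrt(21)),
               tolerance = 1e-12)
})
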