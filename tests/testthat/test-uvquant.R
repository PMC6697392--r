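test_that("uv_depth on exactly collinear points recovers the textbook case", {
  d <- data.frame(category = c("a", "b", "c", "e", "t"),
                  humanlikeness = c(1, 2, 3, 5, 4),
                  likability = c(1, 2, 3, 5, 2))
  res <- uv_depth(d, target_category = "t")
  expect_equal(res$slope, 1)
  expect_equal(res$intercept, 0)
  expect_equal(res$predicted, 4)
  expect_equal(res$observed, 2)
  expect_equal(res$uv_depth, 2)
})

test_that("uv_depth matches a normal-equations oracle on noisy data", {
  set.seed(101)
  means <- sim_subject_means(sample_population(population_config(),
                                               seed = 6)[[1]], seed = 8)
  res <- uv_depth(means)
  keep <- means$category != "artificial_human"
  X <- cbind(1, means$humanlikeness[keep])
  cf <- ols_normal_equations(X, means$likability[keep])
  expect_equal(res$intercept, cf[1], tolerance = 1e-8)
  expect_equal(res$slope, cf[2], tolerance = 1e-8)
})

test_that("uv_depth errors on degenerate or absent inputs", {
  d <- data.frame(category = c("a", "a", "t"), humanlikeness = c(2, 2, 3),
                  likability = c(1, 2, 3))
  expect_error(uv_depth(d, target_category = "t"), "singular")
  expect_error(uv_depth(d, target_category = "zzz"), "absent")
})

test_that("uv_depth is shift-invariant and scale-equivariant in likability", {
  means <- sim_subject_means(sample_population(population_config(),
                                               seed = 16)[[1]], seed = 9)
  base <- uv_depth(means)$uv_depth
  shifted <- means; shifted$likability <- shifted$likability + 0.7
  expect_equal(uv_depth(shifted)$uv_depth, base, tolerance = 1e-10)
  scaled <- means; scaled$likability <- 1.8 * scaled$likability
  expect_equal(uv_depth(scaled)$uv_depth, 1.8 * base, tolerance = 1e-10)
})

test_that("target data never influence the target's predicted value", {
  means <- sim_subject_means(sample_population(population_config(),
                                               seed = 26)[[1]], seed = 10)
  res1 <- uv_depth(means)
  bent <- means
  sel <- bent$category == "artificial_human"
  bent$likability[sel] <- bent$likability[sel] - 2
  res2 <- uv_depth(bent)
  expect_equal(res2$predicted, res1$predicted, tolerance = 1e-12)
  expect_equal(res2$uv_depth, res1$uv_depth + 2, tolerance = 1e-10)
})

test_that("leave-one-category-out residuals isolate the injected dip", {
  # perfectly linear data: all six residuals vanish
  rt0 <- simulate_ratings(noiseless_params(0), default_design$rating_trials,
                          seed = 1)
  prof0 <- uv_depth_residuals(stimulus_rating_means(rt0))$profile
  expect_equal(prof0$residual, rep(0, 6), tolerance = 1e-10)

  rt8 <- simulate_ratings(noiseless_params(0.8), default_design$rating_trials,
                          seed = 1)
  prof8 <- uv_depth_residuals(stimulus_rating_means(rt8))$profile
  # leaving out the dipped category gives a clean fit: residual = -dip
  art <- prof8$residual[prof8$category == "artificial_human"]
  expect_equal(art, -0.8, tolerance = 1e-10)
  # every other fit still contains the dipped data, so the remaining
  # residuals are small and positive but never rival the target's
  expect_true(all(prof8$residual[prof8$category != "artificial_human"] > 0))
  expect_true(all(prof8$residual[prof8$category != "artificial_human"] <
                    abs(art) / 2))
  expect_equal(which.min(prof8$residual),
               which(prof8$category == "artificial_human"))
})

test_that("residual-based UV tracks the continuum UV across a population", {
  pop <- sample_population(population_config(n_subjects = 60), seed = 3)
  vals <- t(vapply(seq_along(pop), function(i) {
    m <- sim_subject_means(pop[[i]], seed = 600 + i)
    prof <- uv_depth_residuals(m)$profile
    c(depth = uv_depth(m)$uv_depth,
      res_uv = -prof$residual[prof$category == "artificial_human"])
  }, numeric(2)))
  expect_gt(cor(vals[, "depth"], vals[, "res_uv"]), 0.7)
})

test_that("cubic fit recovers a noiseless cubic and its R-squared arithmetic", {
  x <- seq(1, 5, length.out = 30)
  y <- 2 - 0.5 * x + 0.3 * x^2 - 0.04 * x^3
  fit <- cubic_uv_fit(x, y)
  expect_equal(unname(fit$coefficients), c(2, -0.5, 0.3, -0.04),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(5)
  yn <- y + rnorm(30, 0, 0.3)
  fitn <- cubic_uv_fit(x, yn)
  # independent brute-force R^2
  sse <- sum((yn - fitn$fitted)^2)
  sst <- sum((yn - mean(yn))^2)
  expect_equal(fitn$r_squared, 1 - sse / sst, tolerance = 1e-12)

  expect_warning(fitc <- cubic_uv_fit(x, rep(2, 30)), "constant")
  expect_equal(fitc$r_squared, 0)
  expect_true(fitc$degenerate)
  expect_error(cubic_uv_fit(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("group UV tests match the closed-form t statistic", {
  x <- c(0.12, 0.45, 0.33, 0.80, 0.05)
  g <- group_uv_tests(x)
  t_hand <- mean(x) / (sd(x) / sqrt(5))
  expect_equal(g$t, t_hand, tolerance = 1e-12)
  expect_equal(g$df, 4)
  expect_equal(g$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)

  g0 <- group_uv_tests(rep(0, 8))
  expect_true(g0$degenerate)
  expect_equal(g0$t, 0)
})

test_that("per-subject deviation tests count significant subjects", {
  pop <- sample_population(population_config(), seed = 8)
  devs <- list(); depths <- numeric(21)
  for (i in 1:21) {
    rt <- simulate_ratings(pop[[i]], default_design$rating_trials,
                           seed = 70 + i)
    fit <- uv_depth(stimulus_rating_means(rt))
    depths[i] <- fit$uv_depth
    devs[[i]] <- uv_trial_deviations(rt, fit)
  }
  expect_true(all(lengths(devs) == 12))  # 6 exemplars x 2 presentations
  g <- group_uv_tests(depths, devs)
  expect_lt(g$p, 0.001)                  # strong group valley at dip 0.8
  expect_gte(g$n_significant, 15)        # most subjects individually out
})
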