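#!/usr/bin/env Rscript
# Step 3: model the choice task.
#
# Per subject: logistic regression of choice on relative likability,
# familiarity and humanlikeness; decision-variable series; psychometric
# curve over equally populated decision-variable bins; delta-decision-
# variable choice UV depth. Group stage: one-sample t tests of the
# coefficients and of the choice UV depths.

library(uvalley)

seed <- 1
study <- simulate_study(population_config(), seed = seed)
n <- length(study$subjects)

fits <- vector("list", n)
dv_all <- c(); y_all <- c()
cuv <- numeric(n)
for (i in seq_len(n)) {
  s <- study$subjects[[i]]
  fits[[i]] <- suppressWarnings(fit_choice_logistic(s$choices))
  tr <- s$choices
  tr$dv <- decision_variable(tr, fits[[i]])$dv
  dv_all <- c(dv_all, tr$dv); y_all <- c(y_all, tr$choice)
  cuv[i] <- choice_uv_depth(tr, category_rating_means(s$ratings))$choice_uv_depth
}

B <- t(vapply(fits, `[[`, numeric(4), "betas"))
g <- choice_group_tests(B)
cat("Group tests on per-subject logistic coefficients:\n")
print(within(g, { mean <- round(mean, 3); t <- round(t, 2)
                  p <- signif(p, 3) }), row.names = FALSE)

acc <- vapply(fits, `[[`, 1, "accuracy")
pr2 <- vapply(fits, `[[`, 1, "pseudo_r2")
cat(sprintf("Mean classification accuracy: %.1f%% (SEM %.2f)\n",
            100 * mean(acc), 100 * sd(acc) / sqrt(n)))
cat(sprintf("Mean McFadden pseudo-R^2: %.2f (SEM %.2f)\n",
            mean(pr2), sd(pr2) / sqrt(n)))

ps <- psychometric_curve(dv_all, y_all, n_bins = 8)
cat(sprintf("Pooled psychometric logit: bias %.3f, slope %.3f\n",
            ps$logit_bias, ps$logit_slope))

tt <- t.test(cuv)
cat(sprintf("Choice UV depth: mean %.3f, t(%d) = %.2f, p = %.2g\n",
            mean(cuv), n - 1, tt$statistic, tt$p.value))

write.csv(data.frame(subject = seq_len(n), B, accuracy = acc,
                     pseudo_r2 = pr2, choice_uv_depth = cuv),
          "results/choice_model.csv", row.names = FALSE)
write.csv(ps$bins, "results/psychometric_bins.csv", row.names = FALSE)
cat("Wrote results/choice_model.csv, results/psychometric_bins.csv\n")
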