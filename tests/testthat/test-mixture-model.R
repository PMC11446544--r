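test_that("above-chance likelihood: normalization, closed form, Monte-Carlo oracle", {
  n <- 120
  expect_lt(abs(sum(above_chance_likelihood(0:n, n, 2, 3)) - 1), 1e-6)

  # alpha = beta = 1: P(k) = (2/(n+1)) * P(Beta(k+1, n-k+1) > 1/2), exactly
  for (k in c(60, 80, 100)) {
    closed <- 2 / (n + 1) * (1 - pbeta(0.5, k + 1, n - k + 1))
    expect_lt(abs(above_chance_likelihood(k, n, 1, 1) - closed), 1e-10)
  }

  # Monte-Carlo oracle, 1e6 draws (Rao-Blackwellized over k)
  set.seed(55)
  p_draws <- 0.5 + runif(1e6) / 2
  for (k in c(60, 80, 100)) {
    vals <- dbinom(k, n, p_draws)
    mc <- mean(vals)
    mc_se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(above_chance_likelihood(k, n, 1, 1) - mc), 3 * mc_se)
  }

  # concentrated accuracy law puts its mass near k = n
  conc <- above_chance_likelihood(0:n, n, 400, 2)
  expect_gt(sum(conc[(n - 5):n + 1]), 0.9)

  expect_error(above_chance_likelihood(60, n, -1, 2), "positive")
  expect_error(above_chance_likelihood(150, n, 2, 2), "0, n")
})

test_that("posterior fitting is deterministic and reacts to saturated evidence", {
  cfg <- cohort_config(n_subjects = 30, prevalence = 0.2)
  disc <- simulate_discrimination(cfg, seed = 61)
  f1 <- fit_mixture(disc, n_draws = 1000, seed = 5)
  f2 <- fit_mixture(disc, n_draws = 1000, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$membership$membership_prob >= 0 &
                  f1$membership$membership_prob <= 1))
  expect_true(all(f1$prevalence_hdi >= 0 & f1$prevalence_hdi <= 1))

  sat <- data.frame(subject = paste0("s", 1:30), k = 120, n = 120)
  fs <- fit_mixture(sat, n_draws = 1000, seed = 5)
  expect_gt(fs$prevalence_mean, 0.9)

  # posterior-predictive mass of the above-chance component sums to 1
  expect_lt(abs(sum(posterior_predictive_above(f1)) - 1), 1e-6)
})

test_that("membership equals the single-draw Bayes ratio and is monotone in k", {
  # hand-built posterior with one repeated draw: closed-loop identity
  one <- structure(
    list(draws = data.frame(prevalence = rep(0.1, 3), alpha = 2, beta = 4),
         n = 120),
    class = "mixture_posterior"
  )
  la <- above_chance_likelihood(85, 120, 2, 4)
  lc <- dbinom(85, 120, 0.5)
  expect_lt(abs(membership_probability(85, one) -
                0.1 * la / (0.1 * la + 0.9 * lc)), 1e-10)

  # zero prevalence forces zero membership (pure-chance reduction)
  zero <- structure(
    list(draws = data.frame(prevalence = rep(0, 5), alpha = 2, beta = 4),
         n = 120),
    class = "mixture_posterior"
  )
  for (k in c(40, 60, 90, 120))
    expect_identical(membership_probability(k, zero), 0)

  cfg <- cohort_config(n_subjects = 40, prevalence = 0.15)
  fit <- fit_mixture(simulate_discrimination(cfg, seed = 71),
                     n_draws = 2000, seed = 8)
  mp <- vapply(60:120, membership_probability, numeric(1), posterior = fit)
  expect_true(all(diff(mp) >= -1e-12))
})

test_that("at-chance screening is threshold-faithful and downward-closed", {
  cfg <- cohort_config(n_subjects = 54, prevalence = 0.1)
  disc <- simulate_discrimination(cfg, seed = 81)
  fit <- fit_mixture(disc, n_draws = 2000, seed = 9)

  all_in <- screen_at_chance(disc, fit, threshold = 1)
  expect_setequal(all_in$retained, disc$subject)

  scr <- screen_at_chance(disc, fit, threshold = 0.05)
  expect_true(all(scr$table$membership_prob[scr$table$retained] <= 0.05))
  # downward-closed in k: every k below a retained k is retained
  if (length(scr$retained)) {
    kmax <- max(scr$table$k[scr$table$retained])
    expect_true(all(scr$table$retained[scr$table$k <= kmax]))
    expect_equal(scr$cutoff, kmax / 120)
  }

  # a near-perfect scorer is never screened as at-chance
  disc2 <- rbind(disc, data.frame(subject = "sub-99", k = 119, n = 120,
                                  accuracy = 119 / 120, above_chance = TRUE))
  fit2 <- fit_mixture(disc2[, c("subject", "k", "n")], n_draws = 2000, seed = 9)
  scr2 <- screen_at_chance(disc2, fit2, threshold = 0.05)
  expect_false("sub-99" %in% scr2$retained)
})

test_that("one-sided binomial screen has the exact tail p-values", {
  b <- binomial_above_chance(60, 120)
  expect_equal(b$p_value, 1 - pbinom(59, 120, 0.5))
  expect_equal(b$p_value, 0.536342, tolerance = 1e-6)
  expect_false(b$above_chance)

  expect_equal(binomial_above_chance(120, 120)$p_value, 0.5^120)
  # matches the stock exact test and decreases in k
  bt <- stats::binom.test(75, 120, 0.5, alternative = "greater")
  expect_equal(binomial_above_chance(75, 120)$p_value, bt$p.value,
               tolerance = 1e-12)
  # strictly decreasing wherever doubles can resolve the tail sums
  ps <- binomial_above_chance(30:120, 120)$p_value
  expect_true(all(diff(ps) < 0))
})

test_that("gridded posterior ranks are uniform under the model's own prior", {
  # simulation-based calibration at reduced scale: cohorts drawn from the
  # prior, rank of the true prevalence among posterior draws
  set.seed(7)
  ranks <- numeric(32)
  for (i in seq_along(ranks)) {
    cfgi <- cohort_config(prevalence = runif(1), alpha = rexp(1, 1),
                          beta = rexp(1, 0.5))
    disc <- simulate_discrimination(cfgi, seed = 800 + i)
    fit <- fit_mixture(disc, n_draws = 1000, seed = 800 + i,
                       grid_size = c(64L, 48L, 48L))
    ranks[i] <- mean(fit$draws$prevalence < cfgi$prevalence)
  }
  h <- table(cut(ranks, breaks = seq(0, 1, by = 0.25)))
  expect_gt(stats::chisq.test(as.numeric(h))$p.value, 0.01)
})
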