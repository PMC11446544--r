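test_that("subject condition means: arithmetic, eye-strata identity, censoring filter", {
  tab <- data.frame(
    subject = "s1",
    condition = c("systole", "systole", "diastole"),
    duration = c(2, 4, 3), censored = FALSE
  )
  m <- subject_condition_means(tab)
  expect_equal(m$mean_duration[m$condition == "systole"], 3)
  expect_equal(m$mean_duration[m$condition == "diastole"], 3)

  # unstratified mean is the count-weighted mean of the eye strata
  tab4 <- fixture_dominance_4rows()
  tab4$duration <- c(2, 3, 6, 5)
  u <- subject_condition_means(tab4)
  s <- subject_condition_means(tab4, stratify_by_eye = TRUE)
  for (cond in c("systole", "diastole")) {
    ss <- s[s$condition == cond, ]
    expect_equal(u$mean_duration[u$condition == cond],
                 sum(ss$mean_duration * ss$n_intervals) / sum(ss$n_intervals))
  }

  # censoring excludes rows; flipping the flag changes the mean
  tabc <- data.frame(subject = "s1",
                     condition = c("systole", "systole", "diastole"),
                     duration = c(2, 10, 3),
                     censored = c(FALSE, TRUE, FALSE))
  expect_equal(subject_condition_means(tabc)$mean_duration, c(3, 2))
  tabc$censored <- FALSE
  expect_equal(subject_condition_means(tabc)$mean_duration, c(3, 6))

  # a subject missing a condition is excluded with a warning
  tabm <- rbind(tab, data.frame(subject = "s2", condition = "systole",
                                duration = 1, censored = FALSE))
  expect_warning(out <- subject_condition_means(tabm), "s2")
  expect_false("s2" %in% out$subject)
})

test_that("paired bootstrap: shared difference, antisymmetry, null coverage", {
  mk <- function(diffs) do.call(rbind, lapply(seq_along(diffs), function(i) {
    data.frame(subject = sprintf("s%02d", i),
               condition = rep(c("systole", "diastole"), each = 2),
               duration = c(3 + diffs[i], 3 + diffs[i], 3, 3))
  }))

  same <- paired_bootstrap(mk(rep(0.25, 6)), n_boot = 500, seed = 1)
  expect_equal(same$mean_diff, 0.25)
  expect_equal(same$ci_low, 0.25)
  expect_equal(same$ci_high, 0.25)

  set.seed(3)
  tab <- mk(rnorm(12, 0.2, 0.3))
  est <- paired_bootstrap(tab, n_boot = 500, seed = 9)
  swapped <- tab
  swapped$condition <- ifelse(tab$condition == "systole", "diastole", "systole")
  est2 <- paired_bootstrap(swapped, n_boot = 500, seed = 9)
  expect_equal(est2$mean_diff, -est$mean_diff)

  expect_error(paired_bootstrap(mk(0.1)), "2 subjects")

  # CI covers a zero true difference at roughly the nominal rate
  set.seed(31)
  hits <- logical(200)
  for (i in seq_along(hits)) {
    est0 <- paired_bootstrap(mk(rnorm(20, 0, 0.4)), n_boot = 1000, seed = i)
    hits[i] <- est0$ci_low <= 0 && 0 <= est0$ci_high
  }
  expect_gte(mean(hits), 0.89)
  expect_lte(mean(hits), 0.99)
})

test_that("gamma GEE is invariant to rescaling and relabeling, equals GLM under independence", {
  cfg <- cohort_config(n_subjects = 10, block_duration = 120)
  dom <- simulate_rivalry_cohort(cfg, seed = 17)

  g <- fit_gamma_gee(dom)
  scaled <- dom; scaled$duration <- dom$duration * 10
  gs <- fit_gamma_gee(scaled)
  expect_equal(gs$beta, g$beta, tolerance = 1e-8)
  expect_equal(gs$intercept, g$intercept + log(10), tolerance = 1e-8)

  relab <- dom
  relab$subject <- factor(dom$subject,
                          labels = sample(sprintf("z%02d", 1:10)))
  gr <- fit_gamma_gee(relab)
  expect_equal(gr$beta, g$beta, tolerance = 1e-12)
  expect_equal(gr$se, g$se, tolerance = 1e-12)

  keep <- !dom$censored
  gi <- fit_gamma_gee(dom, corstr = "independence")
  gl <- stats::glm(duration ~ I(condition == "systole"),
                   family = stats::Gamma(link = "log"), data = dom[keep, ])
  expect_equal(gi$beta, unname(stats::coef(gl)[2L]), tolerance = 1e-8)

  # derived quantities are internally consistent
  expect_equal(g$pct_change, (exp(g$beta) - 1) * 100)
  expect_lte(g$ci_low, g$beta); expect_gte(g$ci_high, g$beta)
})

test_that("gamma GEE recovers a strong generative effect", {
  cfg <- cohort_config(systole_effect = 0.3)
  dom <- simulate_rivalry_cohort(cfg, seed = 23)
  g <- fit_gamma_gee(dom)
  expect_lt(abs(g$beta - log(1.3)), 0.025)
  expect_lt(g$p, 1e-6)
})

test_that("paired t power reproduces planned sample sizes and is monotone", {
  expect_equal(round(paired_t_power(0.38, 58), 2), 0.81)
  expect_equal(round(paired_t_power(0.38, 54), 2), 0.78)
  expect_equal(paired_t_power(0, 30), 0.05, tolerance = 1e-10)

  # matches the stock power calculator
  ref <- stats::power.t.test(n = 47, delta = 0.38, sd = 1, sig.level = 0.05,
                             type = "paired")$power
  expect_equal(paired_t_power(0.38, 47), ref, tolerance = 1e-4)

  pw_n <- sapply(c(10, 20, 40, 80), paired_t_power, d = 0.4)
  pw_d <- sapply(c(0.1, 0.3, 0.5, 0.8), paired_t_power, n = 30)
  expect_true(all(diff(pw_n) > 0))
  expect_true(all(diff(pw_d) > 0))
})
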