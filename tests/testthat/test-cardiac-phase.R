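test_that("the angle map is linear within segments with the stated boundary conventions", {
  ev <- cardiac_events(r_times = c(0, 1, 2), t_offsets = c(0.4, 1.4, NA))
  expect_equal(as.numeric(cardiac_angle(0.4, ev)), 0)
  expect_equal(as.numeric(cardiac_angle(0.2, ev)), -pi / 2)
  expect_equal(as.numeric(cardiac_angle(0.7, ev)), pi / 2)
  # R-peak itself: start of systole, same point as +pi on the circle
  expect_equal(abs(as.numeric(cardiac_angle(0, ev))), pi)
  # monotone within the beat, all in (-pi, pi]
  tt <- seq(0.01, 0.99, by = 0.01)
  a <- as.numeric(cardiac_angle(tt, ev))
  expect_true(all(diff(a) > 0))
  expect_true(all(a > -pi & a <= pi))

  # events in a beat without T-offset are dropped and counted
  ev2 <- cardiac_events(r_times = c(0, 1, 2), t_offsets = c(0.4, NA, NA))
  a2 <- cardiac_angle(c(0.2, 1.5), ev2)
  expect_length(a2, 1L)
  expect_identical(attr(a2, "n_dropped"), 1L)
  expect_warning(cardiac_angle(c(0.5, 9), ev), "outside")
})

test_that("circular mean matches resultant-vector arithmetic and rotates", {
  expect_equal(circular_mean(c(pi / 4, -pi / 4)), 0)
  expect_equal(circular_mean(rep(1.2, 5)), 1.2)
  # resultant of {0, pi/2, pi}: cos sum 0, sin sum 1 -> pi/2
  expect_equal(circular_mean(c(0, pi / 2, pi)), pi / 2)

  set.seed(4)
  for (i in 1:20) {
    a <- runif(30, -pi, pi)
    phi <- runif(1, -pi, pi)
    m1 <- circular_mean(a)
    m2 <- circular_mean(a + phi)
    expect_equal(((m2 - m1 - phi + pi) %% (2 * pi)) - pi, 0, tolerance = 1e-9)
  }
  expect_error(circular_mean(c(0, pi)), "resultant")
  expect_error(circular_mean(numeric(0)), "nonempty")
})

test_that("subject bootstrap: degenerate spread, containment, and coverage calibration", {
  zs <- subject_bootstrap(rep(0.7, 10), n_boot = 200, seed = 1)
  expect_equal(zs$ci_low, 0.7)
  expect_equal(zs$ci_high, 0.7)

  set.seed(8)
  sb <- subject_bootstrap(rnorm(100, 1, 0.5), n_boot = 1000, seed = 2)
  expect_lte(sb$ci_low, sb$mean_angle)
  expect_gte(sb$ci_high, sb$mean_angle)

  # ~95% coverage of the true mean over von Mises samples (kappa = 4)
  set.seed(99)
  hits <- logical(300)
  for (i in seq_along(hits)) {
    a <- rvonmises(200, mu = 0.5, kappa = 4)
    s <- subject_bootstrap(a, n_boot = 500)
    hits[i] <- s$ci_low <= 0.5 && 0.5 <= s$ci_high
  }
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("group bootstrap is hierarchical, order-invariant, and degenerate-safe", {
  # all subjects sharing one identical angle: mean a, zero-width CI
  g0 <- group_bootstrap(list(a = 1.1, b = 1.1, c = 1.1), n_boot = 200, seed = 1)
  expect_equal(g0$mean_angle, 1.1)
  expect_equal(g0$ci_high - g0$ci_low, 0)

  # subject-order invariance at a fixed seed (canonicalized by name)
  set.seed(12)
  gl <- list(s1 = rnorm(80, 1.0, 0.3), s2 = rnorm(60, 1.6, 0.3),
             s3 = rnorm(90, 0.7, 0.3), s4 = rnorm(70, 1.3, 0.3))
  g1 <- group_bootstrap(gl, n_boot = 500, seed = 7)
  g2 <- group_bootstrap(gl[c(3, 1, 4, 2)], n_boot = 500, seed = 7)
  expect_identical(unclass(g1), unclass(g2))

  # with between-subject spread, the hierarchical CI is wider than the
  # pooled (non-hierarchical) bootstrap CI in nearly all datasets
  set.seed(13)
  wider <- logical(40)
  for (i in seq_along(wider)) {
    mus <- rnorm(5, 1, 0.5)
    dat <- lapply(mus, function(m) rnorm(50, m, 0.2))
    names(dat) <- paste0("s", 1:5)
    gb <- group_bootstrap(dat, n_boot = 400, seed = i)
    pb <- subject_bootstrap(unlist(dat), n_boot = 400, seed = i)
    wider[i] <- (gb$ci_high - gb$ci_low) >= (pb$ci_high - pb$ci_low)
  }
  expect_gte(mean(wider), 0.95)
})

test_that("manipulation check flags signs and incomplete subjects", {
  set.seed(21)
  mk <- function(id, mu_in, mu_an) rbind(
    data.frame(subject = id, stimulus = "inphase", angle = rnorm(80, mu_in, 0.3)),
    data.frame(subject = id, stimulus = "antiphase", angle = rnorm(80, mu_an, 0.3))
  )
  good <- do.call(rbind, lapply(1:5, function(i) mk(paste0("s", i), -1.2, 1.8)))
  res <- manipulation_check(good, n_boot = 300, seed = 5)
  expect_true(res$pass)
  expect_identical(nrow(res$table), 5L)

  # negative control: anti-phase pulses forced into systole
  bad <- do.call(rbind, lapply(1:5, function(i) mk(paste0("s", i), -1.2, -0.8)))
  expect_false(manipulation_check(bad, n_boot = 300, seed = 5)$pass)

  # missing stream -> incomplete, excluded from the decision
  partial <- rbind(good,
                   data.frame(subject = "s6", stimulus = "inphase",
                              angle = rnorm(80, -1.2, 0.3)))
  res2 <- manipulation_check(partial, n_boot = 300, seed = 5)
  expect_identical(res2$incomplete, "s6")
  expect_true(res2$pass)
})
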