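test_that("stateful causal filter matches the reference implementation, chunked or not", {
  set.seed(10)
  x <- rnorm(500)
  flt <- signal::butter(2, c(5, 15) / 50, type = "pass")
  ref <- as.numeric(signal::filter(flt, x))
  mine <- cardiorivalry:::iir_filter(as.numeric(flt$b), as.numeric(flt$a), x)$y
  expect_equal(mine, ref, tolerance = 1e-10)

  # chunked processing with carried state is bit-identical to one pass
  st <- NULL
  pieces <- list()
  for (idx in split(seq_along(x), ceiling(seq_along(x) / 37))) {
    r <- cardiorivalry:::iir_filter(as.numeric(flt$b), as.numeric(flt$a),
                                    x[idx], st)
    st <- r$state
    pieces[[length(pieces) + 1L]] <- r$y
  }
  expect_identical(unlist(pieces), mine)
})

test_that("bandpass rejects DC, passes 10 Hz, attenuates 1 Hz, and composes", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  # RMS amplitude away from both ends (edge transients; sparse sampling
  # makes peak-picking a biased amplitude estimate)
  gain_after <- function(y) sqrt(2 * mean(y[t > 5 & t < 15]^2))

  const <- ecg_record(rep(2, length(t)), fs)
  expect_lt(max(abs(bandpass(const, causal = TRUE)$samples[t > 5])), 1e-6)

  s10 <- ecg_record(sin(2 * pi * 10 * t), fs)
  s1 <- ecg_record(sin(2 * pi * 1 * t), fs)
  g10 <- gain_after(bandpass(s10)$samples)
  g1 <- gain_after(bandpass(s1)$samples)
  expect_gte(g10, 0.7)
  expect_lte(g1, 0.3)

  # filtering twice = squared magnitude response at 10 Hz
  g10_twice <- gain_after(bandpass(bandpass(s10))$samples)
  expect_equal(g10_twice, g10^2, tolerance = 0.005)

  expect_error(bandpass(s10, low = 5, high = 60), "fs/2")
})

test_that("0.5 Hz high-pass removes drift and passes the QRS band", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  drift <- ecg_record(0.5 * t, fs)              # linear drift, range 30
  hp <- highpass_clean(drift)$samples
  expect_lte(max(abs(hp[t > 10 & t < 50])), 0.05 * diff(range(drift$samples)))

  zero <- ecg_record(numeric(length(t)), fs)
  expect_equal(highpass_clean(zero)$samples, numeric(length(t)))

  s10 <- ecg_record(sin(2 * pi * 10 * t), fs)
  expect_gte(max(abs(highpass_clean(s10)$samples[t > 5])), 0.95)
})

test_that("detector recovers simulated beats with no false positives", {
  fx <- fixture_recording()
  det <- detect_rpeaks(fx$record)
  truth <- fx$truth$r_times
  miss <- sapply(truth, function(r) min(abs(det$times - r)))
  expect_gte(mean(miss <= 0.05), 0.99)
  # no false positives after the first 2 beats
  fp <- sapply(det$times[det$times > truth[3L]],
               function(d) min(abs(truth - d)))
  expect_identical(sum(fp > 0.05), 0L)
})

test_that("streaming and batch detection agree, at any chunking, scale and polarity", {
  fx <- fixture_recording()
  batch <- detect_rpeaks(fx$record, streaming = FALSE)
  stream <- detect_rpeaks(fx$record, streaming = TRUE)
  expect_identical(batch$times, stream$times)

  # irregular chunk sizes through the low-level detector
  det <- rpeak_detector(fx$record$fs, fx$record$start_time)
  i <- 1L
  set.seed(77)
  while (i <= length(fx$record$samples)) {
    j <- min(i + sample(1:333, 1L) - 1L, length(fx$record$samples))
    det$process(fx$record$samples[i:j])
    i <- j + 1L
  }
  expect_identical(det$peaks(), batch$times)

  scaled <- ecg_record(fx$record$samples * 10, fx$record$fs)
  expect_identical(detect_rpeaks(scaled)$times, batch$times)
  flipped <- ecg_record(-fx$record$samples, fx$record$fs)
  expect_identical(detect_rpeaks(flipped)$times, batch$times)
})

test_that("refractory period suppresses a beat 0.15 s after another", {
  # regular rhythm with one extra QRS 0.15 s after a mid-recording R-peak
  rp <- simulate_rr_series(0.8, 0, 30)
  rec <- simulate_ecg(rp, fs = 100, noise_sd = 0)
  t <- rec$start_time + (seq_along(rec$samples) - 1) / rec$fs
  extra <- 16.15
  rec2 <- ecg_record(rec$samples + exp(-(t - extra)^2 / (2 * 0.015^2)),
                     rec$fs)
  det <- detect_rpeaks(rec2)
  expect_false(any(abs(det$times - extra) < 0.05))
  expect_true(any(abs(det$times - 16.0) < 0.05))
  expect_true(all(diff(det$times) >= 0.2))
})

test_that("degenerate recordings are handled explicitly", {
  expect_error(detect_rpeaks(ecg_record(rnorm(100), 100)), "2 s")
  expect_warning(out <- detect_rpeaks(ecg_record(rep(1, 1000), 100)), "flat")
  expect_length(out$times, 0L)
})

test_that("T-offset delineation is accurate and respects beat boundaries", {
  fx <- fixture_recording()
  det <- detect_rpeaks(fx$record)
  ev <- detect_t_offsets(fx$record, det)
  expect_s3_class(ev, "cardiac_events")

  err <- c()
  for (i in seq_along(ev$r_times)) {
    j <- which.min(abs(fx$truth$r_times - ev$r_times[i]))
    if (!is.na(ev$t_offsets[i]) && !is.na(fx$truth$t_offsets[j]) &&
        abs(fx$truth$r_times[j] - ev$r_times[i]) < 0.05)
      err <- c(err, abs(ev$t_offsets[i] - fx$truth$t_offsets[j]))
  }
  expect_gt(length(err), 300)
  expect_lte(mean(err), 0.030)

  # offsets strictly inside their beat; last beat missing
  n <- length(ev$r_times)
  defined <- which(!is.na(ev$t_offsets))
  expect_true(all(defined < n))
  expect_true(all(ev$t_offsets[defined] > ev$r_times[defined]))
  expect_true(all(ev$t_offsets[defined] < ev$r_times[defined + 1L]))
  expect_true(is.na(ev$t_offsets[n]))

  expect_error(detect_t_offsets(fx$record, rpeak_train(1.0)), "two R-peaks")
})
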