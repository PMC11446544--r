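# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A 300 s noisy synthetic recording with its generating train.
fixture_recording <- function() {
  cached("rec300", function() {
    rp <- simulate_rr_series(0.8, 0.05, 300, seed = 31)
    rec <- simulate_ecg(rp, fs = 100, noise_sd = 0.05, seed = 32)
    list(rpeaks = rp, record = rec, truth = true_events(rec))
  })
}

# Von Mises sampler (Best & Fisher rejection scheme), for bootstrap
# calibration checks; kept in test code because the package itself never
# needs parametric circular draws.
rvonmises <- function(n, mu, kappa) {
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2L] > 0 || log(c_ / u[2L]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3L] - 0.5) * acos(f)
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# Small dominance-table fixture with known means.
fixture_dominance_4rows <- function() {
  data.frame(
    subject = "s1",
    block = 1L,
    eye = c("left", "left", "right", "right"),
    condition = c("systole", "diastole", "systole", "diastole"),
    duration = c(2, 3, 4, 5),
    censored = FALSE,
    stringsAsFactors = FALSE
  )
}
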