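test_that("zero noise and zero amplitude give an all-zero session", {
  p <- short_protocol()
  prof <- activation_profile("RHTF", "CH01", amplitude = 0, jitter_sd = 0)
  reg <- trial_dhrf(p)
  ses <- simulate_session(p, grid_geometry(), prof, no_noise(), reg, seed = 1)
  expect_true(all(ses$data == 0))
})

test_that("a noiseless active channel carries amplitude * dHRF exactly", {
  p <- short_protocol(n_trials = 2)
  geom <- grid_geometry()
  prof <- activation_profile("RHTF", "CH05", amplitude = 0.7, jitter_sd = 0)
  reg <- trial_dhrf(p)
  ses <- simulate_session(p, geom, prof, no_noise(), reg, seed = 1)
  onsets <- build_protocol(p)$onsets
  k <- length(reg$samples)
  seg <- onsets[1]:(onsets[1] + k - 1)
  expect_equal(ses$data[5, seg], 0.7 * reg$samples)
  expect_true(all(ses$data[-5, ] == 0))
})

test_that("identical seeds reproduce a session bit-exactly", {
  p <- short_protocol()
  prof <- activation_profile("RHLF", c("CH02", "CH07"))
  reg <- trial_dhrf(p)
  a <- simulate_session(p, grid_geometry(), prof, noise_params(), reg, seed = 7)
  b <- simulate_session(p, grid_geometry(), prof, noise_params(), reg, seed = 7)
  expect_identical(a$data, b$data)
  d <- simulate_session(p, grid_geometry(), prof, noise_params(), reg, seed = 8)
  expect_false(identical(a$data, d$data))
})

test_that("cohorts have balanced labels and the documented size", {
  pr <- plain_profiles()
  p <- short_protocol(n_trials = 1)
  coh <- make_cohort(3, 1, pr$RHTF, pr$RHLF, noise_params(), seed = 2,
                     protocol = p)
  expect_length(coh$sessions, 6)
  expect_equal(as.vector(table(coh$labels)), c(3, 3))
  expect_equal(coh$protocol$n_trials, 1)
  coh2 <- make_cohort(3, 1, pr$RHTF, pr$RHLF, noise_params(), seed = 2,
                      protocol = p)
  expect_identical(coh$sessions[[4]]$data, coh2$sessions[[4]]$data)
})

test_that("identical class profiles are flagged", {
  pr <- plain_profiles()
  p <- short_protocol(n_trials = 1)
  expect_message(make_cohort(1, 1, pr$RHTF, pr$RHTF, no_noise(), seed = 1,
                             protocol = p),
                 "identical")
})

test_that("profile channels must exist in the geometry", {
  p <- short_protocol()
  prof <- activation_profile("RHTF", "CH99")
  expect_error(simulate_session(p, grid_geometry(), prof, no_noise(),
                                trial_dhrf(p), seed = 1),
               "not in geometry")
})

test_that("cardiac-only noise has its spectral peak at the cardiac frequency", {
  p <- session_protocol(pre_rest_s = 60, post_rest_s = 10, n_trials = 0,
                        fs = 9.19)
  noise <- noise_params(cardiac = list(freq = 1.2, amp = 0.1),
                        respiratory = list(freq = 0.3, amp = 0),
                        mayer = list(freq = 0.1, amp = 0),
                        drift_slope = 0, white_sd = 0)
  prof <- activation_profile("RHTF", character(0), amplitude = 0)
  ses <- simulate_session(p, grid_geometry(), prof, noise, trial_dhrf(p),
                          seed = 5)
  n <- ncol(ses$data)
  freqs <- (seq_len(n) - 1) * p$fs / n
  for (ch in c(1, 20)) {
    spec <- Mod(fft(ses$data[ch, ]))^2
    half <- freqs > 0 & freqs < p$fs / 2
    peak_f <- freqs[half][which.max(spec[half])]
    expect_lte(abs(peak_f - 1.2), p$fs / n + 1e-9)  # within one frequency bin
  }
})

test_that("per-trial jitter keeps amplitudes positive and lognormal-scaled", {
  p <- short_protocol(n_trials = 2)
  geom <- grid_geometry()
  prof <- activation_profile("RHTF", "CH05", amplitude = 0.5, jitter_sd = 0.3)
  reg <- trial_dhrf(p)
  reg$samples <- reg$samples / max(abs(reg$samples))
  ses <- simulate_session(p, geom, prof, no_noise(), reg, seed = 11)
  onsets <- build_protocol(p)$onsets
  peaks <- vapply(onsets, function(o)
    max(abs(ses$data[5, o:(o + length(reg$samples) - 1)])), numeric(1))
  expect_true(all(peaks > 0))
  expect_false(abs(peaks[1] - peaks[2]) < 1e-12)   # jitter differs per trial
})
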