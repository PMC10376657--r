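# Brute-force direct-sum convolution: y[n] = sum_k b[k] c[n-k] / fs
oracle_conv <- function(boxcar, ch, fs) {
  n <- length(boxcar)
  out <- numeric(n)
  for (i in seq_len(n))
    for (k in seq_len(i)) {
      j <- i - k + 1
      if (j <= length(ch)) out[i] <- out[i] + boxcar[k] * ch[j]
    }
  out / fs
}

test_that("cHRF is zero at onset, dips near 2 s, and peaks in 5-7 s", {
  params <- gamma_hrf_params()
  expect_equal(chrf(0, params), 0)
  t_dense <- seq(0, 30, by = 0.001)
  v <- chrf(t_dense, params)
  expect_true(all(is.finite(v)))
  dip_t <- t_dense[t_dense <= 4][which.min(v[t_dense <= 4])]
  expect_gte(dip_t, 1.5)
  expect_lte(dip_t, 2.5)
  peak_t <- t_dense[which.max(v)]
  expect_gte(peak_t, 5)
  expect_lte(peak_t, 7)
  # coarse-grid argmax agrees with the dense grid within one coarse step
  t_coarse <- seq(0, 30, by = 0.25)
  peak_coarse <- t_coarse[which.max(chrf(t_coarse, params))]
  expect_lte(abs(peak_coarse - peak_t), 0.25)
})

test_that("zero-amplitude cHRF is identically zero", {
  z <- list(A = 0, shape = 6, scale = 0.4)
  params <- gamma_hrf_params(dip = z, main = z, undershoot = z)
  expect_true(all(chrf(seq(0, 30, 0.1), params) == 0))
})

test_that("each gamma kernel integrates to its amplitude within 1%", {
  params <- gamma_hrf_params()
  for (nm in c("dip", "main", "undershoot")) {
    cmp <- params[[nm]]
    area <- stats::integrate(function(t)
      stats::dgamma(t, shape = cmp$shape, scale = cmp$scale), 0, 60)$value
    expect_equal(cmp$A * area, cmp$A, tolerance = 0.01)
  }
})

test_that("invalid gamma parameters are rejected", {
  expect_error(gamma_hrf_params(dip = list(A = 1, shape = -1, scale = 1)), "shape")
  expect_error(gamma_hrf_params(main = list(A = -1, shape = 2, scale = 1)), ">= 0")
  expect_error(chrf(c(1, 0.5), gamma_hrf_params()), "increasing")
})

test_that("dHRF equals the boxcar under a discrete unit-area impulse", {
  p <- short_protocol()
  box <- trial_boxcar(p)
  impulse <- c(p$fs, rep(0, length(box) - 1))   # unit area on the fs grid
  reg <- dhrf(impulse, box, p$fs)
  expect_equal(reg$samples, as.numeric(box))
})

test_that("dHRF is linear in the cHRF", {
  p <- short_protocol()
  box <- trial_boxcar(p)
  ch <- chrf((seq_along(box) - 1) / p$fs, gamma_hrf_params())
  expect_equal(dhrf(3 * ch, box, p$fs)$samples, 3 * dhrf(ch, box, p$fs)$samples)
})

test_that("dHRF matches the direct-sum convolution oracle and starts negative", {
  p <- session_protocol()
  box <- trial_boxcar(p)[1:80]                  # keep the O(n^2) oracle small
  t <- (seq_along(box) - 1) / p$fs
  ch <- chrf(t, gamma_hrf_params())
  reg <- dhrf(ch, box, p$fs)
  expect_equal(reg$samples, oracle_conv(box, ch, p$fs), tolerance = 1e-12)
  # initial-dip signature: negative over an early interval, then positive
  # (1e-8 guards the convolution's floating-point dust at the exact zeros)
  sign_change <- which(reg$samples > 1e-8)[1]
  expect_true(all(reg$samples[2:(sign_change - 1)] < 1e-8))
  expect_lt(min(reg$samples), -0.01)
  t_cross <- t[sign_change]
  # the regressor (integrated cHRF) stays negative well past the cHRF's own
  # zero-crossing: the dip area must be repaid before the integral turns
  expect_gt(t_cross, 1)
  expect_lt(t_cross, 8)
})

test_that("windowing truncates consistently with a truncated full convolution", {
  p <- session_protocol()
  box <- trial_boxcar(p)
  t <- (seq_along(box) - 1) / p$fs
  ch <- chrf(t, gamma_hrf_params())
  reg <- dhrf(ch, box, p$fs)
  full <- signal::conv(as.numeric(box), ch) / p$fs
  for (w in c(0.5, 2, 14)) {
    k <- floor(w * p$fs)
    expect_equal(restrict_window(reg, w)$samples, full[1:k])
  }
})

test_that("window sample counts follow floor(window * fs)", {
  reg <- trial_dhrf(session_protocol())
  expect_length(restrict_window(reg, 0.5)$samples, 4)
  expect_length(restrict_window(reg, 14)$samples, 128)
  expect_equal(restrict_window(reg, 30)$samples, reg$samples)  # identity
  expect_error(restrict_window(reg, 31), "exceeds")
  expect_error(restrict_window(reg, -1), "positive")
})

test_that("HRF parameters round-trip through YAML", {
  params <- gamma_hrf_params(dip = list(A = 0.5, shape = 5, scale = 0.3))
  f <- tempfile(fileext = ".yaml")
  write_hrf_yaml(params, f)
  back <- read_hrf_yaml(f)
  expect_equal(back$dip, params$dip)
  expect_equal(back$main, params$main)
  unlink(f)
})
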