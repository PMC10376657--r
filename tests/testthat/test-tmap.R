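test_that("thresholding is strict and normalization maps the max to 1", {
  expect_equal(t_to_activation(c(1.65, 2), c(0.01, 0.01)), c(0, 1))
  expect_equal(t_to_activation(c(2, 4, 1), c(0.03, 0.001, 0.2)), c(0.5, 1, 0))
  expect_equal(t_to_activation(c(1, 1.2, -3), c(0.2, 0.3, 0.9)), c(0, 0, 0))
  expect_equal(t_to_activation(c(3, 2), c(0.2, 0.01)), c(0, 1))  # p gate
  v <- t_to_activation(c(Inf, 5, 1), c(0, 0.01, 0.5))
  expect_equal(v[1], 1)
})

test_that("all-zero maps render as a uniform colormap(0) image", {
  geom <- grid_geometry()
  params <- tmap_params(image_size = 64)
  img <- render_tmap(rep(0, 36), geom, params)
  expect_equal(dim(img), c(64, 64, 3))
  c0 <- round(jet_colormap(256)[1, ] * 255) / 255   # 8-bit table entry
  for (ch in 1:3) expect_true(all(img[, , ch] == c0[ch]))
})

test_that("a single hot channel renders its maximum at the channel position", {
  geom <- grid_geometry()
  size <- 227
  params <- tmap_params(image_size = size)
  for (ch_idx in c(1, 15, 36)) {
    v <- rep(0, 36); v[ch_idx] <- 1
    img <- render_tmap(v, geom, params)
    expect_equal(dim(img), c(size, size, 3))
    # coordinate-transform oracle: channel (x, y) -> col = x*size, row flipped
    xy <- geom$xy[ch_idx, ]
    exp_col <- round(xy[1] * size + 0.5)
    exp_row <- size + 1 - round(xy[2] * size + 0.5)
    intensity <- img[, , 1] - img[, , 3]       # red-vs-blue orders the map
    hot <- which(intensity == max(intensity), arr.ind = TRUE)
    d <- sqrt((hot[, 1] - exp_row)^2 + (hot[, 2] - exp_col)^2)
    expect_lte(min(d), 3)
  }
})

test_that("rendering is deterministic and clips out-of-range values", {
  geom <- grid_geometry()
  params <- tmap_params(image_size = 48)
  set.seed(2)
  v <- runif(36, -0.5, 1.5)
  img1 <- render_tmap(v, geom, params)
  img2 <- render_tmap(v, geom, params)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
})

test_that("rendering with under 3 channels falls back to nearest-neighbour", {
  geom <- channel_geometry(c("A", "B"), rbind(c(0.25, 0.5), c(0.75, 0.5)))
  expect_message(img <- render_tmap(c(1, 0), geom, tmap_params(image_size = 32)),
                 "nearest")
  expect_equal(dim(img), c(32, 32, 3))
})

test_that("windowed fits recover a noiseless activation footprint exactly", {
  profiles <- plain_profiles()   # disjoint footprints, no delayed spread
  coh <- make_cohort(1, 6, profiles$RHTF, profiles$RHLF, no_noise(), seed = 3)
  geom <- coh$geometry
  reg <- trial_dhrf(coh$protocol)
  reg$samples <- reg$samples / max(abs(reg$samples))
  onsets <- build_protocol(coh$protocol)$onsets
  for (ses in coh$sessions) {
    for (o in onsets) {
      tm <- fit_trial_tmap(ses, o, reg, 4, render = FALSE)
      expect_setequal_chr(surviving_channels(tm, geom),
                          ses$truth$active_channels)
    }
  }
})

test_that("dataset construction yields one map per session-trial-window", {
  profiles <- plain_profiles()
  p <- short_protocol(n_trials = 2)
  coh <- make_cohort(2, 2, profiles$RHTF, profiles$RHLF, noise_params(),
                     seed = 7, protocol = p)
  ds <- build_tmap_dataset(coh, windows = c(1, 4),
                           params = tmap_params(image_size = 48),
                           fspec = filter_spec(fs = p$fs))
  # 2 subjects x 2 sessions x 2 trials x 2 windows
  expect_equal(dim(ds$images), c(48, 48, 3, 16))
  expect_equal(as.vector(table(ds$labels)), c(8, 8))
  expect_equal(sort(unique(ds$meta$window_s)), c(1, 4))
  # per-interval size = subjects * trials per class
  expect_equal(sum(ds$meta$window_s == 1 & ds$labels == "RHTF"), 4)
})

test_that("empty cohorts and oversized windows are rejected gracefully", {
  profiles <- plain_profiles()
  p <- short_protocol(n_trials = 2)
  coh <- make_cohort(1, 2, profiles$RHTF, profiles$RHLF, no_noise(),
                     seed = 1, protocol = p)
  expect_error(build_tmap_dataset(coh, windows = 31), "longer than the trial")
  coh0 <- coh; coh0$sessions <- list(); coh0$protocol$n_trials <- 0L
  ds0 <- build_tmap_dataset(coh0, windows = 1,
                            params = tmap_params(image_size = 48))
  expect_equal(dim(ds0$images)[4], 0)
})

test_that("jaccard handles edge cases", {
  expect_equal(jaccard(1:4, 1:4), 1)
  expect_equal(jaccard(1:2, 3:4), 0)
  expect_equal(jaccard(integer(0), integer(0)), 1)
  expect_equal(jaccard(1:3, 2:4), 0.5)
})
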