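# Shared fixtures: everything is generated in code at test time.

# A short protocol for fast unit tests (still floor(duration*fs) samples).
short_protocol <- function(n_trials = 2, fs = 9.19) {
  session_protocol(pre_rest_s = 10, post_rest_s = 5, n_trials = n_trials,
                   task_s = 10, rest_s = 20, fs = fs)
}

# Two disjoint footprints without delayed spread, for clean recovery tests.
plain_profiles <- function(amplitude = 0.3, jitter_sd = 0) {
  list(RHTF = activation_profile("RHTF", sprintf("CH%02d", c(8, 9, 14, 15, 20, 21)),
                                 amplitude, jitter_sd),
       RHLF = activation_profile("RHLF", sprintf("CH%02d", c(10, 11, 16, 17, 22, 23)),
                                 amplitude, jitter_sd))
}

# Linearly separable toy image set: class-distinct bright quadrants on a
# noisy background. Any working CNN saturates on it.
toy_image_dataset <- function(n_per_class = 40, size = 56, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  imgs <- array(0, c(size, size, 3, n))
  labs <- character(n)
  q <- max(2L, size %/% 3L)
  for (i in seq_len(n)) {
    cl <- if (i <= n_per_class) "RHLF" else "RHTF"
    img <- array(stats::runif(size * size * 3, 0, 0.2), c(size, size, 3))
    if (cl == "RHLF") img[1:q, 1:q, ] <- img[1:q, 1:q, ] + 0.8
    else img[(size - q + 1):size, (size - q + 1):size, ] <-
        img[(size - q + 1):size, (size - q + 1):size, ] + 0.8
    imgs[, , , i] <- pmin(img, 1)
    labs[i] <- cl
  }
  structure(list(images = imgs, labels = factor(labs, c("RHLF", "RHTF")),
                 meta = data.frame(subject = rep_len(1:8, n),
                                   session = labs,
                                   trial = seq_len(n),
                                   window_s = rep(1, n))),
            class = "image_dataset")
}

expect_setequal_chr <- function(a, b) expect_true(setequal(a, b))
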