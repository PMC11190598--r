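test_that("generator yields vocabulary x repetitions x subjects epochs", {
  ds <- generate_dataset(synthesis_config("FM-10", n_subjects = 1,
                                          active_duration = 0.2,
                                          rest_duration = 0.2))
  expect_length(ds, 10 * 6 * 1)  # ten movements, six repetitions each
  expect_setequal(unique(emghht:::dataset_labels(ds)),
                  gesture_vocabulary("FM-10"))
  expect_setequal(unique(emghht:::dataset_trials(ds)), 1:6)
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- synthesis_config("HG-6", n_subjects = 1, active_duration = 0.3,
                          rest_duration = 0.3, seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  for (i in seq_along(a$epochs)) {
    expect_identical(a$epochs[[i]]$samples, b$epochs[[i]]$samples)
  }
  c <- generate_dataset(synthesis_config("HG-6", n_subjects = 1,
                                         active_duration = 0.3,
                                         rest_duration = 0.3, seed = 12))
  expect_false(identical(a$epochs[[1]]$samples, c$epochs[[1]]$samples))
})

test_that("noise-free epochs concentrate >= 90% of power in the class band", {
  cfg <- synthesis_config("HG-6", n_subjects = 1, noise_snr_db = Inf,
                          powerline_hz = NA, active_duration = 2,
                          rest_duration = 1, repetitions = 2, seed = 3)
  ds <- generate_dataset(cfg)
  bands <- default_class_bands("HG-6")
  for (e in ds$epochs) {
    x <- e$samples
    n <- length(x)
    P <- Mod(fft(x))^2
    f <- (0:(n - 1)) * e$fs / n
    keep <- f > 0 & f <= e$fs / 2
    b <- bands[bands$label == e$label, ]
    inb <- keep & f >= b$center - b$width / 2 & f <= b$center + b$width / 2
    expect_gt(sum(P[inb]) / sum(P[keep]), 0.9)
  }
})

test_that("each class has most mean power in its own band", {
  cfg <- synthesis_config("HG-6", n_subjects = 1, active_duration = 2,
                          rest_duration = 0.5, seed = 8)
  ds <- generate_dataset(cfg)
  bands <- default_class_bands("HG-6")
  band_power <- function(x, fs, center, width) {
    n <- length(x)
    P <- Mod(fft(x))^2
    f <- (0:(n - 1)) * fs / n
    sum(P[f >= center - width / 2 & f <= center + width / 2 & f <= fs / 2])
  }
  labs <- emghht:::dataset_labels(ds)
  for (lab in ds$vocabulary) {
    eps <- ds$epochs[labs == lab]
    own <- bands[bands$label == lab, ]
    p_own <- mean(vapply(eps, function(e) {
      band_power(e$samples, e$fs, own$center, own$width)
    }, numeric(1)))
    for (other in setdiff(ds$vocabulary, lab)) {
      ob <- bands[bands$label == other, ]
      p_other <- mean(vapply(eps, function(e) {
        band_power(e$samples, e$fs, ob$center, ob$width)
      }, numeric(1)))
      expect_gt(p_own, p_other)
    }
  }
})

test_that("config validation rejects Nyquist violations", {
  bad <- default_class_bands("HG-6")
  bad$center[1] <- 260
  expect_error(synthesis_config("HG-6", class_bands = bad), "Nyquist")
  expect_error(generate_tone_mixture(260, 1, fs = 500), "Nyquist")
})

test_that("tone mixtures are deterministic sums of the requested tones", {
  x <- generate_tone_mixture(50, 1, fs = 500, duration = 1)
  t <- (0:499) / 500
  expect_length(x$samples, 500)
  expect_equal(x$samples, sin(2 * pi * 50 * t), tolerance = 1e-12)

  z <- generate_tone_mixture(numeric(0), numeric(0), fs = 500, duration = 1)
  expect_true(all(z$samples == 0))

  expect_error(generate_tone_mixture(c(50, 5), 1, fs = 500), "length")

  # two tones -> exactly two dominant periodogram peaks
  m <- generate_tone_mixture(c(50, 5), c(1, 1), fs = 500, duration = 2)
  P <- Mod(fft(m$samples))^2
  f <- (0:(length(m) - 1)) * 500 / length(m)
  half <- f > 0 & f < 250
  big <- which(P[half] > max(P[half]) / 10)
  expect_setequal(round(f[half][big]), c(5, 50))
})
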