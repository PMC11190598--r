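test_that("find_extrema matches a brute-force scan on smooth signals", {
  t <- (0:499) / 500
  for (f in c(2, 7, 23)) {
    x <- sin(2 * pi * f * t) + 0.3 * cos(2 * pi * 3 * f * t + 1)
    got <- find_extrema(x)
    want <- brute_extrema(x)
    expect_identical(got$maxima, want$maxima)
    expect_identical(got$minima, want$minima)
  }
  # a 2 Hz sinusoid over 1 s has 2 maxima and 2 minima
  ex <- find_extrema(sin(2 * pi * 2 * t))
  expect_length(ex$maxima, 2)
  expect_length(ex$minima, 2)
})

test_that("monotone, constant, and plateau inputs are handled", {
  expect_length(find_extrema(seq_len(100))$maxima, 0)
  expect_length(find_extrema(rep(1, 100))$maxima, 0)
  expect_error(find_extrema(c(1, 2)), "3 samples")
  # interior plateau maximum -> single midpoint extremum
  x <- c(0, 1, 2, 2, 2, 1, 0, -1, -2, -1, 0)
  ex <- find_extrema(x)
  expect_identical(ex$maxima, 4L)
  expect_identical(ex$minima, 9L)
})

test_that("envelopes of a sinusoid are its amplitude lines", {
  t <- (0:999) / 500
  a <- 1.7
  x <- a * sin(2 * pi * 10 * t)
  ex <- find_extrema(x)
  env <- compute_envelopes(x, ex$maxima, ex$minima)
  interior <- 101:899
  expect_lt(max(abs(env$upper[interior] - a)), 0.02 * a)
  expect_lt(max(abs(env$lower[interior] + a)), 0.02 * a)
  # interpolation constraint: envelopes pass through their extrema exactly
  expect_equal(env$upper[ex$maxima], x[ex$maxima], tolerance = 1e-10)
  expect_equal(env$lower[ex$minima], x[ex$minima], tolerance = 1e-10)
})

test_that("envelopes bracket a triangle wave at interior samples", {
  t <- (0:999) / 500
  x <- 2 * abs(2 * (t * 9 - floor(t * 9 + 0.5))) - 1
  ex <- find_extrema(x)
  env <- compute_envelopes(x, ex$maxima, ex$minima)
  interior <- 60:940
  expect_true(all(env$upper[interior] >= x[interior] - 1e-6))
  expect_true(all(env$lower[interior] <= x[interior] + 1e-6))
})

test_that("envelope_mean is the pointwise average and checks lengths", {
  pair <- list(upper = c(2, 2, 2), lower = c(0, 0, 0))
  expect_equal(envelope_mean(pair), c(1, 1, 1))
  expect_equal(envelope_mean(list(upper = c(1, 2), lower = c(-1, -2))),
               c(0, 0))
  expect_error(envelope_mean(list(upper = 1:3, lower = 1:2)), "length")
  # sinusoid riding on DC: mean recovers the offset away from boundaries
  t <- (0:999) / 500
  x <- sin(2 * pi * 20 * t) + 0.6
  ex <- find_extrema(x)
  m <- envelope_mean(compute_envelopes(x, ex$maxima, ex$minima))
  expect_lt(max(abs(m[101:899] - 0.6)), 0.03)
})

test_that("a pure sinusoid is a sifting fixed point", {
  t <- (0:999) / 500
  x <- sin(2 * pi * 10 * t)
  s <- sift(x, emd_config())
  expect_identical(s$state$stop_reason, "imf_criteria")
  expect_identical(s$state$iteration, 0L)   # returned unchanged after 1 check
  expect_identical(s$imf, x)
})

test_that("sifting terminates within the iteration cap and obeys delta", {
  cfg <- emd_config(delta = 0.025, max_sift_iterations = 30)
  set.seed(9)
  for (rep in 1:5) {
    x <- bandpass_oracle(rnorm(1500), 500, 40, 80) +
      0.5 * bandpass_oracle(rnorm(1500), 500, 5, 15)
    s <- sift(x, cfg)
    expect_lte(s$state$iteration, 30)
    expect_true(is.finite(s$state$sigma) || s$state$iteration == 0)
    if (s$state$stop_reason == "sigma") {
      expect_lt(s$state$sigma, cfg$delta)
    }
  }
  expect_error(sift(seq_len(100), emd_config()), "degenerate")
})

test_that("decomposition is complete: IMFs + residue rebuild the input", {
  x <- generate_tone_mixture(c(50, 5), c(1, 1), fs = 500, duration = 2)
  dec <- emd_decompose(x)
  rec <- Reduce(`+`, dec$imfs) + dec$residue
  expect_lt(max(abs(rec - x$samples)), 1e-8 * diff(range(x$samples)))
})

test_that("a two-tone mixture separates into its band-passed components", {
  x <- generate_tone_mixture(c(50, 5), c(1, 1), fs = 500, duration = 2)
  dec <- emd_decompose(x)
  expect_gte(length(dec$imfs), 2)
  ref_fast <- bandpass_oracle(x$samples, 500, 30, 80)
  ref_slow <- bandpass_oracle(x$samples, 500, 2, 10)
  expect_gte(cor(dec$imfs[[1]], ref_fast), 0.95)
  expect_gte(cor(dec$imfs[[2]], ref_slow), 0.95)
})

test_that("every extracted IMF satisfies the zero-crossing criterion", {
  set.seed(21)
  ds <- small_dataset(seed = 21, dur = 1)
  for (e in ds$epochs[seq(1, 36, by = 7)]) {
    dec <- emd_decompose(e)
    for (h in dec$imfs) {
      ex <- find_extrema(h)
      n_ext <- length(ex$maxima) + length(ex$minima)
      expect_lte(abs(zero_crossings(h) - n_ext), 1)
    }
  }
})

test_that("IMF mean frequencies decrease for well-separated tones", {
  x <- generate_tone_mixture(c(80, 20, 4), c(1, 1, 1), fs = 500,
                             duration = 2)
  dec <- emd_decompose(x)
  mf <- emghht:::mean_instantaneous_frequency(dec)
  expect_true(all(diff(mf[1:min(3, length(mf))]) < 0))
})

test_that("degenerate inputs give zero IMFs with the input as residue", {
  e <- emg_signal(rep(2, 100), fs = 500)
  dec <- emd_decompose(e)
  expect_length(dec$imfs, 0)
  expect_identical(dec$residue, e$samples)
  ramp <- emg_signal(seq(0, 1, length.out = 100), fs = 500)
  expect_length(emd_decompose(ramp)$imfs, 0)
})

test_that("hilbert_spectrum recovers tone amplitude and frequency", {
  a <- 2.3
  x <- generate_tone_mixture(50, a, fs = 500, duration = 2)
  dec <- emd_decompose(x)
  hs <- hilbert_spectrum(dec)
  interior <- 101:899
  expect_lt(abs(median(hs[[1]]$frequency[interior]) - 50), 1)
  expect_lt(max(abs(hs[[1]]$amplitude[interior] - a)), 0.05 * a)
  expect_true(all(hs[[1]]$frequency >= 0 & hs[[1]]$frequency <= 250))

  # zero IMF -> zero amplitude
  z <- emghht:::new_imf_set(list(numeric(100)), numeric(100), 0L, "sigma",
                            100L, 500)
  expect_true(all(hilbert_spectrum(z)[[1]]$amplitude == 0))
  empty <- emghht:::new_imf_set(list(), numeric(10), integer(0),
                                character(0), 10L, 500)
  expect_error(hilbert_spectrum(empty), "no IMFs")
})

test_that("emd_config validates its parameters", {
  expect_error(emd_config(delta = 0), "0, 1")
  expect_error(emd_config(delta = 1.2), "0, 1")
  expect_error(emd_config(max_imfs = 0), ">= 1")
  expect_error(emd_config(spline = "linear"), "cubic")
})
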