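# shared fixtures and independent oracles

# brute-force interior-extrema scan (plateau-free signals): the oracle for
# find_extrema
brute_extrema <- function(x) {
  maxima <- integer(0)
  minima <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima <- c(maxima, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima <- c(minima, i)
  }
  list(maxima = maxima, minima = minima)
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(s[-1] != s[-length(s)])
}

# zero-phase Butterworth band-pass, the independent oracle for tone recovery
bandpass_oracle <- function(x, fs, lo, hi, order = 4) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

snr_db <- function(clean, err) 10 * log10(sum(clean^2) / sum(err^2))

small_dataset <- function(seed = 1, n_subjects = 1, vocabulary = "HG-6",
                          dur = 0.5) {
  generate_dataset(synthesis_config(
    vocabulary, n_subjects = n_subjects, active_duration = dur,
    rest_duration = dur, seed = seed))
}

tiny_net <- function(seed = 42, input = 5, hidden = c(4, 3), k = 3) {
  p <- emghht:::init_params(c(input, hidden, k), seed)
  p$classes <- as.character(seq_len(k))
  p
}
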