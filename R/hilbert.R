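# analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert spectrum of an IMF set
#'
#' Completes the Hilbert-Huang transform: each IMF is turned into its
#' analytic signal, whose modulus gives the instantaneous amplitude and
#' whose unwrapped-phase derivative (central differences, times
#' `fs / (2 pi)`) gives the instantaneous frequency, clipped to the
#' physical range `[0, fs / 2]`.
#'
#' @param imfset An `imf_set` from [emd_decompose()] with at least one IMF.
#' @param fs Sampling rate in Hz; defaults to the rate recorded in the set.
#' @return A list of class `hilbert_spectrum`, one element per IMF, each a
#'   list with numeric vectors `amplitude` and `frequency`.
#' @examples
#' x <- generate_tone_mixture(50, 1, fs = 500, duration = 2)
#' hs <- hilbert_spectrum(emd_decompose(x))
#' median(hs[[1]]$frequency)
#' @export
hilbert_spectrum <- function(imfset, fs = imfset$fs) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imfset$imfs) == 0) {
    stop("imf_set contains no IMFs; nothing to analyse")
  }
  out <- lapply(imfset$imfs, function(h) {
    z <- analytic_signal(h)
    amp <- Mod(z)
    phase <- signal::unwrap(Arg(z))
    freq <- pracma::gradient(phase) * fs / (2 * pi)
    list(amplitude = amp, frequency = pmin(pmax(freq, 0), fs / 2))
  })
  structure(out, class = "hilbert_spectrum")
}

# energy-weighted mean instantaneous frequency of each IMF
mean_instantaneous_frequency <- function(imfset, fs = imfset$fs) {
  hs <- hilbert_spectrum(imfset, fs)
  vapply(hs, function(s) {
    w <- s$amplitude^2
    if (sum(w) == 0) return(0)
    sum(w * s$frequency) / sum(w)
  }, numeric(1))
}
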