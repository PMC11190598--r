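#' Default per-class frequency bands
#'
#' Each gesture class is assigned a distinct surface-EMG frequency band
#' (center, full width, in Hz) spread over 20-200 Hz, inside the usable sEMG
#' band at a 500 Hz sampling rate. Distinct bands give the surrogate classes
#' the spectral separability that real gestures derive from differing muscle
#' recruitment, which is what makes the downstream pipeline testable
#' end-to-end.
#'
#' @param vocabulary `"FM-10"` or `"HG-6"` (or an explicit label vector, in
#'   which case bands are spread evenly over 30-190 Hz).
#' @return A data.frame with columns `label`, `center`, `width`.
#' @export
default_class_bands <- function(vocabulary = "HG-6") {
  labels <- resolve_vocabulary(vocabulary)
  k <- length(labels)
  if (identical(labels, gesture_vocabulary("FM-10"))) {
    centers <- seq(30, 192, by = 18)
    widths <- seq(20, 38, by = 2)
  } else if (identical(labels, gesture_vocabulary("HG-6"))) {
    centers <- seq(40, 190, by = 30)
    widths <- seq(20, 40, by = 4)
  } else {
    centers <- seq(30, 190, length.out = max(k, 2))[seq_len(k)]
    widths <- rep(20, k)
  }
  data.frame(label = labels, center = centers, width = widths,
             stringsAsFactors = FALSE)
}

#' Synthetic sEMG generation settings
#'
#' Describes the surrogate acquisition protocol: for every subject, every
#' gesture class is repeated over `repetitions` trials; each epoch is
#' `active_duration` seconds of gesture activity followed by
#' `rest_duration` seconds of rest. The active segment is zero-mean Gaussian
#' noise band-passed to the class band and amplitude-modulated by an
#' envelope; rest is low-amplitude broadband noise (5 % of the active RMS),
#' not silence, so denoising has something to do. Optional contaminants are
#' a powerline sinusoid and broadband measurement noise at a prescribed SNR.
#'
#' @param vocabulary `"FM-10"` or `"HG-6"`.
#' @param fs Sampling rate, Hz.
#' @param active_duration,rest_duration Segment lengths in seconds.
#' @param repetitions Trials per gesture per subject.
#' @param n_subjects Number of subjects.
#' @param class_bands data.frame `label, center, width` in Hz; defaults to
#'   [default_class_bands()]. Every band must respect Nyquist:
#'   `center + width / 2 < fs / 2`.
#' @param envelope_shape `"trapezoid"` (0.5 s linear ramps) or `"hann"`.
#' @param powerline_hz Powerline interference frequency: `NA` for none, or
#'   50 / 60.
#' @param powerline_amplitude Powerline amplitude relative to the active RMS.
#' @param noise_snr_db Broadband measurement-noise SNR in dB relative to the
#'   active-segment power; `Inf` for noise-free.
#' @param seed Integer RNG seed; identical seeds give bit-identical datasets.
#' @return An object of class `synthesis_config`.
#' @export
synthesis_config <- function(vocabulary = "HG-6", fs = 500,
                             active_duration = 5, rest_duration = 5,
                             repetitions = 6L, n_subjects = 5L,
                             class_bands = default_class_bands(vocabulary),
                             envelope_shape = c("trapezoid", "hann"),
                             powerline_hz = 50, powerline_amplitude = 0.05,
                             noise_snr_db = 15, seed = 1L) {
  envelope_shape <- match.arg(envelope_shape)
  labels <- resolve_vocabulary(vocabulary)
  if (active_duration <= 0 || rest_duration < 0) {
    stop("durations must be positive")
  }
  repetitions <- as.integer(repetitions)
  n_subjects <- as.integer(n_subjects)
  if (repetitions < 1 || n_subjects < 1) {
    stop("repetitions and n_subjects must be >= 1")
  }
  if (!all(labels %in% class_bands$label)) {
    stop("class_bands must provide a band for every vocabulary label")
  }
  if (any(class_bands$center + class_bands$width / 2 >= fs / 2)) {
    stop("class band exceeds the Nyquist frequency fs/2 = ", fs / 2, " Hz")
  }
  if (!is.na(powerline_hz) && powerline_hz >= fs / 2) {
    stop("powerline_hz exceeds the Nyquist frequency")
  }
  structure(
    list(vocabulary = labels, fs = fs, active_duration = active_duration,
         rest_duration = rest_duration, repetitions = repetitions,
         n_subjects = n_subjects, class_bands = class_bands,
         envelope_shape = envelope_shape, powerline_hz = powerline_hz,
         powerline_amplitude = powerline_amplitude,
         noise_snr_db = noise_snr_db, seed = as.integer(seed)),
    class = "synthesis_config"
  )
}

# amplitude envelope over the active segment, in [0, 1]
active_envelope <- function(n, fs, shape) {
  if (shape == "hann") {
    return(0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n)))
  }
  ramp <- min(round(0.5 * fs), floor(n / 2))  # 0.5 s attack/release
  env <- rep(1, n)
  if (ramp > 0) {
    env[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
    env[n - ramp + seq_len(ramp)] <- seq(1, 0, length.out = ramp)
  }
  env
}

# band-limited zero-mean Gaussian noise via zero-phase Butterworth filtering
bandlimited_noise <- function(n, fs, center, width) {
  lo <- max(center - width / 2, 1) / (fs / 2)
  hi <- min(center + width / 2, fs / 2 - 1) / (fs / 2)
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2 * fs))  # pad to settle the filter
  x[fs + seq_len(n)]
}

ACTIVE_RMS_UV <- 100  # nominal active-segment RMS amplitude, microvolts

#' Generate a synthetic gesture dataset
#'
#' Draws one epoch per (subject, class, repetition) under the protocol
#' described in [synthesis_config()]: `|vocabulary| * repetitions *
#' n_subjects` epochs in total, each `active_duration + rest_duration`
#' seconds long with the gesture activity first. The trial index of an epoch
#' is its repetition number, so [split_by_trial()] reproduces the
#' two-trials-train / four-trials-test protocol.
#'
#' @param config A [synthesis_config()].
#' @return A [gesture_dataset]; generation is fully determined by
#'   `config$seed`.
#' @examples
#' ds <- generate_dataset(synthesis_config("HG-6", n_subjects = 1,
#'                                         active_duration = 1,
#'                                         rest_duration = 1))
#' ds
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  set.seed(config$seed)
  fs <- config$fs
  n_act <- round(config$active_duration * fs)
  n_rest <- round(config$rest_duration * fs)
  n <- n_act + n_rest
  t_all <- (seq_len(n) - 1) / fs
  epochs <- vector("list",
                   length(config$vocabulary) * config$repetitions *
                     config$n_subjects)
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (lab in config$vocabulary) {
      band <- config$class_bands[config$class_bands$label == lab, ][1, ]
      for (rep_i in seq_len(config$repetitions)) {
        act <- bandlimited_noise(n_act, fs, band$center, band$width)
        act <- act / sqrt(mean(act^2)) * ACTIVE_RMS_UV
        act <- act * active_envelope(n_act, fs, config$envelope_shape)
        rest <- if (n_rest > 0) {
          rnorm(n_rest, sd = 0.05 * ACTIVE_RMS_UV)
        } else numeric(0)
        x <- c(act, rest)
        if (!is.na(config$powerline_hz)) {
          phase <- runif(1, 0, 2 * pi)
          x <- x + config$powerline_amplitude * ACTIVE_RMS_UV *
            sin(2 * pi * config$powerline_hz * t_all + phase)
        }
        if (is.finite(config$noise_snr_db)) {
          p_sig <- mean(act^2)
          sd_n <- sqrt(p_sig * 10^(-config$noise_snr_db / 10))
          x <- x + rnorm(n, sd = sd_n)
        }
        i <- i + 1L
        epochs[[i]] <- emg_signal(x, fs = fs, label = lab,
                                  subject_id = sprintf("S%02d", s),
                                  trial_index = rep_i)
      }
    }
  }
  gesture_dataset(epochs, config$vocabulary)
}

#' Deterministic multi-tone test signal
#'
#' A sum of sinusoids packaged as an [emg_signal]; the standard fixture for
#' exercising and validating the EMD stage, whose behaviour on well-separated
#' tones has a closed-form answer.
#'
#' @param freqs Frequencies in Hz, all below `fs / 2`.
#' @param amps Amplitudes, one per frequency.
#' @param fs Sampling rate, Hz.
#' @param duration Length in seconds.
#' @param random_phase If `TRUE`, draw a phase per tone (seeded); otherwise
#'   all phases are zero and no randomness is consumed.
#' @param seed RNG seed, used only when `random_phase = TRUE`.
#' @return An unlabelled [emg_signal] of `round(fs * duration)` samples.
#' @examples
#' x <- generate_tone_mixture(c(50, 5), c(1, 1), fs = 500, duration = 2)
#' @export
generate_tone_mixture <- function(freqs, amps, fs = 500, duration = 1,
                                  random_phase = FALSE, seed = 1L) {
  if (length(freqs) != length(amps)) {
    stop("freqs and amps must have the same length")
  }
  if (any(freqs >= fs / 2)) {
    stop("every frequency must be below the Nyquist frequency fs/2")
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  phases <- rep(0, length(freqs))
  if (random_phase && length(freqs) > 0) {
    set.seed(seed)
    phases <- runif(length(freqs), 0, 2 * pi)
  }
  x <- numeric(n)
  for (j in seq_along(freqs)) {
    x <- x + amps[j] * sin(2 * pi * freqs[j] * t + phases[j])
  }
  emg_signal(x, fs = fs)
}
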