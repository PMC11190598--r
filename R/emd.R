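#' Empirical mode decomposition settings
#'
#' @param delta Sifting threshold on the scalar sifting standard deviation
#'   `sigma = sum((h_prev - h)^2) / sum(h_prev^2)`; sifting of one IMF stops
#'   once `sigma < delta`. The conventional range is 2-3 %, and the default
#'   is its midpoint, 0.025.
#' @param max_imfs Maximum number of IMFs to extract (default 8; the count is
#'   kept modest and constant so that feature vectors have a fixed length).
#' @param max_sift_iterations Cap on sifting iterations per IMF (default 50).
#' @param spline Envelope interpolant; only `"cubic"` is implemented.
#' @param boundary Envelope boundary handling; only `"mirror"` (two extrema
#'   reflected about each signal end) is implemented.
#' @return An object of class `emd_config`.
#' @export
emd_config <- function(delta = 0.025, max_imfs = 8L,
                       max_sift_iterations = 50L, spline = "cubic",
                       boundary = "mirror") {
  if (!is.numeric(delta) || delta <= 0 || delta >= 1) {
    stop("delta must lie in (0, 1)")
  }
  spline <- match.arg(spline, "cubic")
  boundary <- match.arg(boundary, "mirror")
  max_imfs <- as.integer(max_imfs)
  max_sift_iterations <- as.integer(max_sift_iterations)
  if (max_imfs < 1) stop("max_imfs must be >= 1")
  if (max_sift_iterations < 1) stop("max_sift_iterations must be >= 1")
  structure(
    list(delta = delta, max_imfs = max_imfs,
         max_sift_iterations = max_sift_iterations, spline = spline,
         boundary = boundary),
    class = "emd_config"
  )
}

#' Locate interior extrema
#'
#' Finds strict local maxima and minima of a sequence, excluding the
#' endpoints. Runs of equal values (plateaus) count as a single extremum at
#' the plateau midpoint (rounded down for even-length plateaus).
#'
#' @param samples Numeric vector, length `>= 3`.
#' @return A list with integer index vectors `maxima` and `minima` (either
#'   may be empty, e.g. for monotone or constant input).
#' @examples
#' find_extrema(sin(2 * pi * 2 * (0:499) / 500))
#' @export
find_extrema <- function(samples) {
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples to search for interior extrema")
  d <- diff(samples)
  nz <- which(d != 0)
  if (length(nz) < 2) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  s <- sign(d[nz])
  chg <- which(s[-1] != s[-length(s)])
  if (length(chg) == 0) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  i1 <- nz[chg] + 1L       # first sample holding the extreme value
  i2 <- nz[chg + 1L]       # last sample of the plateau
  idx <- as.integer(floor((i1 + i2) / 2))
  rising <- s[chg] > 0
  list(maxima = idx[rising], minima = idx[!rising])
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

# knots for one envelope: extrema plus `k` extrema mirrored about each end
mirror_knots <- function(idx, vals, n, k = 2L) {
  m <- length(idx)
  kk <- min(k, m)
  xi <- c(2 - idx[seq_len(kk)], idx, 2 * n - idx[m - seq_len(kk) + 1L])
  yv <- c(vals[seq_len(kk)], vals, vals[m - seq_len(kk) + 1L])
  o <- order(xi)
  xi <- xi[o]
  yv <- yv[o]
  keep <- !duplicated(xi)
  list(x = xi[keep], y = yv[keep])
}

#' Upper and lower signal envelopes
#'
#' Interpolates cubic splines through the local maxima (upper envelope) and
#' minima (lower envelope), evaluated at every sample index. To control the
#' end swings that plague spline extrapolation, two extrema are mirrored
#' about each signal end before fitting.
#'
#' @param samples Numeric vector.
#' @param maxima,minima Interior extrema indices, as from [find_extrema()];
#'   at least two of each are required.
#' @param boundary Only `"mirror"` is implemented.
#' @return A list of class `envelope_pair` with numeric vectors `upper` and
#'   `lower`, each the length of `samples`; each envelope passes exactly
#'   through its extrema.
#' @export
compute_envelopes <- function(samples, maxima, minima, boundary = "mirror") {
  boundary <- match.arg(boundary, "mirror")
  if (length(maxima) < 2 || length(minima) < 2) {
    stop("degenerate signal: need at least 2 maxima and 2 minima to build ",
         "envelopes")
  }
  n <- length(samples)
  up <- mirror_knots(maxima, samples[maxima], n)
  lo <- mirror_knots(minima, samples[minima], n)
  structure(
    list(upper = spline(up$x, up$y, xout = seq_len(n), method = "fmm")$y,
         lower = spline(lo$x, lo$y, xout = seq_len(n), method = "fmm")$y),
    class = "envelope_pair"
  )
}

#' Envelope mean
#'
#' Pointwise mean of the upper and lower envelopes, `(U + L) / 2` — the
#' local trend that each sifting iteration subtracts.
#'
#' @param pair An `envelope_pair` from [compute_envelopes()], or any list
#'   with equal-length numeric `upper` and `lower`.
#' @return Numeric vector of the same length.
#' @export
envelope_mean <- function(pair) {
  if (length(pair$upper) != length(pair$lower)) {
    stop("upper and lower envelopes must have the same length")
  }
  (pair$upper + pair$lower) / 2
}

# IMF validity: zero-crossing and extrema counts within one of each other,
# and the envelope mean negligible against the local amplitude
satisfies_imf_criteria <- function(h, extrema, m, pair) {
  n_ext <- length(extrema$maxima) + length(extrema$minima)
  if (abs(count_zero_crossings(h) - n_ext) > 1) return(FALSE)
  amp <- mean(abs(pair$upper - pair$lower)) / 2
  if (amp == 0) return(TRUE)
  mean(abs(m)) < 0.05 * amp
}

zc_extrema_ok <- function(h) {
  ex <- find_extrema(h)
  abs(count_zero_crossings(h) -
        (length(ex$maxima) + length(ex$minima))) <= 1
}

#' Sift one intrinsic mode function
#'
#' The inner EMD loop: repeatedly subtracts the envelope mean,
#' `h <- h - envelope_mean(h)`, until one of the halting rules fires:
#' the sifting standard deviation `sigma = sum((h_prev - h)^2) /
#' sum(h_prev^2)` drops below `delta` (with the zero-crossing/extrema
#' criterion already satisfied), the candidate itself meets both IMF
#' requirements (`|#zero-crossings - #extrema| <= 1` and a negligible
#' envelope mean), or the iteration cap is reached. An input that already
#' satisfies the IMF requirements is returned unchanged after a single
#' check.
#'
#' @param samples Numeric vector with at least two maxima and two minima.
#' @param config An [emd_config()].
#' @return A list with `imf` (numeric vector) and `state`, a `sift_state`
#'   list carrying `h`, `r` (input minus IMF), `sigma` (last sifting SD,
#'   `Inf` if no subtraction happened), `iteration`, and `stop_reason` (one
#'   of `"imf_criteria"`, `"sigma"`, `"max_iterations"`, or `"degenerate"`
#'   when the candidate loses its oscillation mid-sift and should be
#'   discarded).
#' @export
sift <- function(samples, config = emd_config()) {
  stopifnot(inherits(config, "emd_config"))
  h <- samples
  iteration <- 0L
  sigma <- Inf
  stop_reason <- "max_iterations"
  repeat {
    ex <- find_extrema(h)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) {
      if (iteration == 0L) {
        stop("degenerate signal: too few extrema to sift")
      }
      # the candidate lost its oscillation mid-sift; abandon it
      stop_reason <- "degenerate"
      break
    }
    pair <- compute_envelopes(h, ex$maxima, ex$minima, config$boundary)
    m <- envelope_mean(pair)
    if (satisfies_imf_criteria(h, ex, m, pair)) {
      stop_reason <- "imf_criteria"
      break
    }
    h_new <- h - m
    iteration <- iteration + 1L
    sigma <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    if (sigma < config$delta && zc_extrema_ok(h)) {
      stop_reason <- "sigma"
      break
    }
    if (iteration >= config$max_sift_iterations) {
      stop_reason <- "max_iterations"
      break
    }
  }
  state <- structure(
    list(h = h, r = samples - h, sigma = sigma, iteration = iteration,
         stop_reason = stop_reason),
    class = "sift_state"
  )
  list(imf = h, state = state)
}

new_imf_set <- function(imfs, residue, sift_counts, stop_reasons,
                        source_length, fs) {
  structure(
    list(imfs = imfs, residue = residue, sift_counts = sift_counts,
         stop_reasons = stop_reasons, source_length = source_length,
         fs = fs),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue, %d samples @ %g Hz\n",
              length(x$imfs), x$source_length, x$fs))
  if (length(x$imfs) > 0) {
    cat("  sift iterations:", paste(x$sift_counts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Empirical mode decomposition of an epoch
#'
#' Extracts intrinsic mode functions one at a time — sift an IMF, subtract
#' it from the running residue, repeat — until `max_imfs` are produced or
#' the residue is monotone/degenerate (fewer than two maxima or minima). By
#' construction the decomposition is complete: the IMFs plus the residue sum
#' back to the input to machine precision. IMFs are ordered from the fastest
#' oscillation (broadest band) down.
#'
#' @param signal An [emg_signal] with at least 8 samples.
#' @param config An [emd_config()].
#' @return An `imf_set`: list of IMF vectors `imfs`, the `residue`,
#'   per-IMF `sift_counts` and `stop_reasons`, `source_length` and `fs`. A
#'   degenerate input yields zero IMFs with `residue` equal to the input.
#' @examples
#' x <- generate_tone_mixture(c(50, 5), c(1, 1), fs = 500, duration = 2)
#' dec <- emd_decompose(x)
#' dec
#' @export
emd_decompose <- function(signal, config = emd_config()) {
  stopifnot(inherits(signal, "emg_signal"), inherits(config, "emd_config"))
  x <- signal$samples
  if (length(x) < 8) stop("signal too short to decompose (need >= 8 samples)")
  r <- x
  imfs <- list()
  counts <- integer(0)
  reasons <- character(0)
  while (length(imfs) < config$max_imfs) {
    ex <- find_extrema(r)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    s <- sift(r, config)
    if (s$state$stop_reason == "degenerate") break  # keep r as residue
    imfs[[length(imfs) + 1L]] <- s$imf
    counts <- c(counts, s$state$iteration)
    reasons <- c(reasons, s$state$stop_reason)
    r <- r - s$imf
  }
  new_imf_set(imfs, r, counts, reasons, length(x), signal$fs)
}
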