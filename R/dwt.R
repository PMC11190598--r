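# Periodized orthogonal discrete wavelet transform.
#
# Analysis takes inner products with circularly shifted scaling/wavelet
# filters (shift step 2); synthesis is the adjoint, so reconstruction is
# exact by orthonormality whenever the level length is at least the filter
# length. Odd-length levels are padded by repeating the last sample; the pad
# is dropped on inversion, keeping the round trip exact.

# Daubechies decomposition low-pass filters (orthonormal)
wavelet_filter <- function(name) {
  switch(name,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079, 0.48296291314453416),
    db4 = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    stop("unknown wavelet: ", name, " (available: haar, db2, db4)")
  )
}

qmf <- function(lo) rev(lo) * (-1)^(seq_along(lo) - 1)

dwt_step <- function(x, lo) {
  n0 <- length(x)
  if (n0 %% 2 == 1) x <- c(x, x[n0])
  n <- length(x)
  hi <- qmf(lo)
  k <- seq_len(n / 2)
  a <- numeric(n / 2)
  d <- numeric(n / 2)
  for (m in seq_along(lo)) {
    idx <- ((2 * (k - 1) + m - 1) %% n) + 1
    a <- a + lo[m] * x[idx]
    d <- d + hi[m] * x[idx]
  }
  list(a = a, d = d, n0 = n0)
}

idwt_step <- function(a, d, lo, n0) {
  hi <- qmf(lo)
  n <- 2 * length(a)
  y <- numeric(n)
  k <- seq_len(n / 2)
  for (m in seq_along(lo)) {
    idx <- ((2 * (k - 1) + m - 1) %% n) + 1
    y[idx] <- y[idx] + a * lo[m] + d * hi[m]
  }
  y[seq_len(n0)]
}

# multilevel pyramid: list(a = coarsest approximation,
#                          d = details finest..coarsest, n0 = level lengths)
dwt_pyramid <- function(x, lo, level) {
  d <- vector("list", level)
  n0 <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    if (length(a) < length(lo)) {
      stop("signal too short for decomposition level ", level)
    }
    s <- dwt_step(a, lo)
    d[[l]] <- s$d
    n0[l] <- s$n0
    a <- s$a
  }
  list(a = a, d = d, n0 = n0)
}

idwt_pyramid <- function(w, lo) {
  a <- w$a
  for (l in rev(seq_along(w$d))) a <- idwt_step(a, w$d[[l]], lo, w$n0[l])
  a
}

max_dwt_level <- function(n, lo) {
  lev <- 0L
  while (n >= length(lo) && n >= 2) {
    lev <- lev + 1L
    n <- ceiling(n / 2)
  }
  lev
}

soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)
hard_threshold <- function(d, thr) d * (abs(d) > thr)

# Donoho-Johnstone hybrid SURE threshold for one detail level (sigma-units).
# Falls back to the universal threshold when the level looks sparse.
sure_threshold <- function(d, sigma) {
  n <- length(d)
  t_univ <- sqrt(2 * log(n))
  y <- (d / sigma)^2
  eta <- (sum(y) - n) / n
  if (eta < log2(n)^1.5 / sqrt(n)) return(t_univ * sigma)
  ys <- sort(y)
  i <- seq_len(n)
  risk <- (n - 2 * i + cumsum(ys) + ys * (n - i)) / n
  min(sqrt(ys[which.min(risk)]), t_univ) * sigma
}
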