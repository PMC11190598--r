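# Per-IMF statistical features. The four formulas are implemented exactly as
# the method defines them, which differs from the quantities their names
# usually denote: the "mean" is a mean of squares, the "standard deviation"
# is an unnormalized sum of squares over N - 1 (no centering, no square
# root), and the "entropy" is the energy-weighted negative log-energy
# sum -Σ x_i^2 ln(x_i^2) with the convention 0 * ln 0 := 0. Conventional
# counterparts (arithmetic mean, sample SD, Shannon entropy of the
# normalized energy distribution) are available via form = "conventional".

#' Mean power of a sequence
#'
#' As-printed form: `M = (1/N) * sum(x^2)`, the mean of squares.
#' Conventional form: the arithmetic mean.
#'
#' @param x Numeric vector, non-empty.
#' @param form `"as-printed"` (default) or `"conventional"`.
#' @return A single number.
#' @examples
#' feat_mean_power(c(3, 4))  # (9 + 16) / 2 = 12.5
#' @export
feat_mean_power <- function(x, form = c("as-printed", "conventional")) {
  form <- match.arg(form)
  if (length(x) < 1) stop("empty input")
  if (form == "conventional") mean(x) else mean(x^2)
}

#' Spread feature of a sequence
#'
#' As-printed form: `STD = sum(x^2) / (N - 1)` — no centering, no square
#' root. Conventional form: the sample standard deviation.
#'
#' @inheritParams feat_mean_power
#' @return A single number.
#' @examples
#' feat_std(c(3, 4))  # (9 + 16) / 1 = 25
#' @export
feat_std <- function(x, form = c("as-printed", "conventional")) {
  form <- match.arg(form)
  if (length(x) < 2) stop("need at least 2 samples")
  if (form == "conventional") sd(x) else sum(x^2) / (length(x) - 1)
}

#' Energy of a sequence
#'
#' `E = sum(x^2)` under either form.
#'
#' @inheritParams feat_mean_power
#' @return A single non-negative number.
#' @examples
#' feat_energy(c(1, 2, 3))  # 14
#' @export
feat_energy <- function(x, form = c("as-printed", "conventional")) {
  match.arg(form)
  if (length(x) < 1) stop("empty input")
  sum(x^2)
}

#' Entropy feature of a sequence
#'
#' As-printed form: the energy-weighted log term
#' `U = -sum(x^2 * ln(x^2))` with `0 * ln 0 := 0`; note `U < 0` is possible
#' when samples exceed 1 in magnitude. Conventional form: the Shannon
#' entropy `-sum(p * ln p)` of the normalized energy distribution
#' `p_i = x_i^2 / sum(x^2)` (0 for an all-zero vector).
#'
#' @inheritParams feat_mean_power
#' @return A single number.
#' @examples
#' feat_entropy(exp(-0.5))  # exp(-1)
#' @export
feat_entropy <- function(x, form = c("as-printed", "conventional")) {
  form <- match.arg(form)
  if (length(x) < 1) stop("empty input")
  x2 <- x^2
  if (form == "conventional") {
    e <- sum(x2)
    if (e == 0) return(0)
    p <- x2[x2 > 0] / e
    return(-sum(p * log(p)))
  }
  nz <- x2 > 0
  -sum(x2[nz] * log(x2[nz]))
}

#' Assemble a per-IMF feature vector
#'
#' Applies the four statistical features — mean power `M`, spread `STD`,
#' energy `E`, entropy `U`, in that order — to each of the first `max_imfs`
#' IMFs and concatenates the blocks into a fixed-length vector of
#' `4 * max_imfs` values. Epochs yielding fewer IMFs are zero-padded so the
#' classifier input length is constant across a dataset.
#'
#' @param imfset An `imf_set` from [emd_decompose()].
#' @param max_imfs Number of IMF slots in the vector (default 8).
#' @param form Feature form, see [feat_mean_power()].
#' @param label Optional gesture label carried along with the vector.
#' @return A list of class `feature_vector` with `values` (named numeric
#'   vector of length `4 * max_imfs`), `label`, and `imf_count`. An empty
#'   IMF set gives an all-zero vector with a warning.
#' @export
extract_features <- function(imfset, max_imfs = 8L,
                             form = c("as-printed", "conventional"),
                             label = NA_character_) {
  stopifnot(inherits(imfset, "imf_set"))
  form <- match.arg(form)
  max_imfs <- as.integer(max_imfs)
  k <- length(imfset$imfs)
  if (k == 0) warning("empty IMF set; returning an all-zero feature vector")
  values <- numeric(4 * max_imfs)
  names(values) <- as.vector(vapply(seq_len(max_imfs), function(i) {
    paste0(c("M", "STD", "E", "U"), i)
  }, character(4)))
  for (i in seq_len(min(k, max_imfs))) {
    h <- imfset$imfs[[i]]
    values[(4 * (i - 1)) + 1:4] <- c(
      feat_mean_power(h, form), feat_std(h, form),
      feat_energy(h, form), feat_entropy(h, form))
  }
  structure(list(values = values, label = label,
                 imf_count = min(k, max_imfs)),
            class = "feature_vector")
}

#' Feature matrix for a whole dataset
#'
#' Runs [emd_decompose()] and [extract_features()] over every epoch of a
#' dataset and stacks the results.
#'
#' @param dataset A [gesture_dataset].
#' @param emd An [emd_config()]; its `max_imfs` fixes the vector length.
#' @param form Feature form, see [feat_mean_power()].
#' @return A data.frame with one row per epoch: the `4 * max_imfs` feature
#'   columns, then `label`, `subject`, `trial`, `imf_count`.
#' @export
featurize_dataset <- function(dataset, emd = emd_config(),
                              form = c("as-printed", "conventional")) {
  stopifnot(inherits(dataset, "gesture_dataset"))
  form <- match.arg(form)
  rows <- lapply(dataset$epochs, function(e) {
    fv <- extract_features(emd_decompose(e, emd), emd$max_imfs, form,
                           label = e$label)
    c(as.list(fv$values),
      list(label = e$label, subject = e$subject_id, trial = e$trial_index,
           imf_count = fv$imf_count))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

feature_columns <- function(fm) {
  grep("^(M|STD|E|U)[0-9]+$", names(fm), value = TRUE)
}
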