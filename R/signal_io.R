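#' Construct a labelled sEMG epoch
#'
#' An `emg_signal` holds one single-channel surface-EMG epoch: the sample
#' amplitudes (conventionally microvolts), the sampling rate, and its
#' provenance (gesture label, subject, trial repetition, channel).
#'
#' @param samples Numeric vector of amplitudes; all values must be finite and
#'   at least two samples are required.
#' @param fs Sampling rate in Hz (positive). The acquisition protocol this
#'   package emulates samples at 500 Hz.
#' @param label Gesture label, or `NA` for an unlabelled epoch.
#' @param subject_id Subject identifier.
#' @param trial_index Trial (repetition) index, an integer `>= 1`.
#' @param channel_id Channel identifier.
#' @return An object of class `emg_signal`.
#' @examples
#' s <- emg_signal(sin(2 * pi * 50 * seq(0, 1, by = 1 / 500)), fs = 500)
#' s
#' @export
emg_signal <- function(samples, fs, label = NA_character_,
                       subject_id = "S1", trial_index = 1L,
                       channel_id = "ch1") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("an epoch needs at least 2 samples")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1) stop("trial_index must be >= 1")
  structure(
    list(samples = samples, fs = fs, label = as.character(label),
         subject_id = as.character(subject_id), trial_index = trial_index,
         channel_id = as.character(channel_id)),
    class = "emg_signal"
  )
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("<emg_signal> %d samples @ %g Hz (%.3g s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  cat(sprintf("  label: %s  subject: %s  trial: %d  channel: %s\n",
              ifelse(is.na(x$label), "<none>", x$label),
              x$subject_id, x$trial_index, x$channel_id))
  invisible(x)
}

#' @export
length.emg_signal <- function(x) length(x$samples)

#' Construct a gesture dataset
#'
#' A `gesture_dataset` is a collection of [emg_signal] epochs that share a
#' sampling rate and draw their labels from one ordered vocabulary, plus a
#' trial-role map assigning every trial index to the training or the test
#' split (the acquisition protocol runs six trials per gesture, two used for
#' training and four for testing).
#'
#' @param epochs List of [emg_signal] objects.
#' @param vocabulary A registered vocabulary name (`"FM-10"`, `"HG-6"`) or an
#'   explicit character vector of labels.
#' @param split Optional named character vector mapping trial index (name) to
#'   `"train"` or `"test"`; by default trials 1-2 train, the rest test.
#' @return An object of class `gesture_dataset`.
#' @seealso [split_by_trial()], [read_epochs()], [write_epochs()]
#' @export
gesture_dataset <- function(epochs, vocabulary, split = NULL) {
  if (!is.list(epochs)) stop("epochs must be a list of emg_signal objects")
  if (!all(vapply(epochs, inherits, logical(1), "emg_signal"))) {
    stop("every epoch must be an emg_signal")
  }
  vocabulary <- resolve_vocabulary(vocabulary)
  if (length(epochs) > 0) {
    fs <- vapply(epochs, function(e) e$fs, numeric(1))
    if (length(unique(fs)) > 1) {
      stop("all epochs must share the same sampling rate; found: ",
           paste(unique(fs), collapse = ", "))
    }
    labs <- vapply(epochs, function(e) e$label, character(1))
    bad <- labs[!is.na(labs) & !(labs %in% vocabulary)]
    if (length(bad) > 0) {
      stop("epoch label(s) not in vocabulary: ",
           paste(unique(bad), collapse = ", "))
    }
  }
  trials <- sort(unique(vapply(epochs, function(e) e$trial_index, integer(1))))
  if (is.null(split)) {
    split <- stats::setNames(
      ifelse(trials %in% c(1L, 2L), "train", "test"), trials)
  } else {
    if (!all(split %in% c("train", "test"))) {
      stop("split values must be 'train' or 'test'")
    }
    missing <- setdiff(as.character(trials), names(split))
    if (length(missing) > 0) {
      stop("split does not cover trial index(es): ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(epochs = epochs, vocabulary = vocabulary, split = split),
            class = "gesture_dataset")
}

#' @export
print.gesture_dataset <- function(x, ...) {
  cat(sprintf("<gesture_dataset> %d epochs, %d-label vocabulary\n",
              length(x$epochs), length(x$vocabulary)))
  if (length(x$epochs) > 0) {
    cat(sprintf("  fs: %g Hz  subjects: %d  trials: %s\n",
                x$epochs[[1]]$fs,
                length(unique(vapply(x$epochs, function(e) e$subject_id,
                                     character(1)))),
                paste(names(x$split), unname(x$split), sep = ":",
                      collapse = " ")))
  }
  invisible(x)
}

#' @export
length.gesture_dataset <- function(x) length(x$epochs)

dataset_labels <- function(dataset) {
  vapply(dataset$epochs, function(e) e$label, character(1))
}

dataset_trials <- function(dataset) {
  vapply(dataset$epochs, function(e) e$trial_index, integer(1))
}

epoch_meta <- function(e) {
  list(fs = e$fs, label = e$label, subject = e$subject_id,
       trial = e$trial_index, channel = e$channel_id)
}

#' Write a gesture dataset to disk
#'
#' Two on-disk forms are supported. `"csv"` is a long table with header
#' `time,amplitude,label,subject,trial` (dot decimal separator, one sample
#' per row; the time column is derived from the sampling rate and is for
#' human readability only). `"rds"` is a binary array container holding the
#' sample vectors at full precision. Both formats carry a JSON metadata
#' sidecar (`<path>.json`) recording the sampling rate, vocabulary and
#' per-epoch provenance; readers recover `fs` from the sidecar, never from
#' the time column.
#'
#' @param dataset A [gesture_dataset] with at least one epoch.
#' @param path Output file path.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(dataset, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "gesture_dataset"))
  if (length(dataset$epochs) == 0) stop("dataset has no epochs to write")
  meta <- list(
    fs = dataset$epochs[[1]]$fs,
    vocabulary = dataset$vocabulary,
    split = as.list(dataset$split),
    epochs = lapply(dataset$epochs, epoch_meta)
  )
  if (format == "csv") {
    tabs <- lapply(dataset$epochs, function(e) {
      n <- length(e$samples)
      data.frame(
        time = format((seq_len(n) - 1) / e$fs, digits = 15, trim = TRUE,
                      scientific = FALSE),
        amplitude = format(e$samples, digits = 15, trim = TRUE),
        label = e$label, subject = e$subject_id, trial = e$trial_index,
        stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  } else {
    saveRDS(lapply(dataset$epochs, function(e) e$samples), path)
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gesture dataset from disk
#'
#' Reads files produced by [write_epochs()]. For CSV input, epoch boundaries
#' are detected where the `(label, subject, trial)` triple changes or the
#' time column restarts. The sampling rate and vocabulary come from the JSON
#' sidecar; if the sidecar is absent (a hand-made CSV), `fs` and
#' `vocabulary` must be supplied.
#'
#' @param path File path as written by [write_epochs()].
#' @param format `"csv"` or `"rds"`.
#' @param fs,vocabulary Fallbacks used only when no `<path>.json` sidecar
#'   exists.
#' @return A [gesture_dataset].
#' @export
read_epochs <- function(path, format = c("csv", "rds"), fs = NULL,
                        vocabulary = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (!is.null(meta)) {
    fs <- meta$fs
    vocabulary <- unlist(meta$vocabulary)
  }
  if (is.null(fs)) stop("no metadata sidecar found; supply fs explicitly")

  if (format == "rds") {
    if (is.null(meta)) stop("rds container requires its JSON sidecar")
    samples <- readRDS(path)
    if (length(samples) != length(meta$epochs)) {
      stop("sidecar epoch count does not match container")
    }
    epochs <- Map(function(x, m) {
      emg_signal(x, fs = m$fs, label = m$label, subject_id = m$subject,
                 trial_index = m$trial, channel_id = m$channel)
    }, samples, meta$epochs)
    fss <- vapply(meta$epochs, function(m) as.numeric(m$fs), numeric(1))
    if (length(unique(fss)) > 1) {
      stop("inconsistent sampling rates across epochs in metadata")
    }
    split <- if (!is.null(meta$split)) unlist(meta$split) else NULL
    return(gesture_dataset(unname(epochs), vocabulary, split = split))
  }

  tab <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("malformed csv (", conditionMessage(e), ")")
  )
  required <- c("time", "amplitude", "label", "subject", "trial")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("csv is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab$time <- suppressWarnings(as.numeric(tab$time))
  tab$amplitude <- suppressWarnings(as.numeric(tab$amplitude))
  tab$trial <- suppressWarnings(as.integer(tab$trial))
  bad <- which(!is.finite(tab$amplitude) | !is.finite(tab$time) |
                 is.na(tab$trial))
  if (length(bad) > 0) {
    stop("malformed csv row at line ", bad[1] + 1L,
         " (counting the header as line 1)")
  }
  # epoch boundary: provenance changes or the time column restarts
  key <- paste(tab$label, tab$subject, tab$trial, sep = "\r")
  n <- nrow(tab)
  newblock <- c(TRUE, key[-1] != key[-n] | diff(tab$time) <= 0)
  block <- cumsum(newblock)
  epochs <- lapply(split(seq_len(n), block), function(idx) {
    emg_signal(tab$amplitude[idx], fs = fs, label = tab$label[idx[1]],
               subject_id = tab$subject[idx[1]],
               trial_index = tab$trial[idx[1]])
  })
  split_map <- if (!is.null(meta) && !is.null(meta$split)) {
    unlist(meta$split)
  } else NULL
  if (is.null(vocabulary)) vocabulary <- sort(unique(tab$label))
  gesture_dataset(unname(epochs), vocabulary, split = split_map)
}

#' Trial-based train/test split
#'
#' Partitions a dataset by trial index, mirroring the acquisition protocol in
#' which each gesture is repeated over six trials, two of which train the
#' classifier and four of which test it.
#'
#' @param dataset A [gesture_dataset].
#' @param train_trials Integer vector of trial indices assigned to training;
#'   must be a subset of the trial indices present. Default `c(1, 2)`.
#' @return A list with components `train` and `test`, each a
#'   [gesture_dataset]; together they partition the input epochs.
#' @examples
#' ds <- generate_dataset(synthesis_config("HG-6", n_subjects = 1,
#'                                         active_duration = 0.5,
#'                                         rest_duration = 0.5))
#' sp <- split_by_trial(ds)
#' c(train = length(sp$train), test = length(sp$test))
#' @export
split_by_trial <- function(dataset, train_trials = c(1L, 2L)) {
  stopifnot(inherits(dataset, "gesture_dataset"))
  train_trials <- as.integer(train_trials)
  present <- sort(unique(dataset_trials(dataset)))
  if (!all(train_trials %in% present)) {
    stop("train_trials must be a subset of the trial indices present (",
         paste(present, collapse = ", "), ")")
  }
  trials <- dataset_trials(dataset)
  in_train <- trials %in% train_trials
  split_map <- stats::setNames(
    ifelse(present %in% train_trials, "train", "test"), present)
  mk <- function(sel) {
    structure(list(epochs = dataset$epochs[sel],
                   vocabulary = dataset$vocabulary, split = split_map),
              class = "gesture_dataset")
  }
  list(train = mk(in_train), test = mk(!in_train))
}
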