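#' End-to-end pipeline settings
#'
#' Bundles the per-stage configurations of the full gesture-recognition
#' pipeline: simulate (or load) epochs, amplify, wavelet-denoise, decompose
#' by EMD, extract per-IMF features, split by trial, train the network on
#' the training trials and evaluate on the held-out trials.
#'
#' @param synthesis A [synthesis_config()] (ignored when `run_pipeline()` is
#'   given a dataset).
#' @param gain Amplifier gain (default 1; synthetic epochs are pre-scaled).
#' @param denoise A [denoise_config()].
#' @param emd An [emd_config()]; `max_imfs` also fixes the feature-vector
#'   length.
#' @param feature_form `"as-printed"` or `"conventional"`, see
#'   [feat_mean_power()].
#' @param hidden Hidden-layer sizes of the classifier.
#' @param train A [train_config()].
#' @param train_trials Trial indices used for training (default `c(1, 2)` of
#'   the six repetitions).
#' @param seed Run seed; overrides the synthesis and training seeds so one
#'   integer reproduces the whole run.
#' @param output_dir Optional directory; when set, every stage writes its
#'   artifact there (dataset, denoised dataset, IMF sets, feature matrix,
#'   model, confusion matrix, report, log).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthesis = synthesis_config(),
                            gain = 1,
                            denoise = denoise_config(),
                            emd = emd_config(),
                            feature_form = c("as-printed", "conventional"),
                            hidden = c(64L, 32L),
                            train = train_config(),
                            train_trials = c(1L, 2L),
                            seed = 1L,
                            output_dir = NULL) {
  feature_form <- match.arg(feature_form)
  stopifnot(inherits(synthesis, "synthesis_config"),
            inherits(denoise, "denoise_config"),
            inherits(emd, "emd_config"),
            inherits(train, "train_config"))
  seed <- as.integer(seed)
  synthesis$seed <- seed
  train$seed <- seed + 1L
  structure(
    list(synthesis = synthesis, gain = gain, denoise = denoise, emd = emd,
         feature_form = feature_form, hidden = hidden, train = train,
         train_trials = as.integer(train_trials), seed = seed,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr, log) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  log(sprintf("%-10s done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full gesture-recognition pipeline
#'
#' Executes simulate (or load) -> amplify -> denoise -> EMD -> features ->
#' trial split -> train -> evaluate, deterministically under
#' `config$seed`. Evaluation always happens on the held-out trials; a
#' `train_trials` setting that leaves no test epochs is refused.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional [gesture_dataset] to use instead of synthesis.
#' @param verbose Print one summary line per stage.
#' @return A list of class `pipeline_result`: `report`
#'   ([classification_metrics()] on the test trials), `confusion`, `model`,
#'   `features` (full feature matrix with a `role` column), `dataset`, and
#'   `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   synthesis = synthesis_config("HG-6", n_subjects = 2,
#'                                active_duration = 1, rest_duration = 1))
#' res <- run_pipeline(cfg, verbose = FALSE)
#' res$report$overall_accuracy
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }

  if (is.null(dataset)) {
    dataset <- stage("simulate", generate_dataset(config$synthesis), log)
  } else {
    stopifnot(inherits(dataset, "gesture_dataset"))
    log("simulate   skipped (dataset supplied)")
  }
  present <- sort(unique(dataset_trials(dataset)))
  if (all(present %in% config$train_trials)) {
    stop("train_trials covers every trial; refusing to evaluate on an ",
         "empty test set")
  }

  processed <- stage("preprocess", {
    eps <- lapply(dataset$epochs, function(e) {
      wavelet_denoise(amplify(e, config$gain), config$denoise)
    })
    gesture_dataset(eps, dataset$vocabulary, split = dataset$split)
  }, log)

  feats <- stage("features", {
    featurize_dataset(processed, config$emd, config$feature_form)
  }, log)

  sp <- stage("split", {
    in_train <- feats$trial %in% config$train_trials
    list(train = feats[in_train, , drop = FALSE],
         test = feats[!in_train, , drop = FALSE])
  }, log)

  fcols <- feature_columns(feats)
  model <- stage("train", {
    train_dnn(as.matrix(sp$train[, fcols]), sp$train$label,
              hidden = config$hidden, config = config$train,
              classes = dataset$vocabulary)
  }, log)

  result <- stage("evaluate", {
    pred <- predict(model, as.matrix(sp$test[, fcols]))
    cm <- confusion_matrix(sp$test$label, pred$label, dataset$vocabulary)
    list(confusion = cm, report = classification_metrics(cm))
  }, log)
  log(sprintf("test accuracy %.4f over %d epochs",
              result$report$overall_accuracy, nrow(sp$test)))

  feats$role <- ifelse(feats$trial %in% config$train_trials, "train", "test")

  if (!is.null(out_dir)) {
    write_epochs(dataset, file.path(out_dir, "dataset.rds"), "rds")
    write_epochs(processed, file.path(out_dir, "denoised.rds"), "rds")
    write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    saveRDS(model, file.path(out_dir, "model.rds"))
    write.csv(as.data.frame(unclass(result$confusion)),
              file.path(out_dir, "confusion.csv"))
    jsonlite::write_json(
      list(overall_accuracy = result$report$overall_accuracy,
           macro = as.list(result$report$macro),
           per_class = result$report$per_class,
           seed = config$seed),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  structure(
    list(report = result$report, confusion = result$confusion,
         model = model, features = feats, dataset = dataset,
         config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}
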