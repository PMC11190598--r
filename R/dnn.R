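#' Leaky rectified linear activation
#'
#' `f(x) = x` for `x > 0` and `0.01 x` otherwise; the hidden-unit
#' activation of the classifier.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @examples
#' lrelu(c(5, 0, -2))  # 5, 0, -0.02
#' @export
lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)

lrelu_grad <- function(x) ifelse(x > 0, 1, 0.01)

#' Softmax over logits
#'
#' `p_j = exp(x_j) / sum(exp(x_k))`, computed with max-subtraction so that
#' it is overflow-safe and exactly shift-invariant. Rows of a matrix are
#' treated as independent logit vectors.
#'
#' @param logits Numeric vector, or matrix with one logit vector per row.
#' @return Probabilities of the same shape; each vector is in (0, 1) and
#'   sums to 1.
#' @examples
#' softmax(c(log(2), 0))  # 2/3, 1/3
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

init_params <- function(layer_sizes, seed) {
  set.seed(seed)
  L <- length(layer_sizes) - 1
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- layer_sizes[l]
    weights[[l]] <- matrix(
      runif(fan_in * layer_sizes[l + 1], -1, 1) / sqrt(fan_in),
      nrow = fan_in)
    biases[[l]] <- numeric(layer_sizes[l + 1])
  }
  structure(
    list(layer_sizes = layer_sizes, weights = weights, biases = biases,
         seed = seed, classes = NULL, center = NULL, scale = NULL),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> layers:", paste(x$layer_sizes, collapse = " -> "),
      "\n")
  if (!is.null(x$classes)) {
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  }
  invisible(x)
}

# full forward pass keeping pre-activations (for backprop)
forward_pass <- function(params, X) {
  L <- length(params$weights)
  A <- list(X)           # activations entering each layer
  Z <- vector("list", L) # pre-activations
  a <- X
  for (l in seq_len(L)) {
    z <- a %*% params$weights[[l]] +
      matrix(params$biases[[l]], nrow(a), ncol(params$weights[[l]]),
             byrow = TRUE)
    Z[[l]] <- z
    a <- if (l < L) lrelu(z) else softmax(z)
    A[[l + 1]] <- a
  }
  list(A = A, Z = Z, probs = a)
}

#' Network forward pass
#'
#' Affine map plus leaky-ReLU through each hidden layer, affine map plus
#' softmax at the output. Feature standardization learnt at training time
#' (if any) is applied first.
#'
#' @param params A `network_params` object (from [train_dnn()] or internal
#'   initialization).
#' @param features Numeric feature vector, or a matrix with one example per
#'   row; width must equal the input layer size.
#' @return Probability vector (or matrix of row vectors) over the output
#'   classes.
#' @export
dnn_forward <- function(params, features) {
  stopifnot(inherits(params, "network_params"))
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != params$layer_sizes[1]) {
    stop("feature length ", ncol(X), " does not match input layer size ",
         params$layer_sizes[1])
  }
  if (!is.null(params$center)) {
    X <- sweep(sweep(X, 2, params$center), 2, params$scale, "/")
  }
  p <- forward_pass(params, X)$probs
  if (is.matrix(features)) p else drop(p)
}

# cross-entropy loss and analytic gradients for one batch (Y is a one-hot
# matrix); returns mean loss over the batch
dnn_gradients <- function(params, X, Y) {
  fw <- forward_pass(params, X)
  n <- nrow(X)
  L <- length(params$weights)
  eps <- 1e-12
  loss <- -sum(Y * log(fw$probs + eps)) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (fw$probs - Y) / n
  for (l in rev(seq_len(L))) {
    gW[[l]] <- t(fw$A[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$weights[[l]])) * lrelu_grad(fw$Z[[l - 1]])
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

#' Training settings for the classifier
#'
#' @param learning_rate Gradient-descent step size (default 0.01).
#' @param epochs Passes over the training data (default 1000). The
#'   trial-split protocol leaves only tens of training examples, so many
#'   passes are cheap and needed to fit the network.
#' @param batch_size Mini-batch size (default 16).
#' @param standardize_features If `TRUE` (default), z-score each feature
#'   using statistics of the training split; the per-IMF energy and entropy
#'   features span orders of magnitude, so standardization matters.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 1000L,
                         batch_size = 16L, standardize_features = TRUE,
                         seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (epochs < 1 || batch_size < 1) {
    stop("epochs and batch_size must be >= 1")
  }
  structure(
    list(learning_rate = learning_rate, epochs = epochs,
         batch_size = batch_size, loss = "cross-entropy",
         standardize_features = isTRUE(standardize_features),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train the feedforward classifier
#'
#' Mini-batch gradient descent on the cross-entropy between softmax outputs
#' and one-hot targets, with backpropagated gradients. Weights start from a
#' seeded uniform draw scaled by fan-in, so a fixed seed reproduces the
#' trained network exactly.
#'
#' @param x Numeric feature matrix, one example per row.
#' @param y Labels: a factor or character vector with at least two distinct
#'   classes present.
#' @param hidden Hidden-layer sizes (default `c(64, 32)`).
#' @param config A [train_config()].
#' @param classes Optional full class vector (ordered); defaults to the
#'   distinct values of `y`. Supply the dataset vocabulary so that classes
#'   absent from training keep their output unit.
#' @return A `network_params` object, with the per-epoch mean training loss
#'   in `$loss_history`.
#' @export
train_dnn <- function(x, y, hidden = c(64L, 32L), config = train_config(),
                      classes = NULL) {
  stopifnot(inherits(config, "train_config"))
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y disagree on the number of examples")
  if (is.null(classes)) classes <- sort(unique(y))
  if (!all(y %in% classes)) stop("labels outside the class set")
  if (length(unique(y)) < 2) {
    stop("training requires at least 2 distinct classes present")
  }
  center <- NULL
  scale_ <- NULL
  if (config$standardize_features) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  k <- length(classes)
  Y <- matrix(0, nrow(x), k)
  Y[cbind(seq_len(nrow(x)), match(y, classes))] <- 1

  params <- init_params(c(ncol(x), hidden, k), config$seed)
  params$classes <- classes
  n <- nrow(x)
  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      g <- dnn_gradients(params, x[idx, , drop = FALSE],
                         Y[idx, , drop = FALSE])
      if (!is.finite(g$loss)) {
        stop("training diverged (non-finite loss); reduce learning_rate = ",
             config$learning_rate)
      }
      for (l in seq_along(params$weights)) {
        params$weights[[l]] <- params$weights[[l]] -
          config$learning_rate * g$gW[[l]]
        params$biases[[l]] <- params$biases[[l]] -
          config$learning_rate * g$gb[[l]]
      }
      ep_loss <- ep_loss + g$loss
      nb <- nb + 1L
    }
    loss_history[ep] <- ep_loss / nb
  }
  params$center <- center
  params$scale <- scale_
  params$loss_history <- loss_history
  params
}

#' Predict gesture labels
#'
#' Runs the forward pass and takes the most probable class; ties break
#' toward the earliest class in the class order.
#'
#' @param object A trained `network_params`.
#' @param features Feature vector or matrix (one example per row).
#' @param ... Unused.
#' @return A list with `label` (character vector) and `probs` (probability
#'   matrix, one row per example).
#' @export
predict.network_params <- function(object, features, ...) {
  p <- dnn_forward(object, features)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  cls <- if (!is.null(object$classes)) object$classes else
    as.character(seq_len(ncol(p)))
  idx <- apply(p, 1, which.max)  # which.max: first maximum, lowest index
  list(label = cls[idx], probs = p)
}
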