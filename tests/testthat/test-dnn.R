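test_that("leaky ReLU follows its two branches", {
  expect_equal(lrelu(5), 5)
  expect_equal(lrelu(0), 0)
  expect_equal(lrelu(-2), -0.02)
  expect_equal(lrelu(c(-1, 1)), c(-0.01, 1))
})

test_that("softmax is a shift-invariant probability distribution", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(2)
  z <- rnorm(7) * 10
  p <- softmax(z)
  expect_true(all(p > 0 & p < 1))
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_equal(softmax(z + 123.4), p)
  expect_equal(softmax(c(1000, 1001)), softmax(c(0, 1)))  # overflow-safe
  # matrix rows are independent
  m <- softmax(rbind(z, z + 5))
  expect_equal(m[1, ], p)
})

test_that("forward pass matches an independently coded implementation", {
  p <- tiny_net(seed = 7)
  set.seed(1)
  x <- rnorm(5)
  # independent forward pass, plain loops
  a <- x
  for (l in 1:2) {
    z <- drop(a %*% p$weights[[l]]) + p$biases[[l]]
    a <- ifelse(z > 0, z, 0.01 * z)
  }
  z <- drop(a %*% p$weights[[3]]) + p$biases[[3]]
  expect_equal(dnn_forward(p, x), exp(z - max(z)) / sum(exp(z - max(z))),
               tolerance = 1e-12)
  # zero weights and biases -> uniform output
  p0 <- p
  p0$weights <- lapply(p0$weights, function(w) w * 0)
  expect_equal(unname(dnn_forward(p0, x)), rep(1 / 3, 3))
  expect_error(dnn_forward(p, rnorm(4)), "input layer")
})

test_that("backprop gradients match central finite differences", {
  p <- tiny_net(seed = 42)
  set.seed(5)
  X <- matrix(rnorm(4 * 5), 4, 5)
  Y <- diag(3)[c(1, 2, 3, 1), ]
  g <- emghht:::dnn_gradients(p, X, Y)
  loss_at <- function(params) emghht:::dnn_gradients(params, X, Y)$loss
  eps <- 1e-6
  worst <- 0
  for (l in seq_along(p$weights)) {
    for (idx in seq_len(min(10, length(p$weights[[l]])))) {
      q1 <- p; q1$weights[[l]][idx] <- q1$weights[[l]][idx] + eps
      q2 <- p; q2$weights[[l]][idx] <- q2$weights[[l]][idx] - eps
      num <- (loss_at(q1) - loss_at(q2)) / (2 * eps)
      ana <- g$gW[[l]][idx]
      worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-8))
    }
    for (idx in seq_along(p$biases[[l]])) {
      q1 <- p; q1$biases[[l]][idx] <- q1$biases[[l]][idx] + eps
      q2 <- p; q2$biases[[l]][idx] <- q2$biases[[l]][idx] - eps
      num <- (loss_at(q1) - loss_at(q2)) / (2 * eps)
      worst <- max(worst, abs(num - g$gb[[l]][idx]) /
                     max(abs(num), abs(g$gb[[l]][idx]), 1e-8))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training separates two seeded Gaussian clouds", {
  set.seed(31)
  n <- 100
  x <- rbind(matrix(rnorm(2 * n, mean = 0), ncol = 2),
             matrix(rnorm(2 * n, mean = 3), ncol = 2))
  y <- rep(c("a", "b"), each = n)
  cfg <- train_config(epochs = 200, seed = 31)
  m <- train_dnn(x, y, hidden = c(8), config = cfg)
  pred <- predict(m, x)
  expect_gte(mean(pred$label == y), 0.95)
  # probabilities returned are the forward-pass output
  expect_equal(pred$probs[1, ], unname(dnn_forward(m, x[1, ])))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(8)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c("u", "v", "w"), each = 20)
  cfg <- train_config(epochs = 20, seed = 99)
  m1 <- train_dnn(x, y, hidden = c(6), config = cfg)
  m2 <- train_dnn(x, y, hidden = c(6), config = cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$biases, m2$biases)
})

test_that("full-batch loss decreases monotonically at a small step size", {
  set.seed(12)
  x <- rbind(matrix(rnorm(40, mean = -1), ncol = 2),
             matrix(rnorm(40, mean = 1), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  cfg <- train_config(learning_rate = 0.005, epochs = 60, batch_size = 40,
                      seed = 3)
  m <- train_dnn(x, y, hidden = c(5), config = cfg)
  expect_true(all(diff(m$loss_history) <= 1e-6))
})

test_that("training contracts: class count, divergence, tie-breaks", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(train_dnn(x, rep("a", 10)), "2 distinct classes")
  set.seed(1)
  xb <- matrix(rnorm(40) * 1e6, 20, 2)
  yb <- rep(c("a", "b"), 10)
  expect_error(
    train_dnn(xb, yb, config = train_config(learning_rate = 1e6,
                                            standardize_features = FALSE)),
    "learning_rate")
  # uniform probabilities -> first class by tie-break
  p0 <- tiny_net(seed = 1)
  p0$weights <- lapply(p0$weights, function(w) w * 0)
  p0$biases <- lapply(p0$biases, function(b) b * 0)
  expect_identical(predict(p0, rnorm(5))$label, "1")
})
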