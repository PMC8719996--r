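#' @name bpnn
#' @title Three-layer back-propagation neural network
#' @description
#' A classic fully connected feedforward network with one hidden layer and
#' logistic sigmoid activation on both the hidden and output layers,
#' trained by error back-propagation (gradient descent on squared error).
#' Training stops when the mean squared error reaches the preset goal or
#' the epoch budget is exhausted.  Class decisions are the argmax of the
#' output activations (ties to the lower index).
NULL

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a network with uniform random weights
#'
#' Weights and thresholds are i.i.d. uniform on `[-0.5, 0.5]`.
#'
#' @param n_in,n_hidden,n_out layer sizes (`n_hidden` in 1..64)
#' @param seed integer seed (`NULL` draws from the current RNG)
#' @return a `bpnn_model`: `W1` (n_hidden x n_in), `b1`, `W2`
#'   (n_out x n_hidden), `b2`
#' @export
init_network <- function(n_in, n_hidden, n_out, seed = NULL) {
  check(is_count(n_in) && is_count(n_hidden) && is_count(n_out),
        "layer sizes must be positive integers")
  check(n_hidden <= 64, "n_hidden must be in 1..64")
  with_seed(seed, {
    new_bpnn(matrix(runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
             runif(n_hidden, -0.5, 0.5),
             matrix(runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden),
             runif(n_out, -0.5, 0.5))
  })
}

new_bpnn <- function(W1, b1, W2, b2) {
  check(all(is.finite(W1)) && all(is.finite(b1)) && all(is.finite(W2)) &&
          all(is.finite(b2)), "network parameters must be finite")
  check(nrow(W2) == length(b2) && ncol(W2) == nrow(W1) && nrow(W1) == length(b1),
        "inconsistent network dimensions")
  structure(list(n_in = ncol(W1), n_hidden = nrow(W1), n_out = nrow(W2),
                 W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2)),
            class = "bpnn_model")
}

#' Forward pass
#'
#' `h = sigmoid(W1 x + b1)`, `y = sigmoid(W2 h + b2)`.
#'
#' @param model a `bpnn_model`
#' @param x input vector of length `n_in`, or a matrix with one sample per row
#' @return output activations in `(0,1)`: a vector, or a matrix (samples x n_out)
#' @export
forward <- function(model, x) {
  check(inherits(model, "bpnn_model"), "model must be a bpnn_model")
  if (is.matrix(x)) {
    check(ncol(x) == model$n_in, "input dimension mismatch")
    H <- sigmoid(x %*% t(model$W1) + matrix(model$b1, nrow(x), model$n_hidden, byrow = TRUE))
    sigmoid(H %*% t(model$W2) + matrix(model$b2, nrow(x), model$n_out, byrow = TRUE))
  } else {
    check(length(x) == model$n_in, "input dimension mismatch")
    h <- sigmoid(as.vector(model$W1 %*% x) + model$b1)
    sigmoid(as.vector(model$W2 %*% h) + model$b2)
  }
}

# Gradient of the per-sample squared error E = sum((y - t)^2) / 2 with
# respect to every parameter; shared by training and the finite-difference
# tests.
bpnn_gradient <- function(model, x, target) {
  h <- sigmoid(as.vector(model$W1 %*% x) + model$b1)
  y <- sigmoid(as.vector(model$W2 %*% h) + model$b2)
  delta_out <- (y - target) * y * (1 - y)
  delta_hid <- as.vector(t(model$W2) %*% delta_out) * h * (1 - h)
  list(W1 = outer(delta_hid, x), b1 = delta_hid,
       W2 = outer(delta_out, h), b2 = delta_out, y = y)
}

mse_loss <- function(model, X, Y) mean((forward(model, X) - Y)^2)

#' Train by error back-propagation
#'
#' Online (per-sample) gradient descent on squared error with a seeded
#' per-epoch shuffle, or full-batch descent with `mode = "batch"`.
#' Training ends when the epoch-end mean squared error reaches
#' `error_goal` or after `max_epochs` epochs.
#'
#' @param model a `bpnn_model`
#' @param X samples x n_in matrix
#' @param Y one-hot targets, samples x n_out
#' @param learning_rate step size (> 0)
#' @param max_epochs epoch budget (>= 1)
#' @param error_goal MSE target (>= 0)
#' @param mode `"online"` or `"batch"`
#' @param momentum heavy-ball coefficient in `[0,1)`
#' @param weight_decay L2 penalty coefficient (>= 0)
#' @param seed shuffle seed
#' @return list of `model` (trained) and `history` (per-epoch MSE vector
#'   plus `stop_reason`, `"error_goal"` or `"max_epochs"`)
#' @export
train_backprop <- function(model, X, Y, learning_rate = 0.5, max_epochs = 200L,
                           error_goal = 1e-3, mode = c("online", "batch"),
                           momentum = 0, weight_decay = 0, seed = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  check(nrow(X) >= 1, "training set must be non-empty")
  check(nrow(X) == nrow(Y), "X and Y must have the same number of rows")
  check(ncol(X) == model$n_in && ncol(Y) == model$n_out,
        "data dimensions must match the network topology")
  check(learning_rate > 0, "learning_rate must be > 0")
  check(is_count(max_epochs), "max_epochs must be >= 1")
  check(error_goal >= 0, "error_goal must be >= 0")

  vel <- list(W1 = model$W1 * 0, b1 = model$b1 * 0,
              W2 = model$W2 * 0, b2 = model$b2 * 0)
  errs <- numeric(0)
  stop_reason <- "max_epochs"
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      if (mode == "online") {
        for (i in sample.int(nrow(X))) {
          g <- bpnn_gradient(model, X[i, ], Y[i, ])
          for (p in c("W1", "b1", "W2", "b2")) {
            vel[[p]] <- momentum * vel[[p]] -
              learning_rate * (g[[p]] + weight_decay * model[[p]])
            model[[p]] <- model[[p]] + vel[[p]]
          }
        }
      } else {
        acc <- list(W1 = model$W1 * 0, b1 = model$b1 * 0,
                    W2 = model$W2 * 0, b2 = model$b2 * 0)
        for (i in seq_len(nrow(X))) {
          g <- bpnn_gradient(model, X[i, ], Y[i, ])
          for (p in names(acc)) acc[[p]] <- acc[[p]] + g[[p]]
        }
        for (p in names(acc)) {
          vel[[p]] <- momentum * vel[[p]] -
            learning_rate * (acc[[p]] / nrow(X) + weight_decay * model[[p]])
          model[[p]] <- model[[p]] + vel[[p]]
        }
      }
      e <- mse_loss(model, X, Y)
      if (!is.finite(e))
        stop(sprintf(
          "back-propagation diverged (non-finite loss at epoch %d); reduce learning_rate = %g",
          epoch, learning_rate))
      errs <- c(errs, e)
      if (e <= error_goal) { stop_reason <- "error_goal"; break }
    }
  })
  list(model = model,
       history = structure(list(mse = errs, stop_reason = stop_reason),
                           class = "train_history"))
}

#' Predict class labels by forward-pass argmax
#'
#' @param model a `bpnn_model`
#' @param features matrix of samples (rows) or a single vector
#' @return integer labels in `0 .. n_out-1`, ties to the lower index
#' @export
predict_labels <- function(model, features) {
  if (!is.matrix(features)) features <- matrix(features, 1)
  Y <- forward(model, features)
  max.col(Y, "first") - 1L
}

#' Serialize / restore a network as JSON
#'
#' The round trip is bit-exact (17 significant digits).
#'
#' @param model a `bpnn_model`
#' @param path JSON file path
#' @export
save_bpnn <- function(model, path) {
  doc <- list(n_in = model$n_in, n_hidden = model$n_hidden, n_out = model$n_out,
              W1 = as.vector(model$W1), b1 = model$b1,
              W2 = as.vector(model$W2), b2 = model$b2)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_bpnn
#' @export
load_bpnn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_bpnn(matrix(doc$W1, doc$n_hidden, doc$n_in), doc$b1,
           matrix(doc$W2, doc$n_out, doc$n_hidden), doc$b2)
}
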