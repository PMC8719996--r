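test_that("initialization is seeded, bounded, and correctly sized", {
  a <- init_network(6, 2, 4, seed = 1)
  b <- init_network(6, 2, 4, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, init_network(6, 2, 4, seed = 2)))
  n_params <- length(a$W1) + length(a$b1) + length(a$W2) + length(a$b2)
  expect_equal(n_params, 6 * 2 + 2 + 2 * 4 + 4)  # 26
  expect_true(all(abs(c(a$W1, a$b1, a$W2, a$b2)) <= 0.5))
  expect_error(init_network(0, 2, 2), class = "obstruseg_validation_error")
  expect_error(init_network(2, 65, 2), class = "obstruseg_validation_error")
})

test_that("forward pass matches the logistic closed form", {
  m <- init_network(3, 2, 2, seed = 1)
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2[] <- 0
  expect_equal(forward(m, c(1, 2, 3)), c(0.5, 0.5))
  # single path: output = sigma(b2) = sigma(10)
  m1 <- init_network(1, 1, 1, seed = 1)
  m1$W1[] <- 0; m1$b1[] <- 0; m1$W2[] <- 0; m1$b2[] <- 10
  expect_equal(forward(m1, 0), 1 / (1 + exp(-10)), tolerance = 1e-12)
  set.seed(2)
  y <- forward(init_network(4, 3, 5, seed = 3), matrix(rnorm(40), 10, 4))
  expect_true(all(y > 0 & y < 1))
  expect_error(forward(m, c(1, 2)), class = "obstruseg_validation_error")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- init_network(4, 3, 2, seed = seed)
    x <- runif(4); target <- c(1, 0)
    g <- obstruseg:::bpnn_gradient(m, x, target)
    fd <- oracle_fd_gradient(m, x, target)
    for (p in c("W1", "b1", "W2", "b2")) {
      rel <- abs(g[[p]] - fd[[p]]) / pmax(abs(fd[[p]]), 1e-8)
      expect_lt(max(rel), 1e-5)
    }
  }
})

toy_xor_free <- function() {
  # linearly separable 2-class set in 2-D (four points)
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0L, 0L, 1L, 1L)
  Y <- matrix(0, 4, 2); Y[cbind(1:4, y + 1L)] <- 1
  list(X = X, Y = Y, y = y)
}

test_that("training solves a separable toy problem and keeps its history", {
  toy <- toy_xor_free()
  m <- init_network(2, 2, 2, seed = 4)
  fit <- train_backprop(m, toy$X, toy$Y, learning_rate = 1, max_epochs = 2000L,
                        error_goal = 1e-3, seed = 1)
  expect_equal(predict_labels(fit$model, toy$X), toy$y)
  expect_lte(length(fit$history$mse), 2000L)
  expect_true(fit$history$stop_reason %in% c("error_goal", "max_epochs"))

  one <- train_backprop(m, toy$X, toy$Y, max_epochs = 1L, seed = 1)
  expect_length(one$history$mse, 1L)
  expect_error(train_backprop(m, toy$X, toy$Y, max_epochs = 0L),
               class = "obstruseg_validation_error")
  expect_error(train_backprop(m, toy$X[0, , drop = FALSE], toy$Y[0, , drop = FALSE]),
               class = "obstruseg_validation_error")
})

test_that("full-batch loss is non-increasing at a small learning rate", {
  toy <- toy_xor_free()
  m <- init_network(2, 2, 2, seed = 6)
  fit <- train_backprop(m, toy$X, toy$Y, learning_rate = 0.01,
                        max_epochs = 200L, error_goal = 0, mode = "batch")
  expect_true(all(diff(fit$history$mse) <= 1e-12))
})

test_that("training reports divergence with the learning rate named", {
  toy <- toy_xor_free()
  m <- init_network(2, 2, 2, seed = 6)
  expect_error(train_backprop(m, toy$X, toy$Y, learning_rate = 50,
                              weight_decay = 5, momentum = 0.9,
                              max_epochs = 200L),
               "learning_rate")
})

test_that("label prediction follows the argmax with ties to lower index", {
  m <- init_network(3, 2, 3, seed = 1)
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2[] <- 0
  expect_equal(predict_labels(m, matrix(runif(9), 3)), c(0L, 0L, 0L))
  # sigma is monotone: argmax of outputs equals argmax of pre-activations
  m2 <- init_network(4, 3, 4, seed = 9)
  X <- matrix(rnorm(40), 10, 4)
  H <- 1 / (1 + exp(-(X %*% t(m2$W1) + matrix(m2$b1, 10, 3, byrow = TRUE))))
  pre <- H %*% t(m2$W2) + matrix(m2$b2, 10, 4, byrow = TRUE)
  expect_equal(predict_labels(m2, X), max.col(pre, "first") - 1L)
})

test_that("a single hidden layer fits step data to small error", {
  x <- matrix(seq(-1, 1, length.out = 40), ncol = 1)
  y <- matrix(as.numeric(x > 0), ncol = 1)
  m <- init_network(1, 4, 1, seed = 2)
  fit <- train_backprop(m, x, y, learning_rate = 2, max_epochs = 3000L,
                        error_goal = 1e-3, seed = 3)
  expect_lt(tail(fit$history$mse, 1), 1e-3)
})

test_that("JSON serialization round-trips bit-exactly", {
  m <- init_network(5, 3, 4, seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_bpnn(m, path)
  back <- load_bpnn(path)
  expect_identical(back$W1, m$W1)
  expect_identical(back$b1, m$b1)
  expect_identical(back$W2, m$W2)
  expect_identical(back$b2, m$b2)
})
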