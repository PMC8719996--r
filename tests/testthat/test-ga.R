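test_that("linear ranking matches the stated probabilities at the extremes", {
  pop <- rbind(c(1, 1), c(2, 2))
  # pressure 2: the worse individual has probability 0 (with replacement,
  # more draws than individuals is legitimate)
  sel <- rank_select(pop, c(0.1, 0.9), 50, pressure = 2, seed = 1)
  expect_true(all(sel[, 1] == 2))
  # equal fitness: empirical frequencies uniform within 3 sigma at 1e4 draws
  pop4 <- diag(4)
  sel4 <- rank_select(pop4, rep(1, 4), 1e4, pressure = 1.8, seed = 2)
  freq <- tabulate(max.col(sel4), nbins = 4) / 1e4
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e4)))
  expect_error(rank_select(pop, c(1, 2, 3), 1), class = "obstruseg_validation_error")
  expect_error(rank_select(pop, c(1, 2), 1, pressure = 1),
               class = "obstruseg_validation_error")
})

test_that("selection probability is non-decreasing in rank", {
  for (sp in c(1.2, 1.8, 2)) {
    N <- 7
    pr <- (2 - sp) / N + 2 * (seq_len(N) - 1) * (sp - 1) / (N * (N - 1))
    expect_true(all(diff(pr) >= 0))
    expect_equal(sum(pr), 1)
  }
})

test_that("fitness grouping splits into ordered near-equal groups", {
  pop <- matrix(0, 6, 2)
  g <- group_by_fitness(pop, c(3, 1, 6, 2, 5, 4), 3)
  expect_equal(lengths(g), c(2L, 2L, 2L), ignore_attr = TRUE)
  expect_setequal(g[[1]], c(3, 5))  # the two best
  g2 <- group_by_fitness(matrix(0, 7, 1), c(7, 6, 5, 4, 3, 2, 1), 3)
  expect_equal(lengths(g2), c(3L, 2L, 2L), ignore_attr = TRUE)
  g3 <- group_by_fitness(matrix(0, 5, 1), c(5, 1, 4, 2, 3), 2)
  expect_setequal(g3[[1]], c(1, 3, 5))  # fitnesses {5,4,3}
  expect_setequal(g3[[2]], c(2, 4))     # fitnesses {2,1}
  expect_error(group_by_fitness(matrix(0, 2, 1), c(1, 2), 3),
               class = "obstruseg_validation_error")
})

test_that("mixture offspring stay near a degenerate pool and are seeded", {
  pool <- matrix(rep(c(1, -2, 0.5), each = 6), 6)
  kids <- gmm_offspring(pool, 20, n_components = 2, seed = 3)
  expect_true(all(abs(sweep(kids, 2, c(1, -2, 0.5))) < 1e-2))
  expect_identical(gmm_offspring(pool, 5, seed = 8), gmm_offspring(pool, 5, seed = 8))
})

test_that("mixture offspring reproduce two gene-space clusters", {
  set.seed(4)
  pool <- rbind(matrix(rnorm(60, 0, 0.1), 20, 3),
                matrix(rnorm(30, 5, 0.1), 10, 3))
  kids <- gmm_offspring(pool, 1000, n_components = 2, seed = 5)
  near0 <- rowSums(abs(kids)) < 3
  expect_lt(abs(mean(near0) - 2 / 3), 3 * sqrt(2 / 9 / 1000) + 0.05)
})

test_that("crossover and mutation obey their rates", {
  p1 <- 1:6; p2 <- -(1:6)
  same <- crossover(p1, p2, rate = 0, seed = 1)
  expect_equal(same[[1]], p1)
  expect_equal(same[[2]], p2)
  full <- crossover(p1, p2, rate = 1, seed = 1)
  expect_equal(full[[1]], p2)
  expect_equal(full[[2]], p1)
  # complementarity under partial swap
  mix <- crossover(p1, p2, rate = 0.5, seed = 2)
  took_p2 <- mix[[1]] == p2
  expect_equal(mix[[2]][took_p2], p1[took_p2])

  expect_equal(mutate(p1, rate = 0, sd = 1, seed = 1), p1)
  big <- mutate(numeric(1e4), rate = 1, sd = 0.1, seed = 3)
  expect_equal(sd(big), 0.1, tolerance = 0.05)
})

test_that("evolution is elitist, deterministic, and stops on plateaus", {
  cfg <- default_config()$ga
  cfg$population_size <- 16L
  cfg$max_generations <- 30L
  cfg$seed <- 5L
  f <- function(x) -sum(x^2)
  r1 <- evolve(f, 3, cfg)
  r2 <- evolve(f, 3, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$history$best) >= 0))

  cfg$plateau_tol <- Inf
  cfg$plateau_window <- 4L
  rp <- evolve(f, 3, cfg)
  expect_length(rp$history$best, 4L)
  expect_equal(rp$history$stop_reason, "plateau")

  expect_error(evolve(function(x) NaN, 3, cfg), "generation")
})

test_that("chromosome coding is the exact inverse of model decoding", {
  m <- init_network(6, 2, 4, seed = 6)
  chrom <- encode_model(m)
  expect_length(chrom, 26)
  back <- decode_chromosome(chrom, c(6, 2, 4))
  expect_identical(back$W1, m$W1)
  expect_identical(back$b2, m$b2)
  expect_identical(encode_model(back), chrom)
  # zero chromosome: sigma(0) everywhere
  z <- decode_chromosome(numeric(26), c(6, 2, 4))
  expect_equal(forward(z, runif(6)), rep(0.5, 4))
  expect_error(decode_chromosome(numeric(25), c(6, 2, 4)),
               class = "obstruseg_validation_error")
})

test_that("GA-then-BP solves the separable toy problem end to end", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0L, 0L, 1L, 1L)
  Y <- matrix(0, 4, 2); Y[cbind(1:4, y + 1L)] <- 1
  fit <- optimize_bpnn(X, Y, c(2, 2, 2),
                       ga_cfg = list(population_size = 20L,
                                     max_generations = 20L, seed = 1L),
                       train_cfg = list(learning_rate = 1, max_epochs = 1000L))
  expect_equal(predict_labels(fit$model, X), y)
  expect_s3_class(fit$ga_history, "ga_history")
  # degenerate GA still yields a usable model
  tiny <- optimize_bpnn(X, Y, c(2, 2, 2),
                        ga_cfg = list(population_size = 4L,
                                      max_generations = 1L, seed = 2L),
                        train_cfg = list(max_epochs = 5L))
  expect_s3_class(tiny$model, "bpnn_model")
  expect_length(predict_labels(tiny$model, X), 4L)
})

test_that("GA initialization does not slow back-propagation down", {
  # paired comparison: epochs to reach the error goal from a GA seed vs a
  # random seed, median over 10 RNG streams
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  Y <- matrix(0, 4, 2); Y[cbind(1:4, c(1, 1, 2, 2))] <- 1
  goal <- 0.02
  epochs <- function(model, seed)
    length(train_backprop(model, X, Y, learning_rate = 1, max_epochs = 500L,
                          error_goal = goal, seed = seed)$history$mse)
  ga_e <- rand_e <- numeric(10)
  for (s in 1:10) {
    fitness <- function(chrom) {
      m <- decode_chromosome(chrom, c(2, 2, 2))
      1 / (1 + mean((forward(m, X) - Y)^2))
    }
    ga <- evolve(fitness, 12, list(population_size = 20L, max_generations = 15L,
                                   seed = s))
    ga_e[s] <- epochs(decode_chromosome(ga$best, c(2, 2, 2)), s)
    rand_e[s] <- epochs(init_network(2, 2, 2, seed = s), s)
  }
  expect_lte(median(ga_e), median(rand_e))
})
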