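#' @name ga
#' @title Improved genetic algorithm for network initialization
#' @description
#' A real-valued genetic algorithm that locates good initial weights and
#' thresholds for the block-classifier network.  Its "improved" operators:
#' selection by sorting (linear ranking), grouping of the population by
#' fitness, and generation of part of each new population by sampling a
#' Gaussian mixture fitted to the fittest groups -- new individuals that
#' match the characteristics of the current species.  Evolution stops when
#' the best fitness has stopped improving over a plateau window or at the
#' maximum generation count; the best chromosome is decoded into network
#' weights and handed to back-propagation for fine-tuning.
NULL

#' Linear-ranking ("sorting-based") parent selection
#'
#' With population size N and selection pressure `sp` in (1, 2], the
#' individual of rank r (worst r = 1, best r = N) is selected with
#' probability `(2 - sp)/N + 2 (r - 1)(sp - 1) / (N (N - 1))`; at sp = 2
#' the worst individual is never selected.  Tied fitnesses share their
#' average rank, so equal-fitness populations are sampled uniformly.
#' Sampling is with replacement.
#'
#' @param population N x L chromosome matrix
#' @param fitnesses length-N fitness vector (higher is better)
#' @param n_parents how many parents to draw
#' @param pressure selection pressure in (1, 2]
#' @param seed integer seed (`NULL`: current RNG)
#' @return n_parents x L matrix of selected chromosomes
#' @export
rank_select <- function(population, fitnesses, n_parents, pressure = 1.8,
                        seed = NULL) {
  population <- as.matrix(population)
  N <- nrow(population)
  check(length(fitnesses) == N, "one fitness per individual required")
  # sampling is with replacement, so n_parents may exceed N
  check(is_count(n_parents), "n_parents must be a positive integer")
  check(pressure > 1 && pressure <= 2, "pressure must lie in (1, 2]")
  ranks <- rank(fitnesses, ties.method = "average")  # worst gets rank 1
  prob <- (2 - pressure) / N + 2 * (ranks - 1) * (pressure - 1) / (N * (N - 1))
  idx <- with_seed(seed, sample.int(N, n_parents, replace = TRUE, prob = prob))
  population[idx, , drop = FALSE]
}

#' Group a population into contiguous fitness quantile groups
#'
#' Sorts by fitness (descending, ties by original index) and splits into
#' `n_groups` contiguous groups with sizes differing by at most one,
#' remainders going to the leading (fittest) groups.  Group 1 is fittest.
#'
#' @inheritParams rank_select
#' @param n_groups number of groups (>= 1, <= N)
#' @return list of index vectors into the original population
#' @export
group_by_fitness <- function(population, fitnesses, n_groups) {
  population <- as.matrix(population)
  N <- nrow(population)
  check(is_count(n_groups) && n_groups <= N, "n_groups must be in 1..N")
  ord <- order(-fitnesses, seq_len(N))
  sizes <- rep(N %/% n_groups, n_groups)
  extra <- N %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(ord, rep(seq_len(n_groups), times = sizes))
}

#' Generate offspring by sampling a Gaussian mixture over elite genes
#'
#' Fits [fit_gmm_em()] to the pooled chromosomes of the elite groups and
#' draws `n_offspring` new chromosomes from it.  A degenerate pool (all
#' identical) is handled by the covariance floor: offspring land within
#' its neighborhood.
#'
#' @param elite_pool matrix of pooled elite chromosomes (rows)
#' @param n_offspring number of chromosomes to generate
#' @param n_components mixture branch count (capped at the pool size)
#' @param seed integer seed (`NULL`: current RNG)
#' @return n_offspring x L matrix
#' @export
gmm_offspring <- function(elite_pool, n_offspring, n_components = 2L, seed = NULL) {
  elite_pool <- as.matrix(elite_pool)
  check(nrow(elite_pool) >= 1, "elite pool must be non-empty")
  k <- min(as.integer(n_components), nrow(elite_pool))
  run <- function() {
    params <- fit_gmm_em(elite_pool, k, seed = NULL, max_iter = 50L)
    sample_gmm(params, n_offspring, seed = NULL)
  }
  with_seed(seed, run())
}

#' Uniform crossover
#'
#' Each gene position swaps between the two children with probability
#' `rate`, so at `rate = 1` the children are complementary full swaps.
#'
#' @param p1,p2 parent chromosomes (equal length)
#' @param rate per-gene swap probability
#' @param seed integer seed (`NULL`: current RNG)
#' @return list of two child chromosomes
#' @export
crossover <- function(p1, p2, rate = 0.8, seed = NULL) {
  check(length(p1) == length(p2), "parents must have equal length")
  check(rate >= 0 && rate <= 1, "rate must lie in [0,1]")
  with_seed(seed, {
    swap <- runif(length(p1)) < rate
    c1 <- ifelse(swap, p2, p1)
    c2 <- ifelse(swap, p1, p2)
    list(c1, c2)
  })
}

#' Gaussian mutation
#'
#' Each gene is perturbed with probability `rate` by zero-mean Gaussian
#' noise of standard deviation `sd`.
#'
#' @param chrom chromosome vector
#' @param rate per-gene mutation probability
#' @param sd perturbation standard deviation (> 0)
#' @param seed integer seed (`NULL`: current RNG)
#' @return mutated chromosome
#' @export
mutate <- function(chrom, rate = 0.05, sd = 0.1, seed = NULL) {
  check(rate >= 0 && rate <= 1, "rate must lie in [0,1]")
  check(sd > 0, "sd must be > 0")
  with_seed(seed, {
    hit <- runif(length(chrom)) < rate
    chrom[hit] <- chrom[hit] + rnorm(sum(hit), 0, sd)
    chrom
  })
}

#' Run the improved genetic algorithm
#'
#' Per generation: evaluate fitness, carry over `elitism_count` elites,
#' draw parents by [rank_select()], produce a `1 - gmm_offspring_fraction`
#' share of the new pool by crossover + mutation and the rest by
#' [gmm_offspring()] over the fittest half of the fitness groups.  Stops
#' when the best fitness improved by less than `plateau_tol` over the last
#' `plateau_window` generations, or at `max_generations`.
#'
#' @param fitness_fn function(chromosome) -> finite scalar, higher better
#' @param chrom_length gene count
#' @param cfg list of GA settings, see `default_config()$ga`
#' @return list of `best` (chromosome), `best_fitness`, and `history`
#'   (`best`, `mean` per generation, `stop_reason` in
#'   `{"plateau", "max_generations"}`)
#' @export
#' @examples
#' cfg <- default_config()$ga
#' cfg$max_generations <- 5; cfg$seed <- 1
#' res <- evolve(function(x) -sum(x^2), 3, cfg)
evolve <- function(fitness_fn, chrom_length, cfg) {
  cfg <- merge_lists(default_config()$ga, cfg)
  N <- as.integer(cfg$population_size)
  check(N >= 4, "population_size must be >= 4")
  check(is_count(cfg$max_generations), "max_generations must be >= 1")
  check(is_count(cfg$n_fitness_groups) && cfg$n_fitness_groups >= 2,
        "n_fitness_groups must be >= 2")
  check(cfg$gmm_offspring_fraction >= 0 && cfg$gmm_offspring_fraction <= 1,
        "gmm_offspring_fraction must lie in [0,1]")
  check(is_count(cfg$elitism_count) && cfg$elitism_count < N,
        "elitism_count must be in 1..N-1")
  check(is_count(cfg$plateau_window), "plateau_window must be >= 1")

  with_seed(cfg$seed, {
    pop <- matrix(runif(N * chrom_length, cfg$init_range[1], cfg$init_range[2]),
                  N, chrom_length)
    best_trace <- numeric(0); mean_trace <- numeric(0)
    best_chrom <- NULL; best_fit <- -Inf
    stop_reason <- "max_generations"

    for (g in seq_len(cfg$max_generations)) {
      fit <- apply(pop, 1, fitness_fn)
      if (any(!is.finite(fit)))
        stop(sprintf("non-finite fitness encountered at generation %d", g))
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]
        best_chrom <- pop[gen_best, ]
      }
      best_trace <- c(best_trace, best_fit)
      mean_trace <- c(mean_trace, mean(fit))
      log_msg("generation %d: best %.6g mean %.6g", g, best_fit, mean(fit),
              seed = cfg$seed)

      if (g >= cfg$plateau_window &&
          best_trace[g] - best_trace[g - cfg$plateau_window + 1] < cfg$plateau_tol) {
        stop_reason <- "plateau"
        break
      }
      if (g == cfg$max_generations) break

      elite_idx <- order(-fit, seq_len(N))[seq_len(cfg$elitism_count)]
      n_rest <- N - cfg$elitism_count
      n_gmm <- round(cfg$gmm_offspring_fraction * n_rest)
      n_cx <- n_rest - n_gmm

      kids <- matrix(NA_real_, 0, chrom_length)
      if (n_cx > 0) {
        parents <- rank_select(pop, fit, 2L * ceiling(n_cx / 2), cfg$pressure)
        for (i in seq_len(ceiling(n_cx / 2))) {
          pr <- crossover(parents[2 * i - 1, ], parents[2 * i, ], cfg$crossover_rate)
          kids <- rbind(kids, pr[[1]], pr[[2]])
        }
        kids <- kids[seq_len(n_cx), , drop = FALSE]
        for (i in seq_len(n_cx))
          kids[i, ] <- mutate(kids[i, ], cfg$mutation_rate, cfg$mutation_sd)
      }
      if (n_gmm > 0) {
        groups <- group_by_fitness(pop, fit, cfg$n_fitness_groups)
        pool_idx <- unlist(groups[seq_len(ceiling(cfg$n_fitness_groups / 2))])
        g_kids <- gmm_offspring(pop[pool_idx, , drop = FALSE], n_gmm,
                                cfg$gmm_components)
        kids <- rbind(kids, g_kids)
      }
      pop <- rbind(pop[elite_idx, , drop = FALSE], kids)
    }

    list(best = best_chrom, best_fitness = best_fit,
         history = structure(list(best = best_trace, mean = mean_trace,
                                  stop_reason = stop_reason),
                             class = "ga_history"))
  })
}

# --- chromosome <-> network coding ------------------------------------------

topology_length <- function(n_in, n_hidden, n_out)
  n_in * n_hidden + n_hidden + n_hidden * n_out + n_out

#' Decode a chromosome into a network / encode a network into a chromosome
#'
#' Gene order (fixed, documented): `W1` column-major, `b1`, `W2`
#' column-major, `b2`.  `encode_model(decode_chromosome(c, t))` is the
#' identity.
#'
#' @param chrom flat numeric gene vector
#' @param topology integer vector `(n_in, n_hidden, n_out)`
#' @return `decode_chromosome`: a `bpnn_model`; `encode_model`: a numeric vector
#' @export
decode_chromosome <- function(chrom, topology) {
  n_in <- topology[1]; n_h <- topology[2]; n_out <- topology[3]
  L <- topology_length(n_in, n_h, n_out)
  check(length(chrom) == L,
        sprintf("chromosome length %d does not match topology (expect %d)",
                length(chrom), L))
  i <- 0
  take <- function(k) { v <- chrom[(i + 1):(i + k)]; i <<- i + k; v }
  new_bpnn(matrix(take(n_in * n_h), n_h, n_in), take(n_h),
           matrix(take(n_h * n_out), n_out, n_h), take(n_out))
}

#' @rdname decode_chromosome
#' @param model a `bpnn_model`
#' @export
encode_model <- function(model) {
  check(inherits(model, "bpnn_model"), "model must be a bpnn_model")
  c(as.vector(model$W1), model$b1, as.vector(model$W2), model$b2)
}

#' GA-initialized back-propagation training
#'
#' The full optimization of the block classifier: the genetic algorithm
#' searches weight space with fitness `1 / (1 + MSE)` of the decoded
#' network on the training set; the best chromosome is decoded and
#' fine-tuned by [train_backprop()].
#'
#' @param X samples x n_in feature matrix
#' @param Y one-hot targets (samples x n_out)
#' @param topology `(n_in, n_hidden, n_out)`
#' @param ga_cfg GA settings (see `default_config()$ga`)
#' @param train_cfg back-propagation settings (see `default_config()$bpnn`)
#' @return list of `model`, `ga_history`, `train_history`
#' @export
optimize_bpnn <- function(X, Y, topology, ga_cfg = list(), train_cfg = list()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  check(nrow(X) >= 1, "training data must be non-empty")
  ga_cfg <- merge_lists(default_config()$ga, ga_cfg)
  train_cfg <- merge_lists(default_config()$bpnn, train_cfg)
  fitness <- function(chrom) {
    m <- decode_chromosome(chrom, topology)
    1 / (1 + mse_loss(m, X, Y))
  }
  ga <- evolve(fitness, topology_length(topology[1], topology[2], topology[3]),
               ga_cfg)
  init <- decode_chromosome(ga$best, topology)
  tr <- train_backprop(init, X, Y,
                       learning_rate = train_cfg$learning_rate,
                       max_epochs = train_cfg$max_epochs,
                       error_goal = train_cfg$error_goal,
                       mode = train_cfg$mode,
                       momentum = train_cfg$momentum,
                       weight_decay = train_cfg$weight_decay,
                       seed = ga_cfg$seed)
  list(model = tr$model, ga_history = ga$history, train_history = tr$history)
}
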