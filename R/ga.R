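#' Genetic-algorithm configuration
#'
#' Real-coded GA over a box of actual-unit conditions: seeded uniform
#' initialization, tournament selection of size 2, arithmetic (blend)
#' crossover with a seeded mixing weight, per-gene uniform-reset mutation,
#' and elitist carry-over of the best individual(s).
#'
#' @param bounds 2 x k matrix (rows `low`, `high`) or list of length-2
#'   vectors giving the search box per variable.
#' @param population_size individuals per generation (default 50).
#' @param generations fixed iteration budget (default 600).
#' @param crossover_prob probability a selected pair is blended (default 0.8).
#' @param mutation_prob per-gene reset probability (default 0.1).
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param stagnation_patience optional early stop after this many
#'   generations without best-fitness improvement (`Inf` = fixed budget).
#' @param seed integer seed; the run depends on nothing else.
#' @return a `ga_config` list.
#' @export
ga_config <- function(bounds, population_size = 50L, generations = 600L,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      elitism = 1L, stagnation_patience = Inf, seed = 1L) {
  if (is.list(bounds)) bounds <- vapply(bounds, function(b) c(b[1], b[2]),
                                        numeric(2))
  bounds <- as.matrix(bounds)
  rownames(bounds) <- c("low", "high")
  if (any(bounds["low", ] >= bounds["high", ])) {
    stop("each variable needs low < high bounds", call. = FALSE)
  }
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            elitism >= 0L, elitism < population_size)
  structure(list(bounds = bounds,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism),
                 stagnation_patience = stagnation_patience,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Maximize a yield predictor with a real-coded genetic algorithm
#'
#' @param fitness function taking a length-k actual-unit vector and
#'   returning a finite predicted yield. Individuals on which `fitness` is
#'   non-finite are rejected and resampled uniformly in the box (an
#'   all-rejected generation is an error).
#' @param config a [ga_config()].
#' @param initial optional matrix of individuals injected into generation 0
#'   (rows clipped to the box; extra rows dropped); the rest of the initial
#'   population is sampled uniformly.
#' @return object of class `ga_result`: `best_point`, `best_fitness`, and a
#'   per-generation `trace` data.frame (`generation`, `best_fitness`,
#'   `mean_fitness`). With `elitism >= 1` the best-fitness trace is
#'   non-decreasing. Deterministic given the config seed.
#' @export
run_ga <- function(fitness, config, initial = NULL) {
  with_seed(config$seed, ga_engine(fitness, config, initial))
}

ga_engine <- function(fitness, config, initial) {
  lo <- config$bounds["low", ]
  hi <- config$bounds["high", ]
  k <- length(lo)
  np <- config$population_size

  rand_ind <- function(n) {
    matrix(stats::runif(n * k, rep(lo, each = n), rep(hi, each = n)), n, k)
  }
  eval_pop <- function(pop) {
    f <- apply(pop, 1L, fitness)
    for (tries in 1:100) {
      bad <- which(!is.finite(f))
      if (!length(bad)) return(list(pop = pop, fit = f))
      pop[bad, ] <- rand_ind(length(bad))
      f[bad] <- apply(pop[bad, , drop = FALSE], 1L, fitness)
    }
    stop("fitness domain error: could not sample individuals with finite fitness",
         call. = FALSE)
  }

  pop <- rand_ind(np)
  if (!is.null(initial)) {
    ini <- as.matrix(initial)
    ini <- ini[seq_len(min(nrow(ini), np)), , drop = FALSE]
    ini <- pmin(pmax(ini, rep(lo, each = nrow(ini))), rep(hi, each = nrow(ini)))
    pop[seq_len(nrow(ini)), ] <- ini
  }
  ev <- eval_pop(pop)
  pop <- ev$pop; fit <- ev$fit

  trace <- data.frame(generation = 0:config$generations,
                      best_fitness = NA_real_, mean_fitness = NA_real_)
  trace[1L, 2:3] <- c(max(fit), mean(fit))
  stagnant <- 0L
  last_gen <- 0L

  for (gen in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]

    # tournament selection, size 2
    n_children <- np - config$elitism
    a <- sample.int(np, n_children, replace = TRUE)
    b <- sample.int(np, n_children, replace = TRUE)
    parents <- pop[ifelse(fit[a] >= fit[b], a, b), , drop = FALSE]

    # arithmetic crossover on consecutive pairs
    children <- parents
    for (i in if (n_children >= 2L) seq(1L, n_children - 1L, by = 2L) else integer(0)) {
      if (stats::runif(1) < config$crossover_prob) {
        wgt <- stats::runif(1)
        p1 <- parents[i, ]; p2 <- parents[i + 1L, ]
        children[i, ] <- wgt * p1 + (1 - wgt) * p2
        children[i + 1L, ] <- (1 - wgt) * p1 + wgt * p2
      }
    }

    # per-gene uniform reset mutation
    mut <- matrix(stats::runif(n_children * k) < config$mutation_prob,
                  n_children, k)
    if (any(mut)) {
      idx <- which(mut, arr.ind = TRUE)
      children[mut] <- lo[idx[, 2L]] +
        stats::runif(nrow(idx)) * (hi - lo)[idx[, 2L]]
    }

    pop <- rbind(elite, children)
    ev <- eval_pop(pop)
    pop <- ev$pop; fit <- ev$fit
    trace[gen + 1L, 2:3] <- c(max(fit), mean(fit))
    last_gen <- gen

    improved <- trace$best_fitness[gen + 1L] > trace$best_fitness[gen] + 1e-15
    stagnant <- if (improved) 0L else stagnant + 1L
    if (stagnant >= config$stagnation_patience) break
  }
  trace <- trace[seq_len(last_gen + 1L), ]
  best <- which.max(fit)
  structure(list(best_point = unname(pop[best, ]),
                 best_fitness = unname(fit[best]),
                 trace = trace),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best fitness %.4f at (%s) after %d generations\n",
              x$best_fitness, paste(signif(x$best_point, 6), collapse = ", "),
              max(x$trace$generation)))
  invisible(x)
}

#' Train the neural surrogate and maximize it with the GA
#'
#' Trains the backpropagation network on the dataset, wraps its forward pass
#' as the GA fitness, injects the dataset's own input points into the
#' initial population, and runs the GA over the experimental box. Reported
#' conditions are in actual units.
#'
#' @param data a `doe_dataset` with observed yields.
#' @param train_cfg a [train_config()].
#' @param ga_cfg a [ga_config()]; defaults to the dataset's factor box with
#'   package defaults and the training seed.
#' @return list with `params` (the trained `mlp_params`), `history`, and
#'   `ga` (the `ga_result`).
#' @export
ga_bp_pipeline <- function(data, train_cfg = train_config(), ga_cfg = NULL) {
  trained <- train_mlp(data, train_cfg)
  if (is.null(ga_cfg)) {
    bounds <- vapply(data$factors, function(f) c(f$low, f$high), numeric(2))
    rownames(bounds) <- c("low", "high")
    ga_cfg <- ga_config(bounds, seed = derive_seed(train_cfg$seed, "ga"))
  }
  fitness <- function(x) mlp_predict_quiet(trained$params, x)
  seed_pop <- as.matrix(data$runs[, vapply(data$factors, `[[`, "", "name"),
                                  drop = FALSE])
  res <- run_ga(fitness, ga_cfg, initial = seed_pop)
  list(params = trained$params, history = trained$history, ga = res)
}

# forward pass without the extrapolation warning (the GA stays in the box,
# but the box corners can sit slightly outside the BBD training range)
mlp_predict_quiet <- function(params, x) {
  suppressWarnings(mlp_predict(params, x))
}

#' Write a GA fitness trace as CSV
#'
#' Columns `generation,best_fitness,mean_fitness`, for convergence plots.
#'
#' @param result a `ga_result`.
#' @param path output CSV path.
#' @export
write_ga_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
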