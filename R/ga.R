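# Genetic-algorithm descriptor subset selection over MLR models.

#' Genetic-algorithm search settings
#'
#' Defaults follow common GA-MLR practice: population 100, 300 generations,
#' crossover probability 0.8, per-offspring mutation probability 0.05,
#' tournament size 3, one elite individual, leave-one-out Q2 as fitness,
#' and fixed-size chromosomes of 6 descriptors (the size of the published
#' best model).
#'
#' @param population_size number of chromosomes (>= 4).
#' @param generations number of generations.
#' @param p_crossover crossover probability in `[0, 1]`.
#' @param p_mutation per-offspring mutation probability in `[0, 1]`.
#' @param subset_size number of descriptors per chromosome (>= 1).
#' @param tournament_size selection tournament size.
#' @param elitism number of best individuals copied unchanged.
#' @param fitness `"q2_loo"` or `"r2_adj"`.
#' @param seed integer seed making the whole search deterministic.
#' @return list of class `ga_control`.
#' @export
ga_control <- function(population_size = 100L, generations = 300L,
                       p_crossover = 0.8, p_mutation = 0.05,
                       subset_size = 6L, tournament_size = 3L,
                       elitism = 1L, fitness = c("q2_loo", "r2_adj"),
                       seed = 1L) {
  fitness <- match.arg(fitness)
  stopifnot(population_size >= 4L, generations >= 1L,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            subset_size >= 1L, tournament_size >= 1L, elitism >= 0L)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 subset_size = as.integer(subset_size),
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism), fitness = fitness,
                 seed = as.integer(seed)),
            class = "ga_control")
}

.ga_fitness <- function(matrix, subset, criterion) {
  value <- tryCatch({
    if (criterion == "q2_loo") {
      q2_loo(matrix, subset)
    } else {
      fit <- fit_mlr(matrix, subset)
      n <- fit$stats$n; q <- fit$stats$q
      1 - (1 - fit$stats$r2) * (n - 1) / (n - q - 1)
    }
  }, error = function(e) -Inf)   # singular subsets lose the tournament
  if (!is.finite(value)) -Inf else value
}

#' Select a descriptor subset by GA-MLR
#'
#' Searches fixed-size descriptor subsets with a genetic algorithm:
#' chromosomes are subsets of `subset_size` column names, parents are
#' chosen by tournament, uniform crossover keeps the genes the parents
#' share and fills the rest from their symmetric difference, and mutation
#' swaps one selected descriptor for an unselected one (so subset size is
#' preserved). Fitness is the leave-one-out Q2 (or adjusted R2) of the MLR
#' model on the subset; elitism makes the best-so-far fitness trace
#' non-decreasing. Fully deterministic for a fixed `cfg$seed`.
#'
#' @param matrix a (pre-filtered) `mixture_matrix`.
#' @param cfg a [ga_control()] object.
#' @return list with `subset` (character), `model` (the refitted
#'   [fit_mlr()] model), `fitness` (best value) and `trace` (best fitness
#'   per generation).
#' @export
ga_select <- function(matrix, cfg = ga_control()) {
  stopifnot(inherits(matrix, "mixture_matrix"), inherits(cfg, "ga_control"))
  pool <- colnames(matrix$X)
  k <- cfg$subset_size
  if (k > length(pool)) {
    stop("subset_size (", k, ") exceeds the descriptor pool (",
         length(pool), ")", call. = FALSE)
  }
  if (k == length(pool)) {
    model <- fit_mlr(matrix, pool)
    f <- .ga_fitness(matrix, pool, cfg$fitness)
    return(list(subset = pool, model = model, fitness = f, trace = f))
  }

  withr::with_seed(cfg$seed, {
    pop <- replicate(cfg$population_size, sort(sample(pool, k)),
                     simplify = FALSE)
    fit <- vapply(pop, .ga_fitness, numeric(1),
                  matrix = matrix, criterion = cfg$fitness)
    best_subset <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    trace <- numeric(cfg$generations)

    tournament <- function() {
      cand <- sample.int(cfg$population_size, cfg$tournament_size,
                         replace = TRUE)
      pop[[cand[which.max(fit[cand])]]]
    }
    crossover <- function(p1, p2) {
      core <- intersect(p1, p2)
      rest <- setdiff(union(p1, p2), core)
      extra <- k - length(core)
      sort(c(core, if (extra > 0) sample(rest, extra)))
    }
    mutate <- function(ch) {
      out <- setdiff(pool, ch)
      ch[sample.int(k, 1L)] <- out[sample.int(length(out), 1L)]
      sort(ch)
    }

    for (g in seq_len(cfg$generations)) {
      elite <- pop[order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]]
      children <- vector("list", cfg$population_size - cfg$elitism)
      for (c_ in seq_along(children)) {
        p1 <- tournament()
        child <- if (stats::runif(1) < cfg$p_crossover) {
          crossover(p1, tournament())
        } else p1
        if (stats::runif(1) < cfg$p_mutation) child <- mutate(child)
        children[[c_]] <- child
      }
      pop <- c(elite, children)
      fit <- vapply(pop, .ga_fitness, numeric(1),
                    matrix = matrix, criterion = cfg$fitness)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_subset <- pop[[which.max(fit)]]
      }
      trace[g] <- best_fit
    }
  })
  list(subset = best_subset, model = fit_mlr(matrix, best_subset),
       fitness = best_fit, trace = trace)
}
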