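#' Configuration for the genetic descriptor-subset search
#'
#' Defaults follow the GFA settings used for small congeneric QSAR series:
#' fixed equation length 3, population 1000, up to 500 generations, mutation
#' probability 0.1, fitness = training-set R2. Selection is tournament of
#' size 2 with elitism; the search stops early after `stagnation_patience`
#' generations without improvement of the best fitness.
#'
#' @param equation_length descriptors per candidate model.
#' @param population_size individuals per generation.
#' @param max_generations generation cap.
#' @param mutation_probability per-individual probability that one descriptor
#'   is swapped for an unused one.
#' @param elitism_count individuals copied unchanged into the next generation.
#' @param tournament_size tournament size for parent selection.
#' @param stagnation_patience early-stop patience in generations.
#' @param seed RNG seed; all search randomness derives from it.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(equation_length = 3, population_size = 1000,
                      max_generations = 500, mutation_probability = 0.1,
                      elitism_count = 10, tournament_size = 2,
                      stagnation_patience = 50, seed = 1L) {
  stopifnot(equation_length >= 1, population_size >= 2,
            max_generations >= 1,
            mutation_probability >= 0, mutation_probability <= 1,
            elitism_count >= 0, tournament_size >= 1)
  structure(list(equation_length = as.integer(equation_length),
                 population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 mutation_probability = mutation_probability,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 stagnation_patience = as.integer(stagnation_patience),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Initial random population of descriptor subsets
#'
#' @param cfg a [ga_config()].
#' @param m total descriptor count to draw from.
#' @return list of sorted integer vectors, each of length
#'   `cfg$equation_length` with distinct entries; duplicates may occur
#'   across individuals.
#' @export
ga_init_population <- function(cfg, m) {
  L <- cfg$equation_length
  if (m < L + 1 || choose(m, L) < 2)
    stop_pq("search space too small: C(%d, %d) subsets", m, L,
            class = "search_space_error")
  replicate(cfg$population_size, sort(sample.int(m, L)), simplify = FALSE)
}

#' Uniform crossover of two descriptor subsets
#'
#' Offspring descriptor ids are drawn uniformly without replacement from the
#' union of the parents' ids, so any collision between shared parent genes is
#' repaired by construction. Each offspring has exactly the parents' length.
#'
#' @param a,b sorted integer vectors of equal length (parent subsets).
#' @return list of two offspring (sorted integer vectors).
#' @export
ga_crossover <- function(a, b) {
  pool <- union(a, b)
  L <- length(a)
  list(sort(sample(pool, L)), sort(sample(pool, L)))
}

#' Point mutation of a descriptor subset
#'
#' With probability `cfg$mutation_probability`, one uniformly chosen
#' descriptor in the subset is replaced by a uniformly chosen descriptor not
#' currently in it; otherwise the subset is returned unchanged.
#'
#' @param ids sorted integer vector (the individual).
#' @param cfg a [ga_config()].
#' @param m total descriptor count.
#' @export
ga_mutate <- function(ids, cfg, m) {
  if (stats::runif(1) >= cfg$mutation_probability) return(ids)
  out <- setdiff(seq_len(m), ids)
  if (length(out) == 0) return(ids)
  pos <- sample.int(length(ids), 1)
  ids[pos] <- out[sample.int(length(out), 1)]
  sort(ids)
}

# Training-R2 fitness of one subset; singular fits score 0 with a warning.
ga_fitness <- function(cols, X, y) {
  fit <- tryCatch(ols_core(X[, cols, drop = FALSE], y),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular fit for subset {", paste(colnames(X)[cols], collapse = ","),
            "}; fitness set to 0")
    return(0)
  }
  ss <- sum_of_squares(y, fit$fitted)
  if (ss$tss == 0) 0 else ss$ess / ss$tss
}

#' Genetic-algorithm descriptor-subset selection
#'
#' Evolves fixed-length descriptor subsets to maximize the training-set R2
#' of the corresponding OLS model (GFA-style search without spline terms).
#' Tournament selection, uniform crossover over the parent union, point
#' mutation, and elitism; fitness values are memoized per descriptor set
#' since the fitness landscape is static. Fully deterministic for a fixed
#' `cfg$seed`.
#'
#' @param ds a [qsar_dataset()] (training compounds).
#' @param response `"Y1"`, `"Y2"` or `"Y3"`.
#' @param cfg a [ga_config()].
#' @param top number of distinct top models to return fitted.
#' @return object of class `ga_result`: `ranked_models` (data.frame of
#'   de-duplicated subsets with fitness, best first), `best` (a fitted
#'   [mlr_fit()] model for the top subset), `fitness_history`,
#'   `generations_run`, `seed`.
#' @export
ga_select <- function(ds, response = c("Y1", "Y2", "Y3"), cfg = ga_config(),
                      top = 10) {
  response <- match.arg(response)
  X <- unclass(ds$descriptors)
  y <- ds$activities[[response]]
  m <- ncol(X)
  L <- cfg$equation_length
  if (nrow(X) <= L + 2)
    stop_pq("too few training rows (%d) for equation length %d", nrow(X), L,
            class = "argument_error")
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  score <- function(ids) {
    key <- paste(ids, collapse = ",")
    v <- memo[[key]]
    if (is.null(v)) {
      v <- ga_fitness(ids, X, y)
      memo[[key]] <- v
    }
    v
  }
  with_seed(cfg$seed, {
    pop <- ga_init_population(cfg, m)
    fit <- vapply(pop, score, numeric(1))
    history <- numeric(0)
    best_fit <- -Inf
    stagnant <- 0L
    gens <- 0L
    for (g in seq_len(cfg$max_generations)) {
      gens <- g
      ord <- order(fit, decreasing = TRUE)
      gen_best <- fit[ord[1]]
      history <- c(history, gen_best)
      if (gen_best > best_fit + 1e-12) {
        best_fit <- gen_best
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      if (stagnant >= cfg$stagnation_patience) break
      elite <- pop[ord[seq_len(min(cfg$elitism_count, length(pop)))]]
      nxt <- elite
      while (length(nxt) < cfg$population_size) {
        pa <- tournament_pick(fit, cfg$tournament_size)
        pb <- tournament_pick(fit, cfg$tournament_size)
        kids <- ga_crossover(pop[[pa]], pop[[pb]])
        kids <- lapply(kids, ga_mutate, cfg = cfg, m = m)
        nxt <- c(nxt, kids)
      }
      pop <- nxt[seq_len(cfg$population_size)]
      fit <- vapply(pop, score, numeric(1))
    }
    # rank all evaluated subsets (memo holds the full search history)
    keys <- ls(memo)
    fits <- vapply(keys, function(k) memo[[k]], numeric(1))
    ord <- order(-fits, keys)                    # fitness desc, then lexicographic
    ranked <- data.frame(
      subset = vapply(keys[ord], function(k)
        paste(colnames(X)[as.integer(strsplit(k, ",")[[1]])], collapse = "+"),
        character(1)),
      fitness = fits[ord], stringsAsFactors = FALSE, row.names = NULL)
    best_ids <- colnames(X)[as.integer(strsplit(keys[ord][1], ",")[[1]])]
    best_model <- mlr_fit(ds, response, best_ids)
    structure(list(ranked_models = utils::head(ranked, max(top, 1)),
                   best = best_model,
                   n_evaluated = length(keys),
                   fitness_history = history,
                   generations_run = gens,
                   seed = cfg$seed),
              class = "ga_result")
  })
}

tournament_pick <- function(fit, size) {
  idx <- sample.int(length(fit), size, replace = TRUE)
  idx[which.max(fit[idx])]
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA descriptor selection: %d generations, %d distinct subsets evaluated\n",
              x$generations_run, x$n_evaluated))
  cat(sprintf("Best model (fitness R2 = %.4f):\n", x$ranked_models$fitness[1]))
  print(x$best)
  invisible(x)
}

#' Exhaustive best descriptor subset
#'
#' Enumerates every descriptor subset of the given length and returns the
#' one maximizing training R2 (ties broken lexicographically on descriptor
#' ids). Used as an oracle for the genetic search on small descriptor pools.
#'
#' @param ds a [qsar_dataset()].
#' @param response activity id.
#' @param length subset size.
#' @return list: `descriptor_ids`, `fitness`, `model` (fitted `qsar_mlr`),
#'   `n_evaluated`.
#' @export
exhaustive_best <- function(ds, response = c("Y1", "Y2", "Y3"), length = 3) {
  response <- match.arg(response)
  X <- unclass(ds$descriptors)
  y <- ds$activities[[response]]
  m <- ncol(X)
  if (choose(m, length) > 1e5)
    stop_pq("C(%d, %d) exceeds the exhaustive-search cap of 1e5", m, length,
            class = "search_space_error")
  combos <- utils::combn(m, length)
  best <- NULL; best_fit <- -Inf
  for (j in seq_len(ncol(combos))) {
    f <- suppressWarnings(ga_fitness(combos[, j], X, y))
    if (f > best_fit + 1e-15) { best_fit <- f; best <- combos[, j] }
  }
  ids <- colnames(X)[best]
  list(descriptor_ids = ids, fitness = best_fit,
       model = mlr_fit(ds, response, ids), n_evaluated = ncol(combos))
}
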