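## African vulture optimization: a population metaheuristic alternating
## random exploration steps with moves toward the best candidate
## (scavenging), plus midpoint breeding and an optional greedy Gaussian
## local search.  Minimization convention throughout; positions are kept
## inside the search box by clipping.  Log-scaled dimensions are handled in
## log10 coordinates internally and decoded before each fitness call.

#' Box search space for the optimizer
#'
#' @param lower,upper numeric bounds per dimension (`lower < upper`).
#' @param scale per-dimension scale, `"linear"` or `"log10"`; log-scaled
#'   dimensions are sampled and perturbed uniformly in log10 space.
#' @param names optional dimension names.
#' @return A list of class `searchSpace`.
#' @export
searchSpace <- function(lower, upper, scale = "linear", names = NULL) {
  d <- length(lower)
  if (length(scale) == 1L) scale <- rep(scale, d)
  stopifnot(length(upper) == d, length(scale) == d,
            all(scale %in% c("linear", "log10")))
  if (any(lower >= upper))
    sepnetStop("each lower bound must be below its upper bound",
               "sepnetConfigError")
  if (any(scale == "log10" & lower <= 0))
    sepnetStop("log10-scaled dimensions need positive bounds",
               "sepnetConfigError")
  ilo <- ifelse(scale == "log10", log10(lower), lower)
  iup <- ifelse(scale == "log10", log10(upper), upper)
  structure(list(lower = lower, upper = upper, scale = scale,
                 ilo = ilo, iup = iup, names = names, d = d),
            class = "searchSpace")
}

.decode <- function(space, pos) {
  out <- ifelse(space$scale == "log10", 10^pos, pos)
  if (!is.null(space$names)) names(out) <- space$names
  out
}
.clip <- function(space, pos) pmin(pmax(pos, space$ilo), space$iup)

#' Optimizer configuration
#'
#' @param population_size number of vultures (>= 2), default 20.
#' @param max_iter iterations of the main loop, default 30.
#' @param step_size exploration half-width per dimension in internal
#'   coordinates, as a fraction of the dimension range, default 0.25.
#' @param exploration_radius probability of a random exploration step (the
#'   alternative is a scavenging move toward the best), default 0.3.
#' @param exploitation_factor step fraction toward the best candidate in
#'   the scavenging move, default 0.7.
#' @param reproduction_rate probability a candidate is replaced by a bred
#'   child each iteration, default 0.2.
#' @param breeding_factor multiplier on the parents' midpoint, default 1.
#' @param local_search apply one greedy Gaussian refinement per candidate
#'   per iteration (accepted only when fitness improves), default `TRUE`.
#' @param local_scale Gaussian scale as a fraction of each dimension range,
#'   default 0.01.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @return A list of class `avoaConfig`.
#' @export
avoaConfig <- function(population_size = 20L, max_iter = 30L,
                       step_size = 0.25, exploration_radius = 0.3,
                       exploitation_factor = 0.7, reproduction_rate = 0.2,
                       breeding_factor = 1, local_search = TRUE,
                       local_scale = 0.01, seed = 1L) {
  stopifnot(population_size >= 2, max_iter >= 1,
            exploration_radius >= 0, exploration_radius <= 1,
            reproduction_rate >= 0, reproduction_rate <= 1,
            step_size >= 0, local_scale >= 0)
  structure(list(population_size = as.integer(population_size),
                 max_iter = as.integer(max_iter), step_size = step_size,
                 exploration_radius = exploration_radius,
                 exploitation_factor = exploitation_factor,
                 reproduction_rate = reproduction_rate,
                 breeding_factor = breeding_factor,
                 local_search = isTRUE(local_search),
                 local_scale = local_scale, seed = as.integer(seed)),
            class = "avoaConfig")
}

#' Initialize the vulture population
#'
#' Positions drawn uniformly per dimension inside the box (uniform in log10
#' coordinates for log-scaled dimensions).
#'
#' @param space a [searchSpace()].
#' @param config an [avoaConfig()] (only `population_size` is used).
#' @return Matrix `population_size x d` of internal-coordinate positions.
#' @export
initializePopulation <- function(space, config) {
  P <- matrix(stats::runif(config$population_size * space$d), ncol = space$d)
  sweep(sweep(P, 2, space$iup - space$ilo, "*"), 2, space$ilo, "+")
}

#' One exploration-or-exploitation move
#'
#' With probability `exploration_radius` the candidate takes a uniform
#' random step of at most `step_size` times the dimension range per
#' dimension; otherwise it moves `exploitation_factor` of the way to the
#' best candidate.  The result is clipped to the box.
#'
#' @param position,best internal-coordinate vectors.
#' @param space a [searchSpace()].
#' @param config an [avoaConfig()].
#' @return The new position (internal coordinates).
#' @export
exploreOrExploit <- function(position, best, space, config) {
  rng <- space$iup - space$ilo
  if (stats::runif(1) < config$exploration_radius) {
    step <- stats::runif(space$d, -config$step_size, config$step_size) * rng
    .clip(space, position + step)
  } else {
    .clip(space, position + config$exploitation_factor * (best - position))
  }
}

#' Breed two candidates
#'
#' Child = `breeding_factor * (parent1 + parent2) / 2`, clipped to the box.
#'
#' @param parent1,parent2 internal-coordinate vectors.
#' @param breedingFactor multiplier on the midpoint.
#' @param space a [searchSpace()]; omit for the raw (unclipped) child.
#' @return The child position.
#' @export
breed <- function(parent1, parent2, breedingFactor = 1, space = NULL) {
  child <- breedingFactor * (parent1 + parent2) / 2
  if (is.null(space)) child else .clip(space, child)
}

#' Greedy Gaussian local search
#'
#' Perturbs the position once with independent Gaussian noise and keeps the
#' move only if it improves fitness.
#'
#' @param position internal-coordinate vector.
#' @param fitnessFn fitness of a decoded position (minimized).
#' @param scale per-dimension Gaussian standard deviation.
#' @param space a [searchSpace()].
#' @param fitness current fitness (computed if missing).
#' @return List with `position`, `fitness` and `evals` (extra evaluations).
#' @export
localSearch <- function(position, fitnessFn, scale, space,
                        fitness = NULL) {
  if (is.null(fitness)) fitness <- fitnessFn(.decode(space, position))
  if (all(scale == 0))
    return(list(position = position, fitness = fitness, evals = 0L))
  cand <- .clip(space, position + stats::rnorm(space$d, 0, scale))
  f <- fitnessFn(.decode(space, cand))
  if (is.finite(f) && f < fitness)
    list(position = cand, fitness = f, evals = 1L)
  else
    list(position = position, fitness = fitness, evals = 1L)
}

#' Run the vulture optimizer
#'
#' Each iteration evaluates every candidate, updates the best solution,
#' applies the exploration/scavenging move, midpoint breeding, and the
#' optional local search.  Non-finite fitness values are penalized with
#' `+Inf` and a warning.  The best-so-far fitness trace is non-increasing
#' and the whole run is reproducible from the seed.
#'
#' @param fitnessFn function of a decoded position vector returning a
#'   scalar to minimize.
#' @param space a [searchSpace()].
#' @param config an [avoaConfig()].
#' @return List with `bestPosition` (decoded), `bestFitness`, `trace`
#'   (data frame: iteration, best fitness, cumulative evaluations, best
#'   position components) and `evals`.
#' @export
avoaOptimize <- function(fitnessFn, space, config = avoaConfig()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  P <- initializePopulation(space, config)
  np <- config$population_size
  bestPos <- P[1, ]; bestFit <- Inf
  evals <- 0L
  trace <- vector("list", config$max_iter)
  scale <- config$local_scale * (space$iup - space$ilo)
  warned <- FALSE

  for (iter in seq_len(config$max_iter)) {
    fit <- numeric(np)
    for (i in seq_len(np)) {
      f <- fitnessFn(.decode(space, P[i, ]))
      evals <- evals + 1L
      if (!is.finite(f)) {
        if (!warned) {
          warning("non-finite fitness; candidate penalized with +Inf")
          warned <- TRUE
        }
        f <- Inf
      }
      fit[i] <- f
      if (f < bestFit) { bestFit <- f; bestPos <- P[i, ] }
    }
    for (i in seq_len(np))
      P[i, ] <- exploreOrExploit(P[i, ], bestPos, space, config)
    for (i in seq_len(np)) {
      if (stats::runif(1) < config$reproduction_rate) {
        j <- sample.int(np, 1)
        P[i, ] <- breed(P[i, ], P[j, ], config$breeding_factor, space)
      }
    }
    if (config$local_search) {
      for (i in seq_len(np)) {
        ls <- localSearch(P[i, ], fitnessFn, scale, space)
        evals <- evals + 1L + ls$evals
        P[i, ] <- ls$position
        if (ls$fitness < bestFit) { bestFit <- ls$fitness; bestPos <- ls$position }
      }
    }
    trace[[iter]] <- data.frame(iteration = iter, best_fitness = bestFit,
                                evaluations = evals,
                                t(.decode(space, bestPos)))
  }
  trace <- do.call(rbind, trace)
  list(bestPosition = .decode(space, bestPos), bestFitness = bestFit,
       trace = trace, evals = evals)
}

#' Export an optimization trace as CSV
#'
#' @param trace the `trace` data frame from [avoaOptimize()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  utils::write.table(trace, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tune learning rate and dropout with the vulture optimizer
#'
#' Fitness of a candidate is the final validation loss of a budget-limited
#' training run at the candidate's hyperparameters.  The default search
#' space is learning rate log10-uniform in [1e-4, 1e-1] and dropout in
#' [0.1, 0.7].
#'
#' @param xTrain,yTrain,xVal,yVal tensorized windows and labels.
#' @param space a [searchSpace()]; default as above with dimension names
#'   `lr` and `dropout`.
#' @param config an [avoaConfig()].
#' @param modelConfig a [modelConfig()] for the candidate models.
#' @param trainConfig a [trainConfig()]; its `max_epochs` is the training
#'   budget per candidate (default 3).
#' @return List with `best` (named: lr, dropout), `bestFitness` and `trace`.
#' @export
tuneHyperparameters <- function(xTrain, yTrain, xVal, yVal,
                                space = NULL, config = avoaConfig(),
                                modelConfig, trainConfig = NULL) {
  if (is.null(space))
    space <- searchSpace(lower = c(1e-4, 0.1), upper = c(1e-1, 0.7),
                         scale = c("log10", "linear"),
                         names = c("lr", "dropout"))
  if (is.null(trainConfig))
    trainConfig <- sepnet::trainConfig(max_epochs = 3L, patience = 3L)
  fitness <- function(pos) {
    mc <- modelConfig
    mc$dropout <- unname(pos[["dropout"]])
    tc <- trainConfig
    tc$lr <- unname(pos[["lr"]])
    mdl <- buildModel(mc, seed = trainConfig$seed)
    out <- tryCatch(
      trainModel(mdl, xTrain, yTrain, xVal, yVal, tc),
      error = function(e) NULL)
    if (is.null(out)) return(Inf)
    min(out$history$val_loss)
  }
  res <- avoaOptimize(fitness, space, config)
  list(best = res$bestPosition, bestFitness = res$bestFitness,
       trace = res$trace, evals = res$evals)
}
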