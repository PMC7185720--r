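# Genetic-algorithm search over the demographic parameter space.
#
# A genome is a named numeric vector of the five free simulation parameters
# (growth rate is fixed and is not a gene). Fitness is supplied by the
# caller, typically a closure that runs the expansion simulator and scores
# its arrival raster against the calibrated record.

.GENES <- c("k_star", "catchment_km", "fission_threshold", "leap_km",
            "permanence")

#' Default parameter ranges for the optimizer
#'
#' @return Named list of `c(min, max)` ranges per gene. `leap_km` is special:
#'   initialisation and mutation draw 0 (no leapfrogging) with probability
#'   1/2 and otherwise uniformly within its range.
#' @export
param_ranges <- function() {
  list(k_star = c(20, 100), catchment_km = c(10, 30),
       fission_threshold = c(50, 300), leap_km = c(150, 250),
       permanence = c(10, 30))
}

.draw_gene <- function(name, ranges) {
  rg <- ranges[[name]]
  if (name == "leap_km") {
    if (stats::runif(1) < 0.5) 0 else stats::runif(1, rg[1], rg[2])
  } else stats::runif(1, rg[1], rg[2])
}

#' Draw a random genome
#'
#' Each parameter is drawn uniformly within its range; `leap_km` is 0 with
#' probability 1/2 and otherwise uniform in its range.
#'
#' @param ranges Ranges as from [param_ranges].
#' @param fixed_catchment Optional value at which `catchment_km` is held
#'   (the equifinality control mode).
#' @return Named numeric vector of length 5.
#' @export
random_genome <- function(ranges = param_ranges(), fixed_catchment = NULL) {
  g <- vapply(.GENES, .draw_gene, numeric(1), ranges = ranges)
  if (!is.null(fixed_catchment)) g[["catchment_km"]] <- fixed_catchment
  g
}

#' Single-point crossover of two genomes
#'
#' With probability `p`, a cut point is drawn in the fixed gene order and
#' the offspring takes genes before the cut from `p1` and after it from
#' `p2`; otherwise the offspring is a copy of `p1`.
#'
#' @param p1,p2 Parent genomes.
#' @param p Crossover probability.
#' @return Offspring genome.
#' @export
crossover <- function(p1, p2, p = 0.8) {
  if (stats::runif(1) >= p) return(p1)
  cut <- sample.int(length(.GENES) - 1L, 1L)
  c(p1[seq_len(cut)], p2[seq.int(cut + 1L, length(.GENES))])
}

#' Mutate a genome
#'
#' Independently per gene, with probability `p` the value is redrawn
#' uniformly from its range (`leap_km` by the 0-or-range rule used at
#' initialisation). Results always stay within range.
#'
#' @param g Genome.
#' @param ranges Ranges as from [param_ranges].
#' @param p Per-gene mutation probability.
#' @param fixed_catchment Optional held value for `catchment_km`.
#' @return Mutated genome.
#' @export
mutate <- function(g, ranges = param_ranges(), p = 0.2,
                   fixed_catchment = NULL) {
  for (nm in .GENES) {
    if (!is.null(fixed_catchment) && nm == "catchment_km") next
    if (stats::runif(1) < p) g[[nm]] <- .draw_gene(nm, ranges)
  }
  if (!is.null(fixed_catchment)) g[["catchment_km"]] <- fixed_catchment
  g
}

#' Genetic-algorithm settings
#'
#' Defaults: population of 100 genomes, the best 40 selected as parents,
#' crossover probability 0.8, per-gene mutation probability 0.2, 5 elites
#' copied verbatim, 20 generations.
#'
#' @param pop_size,n_parents,p_crossover,p_mutation,n_elite,generations
#'   Settings; see Description.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100L, n_parents = 40L, p_crossover = 0.8,
                      p_mutation = 0.2, n_elite = 5L, generations = 20L) {
  if (!(n_elite <= n_parents && n_parents <= pop_size))
    stop("need n_elite <= n_parents <= pop_size", call. = FALSE)
  structure(list(pop_size = pop_size, n_parents = n_parents,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 n_elite = n_elite, generations = generations),
            class = "ga_config")
}

#' Evolve the genome population
#'
#' Each generation: all genomes are evaluated; the `n_parents` highest-fit
#' genomes reproduce, with parents paired uniformly at random with
#' replacement; `n_elite` best genomes are copied unchanged; the remaining
#' `pop_size - n_elite` offspring pass through crossover and mutation.
#' Identical genomes are re-evaluated rather than cached because the
#' simulator is stochastic.
#'
#' @param fitness_fn Function mapping a genome to a fitness in [0, 1].
#' @param config A [ga_config].
#' @param ranges Ranges as from [param_ranges].
#' @param seed Optional integer seed.
#' @param fixed_catchment Optional constant catchment radius (10, 20 or
#'   30 km) removing `catchment_km` from the search.
#' @return List with `best` (best-ever genome), `best_fitness`, and
#'   `history` data.frame (generation, mean_fitness, max_fitness,
#'   best_ever).
#' @export
evolve <- function(fitness_fn, config = ga_config(),
                   ranges = param_ranges(), seed = NULL,
                   fixed_catchment = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- replicate(config$pop_size,
                   random_genome(ranges, fixed_catchment), simplify = FALSE)
  best <- NULL
  best_fit <- -Inf
  hist <- data.frame(generation = integer(), mean_fitness = numeric(),
                     max_fitness = numeric(), best_ever = numeric())
  for (gen in seq_len(config$generations)) {
    fit <- vapply(pop, fitness_fn, numeric(1))
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best <- pop[[which.max(fit)]]
    }
    hist <- rbind(hist, data.frame(generation = gen,
                                   mean_fitness = mean(fit),
                                   max_fitness = max(fit),
                                   best_ever = best_fit))
    ord <- order(fit, decreasing = TRUE)
    parents <- pop[ord[seq_len(config$n_parents)]]
    elites <- pop[ord[seq_len(config$n_elite)]]
    n_off <- config$pop_size - config$n_elite
    offspring <- vector("list", n_off)
    for (k in seq_len(n_off)) {
      pr <- sample.int(config$n_parents, 2L, replace = TRUE)
      child <- crossover(parents[[pr[1]]], parents[[pr[2]]],
                         p = config$p_crossover)
      offspring[[k]] <- mutate(child, ranges, p = config$p_mutation,
                               fixed_catchment = fixed_catchment)
    }
    pop <- c(elites, offspring)
  }
  list(best = best, best_fitness = best_fit, history = hist)
}

#' Convert a genome to simulator parameters
#'
#' @param g Genome from [random_genome]/[evolve].
#' @return A [sim_params] object.
#' @export
genome_params <- function(g) {
  sim_params(k_star = g[["k_star"]], catchment_km = g[["catchment_km"]],
             fission_threshold = g[["fission_threshold"]],
             leap_km = g[["leap_km"]], permanence = g[["permanence"]])
}
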