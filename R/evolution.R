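#' Configuration of an evolutionary run
#'
#' Bundles and validates the parameters of the simulation. The historical
#' study conditions are a population of 1000 codes evolved for 50,000
#' generations, 50 replicates per scenario; desk-scale experiments use
#' smaller budgets (see the package vignette).
#'
#' @param population_size number of candidate code matrices (>= 2).
#' @param generations number of mutation/selection steps (>= 1).
#' @param replicates number of independent repetitions for
#'   [run_replicates()].
#' @param model neighbourhood model (`nbhd_model` or name "M1"/"M2"/"M3").
#' @param mutation_sigma standard deviation of the additive Gaussian
#'   perturbation; 0 disables mutation (selection-only runs).
#' @param mutation_rows_per_individual codon rows perturbed per mutated
#'   individual per generation.
#' @param mutation_prob probability that an individual is mutated in a
#'   given generation.
#' @param mutation_single_entry if `TRUE` (default) a mutation event
#'   perturbs the probability of a single randomly chosen label of the
#'   selected codon row (then renormalises the row); if `FALSE` all 21
#'   entries of the row are perturbed independently.
#' @param probability_floor lower clip applied to perturbed entries before
#'   renormalisation, in (0, 1/21); keeps label columns non-degenerate.
#' @param seed master seed; replicate i runs with `seed + i - 1`.
#' @param log_every trajectory logging stride in generations.
#' @return an object of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 1000L,
                             generations = 50000L,
                             replicates = 50L,
                             model = "M1",
                             mutation_sigma = 0.1,
                             mutation_rows_per_individual = 1L,
                             mutation_prob = 1,
                             mutation_single_entry = TRUE,
                             probability_floor = 1e-6,
                             seed = 1L,
                             log_every = 100L) {
  model <- as_nbhd_model(model)
  cfg <- list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    replicates = as.integer(replicates),
    model = model,
    mutation_sigma = as.numeric(mutation_sigma),
    mutation_rows_per_individual = as.integer(mutation_rows_per_individual),
    mutation_prob = as.numeric(mutation_prob),
    mutation_single_entry = isTRUE(mutation_single_entry),
    probability_floor = as.numeric(probability_floor),
    seed = as.integer(seed),
    log_every = as.integer(log_every)
  )
  stopifnot(cfg$population_size >= 2L, cfg$generations >= 1L,
            cfg$replicates >= 1L, cfg$mutation_sigma >= 0,
            cfg$mutation_rows_per_individual >= 0L,
            cfg$mutation_prob >= 0, cfg$mutation_prob <= 1,
            cfg$probability_floor > 0, cfg$probability_floor < 1 / 21,
            cfg$log_every >= 1L)
  structure(cfg, class = "evolution_config")
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf(paste0(
    "evolution config: %s, population %d, %d generations, %d replicate(s)\n",
    "  mutation: sigma %.4g on %d row(s)/individual, floor %.1g; seed %d\n"),
    x$model$name, x$population_size, x$generations, x$replicates,
    x$mutation_sigma, x$mutation_rows_per_individual,
    x$probability_floor, x$seed))
  invisible(x)
}

#' Mutate a code matrix
#'
#' The mutation operator of the evolutionary algorithm: for each of `rows`
#' randomly chosen codon rows, the probability that the codon encodes one
#' randomly chosen label receives additive Normal(0, `sigma`) noise
#' (`single_entry = TRUE`, the default), or all 21 entries of the row are
#' perturbed independently (`single_entry = FALSE`); perturbed entries are
#' clipped below at `floor_p` and the row is renormalised to sum to one.
#' With `sigma = 0` the matrix is returned unchanged.
#'
#' @param m code matrix.
#' @param sigma noise standard deviation.
#' @param rows number of rows perturbed (chosen uniformly, with
#'   replacement).
#' @param floor_p lower clip for perturbed entries.
#' @param single_entry perturb one label's probability per row (default)
#'   or the whole row.
#' @return the mutated code matrix (row-stochastic, entries of perturbed
#'   rows >= `floor_p` before renormalisation).
#' @export
mutate_code <- function(m, sigma = 0.1, rows = 1L, floor_p = 1e-6,
                        single_entry = TRUE) {
  if (sigma <= 0 || rows < 1L) return(m)
  for (r in sample.int(N_CODONS, rows, replace = TRUE)) {
    row <- m[r, ]
    if (single_entry) {
      l <- sample.int(N_LABELS, 1L)
      row[l] <- row[l] + rnorm(1L, sd = sigma)
    } else {
      row <- row + rnorm(N_LABELS, sd = sigma)
    }
    row <- pmax(row, floor_p)
    m[r, ] <- row / sum(row)
  }
  m
}

#' Fitness-proportional selection
#'
#' Resamples a population with replacement, each individual drawn with
#' probability proportional to its fitness (roulette-wheel selection). If
#' every fitness is zero the resampling falls back to uniform, with a
#' warning.
#'
#' @param population list of code matrices (or 64 x 21 x n array).
#' @param fitnesses non-negative numeric vector, one value per individual.
#' @return a list of code matrices of the same size as the input.
#' @export
select_population <- function(population, fitnesses) {
  population <- as_population(population)
  n <- length(population)
  stopifnot(length(fitnesses) == n, all(fitnesses >= 0))
  if (sum(fitnesses) > 0) {
    idx <- sample.int(n, n, replace = TRUE, prob = fitnesses)
  } else {
    warning("all fitnesses are zero; falling back to uniform resampling")
    idx <- sample.int(n, n, replace = TRUE)
  }
  population[idx]
}

#' Run the evolutionary algorithm
#'
#' Initialises a population of random ambiguous codes ([random_code()]),
#' then alternates mutation, stochastic fitness evaluation (one fresh
#' label-representative codon draw per individual per generation, scored by
#' the forward/factorised fitness), and fitness-proportional selection.
#' The loop runs compiled (see `src/evolve.cpp`) on R's RNG, so results are
#' bit-reproducible from the seed.
#'
#' @param cfg an `evolution_config`.
#' @param seed seed override (defaults to `cfg$seed`).
#' @return an object of class `evo_trajectory`: list with `trajectory`
#'   (data.frame of generation, H_av, F_best, F_mean), `final_population`
#'   (64 x 21 x n array), `config`, `seed`.
#' @examples
#' cfg <- evolution_config(population_size = 20, generations = 50,
#'                         model = "M1", log_every = 10, seed = 42)
#' run <- run_evolution(cfg)
#' tail(run$trajectory, 2)
#' @export
run_evolution <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "evolution_config"))
  set.seed(seed)
  pop <- random_code(cfg$population_size)
  res <- cpp_evolve(pop, cfg$generations, nbhd_table(cfg$model),
                    cfg$mutation_sigma, cfg$mutation_rows_per_individual,
                    cfg$probability_floor, cfg$log_every,
                    cfg$mutation_prob, cfg$mutation_single_entry)
  if (res$zero_fitness_events > 0) {
    warning(res$zero_fitness_events,
            " generation(s) had all-zero fitness; uniform resampling used")
  }
  traj <- data.frame(generation = res$generation, H_av = res$H_av,
                     F_best = res$F_best, F_mean = res$F_mean)
  structure(list(trajectory = traj,
                 final_population = res$final_population,
                 config = cfg, seed = seed),
            class = "evo_trajectory")
}

#' @export
print.evo_trajectory <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf(paste0(
    "evolutionary run (%s, n = %d, seed %d): %d generations\n",
    "  H_av %0.2f -> %0.2f; final mean fitness %.4g\n"),
    x$config$model$name, x$config$population_size, x$seed,
    last$generation, tr$H_av[1], last$H_av, last$F_mean))
  invisible(x)
}

#' Run independent replicates
#'
#' Repeats [run_evolution()] `cfg$replicates` times; replicate i uses seed
#' `cfg$seed + i - 1`, so each replicate is independently reproducible and
#' replicate 1 coincides with `run_evolution(cfg)`. Optionally writes each
#' trajectory as CSV plus a JSON run manifest sufficient to re-execute any
#' replicate.
#'
#' @param cfg an `evolution_config`.
#' @param out_dir optional output directory for trajectory CSVs and the
#'   manifest.
#' @return a list of `evo_trajectory` objects (invisibly carries
#'   `out_dir` as an attribute when written).
#' @export
run_replicates <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "evolution_config"))
  runs <- vector("list", cfg$replicates)
  paths <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  for (i in seq_len(cfg$replicates)) {
    runs[[i]] <- run_evolution(cfg, seed = cfg$seed + i - 1L)
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, sprintf("trajectory_rep%03d.csv", i))
      write.csv(runs[[i]]$trajectory, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(out_dir)) {
    write_run_manifest(cfg, paths, out_dir)
    attr(runs, "out_dir") <- out_dir
  }
  runs
}

# JSON manifest: config, per-replicate seeds and files, checksums
write_run_manifest <- function(cfg, paths, out_dir) {
  manifest <- list(
    package = "ambicode",
    version = as.character(utils::packageVersion("ambicode")),
    config = list(
      population_size = cfg$population_size,
      generations = cfg$generations,
      replicates = cfg$replicates,
      model = cfg$model$name,
      varied_positions = cfg$model$varied_positions,
      mutation_sigma = cfg$mutation_sigma,
      mutation_rows_per_individual = cfg$mutation_rows_per_individual,
      probability_floor = cfg$probability_floor,
      seed = cfg$seed,
      log_every = cfg$log_every
    ),
    replicate_seeds = cfg$seed + seq_len(cfg$replicates) - 1L,
    files = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
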