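test_that("mutation preserves the row-stochastic contract", {
  set.seed(51)
  m <- random_code()
  expect_identical(mutate_code(m, sigma = 0), m)
  for (single in c(TRUE, FALSE)) {
    m2 <- mutate_code(m, sigma = 0.1, rows = 5L, floor_p = 1e-6,
                      single_entry = single)
    expect_equal(rowSums(m2), setNames(rep(1, 64), CODONS), tolerance = 1e-12)
    expect_true(all(m2 > 0))
    expect_lte(sum(apply(m2 != m, 1, any)), 5L)   # at most 5 rows touched
  }
})

test_that("symmetric mutation noise leaves a uniform row unbiased", {
  set.seed(52)
  u <- uniform_matrix()
  n <- 2000
  acc <- matrix(0, 2, 21)
  for (i in seq_len(n)) {
    acc[1, ] <- acc[1, ] + mutate_code(u, sigma = 0.05, rows = 64L,
                                       single_entry = TRUE)[1, ]
    acc[2, ] <- acc[2, ] + mutate_code(u, sigma = 0.05, rows = 64L,
                                       single_entry = FALSE)[1, ]
  }
  for (mode in 1:2) {
    mean_row <- acc[mode, ] / n
    # label symmetry: each entry should stay near 1/21 within 3 MC sigmas
    se <- sd(mean_row) / sqrt(21)
    expect_true(all(abs(mean_row - 1 / 21) < max(6 * se, 0.002)))
    expect_equal(sum(mean_row), 1, tolerance = 1e-9)
  }
})

test_that("selection is proportional, size-preserving and degenerate-safe", {
  pop <- random_code(4)
  pop <- lapply(seq_len(dim(pop)[3]), function(i) pop[, , i])
  # only individual 2 has positive fitness
  set.seed(53)
  sel <- select_population(pop, c(0, 1, 0, 0))
  expect_length(sel, 4L)
  for (s in sel) expect_identical(s, pop[[2]])
  # equal fitnesses: counts consistent with multinomial(n, uniform)
  set.seed(54)
  counts <- integer(4)
  for (i in 1:1000) {
    sel <- select_population(pop, rep(1, 4))
    for (j in 1:4) counts[j] <- counts[j] + sum(vapply(sel, identical,
                                                      logical(1), pop[[j]]))
  }
  expect_gt(chisq.test(counts)$p.value, 0.001)
  # all-zero fitness: uniform fallback with a warning
  expect_warning(select_population(pop, rep(0, 4)), "all fitnesses are zero")
})

test_that("runs are bit-reproducible from the seed and replicates differ", {
  cfg <- evolution_config(population_size = 30, generations = 80,
                          replicates = 2, model = "M2", log_every = 20,
                          seed = 99)
  r1 <- run_evolution(cfg)
  r2 <- run_evolution(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_population, r2$final_population)

  reps <- run_replicates(cfg)
  expect_identical(reps[[1]]$trajectory, r1$trajectory)  # replicate 1 = base seed
  expect_false(identical(reps[[1]]$trajectory$H_av, reps[[2]]$trajectory$H_av))
})

test_that("initial populations have the expected mean entropy", {
  cfg <- evolution_config(population_size = 1000, generations = 1,
                          model = "M1", log_every = 1, seed = 5)
  run <- run_evolution(cfg)
  expect_equal(run$trajectory$H_av[1], 182.5, tolerance = 1)
  expect_equal(run$trajectory$generation[1], 0)
})

test_that("entropy declines and fitness rises over a short evolved run", {
  cfg <- evolution_config(population_size = 100, generations = 600,
                          model = "M1", log_every = 600, seed = 17)
  run <- run_evolution(cfg)
  tr <- run$trajectory
  expect_lt(tr$H_av[nrow(tr)], tr$H_av[1])
  expect_gt(log(tr$F_mean[nrow(tr)]), log(tr$F_mean[1]))
  expect_true(all(diff(tr$generation) > 0))
  # population invariants at the end
  pop <- run$final_population
  expect_equal(apply(pop, 3, rowSums), matrix(1, 64, 100), tolerance = 1e-9)
  expect_true(all(pop > 0))
})

test_that("replicate outputs are written with a replayable manifest", {
  out <- withr::local_tempdir()
  cfg <- evolution_config(population_size = 10, generations = 20,
                          replicates = 2, model = "M1", log_every = 10,
                          seed = 3)
  run_replicates(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "trajectory_rep001.csv")))
  expect_true(file.exists(file.path(out, "trajectory_rep002.csv")))
  man <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(man$config$seed, 3L)
  expect_equal(unlist(man$replicate_seeds), c(3L, 4L))
  # re-running replicate 2 from its manifest seed reproduces the CSV
  redo <- run_evolution(cfg, seed = man$replicate_seeds[[2]])
  disk <- read.csv(file.path(out, "trajectory_rep002.csv"))
  expect_equal(disk$H_av, redo$trajectory$H_av, tolerance = 1e-12)
})
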