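test_that("GGG neighbourhoods match the canonical worked example", {
  expect_setequal(neighbourhood("GGG", "M1"), c("GGG", "GGA", "GGC", "GGT"))
  expect_setequal(neighbourhood("GGG", "M2"),
                  c("GGG", "AGG", "CGG", "TGG", "GAG", "GCG", "GTG"))
  expect_setequal(neighbourhood("GGG", "M3"),
                  c("GGG", "AGG", "CGG", "TGG", "GAG", "GCG", "GTG",
                    "GGA", "GGC", "GGT"))
})

test_that("neighbourhood sizes are constant and follow the size law", {
  sizes <- c(M1 = 4L, M2 = 7L, M3 = 10L)
  for (name in names(sizes)) {
    nb <- nbhd_table(name)
    expect_equal(nrow(nb), sizes[[name]])
    model <- nbhd_model(name)
    expect_equal(sizes[[name]], 1L + 3L * length(model$varied_positions))
    # every neighbourhood contains its own codon
    expect_equal(nb[1, ], setNames(1:64, CODONS))
    # all members distinct
    expect_true(all(apply(nb, 2, anyDuplicated) == 0))
  }
})

test_that("the M3 neighbourhood relation is symmetric", {
  nb <- nbhd_table("M3")
  for (c1 in seq(1, 64, by = 7)) {
    for (c2 in nb[, c1]) {
      expect_true(c1 %in% nb[, c2])
    }
  }
})

test_that("varied positions are configurable but constrained per model", {
  m1 <- nbhd_model("M1", varied_positions = 1)
  expect_setequal(neighbourhood("GGG", m1), c("GGG", "AGG", "CGG", "TGG"))
  expect_error(nbhd_model("M1", varied_positions = c(1, 2)), "exactly 1")
  expect_error(nbhd_model("M2", varied_positions = 4), "1..3")
})

test_that("label-conditioned codon draws follow the normalised column", {
  # degenerate column: all mass on one codon
  m <- matrix(0, 64, 21, dimnames = list(CODONS, CODE_LABELS))
  m[, 1] <- 0
  m[5, ] <- 0
  m[5, 1] <- 1
  m[-5, 2:21] <- 1 / 20
  expect_equal(unique(draw_codon_for_label(m, 1, n = 100)), 5L)

  # all-zero column errors
  m2 <- uniform_matrix()
  m2[, 3] <- 0
  expect_error(draw_codon_for_label(m2, 3), "all-zero")

  # multinomial frequencies recover the normalised column within 3 sigma
  m3 <- uniform_matrix()
  m3[, 1] <- 0
  m3[1:3, 1] <- c(0.2, 0.6, 0.2)
  set.seed(42)
  n <- 100000
  draws <- draw_codon_for_label(m3, 1, n = n)
  for (j in 1:3) {
    p <- c(0.2, 0.6, 0.2)[j]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws == j) - p), 3 * se)
  }
  # uniform matrix: every codon equally likely
  set.seed(43)
  u <- draw_codon_for_label(uniform_matrix(), 7, n = 64000)
  expect_gt(suppressWarnings(chisq.test(table(factor(u, levels = 1:64)))$p.value),
            0.001)
})

test_that("uniform matrix fitness has the closed form (|N|/21)^k", {
  m <- uniform_matrix()
  d <- rep(1L, 21)
  expect_equal(as.numeric(fitness_forward(m, d, "M1")), (4 / 21)^21,
               tolerance = 1e-12)
  expect_equal(as.numeric(fitness_forward(m, d, "M3")), (10 / 21)^21,
               tolerance = 1e-12)
  expect_equal(fitness_factorized(m, d, "M2"), (7 / 21)^21, tolerance = 1e-12)
})

test_that("forward recursion, closed form and brute force agree", {
  set.seed(7)
  for (i in 1:60) {
    model <- sample(c("M1", "M2", "M3"), 1)
    k <- switch(model, M1 = sample(2:6, 1), M2 = sample(2:4, 1),
                M3 = sample(2:3, 1))
    m <- random_code()
    d <- sample.int(64, k, replace = TRUE)
    f_fwd <- as.numeric(fitness_forward(m, d, model))
    f_fac <- fitness_factorized(m, d, model)
    f_dir <- fitness_direct(m, d, model)
    expect_equal(f_fwd, f_dir, tolerance = 1e-12)
    expect_equal(f_fac, f_dir, tolerance = 1e-12)
  }
})

test_that("single-label fitness is the neighbourhood sum", {
  m <- toy_matrix()
  d <- codon_index("GGG")
  lab <- 4L
  expected <- sum(m[neighbourhood("GGG", "M1"), lab])
  expect_equal(fitness_direct(m, d, "M1", labels = lab), expected)
  expect_equal(as.numeric(fitness_forward(m, d, "M1", labels = lab)), expected)
})

test_that("brute force refuses exponential enumeration", {
  m <- toy_matrix()
  expect_error(fitness_direct(m, rep(1L, 21), "M1"), "refusing")
})

test_that("increasing a neighbourhood entry never decreases fitness", {
  set.seed(8)
  m <- random_code()
  d <- sample.int(64, 21, replace = TRUE)
  f0 <- fitness_factorized(m, d, "M1")
  nb <- nbhd_table("M1")
  for (i in c(1, 10, 21)) {
    m2 <- m
    m2[nb[2, d[i]], i] <- m2[nb[2, d[i]], i] + 0.1  # raw increase, no renorm
    expect_gte(fitness_factorized(m2, d, "M1"), f0)
  }
})

test_that("total probability rescales fitness by (1/64)^21", {
  f <- 2.5
  expect_equal(total_probability(f), 2.5 * (1 / 64)^21)
})
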