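test_that("codon indexing is a lexicographic bijection that round-trips", {
  expect_equal(codon_index("AAA"), 1L)
  expect_equal(codon_index("AAC"), 2L)
  expect_equal(codon_index("TTT"), 64L)
  expect_equal(codon_from_index(codon_index(CODONS)), CODONS)
  expect_equal(sort(codon_index(CODONS)), 1:64)
  expect_error(codon_index("AAU"), "invalid codon")
  expect_error(codon_index("AA"), "invalid codon")
  expect_error(codon_from_index(65), "out of range")
})

test_that("random codes are row-stochastic with the expected row entropy", {
  set.seed(11)
  m <- random_code()
  expect_equal(dim(m), c(64L, 21L))
  expect_true(all(m >= 0))
  expect_equal(rowSums(m), setNames(rep(1, 64), CODONS), tolerance = 1e-9)

  # E[-sum p log p] for 21 normalised uniforms is about 2.85 nats/row
  set.seed(12)
  rows <- matrix(runif(10000 * 21), ncol = 21)
  rows <- rows / rowSums(rows)
  h <- -rowSums(rows * log(rows))
  expect_equal(mean(h), 2.85, tolerance = 0.01)
})

test_that("the standard genetic code partition has the canonical structure", {
  sgc <- sgc_partition()
  expect_s3_class(sgc, "code_partition")
  expect_length(sgc, 21L)
  expect_setequal(unlist(sgc), CODONS)
  expect_setequal(sgc[["*"]], c("TAA", "TAG", "TGA"))
  expect_equal(sgc[["W"]], "TGG")
  expect_equal(sgc[["M"]], "ATG")
  expect_equal(lengths(sgc)[c("L", "R")], c(L = 6L, R = 6L))
  expect_setequal(unique(lengths(sgc)), c(1L, 2L, 3L, 4L, 6L))
})

test_that("bundled SGC agrees with the canonical translation table", {
  skip_if_not_installed("Biostrings")
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  sgc <- sgc_partition()
  for (lab in names(sgc)) {
    expect_setequal(sgc[[lab]], names(gc)[gc == lab])
  }
})

test_that("partition -> degenerate matrix -> MLGP round-trips", {
  sgc <- sgc_partition()
  m <- partition_to_matrix(sgc)
  expect_equal(m["TGG", "W"], 1)
  expect_equal(sum(m["TGG", ]), 1)
  expect_equal(code_entropy(m), 0)
  back <- mlgp(m)
  expect_equal(back[names(sgc)], sgc[names(sgc)], ignore_attr = TRUE)
})

test_that("partition validation rejects malformed groupings", {
  groups <- sgc_partition()
  bad <- unclass(groups)
  bad[["A"]] <- bad[["A"]][-1]          # drop a codon
  expect_error(code_partition(bad), "covers 63")
  bad2 <- unclass(groups)
  bad2[["C"]] <- c(bad2[["C"]], bad2[["A"]][1])   # duplicate a codon
  expect_error(code_partition(bad2), "more than one group")
  expect_error(code_partition(unclass(groups)[1:20]), "21 groups")
})

test_that("code matrix TSV I/O round-trips and validates", {
  m <- toy_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_code_matrix(m, path)
  m2 <- read_code_matrix(path)
  expect_equal(m2, m, tolerance = 1e-12)

  # missing codon row
  df <- read.delim(path, check.names = FALSE)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[df$codon != "GGT", ], path2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_code_matrix(path2), "GGT")

  # row sum far from 1
  df2 <- df
  df2[df2$codon == "AAA", -1] <- df2[df2$codon == "AAA", -1] / 2
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df2, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_code_matrix(path3), "AAA")

  # negative entry
  df3 <- df
  df3[1, 2] <- -0.5
  path4 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df3, path4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_code_matrix(path4), "negative")
})

test_that("partition TSV I/O round-trips", {
  sgc <- sgc_partition()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(sgc, path)
  expect_equal(read_partition(path), sgc)
})
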