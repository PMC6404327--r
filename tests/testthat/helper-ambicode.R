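# shared fixtures, built in code

# degenerate matrix of the standard genetic code
sgc_matrix <- function() partition_to_matrix(sgc_partition())

# a small deterministic non-uniform code matrix (valid, strictly positive)
toy_matrix <- function(seed = 123) {
  set.seed(seed)
  random_code()
}

# uniform code matrix (maximum ambiguity)
uniform_matrix <- function() {
  matrix(1 / 21, 64, 21, dimnames = list(CODONS, CODE_LABELS))
}
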