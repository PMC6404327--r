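#' Genetic code entropy
#'
#' The ambiguity of a code matrix, measured as the sum over all 64 codon
#' rows of the Shannon entropy (natural logarithm) of the row distribution:
#' \deqn{H(P) = -\sum_{c=1}^{64} \sum_{l=1}^{21} p_{cl} \log p_{cl},}
#' with \eqn{0 \log 0 := 0}. A fully unambiguous (degenerate) code has
#' \eqn{H = 0}; the maximum is \eqn{64 \log 21 \approx 194.9} nats; freshly
#' initialised random codes average about 182 nats.
#'
#' @param m code matrix.
#' @return entropy in nats (non-negative scalar).
#' @examples
#' code_entropy(partition_to_matrix(sgc_partition()))  # 0
#' @export
code_entropy <- function(m) {
  p <- m[m > 0]
  -sum(p * log(p))
}

#' Mean code entropy of a population
#'
#' @param population a list of code matrices or a 64 x 21 x n array.
#' @return the arithmetic mean of [code_entropy()] over individuals.
#' @export
average_entropy <- function(population) {
  population <- as_population(population)
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  mean(vapply(population, code_entropy, numeric(1)))
}

# normalize population representations to a list of matrices
as_population <- function(population) {
  if (is.array(population) && length(dim(population)) == 3L) {
    lapply(seq_len(dim(population)[3L]), function(i) population[, , i])
  } else if (is.list(population)) {
    population
  } else if (is.matrix(population)) {
    list(population)
  } else {
    stop("population must be a list of code matrices or a 64x21xn array",
         call. = FALSE)
  }
}

#' Maximum-likelihood graph partition (MLGP)
#'
#' Collapses an ambiguous code matrix to an unambiguous partition by
#' assigning every codon to its highest-probability label (ties broken
#' towards the lowest label index, deterministically). The partition exists
#' only if every label is the row maximum of at least one codon; otherwise
#' the strict mode raises an error naming the empty labels, and the lenient
#' mode returns the partial grouping for diagnostics.
#'
#' @param m code matrix.
#' @param lenient if `TRUE`, return a list with elements `groups` (label ->
#'   codons, possibly with empty entries) and `empty_labels` instead of
#'   erroring.
#' @return a `code_partition` (strict mode), or the lenient list.
#' @examples
#' mlgp(partition_to_matrix(sgc_partition()))
#' @export
mlgp <- function(m, lenient = FALSE) {
  m <- validate_code_matrix(m)
  best <- max.col(m, ties.method = "first")
  groups <- lapply(seq_len(N_LABELS), function(l) CODONS[best == l])
  names(groups) <- CODE_LABELS
  empty <- CODE_LABELS[lengths(groups) == 0L]
  if (lenient) {
    return(list(groups = groups, empty_labels = empty))
  }
  if (length(empty)) {
    stop("MLGP does not exist: no codon attains its maximum at label(s) ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  code_partition(groups)
}

#' Coding strength of a partitioned code
#'
#' For each group \eqn{S_l} of a partition, the coding strength
#' \eqn{\psi(S_l) = |S_l|^{-1} \sum_{c \in S_l} p_{cl}} is the mean
#' probability with which the group's codons encode the group's label; the
#' average coding strength \eqn{\Psi} is the arithmetic mean of the 21
#' group values. Degenerate matrices paired with their own partition give
#' \eqn{\psi = 1} everywhere.
#'
#' @param m code matrix.
#' @param part a `code_partition`; defaults to `mlgp(m)`. Groups are matched
#'   to label columns by name when the partition uses the canonical symbols,
#'   otherwise positionally.
#' @return a list with `psi` (named vector of 21 group strengths) and
#'   `Psi` (their mean).
#' @export
coding_strength <- function(m, part = mlgp(m)) {
  stopifnot(inherits(part, "code_partition"))
  cols <- if (all(names(part) %in% CODE_LABELS)) {
    match(names(part), CODE_LABELS)
  } else {
    seq_len(N_LABELS)
  }
  psi <- vapply(seq_along(part), function(i) {
    mean(m[codon_index(part[[i]]), cols[i]])
  }, numeric(1))
  names(psi) <- names(part)
  list(psi = psi, Psi = mean(psi))
}
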