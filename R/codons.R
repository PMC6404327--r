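#' Codons, labels and the probabilistic code matrix
#'
#' A genetic code is modelled as a 64x21 row-stochastic matrix \eqn{P} whose
#' entry \eqn{p_{cl}} is the probability that codon \eqn{c} encodes label
#' \eqn{l}. The 64 codons are the triplets over \{A,C,G,T\}, ordered
#' lexicographically (AAA = 1, ..., TTT = 64); the 21 labels are the 20
#' amino acids in alphabetical one-letter order followed by the stop signal
#' `*` (label 21).
#'
#' @name code-space
NULL

#' The four nucleotide bases, in the order used for codon ranking.
#' @export
CODON_BASES <- c("A", "C", "G", "T")

#' The 64 codons in lexicographic order (AAA first, TTT last).
#' @export
CODONS <- sort(as.vector(outer(outer(CODON_BASES, CODON_BASES, paste0),
                               CODON_BASES, paste0)))

#' The 21 labels: amino-acid one-letter codes (alphabetical) plus `*` (stop).
#' @export
CODE_LABELS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

N_CODONS <- 64L
N_LABELS <- 21L

#' Rank of a codon in lexicographic order
#'
#' Maps codon triplets to their 1-based lexicographic rank under the base
#' order A < C < G < T, so `codon_index("AAA") == 1` and
#' `codon_index("TTT") == 64`. Inverse of [codon_from_index()].
#'
#' @param bases character vector of 3-letter codons over \{A,C,G,T\}.
#' @return integer vector of ranks in 1..64.
#' @examples
#' codon_index(c("AAA", "AAC", "TTT"))
#' codon_from_index(codon_index("GGT"))
#' @export
codon_index <- function(bases) {
  idx <- match(bases, CODONS)
  if (anyNA(idx)) {
    bad <- unique(bases[is.na(idx)])
    stop("invalid codon(s): ", paste(bad, collapse = ", "),
         " (expected 3-mers over A,C,G,T)", call. = FALSE)
  }
  idx
}

#' @rdname codon_index
#' @param index integer vector of ranks in 1..64.
#' @export
codon_from_index <- function(index) {
  index <- as.integer(index)
  if (anyNA(index) || any(index < 1L | index > N_CODONS)) {
    stop("codon index out of range 1..64", call. = FALSE)
  }
  CODONS[index]
}

#' Random ambiguous code matrix
#'
#' Draws a fresh 64x21 code matrix in which each row is 21 independent
#' Uniform(0,1) variates divided by their sum. This is the initial state of
#' every simulated individual: an unbiased, highly ambiguous code whose
#' expected total entropy is about 182 nats (about 2.85 nats per codon row).
#'
#' @param n number of matrices to draw.
#' @return for `n = 1` a single code matrix (64x21, dimnames codons x
#'   labels); otherwise a 64 x 21 x n array.
#' @examples
#' set.seed(1)
#' m <- random_code()
#' range(rowSums(m))
#' @export
random_code <- function(n = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  draw1 <- function() {
    m <- matrix(runif(N_CODONS * N_LABELS), nrow = N_CODONS,
                dimnames = list(CODONS, CODE_LABELS))
    m / rowSums(m)
  }
  if (n == 1L) return(draw1())
  out <- array(0, dim = c(N_CODONS, N_LABELS, n),
               dimnames = list(CODONS, CODE_LABELS, NULL))
  for (i in seq_len(n)) out[, , i] <- draw1()
  out
}

#' Validate a code matrix
#'
#' Checks that `m` is a numeric 64x21 matrix with non-negative entries and
#' row sums equal to 1 within `tol`. Returns the matrix (with canonical
#' dimnames attached) invisibly re-normalised row-wise, so accumulated
#' floating-point drift within tolerance is removed; anything outside
#' tolerance is an error naming the offending row.
#'
#' @param m candidate matrix.
#' @param tol row-sum tolerance (default 1e-9).
#' @return the validated (re-normalised) code matrix.
#' @export
validate_code_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m) ||
      nrow(m) != N_CODONS || ncol(m) != N_LABELS) {
    stop("a code matrix must be a numeric 64x21 matrix", call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(apply(m, 1L, function(r) any(r < 0)))
    stop("negative probabilities in row(s): ",
         paste(CODONS[bad], collapse = ", "), call. = FALSE)
  }
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off)) {
    stop("row sum outside tolerance for codon(s): ",
         paste0(CODONS[off], " (sum=", signif(rs[off], 8), ")",
                collapse = ", "),
         call. = FALSE)
  }
  m <- m / rs
  dimnames(m) <- list(CODONS, CODE_LABELS)
  m
}

#' Read / write a code matrix as TSV
#'
#' The on-disk dialect is a tab-separated table with a `codon` column and 21
#' probability columns named by the label symbols; 64 data rows. Writing
#' uses 15 significant digits so that write/read round-trips are lossless at
#' double precision; reading re-validates rows (non-negative, sums within
#' tolerance) and renormalises.
#'
#' @param path file path.
#' @param tol row-sum tolerance applied on read.
#' @return `read_code_matrix` returns a validated code matrix;
#'   `write_code_matrix` returns `path` invisibly.
#' @export
read_code_matrix <- function(path, tol = 1e-9) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"codon" %in% names(df)) {
    stop("code matrix TSV must have a 'codon' column", call. = FALSE)
  }
  missing <- setdiff(CODONS, df$codon)
  if (length(missing)) {
    stop("code matrix TSV is missing codon row(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(df$codon, CODONS)
  if (length(extra) || nrow(df) != N_CODONS) {
    stop("code matrix TSV has unexpected row(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  lab_cols <- setdiff(names(df), "codon")
  if (!setequal(lab_cols, CODE_LABELS)) {
    stop("code matrix TSV must have the 21 label columns ",
         paste(CODE_LABELS, collapse = " "), call. = FALSE)
  }
  m <- as.matrix(df[match(CODONS, df$codon), CODE_LABELS])
  rownames(m) <- CODONS
  validate_code_matrix(m, tol = tol)
}

#' @rdname read_code_matrix
#' @param m code matrix to write.
#' @export
write_code_matrix <- function(m, path) {
  m <- validate_code_matrix(m)
  chr <- matrix(sprintf("%.17g", m), nrow = N_CODONS,
                dimnames = list(NULL, CODE_LABELS))
  df <- data.frame(codon = CODONS, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
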