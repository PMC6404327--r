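#' The codon point-mutation graph
#'
#' The 64 codons as vertices, with an edge between two codons iff they
#' differ at exactly one position (Hamming distance 1). Every vertex has
#' degree 9 (3 positions x 3 alternative bases), giving 288 edges and total
#' volume 576; the graph is connected.
#'
#' @return an `igraph` graph with vertices named by codon.
#' @examples
#' g <- codon_graph()
#' igraph::degree(g)[["AAA"]]
#' @export
codon_graph <- function() {
  igraph::graph_from_adjacency_matrix(codon_adjacency(), mode = "undirected")
}

# 64x64 0/1 adjacency matrix, cached
codon_adjacency <- function() {
  if (is.null(.ambicode_cache$adj)) {
    chars <- do.call(rbind, strsplit(CODONS, ""))
    d <- matrix(0L, N_CODONS, N_CODONS, dimnames = list(CODONS, CODONS))
    for (p in 1:3) {
      d <- d + outer(chars[, p], chars[, p], "!=")
    }
    .ambicode_cache$adj <- matrix(as.integer(d == 1L), N_CODONS,
                                  dimnames = list(CODONS, CODONS))
  }
  .ambicode_cache$adj
}

# exact fraction helpers -------------------------------------------------

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

reduce_frac <- function(num, den) {
  num <- unname(num)
  den <- unname(den)
  g <- gcd(num, den)
  c(num = num / g, den = den / g)
}

conductance_value <- function(num, den) {
  r <- reduce_frac(num, den)
  structure(list(value = num / den, numerator = unname(r["num"]),
                 denominator = unname(r["den"])),
            class = "conductance_value")
}

#' @export
print.conductance_value <- function(x, ...) {
  cat(sprintf("conductance %d/%d = %.6f%s\n", x$numerator, x$denominator,
              x$value,
              if (isTRUE(x$upper_bound)) " (upper bound, not certified)" else ""))
  invisible(x)
}

#' Conductance of a codon set
#'
#' For a non-empty proper subset S of the codon graph,
#' \eqn{\phi(S) = E(S, \bar S) / \mathrm{vol}(S)} where \eqn{E(S,\bar S)}
#' counts edges leaving S and \eqn{\mathrm{vol}(S) = 9|S|}. Low conductance
#' means point mutations rarely change the encoded label, i.e. a robust
#' codon group. Exact integer numerator/denominator are retained.
#'
#' @param S character vector of codons (or indices in 1..64).
#' @return a `conductance_value`: list with `value`, `numerator`
#'   (crossing edges), `denominator` (9|S|).
#' @examples
#' set_conductance(c("GGA", "GGT"))$value  # 8/9
#' @export
set_conductance <- function(S) {
  if (is.numeric(S)) S <- codon_from_index(S)
  idx <- codon_index(unique(S))
  if (length(idx) == 0L || length(idx) == N_CODONS) {
    stop("conductance is defined for non-empty proper subsets of the 64 codons",
         call. = FALSE)
  }
  A <- codon_adjacency()
  internal2 <- sum(A[idx, idx, drop = FALSE])   # 2 * internal edges
  vol <- 9L * length(idx)
  crossing <- vol - internal2
  conductance_value(crossing, vol)
}

#' Minimum conductance over codon sets of size k
#'
#' \eqn{\phi_k(G) = \min_{|S| = k} \phi(S)}. For \eqn{k \le 4} the minimum
#' is found by exhaustive enumeration of all k-subsets (certified). For
#' larger k exhaustive enumeration is refused; the candidate mode instead
#' enumerates all k-subsets inside each single-position plane (the 12 sets
#' of 16 codons sharing one fixed position value), where the densest small
#' codon groups live, and reports the best set found as an upper bound.
#' Known certified values: \eqn{\phi_1 = 1}, \eqn{\phi_2 = 8/9},
#' \eqn{\phi_3 = 7/9}, \eqn{\phi_4 = 2/3}.
#'
#' @param k group size, 1..63.
#' @param mode `"auto"` (exhaustive for k <= 4, candidate above),
#'   `"exhaustive"`, or `"candidate"`.
#' @return a `conductance_value` with extra fields `k`, `exhaustive`
#'   (certified minimum?), `upper_bound`, and `argmin` (one attaining set).
#' @export
k_size_conductance <- function(k, mode = c("auto", "exhaustive", "candidate")) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 63L)
  if (mode == "auto") mode <- if (k <= 4L) "exhaustive" else "candidate"
  if (mode == "exhaustive" && k > 4L) {
    stop("exhaustive enumeration of C(64,", k, ") subsets is refused; ",
         "use mode = 'candidate' for k > 4 (reports an upper bound)",
         call. = FALSE)
  }
  A <- codon_adjacency()
  best_from <- function(subsets) {
    # subsets: k x n matrix of codon indices; maximise internal edges
    n <- ncol(subsets)
    internal <- numeric(n)
    if (k >= 2L) {
      pairs <- combn(k, 2L)
      for (j in seq_len(ncol(pairs))) {
        internal <- internal +
          A[cbind(subsets[pairs[1L, j], ], subsets[pairs[2L, j], ])]
      }
    }
    i <- which.max(internal)
    list(internal = internal[i], set = CODONS[subsets[, i]])
  }
  if (mode == "exhaustive") {
    res <- best_from(combn(N_CODONS, k))
    certified <- TRUE
  } else {
    chars <- do.call(rbind, strsplit(CODONS, ""))
    best <- NULL
    for (pos in 1:3) {
      for (b in CODON_BASES) {
        plane <- which(chars[, pos] == b)   # 16 codons
        if (k > length(plane)) next
        r <- best_from(matrix(plane[combn(length(plane), k)], nrow = k))
        if (is.null(best) || r$internal > best$internal) best <- r
      }
    }
    if (is.null(best)) {
      stop("no candidate plane can hold a set of size ", k, call. = FALSE)
    }
    res <- best
    certified <- FALSE
  }
  vol <- 9L * k
  out <- conductance_value(vol - 2L * res$internal, vol)
  out$k <- k
  out$exhaustive <- certified
  out$upper_bound <- !certified
  out$argmin <- res$set
  out
}

#' Average code conductance
#'
#' The mean of the 21 group conductances of a code partition,
#' \eqn{\Phi(C) = \frac{1}{21}\sum_{S \in C} \phi(S)} — the robustness
#' score of a whole code (lower = more robust to point mutations). The
#' standard genetic code scores 0.8113; the best wobble-like (M1) simulated
#' code attains 146/189 = 0.7725.
#'
#' @param part a `code_partition`.
#' @return a list with `value`, exact `numerator`/`denominator`, and
#'   `per_group` (list of `conductance_value` per group).
#' @examples
#' round(average_code_conductance(sgc_partition())$value, 4)
#' @export
average_code_conductance <- function(part) {
  stopifnot(inherits(part, "code_partition"))
  per <- lapply(part, set_conductance)
  # exact mean: common denominator 9 * lcm over group sizes * 21
  num <- 0
  den <- 1
  for (cv in per) {
    # num/den + cv$num/cv$den
    nd <- cv$denominator
    num <- num * nd + cv$numerator * den
    den <- den * nd
    r <- reduce_frac(num, den)
    num <- r["num"]; den <- r["den"]
  }
  den <- den * N_LABELS
  r <- reduce_frac(num, den)
  list(value = unname(num / den),
       numerator = unname(r["num"]), denominator = unname(r["den"]),
       per_group = per)
}
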