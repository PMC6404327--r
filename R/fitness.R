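#' Fitness of a code on a drawn codon sequence
#'
#' Given a code matrix \eqn{P}, a drawn sequence of representative codons
#' \eqn{c_{r_1}, \dots, c_{r_k}} (one per label) and a neighbourhood model,
#' the fitness is
#' \deqn{F = \sum_{c'_{r_1} \in N(c_{r_1})} \cdots \sum_{c'_{r_k} \in N(c_{r_k})}
#'       \prod_i P(l_i \mid c'_{r_i}),}
#' the total weight, over all combinations of misreadings of the drawn
#' codons, of producing the full label sequence. \eqn{F \cdot (1/64)^k} is
#' the total probability of the label sequence under a uniform codon prior.
#' Because the misreadings of different labels are independent, \eqn{F}
#' factorises into a product over labels of neighbourhood sums; all three
#' implementations below agree to floating-point accuracy.
#'
#' * `fitness_forward()` — the dynamic-programming forward recursion
#'   \eqn{\alpha_1(c) = P(l_1|c)}, \eqn{\alpha_k(c) = P(l_k|c)
#'   \sum_{c' \in N(c_{r_{k-1}})} \alpha_{k-1}(c')}, with
#'   \eqn{F = \sum_{c \in N(c_{r_k})} \alpha_k(c)}; cost per label is
#'   \eqn{O(|N|^2)} (about 2100 multiply–accumulate steps for 21 labels at
#'   |N| = 10, versus about \eqn{10^{21}} for direct enumeration).
#' * `fitness_factorized()` — the closed form, product of per-label
#'   neighbourhood sums; used by the simulation loop.
#' * `fitness_direct()` — brute-force enumeration of all \eqn{|N|^k}
#'   misreading tuples; exponential, so it refuses more than `max_labels`
#'   labels. It serves as an independent oracle for the other two.
#'
#' @param m code matrix (row-stochastic 64x21).
#' @param draw integer vector of drawn codon indices, one per label
#'   (typically from [draw_label_codons()]; shorter draws evaluate a
#'   truncated label sequence for testing).
#' @param model a `nbhd_model` or model name.
#' @param labels label indices matching `draw` (default `seq_along(draw)`).
#' @return the fitness value `F` (non-negative scalar).
#'   `fitness_forward` attaches an attribute `ops`, the number of
#'   multiply–accumulate steps \eqn{\sum_k |N(c_{r_k})|^2} of the recursion.
#' @examples
#' m <- matrix(1 / 21, 64, 21)
#' d <- rep(1L, 21)
#' fitness_forward(m, d, "M1")   # (4/21)^21
#' @export
fitness_forward <- function(m, draw, model, labels = seq_along(draw)) {
  model <- as_nbhd_model(model)
  nb <- nbhd_table(model)
  stopifnot(length(draw) == length(labels), length(draw) >= 1L)
  ops <- 0L
  # alpha over the current neighbourhood
  N1 <- nb[, draw[1L]]
  alpha <- m[N1, labels[1L]]
  ops <- ops + length(N1)^2
  if (length(draw) > 1L) {
    for (k in 2L:length(draw)) {
      Nk <- nb[, draw[k]]
      s <- sum(alpha)
      alpha <- s * m[Nk, labels[k]]
      ops <- ops + length(Nk)^2
    }
  }
  structure(sum(alpha), ops = ops)
}

#' @rdname fitness_forward
#' @export
fitness_factorized <- function(m, draw, model, labels = seq_along(draw)) {
  model <- as_nbhd_model(model)
  nb <- nbhd_table(model)
  f <- 1
  for (i in seq_along(draw)) {
    f <- f * sum(m[nb[, draw[i]], labels[i]])
  }
  f
}

#' @rdname fitness_forward
#' @param max_labels refusal threshold for the exponential enumeration
#'   (default 6).
#' @export
fitness_direct <- function(m, draw, model, labels = seq_along(draw),
                           max_labels = 6L) {
  model <- as_nbhd_model(model)
  k <- length(draw)
  if (k > max_labels) {
    stop("fitness_direct enumerates |N|^k tuples; refusing k = ", k,
         " > max_labels = ", max_labels,
         " (use fitness_forward for full-length draws)", call. = FALSE)
  }
  nb <- nbhd_table(model)
  sets <- lapply(seq_len(k), function(i) nb[, draw[i]])
  grid <- as.matrix(expand.grid(sets, KEEP.OUT.ATTRS = FALSE))
  f <- 0
  vals <- rep(1, nrow(grid))
  for (i in seq_len(k)) {
    vals <- vals * m[cbind(grid[, i], labels[i])]
  }
  sum(vals)
}

#' Total probability of the full label sequence
#'
#' Converts a fitness value into the total probability that the code
#' generates all 21 labels, \eqn{P(l_1, \dots, l_{21}) = F (1/64)^{21}}.
#'
#' @param f fitness value from one of the fitness functions.
#' @return the total probability (a very small positive number).
#' @export
total_probability <- function(f) {
  as.numeric(f) * (1 / N_CODONS)^N_LABELS
}
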