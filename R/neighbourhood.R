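#' Mistranslation neighbourhood models
#'
#' A neighbourhood model describes which codons the translation machinery
#' may confuse with a given codon: the codon itself plus every codon
#' differing by one nucleotide at an allowed ("varied") position.
#'
#' * `M1` — one varied position (default: the third), the wobble-like rule;
#'   |N(c)| = 4.
#' * `M2` — two varied positions (default: first and second); |N(c)| = 7.
#' * `M3` — all three positions; |N(c)| = 10.
#'
#' The defaults follow the canonical worked example for codon GGG; the
#' varied positions for M1/M2 are configurable because only the default
#' placement is canonical.
#'
#' @param name one of `"M1"`, `"M2"`, `"M3"`.
#' @param varied_positions integer positions in 1..3 that may be misread;
#'   defaults: 3 for M1, c(1, 2) for M2, 1:3 for M3 (fixed).
#' @return an object of class `nbhd_model` with elements `name` and
#'   `varied_positions`; neighbourhood size is `1 + 3 * length(varied_positions)`.
#' @examples
#' neighbourhood("GGG", nbhd_model("M1"))
#' @export
nbhd_model <- function(name = c("M1", "M2", "M3"), varied_positions = NULL) {
  name <- match.arg(name)
  default <- switch(name, M1 = 3L, M2 = c(1L, 2L), M3 = 1:3)
  vp <- if (is.null(varied_positions)) default else
    sort(unique(as.integer(varied_positions)))
  if (!all(vp %in% 1:3)) stop("varied positions must be in 1..3", call. = FALSE)
  expected <- switch(name, M1 = 1L, M2 = 2L, M3 = 3L)
  if (length(vp) != expected) {
    stop(name, " varies exactly ", expected, " codon position(s)",
         call. = FALSE)
  }
  structure(list(name = name, varied_positions = vp), class = "nbhd_model")
}

#' @export
print.nbhd_model <- function(x, ...) {
  cat(sprintf("neighbourhood model %s: varied position(s) %s, |N(c)| = %d\n",
              x$name, paste(x$varied_positions, collapse = ","),
              1L + 3L * length(x$varied_positions)))
  invisible(x)
}

as_nbhd_model <- function(model) {
  if (inherits(model, "nbhd_model")) model else nbhd_model(model)
}

#' Codon neighbourhood under a model
#'
#' The set of codons a given codon can be misread as, including the codon
#' itself: size 4 under M1, 7 under M2, 10 under M3.
#'
#' @param codon a codon string (e.g. `"GGG"`) or index in 1..64.
#' @param model a `nbhd_model` or model name.
#' @return character vector of codons, the original first, then the
#'   single-position variants in base order by position.
#' @examples
#' neighbourhood("GGG", "M2")
#' @export
neighbourhood <- function(codon, model) {
  model <- as_nbhd_model(model)
  if (is.numeric(codon)) codon <- codon_from_index(codon)
  stopifnot(length(codon) == 1L)
  codon_index(codon)  # validates
  chars <- strsplit(codon, "")[[1]]
  out <- codon
  for (pos in model$varied_positions) {
    for (b in setdiff(CODON_BASES, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      out <- c(out, paste(alt, collapse = ""))
    }
  }
  out
}

#' Neighbourhood lookup table
#'
#' All 64 neighbourhoods as an index matrix: column `c` holds the codon
#' indices of `N(c)` (the codon itself in the first row). Used by the
#' fitness functions and the compiled simulation loop.
#'
#' @param model a `nbhd_model` or model name.
#' @return an |N| x 64 integer matrix of codon indices.
#' @export
nbhd_table <- function(model) {
  model <- as_nbhd_model(model)
  vapply(CODONS, function(cd) codon_index(neighbourhood(cd, model)),
         integer(1L + 3L * length(model$varied_positions)))
}

#' Sample a codon for a label (Bayes draw)
#'
#' Draws the representative codon of a label from the code matrix by Bayes'
#' rule with a uniform prior over codons: codon j is selected with
#' probability \eqn{p_{jl} / \sum_j p_{jl}}.
#'
#' @param m code matrix.
#' @param label label index in 1..21 or label symbol.
#' @param n number of draws.
#' @return integer codon indices (length `n`).
#' @export
draw_codon_for_label <- function(m, label, n = 1L) {
  if (is.character(label)) label <- match(label, CODE_LABELS)
  stopifnot(length(label) == 1L, !is.na(label), label >= 1L, label <= N_LABELS)
  col <- m[, label]
  tot <- sum(col)
  if (tot <= 0) {
    stop("label ", CODE_LABELS[label],
         " has an all-zero column: no codon can encode it", call. = FALSE)
  }
  sample.int(N_CODONS, n, replace = TRUE, prob = col / tot)
}

#' Sample a full label-representative codon sequence
#'
#' One codon per label (21 in total, repeats allowed), each drawn
#' independently via [draw_codon_for_label()]. This is the random codon
#' sequence on which the stochastic fitness of a code is evaluated.
#'
#' @param m code matrix.
#' @return integer vector of 21 codon indices, one per label in label order.
#' @export
draw_label_codons <- function(m) {
  vapply(seq_len(N_LABELS), function(l) draw_codon_for_label(m, l), integer(1))
}
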