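#' Code partitions
#'
#' An unambiguous genetic code is a partition of the 64 codons into 21
#' disjoint, non-empty groups, one per label. A partition is represented as
#' a named list of character vectors of codons (class `code_partition`),
#' with names taken from the label symbols (or group identifiers for
#' anonymous codes such as the best simulated codes).
#'
#' @name code-partition
NULL

#' Construct and validate a code partition
#'
#' @param groups named list: label -> character vector of codons. The groups
#'   must be pairwise disjoint, jointly cover all 64 codons, and each must be
#'   non-empty; there must be exactly 21 of them.
#' @return an object of class `code_partition`.
#' @examples
#' sgc <- sgc_partition()
#' lengths(sgc)
#' @export
code_partition <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) != N_LABELS) {
    stop("a code partition needs exactly 21 groups, got ", length(groups),
         call. = FALSE)
  }
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must be uniquely named", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) {
    stop("empty group(s): ",
         paste(names(groups)[lengths(groups) == 0L], collapse = ", "),
         call. = FALSE)
  }
  all_codons <- unlist(groups, use.names = FALSE)
  codon_index(all_codons)  # errors on invalid codons
  if (anyDuplicated(all_codons)) {
    stop("codon(s) assigned to more than one group: ",
         paste(unique(all_codons[duplicated(all_codons)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(all_codons) != N_CODONS) {
    stop("partition covers ", length(all_codons), " codons, expected 64 (",
         "missing: ", paste(setdiff(CODONS, all_codons), collapse = ", "), ")",
         call. = FALSE)
  }
  groups <- lapply(groups, function(g) sort(unname(g)))
  structure(groups, class = "code_partition")
}

#' @export
print.code_partition <- function(x, ...) {
  cat("code partition: 21 groups over 64 codons\n")
  sizes <- lengths(x)
  for (nm in names(x)) {
    cat(sprintf("  %-3s (%d): %s\n", nm, sizes[[nm]],
                paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' The standard genetic code as a partition
#'
#' The canonical assignment of the 64 codons to the 20 amino acids and the
#' stop signal (`*`): 21 groups, with the familiar block structure
#' (e.g. stop = \{TAA, TAG, TGA\}, tryptophan = \{TGG\}, leucine and
#' arginine with six codons each). Loaded from the partition TSV shipped
#' with the package.
#'
#' @return a `code_partition` whose names are the 21 label symbols.
#' @export
sgc_partition <- function() {
  if (is.null(.ambicode_cache$sgc)) {
    path <- system.file("extdata", "sgc_partition.tsv", package = "ambicode",
                        mustWork = TRUE)
    .ambicode_cache$sgc <- read_partition(path)
  }
  .ambicode_cache$sgc
}

#' Degenerate code matrix of a partition
#'
#' Each codon row becomes the indicator distribution of its group's label:
#' \eqn{p_{cl} = 1} iff codon c belongs to group l. Such matrices have zero
#' code entropy and coding strength 1 for every group. Groups are matched to
#' label columns by name when the partition uses label symbols, otherwise by
#' position (group i -> label i).
#'
#' @param part a `code_partition`.
#' @return a 64x21 degenerate code matrix.
#' @export
partition_to_matrix <- function(part) {
  stopifnot(inherits(part, "code_partition"))
  cols <- if (all(names(part) %in% CODE_LABELS)) {
    match(names(part), CODE_LABELS)
  } else {
    seq_len(N_LABELS)
  }
  m <- matrix(0, N_CODONS, N_LABELS, dimnames = list(CODONS, CODE_LABELS))
  for (i in seq_along(part)) {
    m[codon_index(part[[i]]), cols[i]] <- 1
  }
  validate_code_matrix(m)
}

#' Read / write a partition as TSV
#'
#' Two tab-separated columns, `codon` and `label`, 64 rows. Labels may be
#' the canonical symbols or arbitrary group identifiers.
#'
#' @param path file path.
#' @return `read_partition` returns a `code_partition`; `write_partition`
#'   returns `path` invisibly.
#' @export
read_partition <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("codon", "label") %in% names(df))) {
    stop("partition TSV needs 'codon' and 'label' columns", call. = FALSE)
  }
  groups <- split(df$codon, factor(df$label, levels = unique(df$label)))
  # canonical label order when the file uses the standard symbols
  if (setequal(names(groups), CODE_LABELS)) {
    groups <- groups[CODE_LABELS]
  }
  code_partition(groups)
}

#' @rdname read_partition
#' @param part partition to write.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "code_partition"))
  df <- data.frame(
    codon = unlist(part, use.names = FALSE),
    label = rep(names(part), lengths(part)),
    stringsAsFactors = FALSE
  )
  df <- df[order(codon_index(df$codon)), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
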