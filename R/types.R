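#' Construct a gene universe
#'
#' The universe (background) is the finite set of gene identifiers that every
#' enrichment statistic conditions on: permutation draws are taken from it and
#' hypergeometric tails are computed against its size. Identifiers are opaque
#' tokens compared by exact, case-sensitive string equality.
#'
#' @param genes Character vector of gene identifiers. Duplicates are collapsed
#'   (first occurrence kept) with a warning; empty tokens are an error.
#' @return An object of class `gene_universe`: a character vector with the
#'   input (first-seen) order preserved.
#' @examples
#' u <- gene_universe(c("FBgn01", "FBgn02", "FBgn03"))
#' length(u)
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty universe")
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop("universe contains empty or missing identifiers")
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    warning(sprintf("%d duplicate identifier(s) collapsed in universe", n_dup))
    genes <- genes[!duplicated(genes)]
  }
  structure(genes, class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("gene_universe with %d genes\n", length(x)))
  show <- utils::head(unclass(x), 6L)
  cat("  ", paste(show, collapse = ", "),
      if (length(x) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of genes in the background
#'
#' @param universe A `gene_universe`.
#' @return Integer count of background genes (N).
#' @export
universe_size <- function(universe) {
  stopifnot(inherits(universe, "gene_universe"))
  length(universe)
}

#' Construct a gene set
#'
#' A named collection of unique gene identifiers, e.g. a differential-expression
#' list. Mirrors one line of a GMT file.
#'
#' @param name Non-empty set name.
#' @param members Character vector of member identifiers; duplicates collapsed
#'   with a warning.
#' @param description Free-text description (GMT column 2); default `""`.
#' @return An object of class `gene_set` with fields `name`, `description`,
#'   `members`.
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("gene set name must be a non-empty string")
  }
  members <- as.character(members)
  if (anyNA(members) || any(!nzchar(members))) {
    stop("gene set members contain empty or missing identifiers")
  }
  if (anyDuplicated(members)) {
    warning(sprintf("%d duplicate member(s) collapsed in gene set '%s'",
                    sum(duplicated(members)), name))
    members <- members[!duplicated(members)]
  }
  structure(list(name = name, description = as.character(description)[1L],
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Restrict a gene set to a universe
#'
#' Off-universe members are dropped with a warning: statistics must condition
#' on the declared background, and genes outside it have no null distribution.
#'
#' @param set A `gene_set`.
#' @param universe A `gene_universe`.
#' @return The restricted `gene_set`. Erroring if no members survive, since an
#'   empty query admits no enrichment test.
#' @export
restrict_to_universe <- function(set, universe) {
  stopifnot(inherits(set, "gene_set"), inherits(universe, "gene_universe"))
  keep <- set$members %in% universe
  if (!all(keep)) {
    warning(sprintf("%d member(s) of '%s' absent from universe; dropped",
                    sum(!keep), set$name))
  }
  members <- set$members[keep]
  if (length(members) == 0L) stop("empty query set")
  gene_set(set$name, members, set$description)
}
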