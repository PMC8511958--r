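#' Read a gene universe from a plain-text file
#'
#' One identifier per line, UTF-8. Blank lines are skipped; duplicate lines
#' collapse to one occurrence with a warning. First-seen order is preserved.
#'
#' @param path Path to the universe file.
#' @return A [gene_universe].
#' @export
read_universe <- function(path) {
  if (!file.exists(path)) stop(sprintf("universe file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty universe")
  gene_universe(lines)
}

#' Write a gene universe
#'
#' @param universe A [gene_universe].
#' @param path Output path; one identifier per line, LF endings.
#' @export
write_universe <- function(universe, path) {
  stopifnot(inherits(universe, "gene_universe"))
  writeLines(unclass(universe), path, sep = "\n")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is the standard tab-separated gene-set exchange format: each line holds
#' a set name, a description, then one or more member identifiers.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set] objects, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file")
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)))
    }
    sets[[i]] <- gene_set(fields[1L], fields[-(1:2)], fields[2L])
  }
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of [gene_set] objects (a bare `gene_set` is accepted).
#' @param path Output path. Lines are written in input order with LF endings.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (length(sets) == 0L) stop("no gene sets to write")
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    if (length(s$members) == 0L) {
      stop(sprintf("gene set '%s' has no members; refusing to write", s$name))
    }
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a TF target table
#'
#' Reads a three-column TSV (`tf_id`, `gene_id`, `score`) of ChIP-seq-derived
#' TF target assignments with peak scores, and conditions it on a declared
#' gene universe: rows whose gene is absent from the universe are dropped
#' (with a counted warning) so that the permutation and hypergeometric nulls
#' share a single background. Duplicate (tf, gene) rows keep the maximum
#' score — a gene is either a target or not, and its strongest peak
#' represents it.
#'
#' @param path Path to the TSV (header `tf_id\tgene_id\tscore`).
#' @param universe A [gene_universe]; the single source of truth for the
#'   background size.
#' @return A `tf_target_table`: a data.frame with columns `tf_id`, `gene_id`,
#'   `score`, attribute `n_dropped` (off-universe rows removed).
#' @export
read_tf_targets <- function(path, universe) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop(sprintf("TF target file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character"),
                          quote = "", comment.char = "")
  need <- c("tf_id", "gene_id", "score")
  if (!all(need %in% names(df))) {
    stop(sprintf("TF target file must have columns %s", paste(need, collapse = ", ")))
  }
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(!is.finite(score) | score <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-positive or non-numeric score at data row %d (value '%s')",
                 bad[1L], df$score[bad[1L]]))
  }
  tf_target_table(data.frame(tf_id = df$tf_id, gene_id = df$gene_id,
                             score = score, stringsAsFactors = FALSE),
                  universe)
}

#' Construct/validate a TF target table
#'
#' @param df A data.frame with columns `tf_id`, `gene_id`, `score`.
#' @param universe A [gene_universe] to condition on.
#' @return A validated `tf_target_table` (see [read_tf_targets]).
#' @export
tf_target_table <- function(df, universe) {
  stopifnot(is.data.frame(df), inherits(universe, "gene_universe"))
  stopifnot(all(c("tf_id", "gene_id", "score") %in% names(df)))
  if (!all(is.finite(df$score)) || any(df$score <= 0)) {
    stop("all peak scores must be finite and > 0")
  }
  in_uni <- df$gene_id %in% universe
  n_dropped <- sum(!in_uni)
  if (n_dropped > 0L) {
    warning(sprintf("%d target row(s) with genes absent from universe dropped", n_dropped))
    df <- df[in_uni, , drop = FALSE]
  }
  key <- paste(df$tf_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (tf, gene) row(s); keeping maximum score",
                    sum(duplicated(key))))
    o <- order(key, -df$score)
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(key[o]), , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("TF target table is empty after restriction to universe")
  rownames(df) <- NULL
  structure(df, class = c("tf_target_table", "data.frame"),
            n_dropped = n_dropped)
}

#' Write a TF target table
#'
#' @param table A `tf_target_table`.
#' @param path Output TSV path (header `tf_id\tgene_id\tscore`, LF endings).
#' @export
write_tf_targets <- function(table, path) {
  stopifnot(inherits(table, "tf_target_table"))
  utils::write.table(as.data.frame(table)[, c("tf_id", "gene_id", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' TF identifiers present in a target table
#'
#' @param table A `tf_target_table`.
#' @return Character vector of distinct TF ids, in first-seen order.
#' @export
tf_ids <- function(table) {
  stopifnot(inherits(table, "tf_target_table"))
  unique(table$tf_id)
}
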