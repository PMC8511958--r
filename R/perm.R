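#' Permutation test configuration
#'
#' Settings for the Monte-Carlo null of the TF enrichment test.
#'
#' @param n_perm Number of random draws (default 1e6, the conventional scale
#'   for per-TF permutation p-values; tests and interactive work typically use
#'   1e4 or less).
#' @param seed Integer seed; the draw stream is fully reproducible from it and
#'   is recorded in every output row.
#' @param convention P-value convention. `"plain"` (default) is the plain
#'   proportion b / n_perm of draws whose statistic meets or exceeds the
#'   observed one; it can be exactly 0. `"addone"` is (b + 1) / (n_perm + 1),
#'   strictly positive and never anti-conservative.
#' @param enumeration_threshold When the number of distinct draws
#'   `choose(N, draw_size)` is at most this, all subsets are enumerated and
#'   p-values are exact (and independent of `seed` and `convention`).
#' @param chunk_size Draws evaluated per block (memory/speed trade-off only;
#'   results are independent of it).
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_perm = 1e6, seed = 1L,
                        convention = c("plain", "addone"),
                        enumeration_threshold = 10000,
                        chunk_size = 20000) {
  convention <- match.arg(convention)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  structure(list(n_perm = n_perm, seed = as.integer(seed),
                 convention = convention,
                 enumeration_threshold = enumeration_threshold,
                 chunk_size = as.integer(chunk_size)),
            class = "perm_config")
}

#' Observed per-TF intersection statistics
#'
#' For each TF in the table: the count of query genes among its targets and
#' the summed peak score of those genes (non-targets contribute zero). The
#' score statistic is the sum, which is monotone in both membership and score
#' magnitude and reduces to the count statistic under unit scores.
#'
#' @param query A [gene_set]; off-universe members are dropped with a warning
#'   before computation.
#' @param table A `tf_target_table` (see [read_tf_targets]).
#' @param universe The [gene_universe] the table was conditioned on.
#' @return A data.frame with columns `tf_id`, `n_targets_total`, `k_observed`,
#'   `score_observed`, one row per TF in first-seen table order.
#' @export
observed_stats <- function(query, table, universe) {
  stopifnot(inherits(table, "tf_target_table"), inherits(universe, "gene_universe"))
  query <- restrict_to_universe(query, universe)
  tfs <- tf_ids(table)
  hit <- table$gene_id %in% query$members
  k <- vapply(tfs, function(tf) sum(hit & table$tf_id == tf), integer(1L))
  s <- vapply(tfs, function(tf) sum(table$score[hit & table$tf_id == tf]), numeric(1L))
  ntot <- vapply(tfs, function(tf) sum(table$tf_id == tf), integer(1L))
  data.frame(tf_id = tfs, n_targets_total = ntot,
             k_observed = k, score_observed = s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate the shared null draws
#'
#' Uniform samples of `draw_size` distinct genes (without replacement) from
#' the universe. One stream of draws is shared across all TFs: the null is
#' identical either way, and sharing makes a 445-TF scan at 1e6 draws
#' tractable, at the cost of cross-TF dependence only in the Monte-Carlo
#' noise.
#'
#' When `choose(N, draw_size) <= config$enumeration_threshold` every distinct
#' subset is returned exactly once (exhaustive mode) and the result does not
#' depend on the seed.
#'
#' @param universe A [gene_universe].
#' @param draw_size Draw size, `1 <= draw_size <= length(universe)`.
#' @param config A [perm_config].
#' @return An integer matrix (draws in rows, gene indices into `universe` in
#'   columns) with attribute `exhaustive` (logical).
#' @export
permutation_draws <- function(universe, draw_size, config = perm_config()) {
  stopifnot(inherits(universe, "gene_universe"), inherits(config, "perm_config"))
  N <- length(universe)
  if (draw_size < 1L || draw_size > N) {
    stop(sprintf("draw_size must lie in [1, %d]", N))
  }
  if (choose(N, draw_size) <= config$enumeration_threshold) {
    idx <- t(utils::combn(N, draw_size))
    return(structure(idx, exhaustive = TRUE))
  }
  set.seed(config$seed)
  idx <- draw_chunk(N, draw_size, config$n_perm)
  structure(idx, exhaustive = FALSE)
}

# b draws of size q from 1..N, one matrix row per draw; advances the RNG
draw_chunk <- function(N, q, b) {
  out <- matrix(0L, nrow = b, ncol = q)
  for (i in seq_len(b)) out[i, ] <- sample.int(N, q)
  out
}

# Evaluate count and score statistics of a block of draws against all TFs.
# score_mat is the N x T dense matrix of per-gene scores (0 for non-targets);
# member_mat the 0/1 version. Returns list(counts, scores), each b x T.
draw_statistics <- function(idx, member_mat, score_mat) {
  b <- nrow(idx)
  q <- ncol(idx)
  D <- Matrix::sparseMatrix(i = rep(seq_len(b), each = q),
                            j = as.vector(t(idx)),
                            x = 1,
                            dims = c(b, nrow(score_mat)))
  list(counts = as.matrix(D %*% member_mat),
       scores = as.matrix(D %*% score_mat))
}

#' Permutation enrichment test of TF targets in a query gene set
#'
#' The core test: for every TF, the observed target count and peak-score mass
#' inside the query set are compared against `n_perm` uniform draws of the
#' same size from the background universe, giving two permutation p-values —
#' `p_count` for the number of targets hit and `p_score` for their summed
#' peak scores. Exceedance is `>=` (ties count toward the p-value), which
#' keeps the p-values valid (super-uniform) under the null. All TFs are
#' evaluated against one shared draw stream.
#'
#' `p_score` is adjusted across the family of all TFs by both
#' Benjamini-Hochberg and Bonferroni; set `adjust_count = TRUE` to also
#' adjust `p_count`.
#'
#' @inheritParams observed_stats
#' @param config A [perm_config].
#' @param adjust_count Also adjust the count p-values (default FALSE; the
#'   default report adjusts only the score p-values).
#' @return A data.frame of class `tf_enrichment` sorted by ascending
#'   `p_score` (ties: ascending `p_count`, then `tf_id`), with columns
#'   `tf_id`, `n_targets_total`, `k_observed`, `score_observed`, `p_count`,
#'   `p_score`, `p_score_bh`, `p_score_bonferroni` (and `p_count_bh`,
#'   `p_count_bonferroni` when requested), plus provenance columns `n_perm`
#'   and `seed`. Attribute `exhaustive` records whether the null was
#'   enumerated exactly.
#' @examples
#' u <- make_universe(30, seed = 1)
#' tab <- tf_target_table(
#'   data.frame(tf_id = "tf1", gene_id = u[1:8], score = 1:8), u)
#' q <- gene_set("q", u[c(1, 2, 20)])
#' tf_enrichment_test(q, tab, u, perm_config(n_perm = 1000, seed = 7))
#' @export
tf_enrichment_test <- function(query, table, universe,
                               config = perm_config(), adjust_count = FALSE) {
  stopifnot(inherits(table, "tf_target_table"),
            inherits(universe, "gene_universe"),
            inherits(config, "perm_config"))
  query <- restrict_to_universe(query, universe)
  N <- length(universe)
  q <- length(query$members)
  tfs <- tf_ids(table)
  T_n <- length(tfs)
  if (T_n == 0L) stop("no TFs in target table")

  gi <- match(table$gene_id, universe)           # validated members, no NA
  ti <- match(table$tf_id, tfs)
  score_mat <- matrix(0, nrow = N, ncol = T_n)
  score_mat[cbind(gi, ti)] <- table$score
  member_mat <- matrix(0, nrow = N, ncol = T_n)
  member_mat[cbind(gi, ti)] <- 1

  qidx <- match(query$members, universe)
  k_obs <- as.integer(colSums(member_mat[qidx, , drop = FALSE]))
  s_obs <- colSums(score_mat[qidx, , drop = FALSE])
  # tolerance so that summation order cannot break exact score ties
  s_tol <- s_obs - 1e-12 * (1 + abs(s_obs))

  exhaustive <- choose(N, q) <= config$enumeration_threshold
  b_count <- numeric(T_n)
  b_score <- numeric(T_n)
  if (exhaustive) {
    idx <- t(utils::combn(N, q))
    n_draws <- nrow(idx)
    st <- draw_statistics(idx, member_mat, score_mat)
    b_count <- colSums(st$counts >= rep(k_obs, each = n_draws))
    b_score <- colSums(st$scores >= rep(s_tol, each = n_draws))
    p_count <- b_count / n_draws
    p_score <- b_score / n_draws
  } else {
    n_draws <- config$n_perm
    set.seed(config$seed)
    done <- 0L
    while (done < n_draws) {
      b <- min(config$chunk_size, n_draws - done)
      idx <- draw_chunk(N, q, b)
      st <- draw_statistics(idx, member_mat, score_mat)
      b_count <- b_count + colSums(st$counts >= rep(k_obs, each = b))
      b_score <- b_score + colSums(st$scores >= rep(s_tol, each = b))
      done <- done + b
    }
    if (config$convention == "plain") {
      p_count <- b_count / n_draws
      p_score <- b_score / n_draws
    } else {
      p_count <- (b_count + 1) / (n_draws + 1)
      p_score <- (b_score + 1) / (n_draws + 1)
    }
  }

  rec <- data.frame(tf_id = tfs,
                    n_targets_total = as.integer(tabulate(ti, nbins = T_n)),
                    k_observed = k_obs,
                    score_observed = s_obs,
                    p_count = p_count,
                    p_score = p_score,
                    stringsAsFactors = FALSE)
  rec$p_score_bh <- bh_adjust(rec$p_score, m = T_n)
  rec$p_score_bonferroni <- bonferroni(rec$p_score, m = T_n)
  if (adjust_count) {
    rec$p_count_bh <- bh_adjust(rec$p_count, m = T_n)
    rec$p_count_bonferroni <- bonferroni(rec$p_count, m = T_n)
  }
  rec$n_perm <- n_draws
  rec$seed <- if (exhaustive) NA_integer_ else config$seed
  rec <- rec[order(rec$p_score, rec$p_count, rec$tf_id), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, class = c("tf_enrichment", "data.frame"),
            exhaustive = exhaustive, query = query$name)
}

#' Ranked TF enrichment report
#'
#' Lays out enrichment records as a TSV-ready table in the conventional
#' column order: TF, total targets, targets in set, count p, score p, then
#' the BH- and Bonferroni-corrected score p-values, with provenance.
#'
#' @param records A `tf_enrichment` data.frame from [tf_enrichment_test].
#' @return A data.frame with columns `tf_id`, `n_targets_total`,
#'   `k_observed`, `p_count`, `p_score`, `p_score_bh`, `p_score_bonferroni`,
#'   `n_perm`, `seed`, in the records' (already deterministic) order.
#' @export
rank_report <- function(records) {
  stopifnot(inherits(records, "tf_enrichment"), nrow(records) >= 1L)
  cols <- c("tf_id", "n_targets_total", "k_observed", "p_count", "p_score",
            "p_score_bh", "p_score_bonferroni")
  extra <- intersect(c("p_count_bh", "p_count_bonferroni"), names(records))
  as.data.frame(records)[, c(cols, extra, "n_perm", "seed"), drop = FALSE]
}

#' @export
print.tf_enrichment <- function(x, ...) {
  cat(sprintf("TF permutation enrichment: %d TF(s), %s null (%s draws)\n",
              nrow(x),
              if (isTRUE(attr(x, "exhaustive"))) "exhaustive" else "Monte-Carlo",
              format(x$n_perm[1L], big.mark = ",")))
  df <- as.data.frame(x)
  for (cc in grep("^p_", names(df))) df[[cc]] <- signif(df[[cc]], 3)
  print.data.frame(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat(sprintf("... and %d more row(s)\n", nrow(df) - 10L))
  invisible(x)
}
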