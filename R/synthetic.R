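#' Specification of a synthetic benchmark
#'
#' Bundles the parameters of the planted-signal generator. The defaults
#' emulate a genome-scale regulatory screen: a universe of about 14,000
#' genes, 445 TFs whose per-TF target counts span roughly 500-9,000 genes,
#' log-normal (positive, right-skewed) peak scores as ChIP peak scores
#' typically are, and query sets of 45-100 genes as differential-expression
#' lists of that size produce.
#'
#' @param N_bg Universe size.
#' @param T_n Number of TFs.
#' @param target_count_range Integer interval the per-TF target counts are
#'   drawn from (uniformly). Must fit inside `[1, N_bg]`.
#' @param score_meanlog,score_sdlog Log-normal peak-score parameters
#'   (location/scale on the log scale).
#' @param planted_tfs Character ids of TFs whose targets seed the query (the
#'   first is used by [make_query_with_planted]).
#' @param enrichment_fraction Fraction of the query drawn from the planted
#'   TF's targets, in `[0, 1]`.
#' @param high_score_bias Exponent b >= 0; planted targets are sampled with
#'   weight proportional to score^b, so b > 0 concentrates the plant in
#'   high-score targets and separates the score signal from the count signal.
#' @param query_size Query set size (<= N_bg).
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N_bg = 13964, T_n = 445,
                           target_count_range = c(500, 9000),
                           score_meanlog = 0, score_sdlog = 1,
                           planted_tfs = character(0),
                           enrichment_fraction = 0,
                           high_score_bias = 0,
                           query_size = 100, seed = 1L) {
  stopifnot(N_bg >= 1, T_n >= 1, length(target_count_range) == 2L)
  target_count_range <- as.integer(target_count_range)
  if (target_count_range[1L] < 1L || target_count_range[2L] > N_bg ||
      target_count_range[1L] > target_count_range[2L]) {
    stop("target_count_range must be an increasing interval inside [1, N_bg]")
  }
  if (enrichment_fraction < 0 || enrichment_fraction > 1) {
    stop("enrichment_fraction must lie in [0, 1]")
  }
  if (high_score_bias < 0) stop("high_score_bias must be >= 0")
  if (query_size < 1 || query_size > N_bg) stop("query_size must lie in [1, N_bg]")
  structure(list(N_bg = as.integer(N_bg), T_n = as.integer(T_n),
                 target_count_range = target_count_range,
                 score_meanlog = score_meanlog, score_sdlog = score_sdlog,
                 planted_tfs = as.character(planted_tfs),
                 enrichment_fraction = enrichment_fraction,
                 high_score_bias = high_score_bias,
                 query_size = as.integer(query_size), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Small benchmark profile
#'
#' A reduced configuration (50 TFs over a 5,000-gene universe, target counts
#' 250-3,000 — the same 5-60% span of the universe as the genome-scale
#' defaults) that keeps calibration and power runs fast.
#'
#' @param ... Overrides passed to [synthetic_spec].
#' @export
synthetic_spec_small <- function(...) {
  args <- list(...)
  base <- list(N_bg = 5000, T_n = 50, target_count_range = c(250, 3000),
               query_size = 100)
  base[names(args)] <- args
  do.call(synthetic_spec, base)
}

#' Generate a synthetic gene universe
#'
#' @param N_bg Number of genes (>= 1).
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return A [gene_universe] of `N_bg` unique identifiers, deterministic
#'   from `seed` (the seed shuffles the identifier order so downstream index
#'   arithmetic never relies on lexicographic layout).
#' @export
make_universe <- function(N_bg, seed = 1L, prefix = "gene") {
  if (N_bg < 1) stop("N_bg must be >= 1")
  set.seed(seed)
  ids <- sprintf("%s%0*d", prefix, nchar(as.character(N_bg)), seq_len(N_bg))
  gene_universe(sample(ids))
}

#' Generate a synthetic TF target table
#'
#' Each TF's target count is drawn uniformly from the spec's range, its
#' targets sampled without replacement from the universe, and its peak
#' scores i.i.d. log-normal.
#'
#' @param spec A [synthetic_spec].
#' @param universe A [gene_universe] of size `spec$N_bg` (generated if
#'   missing).
#' @return A `tf_target_table` with TFs named `tf001`, `tf002`, ...
#' @export
make_tf_table <- function(spec, universe = make_universe(spec$N_bg, spec$seed)) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(universe, "gene_universe"))
  if (spec$target_count_range[2L] > length(universe)) {
    stop("target_count_range exceeds universe size")
  }
  set.seed(spec$seed + 1L)
  tfs <- sprintf("tf%03d", seq_len(spec$T_n))
  counts <- sample.int(spec$target_count_range[2L] - spec$target_count_range[1L] + 1L,
                       spec$T_n, replace = TRUE) + spec$target_count_range[1L] - 1L
  parts <- lapply(seq_len(spec$T_n), function(t) {
    genes <- sample(unclass(universe), counts[t])
    data.frame(tf_id = tfs[t], gene_id = genes,
               score = stats::rlnorm(counts[t], spec$score_meanlog, spec$score_sdlog),
               stringsAsFactors = FALSE)
  })
  tf_target_table(do.call(rbind, parts), universe)
}

#' Generate a query set with a planted TF signal
#'
#' Builds a query of `query_size` genes in which
#' `round(enrichment_fraction * query_size)` genes are sampled (without
#' replacement) from the planted TF's targets with weight proportional to
#' score^`high_score_bias`, and the remainder uniformly from the rest of the
#' universe. With `enrichment_fraction = 0` the query is a uniform draw (a
#' true null); with 1 it lies entirely inside the planted target set.
#'
#' @param spec A [synthetic_spec] with at least one planted TF when
#'   `enrichment_fraction > 0`.
#' @param table A `tf_target_table` containing the planted TF.
#' @param universe The [gene_universe].
#' @return A list with elements `query` (a [gene_set]) and `truth` (list:
#'   `planted_tf`, `n_planted` genes actually taken from the target set,
#'   `enrichment_fraction`, `high_score_bias`, `seed`).
#' @export
make_query_with_planted <- function(spec, table, universe) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(table, "tf_target_table"),
            inherits(universe, "gene_universe"))
  set.seed(spec$seed + 2L)
  n_plant <- round(spec$enrichment_fraction * spec$query_size)
  planted_tf <- NA_character_
  planted <- character(0)
  if (n_plant > 0L) {
    if (length(spec$planted_tfs) == 0L) stop("enrichment_fraction > 0 requires a planted TF")
    planted_tf <- spec$planted_tfs[1L]
    rows <- table$tf_id == planted_tf
    if (!any(rows)) stop(sprintf("planted TF '%s' not in target table", planted_tf))
    tgt_genes <- table$gene_id[rows]
    tgt_scores <- table$score[rows]
    if (n_plant > length(tgt_genes)) {
      stop(sprintf("cannot plant %d genes from %d targets of '%s'",
                   n_plant, length(tgt_genes), planted_tf))
    }
    w <- tgt_scores^spec$high_score_bias
    planted <- sample(tgt_genes, n_plant, prob = w / sum(w))
  }
  rest_pool <- setdiff(unclass(universe), planted)
  filler <- sample(rest_pool, spec$query_size - n_plant)
  query <- gene_set("synthetic_query", c(planted, filler))
  list(query = query,
       truth = list(planted_tf = planted_tf, n_planted = n_plant,
                    enrichment_fraction = spec$enrichment_fraction,
                    high_score_bias = spec$high_score_bias, seed = spec$seed))
}

#' Construct two sets with an exact overlap
#'
#' Builds a universe of size N and two gene sets with |A| = nA, |B| = nB and
#' |A intersect B| = k exactly — fixtures for overlap-table rows with known
#' ground truth.
#'
#' @param N Universe size.
#' @param nA,nB Set sizes.
#' @param k Exact overlap, `k <= min(nA, nB)` and `nA + nB - k <= N`.
#' @param seed Integer seed.
#' @return A list with `set_a`, `set_b` ([gene_set]s) and `universe`.
#' @export
make_overlapping_sets <- function(N, nA, nB, k, seed = 1L) {
  if (k > min(nA, nB)) stop("overlap k exceeds a set size")
  if (nA + nB - k > N) stop("infeasible: nA + nB - k exceeds universe size N")
  universe <- make_universe(N, seed)
  set.seed(seed + 1L)
  perm <- sample(unclass(universe))
  shared <- perm[seq_len(k)]
  a_only <- perm[k + seq_len(nA - k)]
  b_only <- perm[nA + seq_len(nB - k)]
  list(set_a = gene_set("A", c(shared, a_only)),
       set_b = gene_set("B", c(shared, b_only)),
       universe = universe)
}
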