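#!/usr/bin/env Rscript
# Opt-in full-scale smoke run: 445 TFs over a ~14,000-gene universe with one
# shared stream of 1e6 draws, as a genome-scale TF scan would be configured.
# Prints per-stage timings; not part of the default test suite.
#   Rscript scripts/full_scale_smoke.R [--seed <int>] [--n-perm <int>]

suppressPackageStartupMessages(library(permenrich))

args <- commandArgs(trailingOnly = TRUE)
get_flag <- function(name, default) {
  i <- which(args == name)
  if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
}
seed <- as.integer(get_flag("--seed", "1"))
n_perm <- as.integer(get_flag("--n-perm", "1000000"))

spec <- synthetic_spec(N_bg = 13964, T_n = 445,
                       target_count_range = c(500, 9000),
                       planted_tfs = "tf007", enrichment_fraction = 0.4,
                       high_score_bias = 2, query_size = 100, seed = seed)

t0 <- proc.time()["elapsed"]
universe <- make_universe(spec$N_bg, spec$seed)
targets <- make_tf_table(spec, universe)
query <- make_query_with_planted(spec, targets, universe)
cat(sprintf("generation: %.1f s (%d target rows)\n",
            proc.time()["elapsed"] - t0, nrow(targets)))

t1 <- proc.time()["elapsed"]
res <- tf_enrichment_test(query$query, targets, universe,
                          perm_config(n_perm = n_perm, seed = seed + 1L,
                                      enumeration_threshold = 0))
cat(sprintf("enrichment scan: %.1f s (%d TFs x %d draws)\n",
            proc.time()["elapsed"] - t1, nrow(res), n_perm))
cat(sprintf("planted TF rank by p_score: %d (p_score = %g, BH = %g)\n",
            which(res$tf_id == "tf007"),
            res$p_score[res$tf_id == "tf007"],
            res$p_score_bh[res$tf_id == "tf007"]))
print(utils::head(rank_report(res), 5))
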