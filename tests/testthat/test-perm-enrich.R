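test_that("observed statistics are the intersection count and score mass", {
  u <- gene_universe(c("a", "b", "c", "d", "e"))
  tab <- toy_table(u, c("b", "c", "d"), c(2, 3, 1))
  st <- observed_stats(gene_set("q", c("a", "b", "c")), tab, u)
  expect_identical(st$k_observed, 2L)
  expect_equal(st$score_observed, 5)
  expect_identical(st$n_targets_total, 3L)

  st0 <- observed_stats(gene_set("q", c("a", "e")), tab, u)
  expect_identical(st0$k_observed, 0L)
  expect_equal(st0$score_observed, 0)

  full <- observed_stats(gene_set("q", c("a", "b", "c", "d", "e")), tab, u)
  expect_identical(full$k_observed, 3L)
  expect_equal(full$score_observed, 6)
})

test_that("permutation draws are uniform without replacement and reproducible", {
  u <- toy_universe(10)
  cfg <- perm_config(n_perm = 5000, seed = 3, enumeration_threshold = 0)

  d1 <- permutation_draws(u, 1, cfg)
  freq <- tabulate(d1[, 1], nbins = 10) / nrow(d1)
  se <- sqrt(0.1 * 0.9 / nrow(d1))
  expect_true(all(abs(freq - 0.1) <= 4 * se))

  # forced draw: size-N draws contain every gene
  dN <- permutation_draws(u, 10, cfg)
  expect_true(all(apply(dN, 1, function(r) identical(sort(r), 1:10))))

  d2 <- permutation_draws(u, 3, cfg)
  d3 <- permutation_draws(u, 3, cfg)
  expect_identical(d2, d3)
  expect_true(all(apply(d2, 1, anyDuplicated) == 0L))

  expect_error(permutation_draws(u, 11, cfg), "draw_size")
  # small problems enumerate exactly once per subset
  dE <- permutation_draws(u, 3, perm_config(enumeration_threshold = 500))
  expect_true(attr(dE, "exhaustive"))
  expect_identical(nrow(dE), 120L)
  expect_identical(anyDuplicated(as.data.frame(dE)), 0L)
})

test_that("exhaustive enumeration gives the exact hypergeometric p-value", {
  u <- toy_universe(10)
  tab <- toy_table(u, paste0("g", 1:4))
  q <- gene_set("q", c("g1", "g2", "g10"))
  r <- tf_enrichment_test(q, tab, u, perm_config(enumeration_threshold = 200))
  expect_true(attr(r, "exhaustive"))
  expect_equal(r$p_count, 40 / 120)
  expect_equal(r$p_score, 40 / 120)
  expect_equal(r$p_count, hypergeom_tail(10, 4, 3, 2, "over"))
  # exact mode is independent of the seed
  r2 <- tf_enrichment_test(q, tab, u,
                           perm_config(seed = 999, enumeration_threshold = 200))
  expect_equal(r$p_count, r2$p_count)
  expect_equal(r$p_score, r2$p_score)
})

test_that("degenerate target sets give p = 1", {
  u <- toy_universe(10)
  # targets = whole universe: the count statistic is constant at |query|
  tab <- toy_table(u, paste0("g", 1:10))
  r <- tf_enrichment_test(gene_set("q", c("g1", "g5")), tab, u,
                          perm_config(n_perm = 500, enumeration_threshold = 0))
  expect_equal(r$p_count, 1)
  expect_equal(r$p_score, 1)
  # query disjoint from targets: statistic identically 0 ties every draw
  tab2 <- toy_table(u, c("g1", "g2"))
  r2 <- tf_enrichment_test(gene_set("q", c("g9", "g10")), tab2, u,
                           perm_config(n_perm = 500, enumeration_threshold = 0))
  expect_equal(r2$p_count, 1)
  expect_equal(r2$p_score, 1)
})

test_that("with unit scores the score and count p-values coincide", {
  set.seed(81)
  u <- toy_universe(40)
  tab <- tf_target_table(
    data.frame(tf_id = rep(c("tfA", "tfB", "tfC"), times = c(12, 20, 5)),
               gene_id = c(sample(unclass(u), 12), sample(unclass(u), 20),
                           sample(unclass(u), 5)),
               score = 1),
    u)
  q <- gene_set("q", sample(unclass(u), 8))
  r <- tf_enrichment_test(q, tab, u,
                          perm_config(n_perm = 2000, seed = 4,
                                      enumeration_threshold = 0))
  expect_equal(r$p_score, r$p_count)
})

test_that("Monte-Carlo count p-values converge to the hypergeometric tail", {
  u <- toy_universe(60)
  tab <- toy_table(u, paste0("g", 1:15))
  q <- gene_set("q", paste0("g", c(1:5, 40:49)))   # k = 5 of 15 targets
  n_perm <- 20000
  r <- tf_enrichment_test(q, tab, u,
                          perm_config(n_perm = n_perm, seed = 2,
                                      enumeration_threshold = 0))
  p_exact <- hypergeom_tail(60, 15, 15, 5, "over")
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(r$p_count - p_exact), 4 * se)
})

test_that("adding non-target genes to the query cannot lower exact p-values", {
  u <- toy_universe(12)
  tab <- toy_table(u, paste0("g", 1:5), scores = c(3, 1, 4, 2, 5))
  cfg <- perm_config(enumeration_threshold = 10000)
  base <- tf_enrichment_test(gene_set("q", c("g1", "g3")), tab, u, cfg)
  for (extra in list("g10", c("g10", "g11"), c("g10", "g11", "g12"))) {
    grown <- tf_enrichment_test(gene_set("q", c("g1", "g3", extra)), tab, u, cfg)
    expect_identical(grown$k_observed, base$k_observed)
    expect_equal(grown$score_observed, base$score_observed)
    expect_gte(grown$p_count, base$p_count)
    expect_gte(grown$p_score, base$p_score)
  }
})

test_that("records sort by score p, then count p, then TF id", {
  set.seed(19)
  u <- toy_universe(30)
  tab <- tf_target_table(
    data.frame(tf_id = rep(c("tfZ", "tfA", "tfM"), each = 10),
               gene_id = c(paste0("g", 1:10), paste0("g", 11:20), paste0("g", 11:20)),
               score = c(10:1, rep(1, 20))),
    u)
  q <- gene_set("q", paste0("g", c(1, 2, 3, 25)))
  r <- tf_enrichment_test(q, tab, u,
                          perm_config(n_perm = 1000, seed = 8,
                                      enumeration_threshold = 0))
  expect_false(is.unsorted(r$p_score))
  # tfA and tfM share a target set and unit scores: identical p-values,
  # alphabetical tie-break
  ties <- r[r$tf_id %in% c("tfA", "tfM"), ]
  expect_equal(ties$p_score[1], ties$p_score[2])
  expect_identical(ties$tf_id, c("tfA", "tfM"))

  rep_tab <- rank_report(r)
  expect_identical(names(rep_tab)[1:5],
                   c("tf_id", "n_targets_total", "k_observed", "p_count", "p_score"))
  expect_identical(rep_tab$tf_id, r$tf_id)
})

test_that("the add-one convention gives strictly positive, shifted p-values", {
  u <- toy_universe(25)
  tab <- toy_table(u, paste0("g", 1:6))
  q <- gene_set("q", paste0("g", 1:6))    # maximal observed statistic
  n_perm <- 400
  plain <- tf_enrichment_test(q, tab, u,
                              perm_config(n_perm = n_perm, seed = 1,
                                          enumeration_threshold = 0))
  addone <- tf_enrichment_test(q, tab, u,
                               perm_config(n_perm = n_perm, seed = 1,
                                           convention = "addone",
                                           enumeration_threshold = 0))
  expect_equal(plain$p_count, 0)           # exact zeros are possible
  expect_gt(addone$p_count, 0)
  b <- plain$p_count * n_perm
  expect_equal(addone$p_count, (b + 1) / (n_perm + 1))
})

test_that("the full test is deterministic in the seed and records provenance", {
  sp <- synthetic_spec_small(seed = 6)
  u <- make_universe(sp$N_bg, sp$seed)
  tab <- make_tf_table(synthetic_spec_small(T_n = 8, seed = 6), u)
  q <- gene_set("q", sample(unclass(u), 50))
  cfg <- perm_config(n_perm = 1000, seed = 17, enumeration_threshold = 0,
                     chunk_size = 300)   # several partial chunks
  r1 <- tf_enrichment_test(q, tab, u, cfg)
  r2 <- tf_enrichment_test(q, tab, u, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(unique(r1$seed), 17L)
  expect_identical(unique(r1$n_perm), 1000L)
  # chunking is a memory knob only
  r3 <- tf_enrichment_test(q, tab, u,
                           perm_config(n_perm = 1000, seed = 17,
                                       enumeration_threshold = 0,
                                       chunk_size = 1000))
  expect_equal(r1$p_score, r3$p_score)
  expect_equal(r1$p_count, r3$p_count)
})
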