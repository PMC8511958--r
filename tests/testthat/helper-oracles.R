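# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the code paths they check.

# Hypergeometric tail by exhaustive enumeration of all C(N, n) subsets:
# successes are elements 1..K of 1..N.
hyper_tail_enum <- function(N, K, n, k, direction) {
  subs <- utils::combn(N, n)
  hits <- if (n == 1L) as.integer(subs <= K) else colSums(subs <= K)
  if (direction == "over") mean(hits >= k) else mean(hits <= k)
}

# Literal BH step-up: adjusted at sorted rank j is the suffix minimum over
# j' >= j of min(1, p(j') * m / j'), restricted to supplied ranks.
bh_stepup_literal <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  lp <- length(p)
  adj <- numeric(lp)
  for (j in seq_len(lp)) {
    adj[o[j]] <- min(vapply(j:lp, function(jp) min(1, ps[jp] * m / jp), numeric(1)))
  }
  adj
}

# Classical step-up rejection set at level alpha: reject ranks 1..j* where
# j* is the largest j with p(j) <= j * alpha / m.
bh_reject_classical <- function(p, alpha, m = length(p)) {
  o <- order(p)
  ok <- p[o] <= seq_along(p) * alpha / m
  jstar <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(length(p))
  if (jstar > 0L) rej[o[seq_len(jstar)]] <- TRUE
  rej
}

# Tiny universe + one-TF table used across permutation tests.
toy_universe <- function(n = 10L) gene_universe(paste0("g", seq_len(n)))

toy_table <- function(universe, targets, scores = rep(1, length(targets)),
                      tf = "tfA") {
  tf_target_table(
    data.frame(tf_id = tf, gene_id = targets, score = scores,
               stringsAsFactors = FALSE),
    universe)
}

# Published overlap counts and TF score p-values shipped as package data.
published_overlap_counts <- function() {
  utils::read.delim(system.file("extdata", "stress_overlap_counts.tsv",
                                package = "permenrich"),
                    stringsAsFactors = FALSE)
}

published_tf_pvalues <- function() {
  utils::read.delim(system.file("extdata", "tf_score_pvalues.tsv",
                                package = "permenrich"),
                    stringsAsFactors = FALSE)
}

# Compare a computed value to a printed one at the printed decimal precision.
expect_printed <- function(computed, printed) {
  dp <- nchar(sub("^[^.]*\\.?", "", as.character(printed)))
  expect_equal(round(computed, dp), printed)
}
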