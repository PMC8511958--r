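---
title: "Permutation enrichment of TF targets: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation enrichment of TF targets: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permenrich)
```

## The statistical problem

A regulatory screen asks whether the targets of a transcription factor (TF),
as called from ChIP-seq peaks, are over-represented in a query gene list —
and whether the *binding evidence* (peak scores) carried by those targets is
stronger than chance would give. `permenrich` answers both questions per TF
with a Monte-Carlo permutation null, and complements them with exact
hypergeometric overlap statistics for two-list comparisons on a shared
background.

Everything conditions on a declared **gene universe**: the finite list of
genes the experiment could have reported. The universe file is authoritative
— target genes outside it are dropped on input, never added, because the
permutation and hypergeometric nulls must share a single background.
Identifier matching is exact, case-sensitive string equality; harmonising
gene symbols to a common identifier scheme is the caller's job, since mapping
services are external and version-dependent.

## The permutation test

For TF $t$ with in-universe target set $G_t$ and scores $s_{tg} > 0$, and a
query $Q$ of size $q$ (after restriction to the universe), the observed
statistics are the target count $k_t = |Q \cap G_t|$ and the score mass
$S_t = \sum_{g \in Q \cap G_t} s_{tg}$. The null consists of $B$ uniform
draws of $q$ genes **without replacement** from the universe; the empirical
p-values are the proportions of draws whose count (resp. score) statistic is
$\ge$ the observed one.

Key conventions, each chosen once and fixed:

* **Score statistic = sum.** The sum is monotone in both membership and
  score magnitude and collapses to the count statistic under unit scores —
  which the test suite exploits as an internal consistency oracle
  (`p_score == p_count` whenever all scores are 1). Mean-based variants
  confound membership and magnitude and are not offered.
* **Exceedance is `>=`** (ties count toward the p-value). This makes the
  p-values valid — super-uniform — under the null even with the discrete
  count statistic.
* **Plain-proportion p-values by default** ($b/B$), so a TF whose observed
  statistic exceeds every draw reports exactly 0, as permutation scans of
  this kind conventionally print. The add-one convention
  $(b+1)/(B+1)$ is available via `perm_config(convention = "addone")` for
  users who need strictly positive p-values.
* **One shared draw stream for all TFs.** Evaluating fresh draws per TF at
  $B = 10^6$ over hundreds of TFs is prohibitive and changes nothing about
  the marginal null of any TF; sharing induces cross-TF dependence only in
  the Monte-Carlo noise. A 445-TF scan over a 13,964-gene universe at
  $B = 10^6$ completes in a few minutes on one CPU with the vectorised
  sparse-matrix evaluation (`scripts/full_scale_smoke.R` prints the
  timings; at $5\times10^4$ draws the scan stage takes ~13 s, and the cost
  is linear in $B$).
* **Exhaustive mode.** When $\binom{N}{q} \le$
  `enumeration_threshold` (default 10,000 distinct subsets) every subset is
  enumerated once: p-values become exact, independent of seed and
  convention. The default threshold engages this automatically on toy
  problems while keeping memory trivial; the count p-value in that mode
  equals the hypergeometric upper tail identically.
* **Only `p_score` is multiplicity-adjusted in the default report** (BH and
  Bonferroni over the family of all $T$ TFs scanned); `adjust_count = TRUE`
  additionally adjusts `p_count`. The dual raw p-values are always reported.

Two numerical details. First, score exceedance is tested against
$S_t - 10^{-12}(1 + |S_t|)$ rather than $S_t$ itself, so that a draw hitting
*exactly* the observed target subset can never fall on the wrong side of the
tie through floating-point summation order. Second, the draw stream is
generated draw-by-draw from a single seeded generator, so results are
independent of the evaluation chunk size (`chunk_size` is purely a memory
knob, and the suite asserts this).

### Calibration and power checks

The suite verifies, on generated data: (i) exact agreement with exhaustive
enumeration; (ii) convergence of `p_count` to the hypergeometric upper tail
within four Monte-Carlo standard errors at $B = 10^5$; (iii) uniformity of
raw `p_score` under queries with no planted signal (Kolmogorov–Smirnov at
$\alpha = 0.01$ over 200 replicates); and (iv) recovery of a planted TF at
BH-adjusted `p_score` $\le 0.05$ in at least 18 of 20 replicates at planting
fraction 0.4. Replicate seeds are drawn from one master stream rather than
formed as master-plus-offset sequences: sequential integer seeding can
correlate replicate streams and masquerade as miscalibration.

## Hypergeometric overlap statistics

For two sets of sizes $n_A$, $n_B$ on a universe of $N$ genes with overlap
$k$, the expected overlap is $e = n_A n_B / N$. The direction label is
decided by comparing $k$ to $e$ — not by the p-value — and the reported
fold is $k/e$ ("over") or $e/k$ ("under"), so the fold is always $\ge 1$
with an explicit direction. Ties ($k = e$) classify as "over" with fold 1;
$k = 0$ below expectation yields a flagged infinite under-fold rather than
an error. The tail probability is one-sided *in the observed direction*:
$P(X \ge k)$ for over-representation, $P(X \le k)$ for
under-representation. This convention reproduces published over/under labels
together with their printed p-values (an under-represented overlap carries a
lower-tail probability, which an upper tail could not produce).

The tail itself is accumulated on the log scale from `lchoose` terms with a
max-shifted (log-sum-exp) summation. This keeps relative accuracy at the
$10^{-10}$ level down to tails around $10^{-300}$, far beyond where naive
products of binomial coefficients overflow; the suite checks it against both
brute-force subset enumeration (small $N$) and `stats::phyper` (deep
tails).

`overlap_table()` reports, alongside the per-row statistics, the Bonferroni
family-wise threshold $\alpha/m$ for its $m$ rows — the conventional
significance bar for a table of $m$ two-list comparisons.

## Multiple-testing adjustment with explicit family size

`bh_adjust(raw, m)` and `bonferroni(raw, m)` take the family size $m$ as an
explicit parameter, defaulting to `length(raw)`. The $m >$ `length(raw)`
mode treats the supplied vector as the $m$-family's *smallest* p-values
(ranks $1..\ell$). For BH this is exact, not an approximation: unobserved
larger p-values occupy ranks $> \ell$ and can never lower a step-up suffix
minimum at the supplied ranks. This mode exists to reproduce corrected
values computed over a full family (e.g. 445 TFs) from only a published
top-hit list, and the command-line `adjust` subcommand labels partial-family
runs in its log. Internally both methods delegate to `stats::p.adjust`
(whose `n` argument implements exactly these semantics); the test suite
carries an independent, literal step-up implementation as the oracle,
together with rejection-set equivalence against the classical step-up
procedure. Ties share the larger rank's divisor before the suffix minimum —
the standard treatment. No other procedures (BY, q-values) are included.

## The synthetic-data generator

The generator emulates the study conditions of a genome-scale TF scan:

| parameter | default | rationale |
|---|---|---|
| `N_bg` | 13,964 | genome-scale *Drosophila* background, the size such overlap tables condition on |
| `T_n` | 445 | a larval ChIP-seq compendium's TF count |
| `target_count_range` | 500–9,000 | spans the per-TF target totals such compendia report (roughly 700–9,300) |
| score distribution | log-normal(0, 1) | positive and right-skewed, as ChIP peak scores typically are; no published score distribution exists to copy |
| `query_size` | 100 | the size of a typical differential-expression list (published examples: 45 and 100) |
| `enrichment_fraction` | 0 | fraction of the query planted from the chosen TF's targets |
| `high_score_bias` | 0 | planting weight $\propto$ score$^b$; $b>0$ separates the score signal from the count signal |

`synthetic_spec_small()` is the profile the test suite runs (50 TFs over a
5,000-gene universe, target counts 250–3,000 — the same 5–60% span of the
universe as the full-scale defaults), keeping calibration (200 replicates at
$B$ = 2,000) and recovery (20 replicates) runs around a minute in total.
These sizes are the package's fixture choice; the full-scale configuration
is exercised by the opt-in smoke script.

Planting with `high_score_bias > 0` is a deliberate extension beyond what
any published analysis describes: it is what makes the two p-values
*separable* in benchmarks, because a high-bias plant inflates the score mass
far more than the count. All generators are pure functions of their
`(spec, seed)` arguments — bitwise-identical outputs across runs.

What the generator does **not** emulate: correlation between TFs' target
sets beyond random overlap, peak-score dependence between co-bound genes,
non-uniform gene "reportability" (length or expression bias), or any
structure in the query beyond the planted fraction. Passing calibration and
recovery tests on this generator therefore demonstrates correctness of the
statistics under their stated null — not robustness to the biological
confounders (co-binding, expression-level bias) that real ChIP compendia
carry.

## Degenerate inputs and edge behaviour

* A query with no in-universe members is an error ("empty query set");
  off-universe members are dropped with a warning.
* A TF whose observed intersection is empty has score mass 0 and both
  p-values 1 (every draw ties at $\ge 0$).
* A TF targeting the whole universe has a constant count statistic, hence
  `p_count = 1`.
* Duplicate `(tf, gene)` rows keep the maximum score — a gene is either a
  target or not, and its strongest peak represents it.
* Records sort by ascending `p_score`, ties broken by ascending `p_count`,
  then `tf_id` — so reports are deterministic.

## Display conventions

Report writers round folds to 2 decimals, family-wise thresholds to 4
decimals, and p-values to 3 significant figures, matching the conventional
table formats; `--precision full` (CLI) or the returned data frames give
full precision. Internally nothing is rounded.

## Known limitations

* The permutation engine holds an $N \times T$ dense score matrix
  (~50 MB at genome scale); far larger compendia would need a sparse
  observed-statistics path.
* Monte-Carlo p-values at $B$ draws have granularity $1/B$; BH adjustment
  of many exact zeros is reported as 0, which is faithful to the plain
  convention but understates the Monte-Carlo uncertainty — use
  `convention = "addone"` when downstream analysis needs positive p-values.
* No GSEA-style weighted running-sum statistic, no peak calling or
  peak-to-gene assignment, and no identifier mapping: the TF target table is
  consumed as given.
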