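#' Bonferroni adjustment with explicit family size
#'
#' adjusted_i = min(1, raw_i * m). The family size m may exceed the number of
#' p-values supplied, e.g. when only the top-ranked tests of a family of 445
#' TFs are in hand.
#'
#' @param raw Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size, `m >= length(raw)`; defaults to `length(raw)`.
#' @return Adjusted p-values, same order as `raw`.
#' @examples
#' bonferroni(0.000013, m = 445)   # 0.005785
#' @export
bonferroni <- function(raw, m = length(raw)) {
  check_pvalues(raw, m)
  stats::p.adjust(raw, method = "bonferroni", n = m)
}

#' Benjamini-Hochberg step-up adjustment with explicit family size
#'
#' Classical step-up FDR adjustment: with the raw p-values sorted ascending at
#' ranks j = 1..length(raw), adjusted(j) is the suffix minimum over j' >= j of
#' min(1, raw(j') * m / j'), mapped back to input order.
#'
#' When `m > length(raw)` the supplied vector is treated as the m-family's
#' smallest p-values (ranks 1..length(raw)); the unobserved larger p-values
#' cannot lower any step-up minimum, so the adjusted values for the supplied
#' ranks are exact. This reproduces published corrected values computed over a
#' full family (e.g. 445 TFs) from only the reported top hits.
#'
#' @inheritParams bonferroni
#' @return Adjusted p-values, same order as `raw`.
#' @examples
#' # rank-1 entry inherits rank 3's 0.000002 * 445 / 3
#' bh_adjust(c(0.000001, 0.000002, 0.000002), m = 445)
#' @export
bh_adjust <- function(raw, m = length(raw)) {
  check_pvalues(raw, m)
  stats::p.adjust(raw, method = "BH", n = m)
}

#' Adjust p-values under a named method
#'
#' @inheritParams bonferroni
#' @param method `"bh"` or `"bonferroni"`.
#' @return A data.frame of class `adjusted_pvalues` with columns `raw` and
#'   `adjusted`, attributes `method` and `m`.
#' @export
adjust_pvalues <- function(raw, method = c("bh", "bonferroni"), m = length(raw)) {
  method <- match.arg(method)
  adjusted <- switch(method,
                     bh = bh_adjust(raw, m),
                     bonferroni = bonferroni(raw, m))
  structure(data.frame(raw = raw, adjusted = adjusted),
            class = c("adjusted_pvalues", "data.frame"),
            method = method, m = m)
}

check_pvalues <- function(raw, m) {
  if (!is.numeric(raw) || length(raw) == 0L) stop("raw p-values must be a non-empty numeric vector")
  if (anyNA(raw) || any(raw < 0 | raw > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(raw)) stop("family size m must be >= length(raw)")
  invisible(TRUE)
}
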