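#' Exact hypergeometric tail probability
#'
#' One-sided tail of X ~ Hypergeometric(N, K, n): drawing n items without
#' replacement from a universe of N containing K successes. `direction = "over"`
#' gives the upper tail P(X >= k) (over-representation); `direction = "under"`
#' gives the lower tail P(X <= k).
#'
#' Terms are accumulated on the log scale via `lchoose` with a max-shifted
#' (log-sum-exp) summation, so tails remain accurate to full double precision
#' far below the smallest normalised double's neighbourhood (p ~ 1e-300).
#'
#' @param N Universe size.
#' @param K Number of successes in the universe.
#' @param n Sample (draw) size.
#' @param k Observed success count, `0 <= k <= min(K, n)`.
#' @param direction `"over"` (upper tail, default) or `"under"` (lower tail).
#' @return The tail probability, in (0, 1].
#' @examples
#' hypergeom_tail(10, 4, 3, 2, "over")   # 40/120 = 1/3
#' @export
hypergeom_tail <- function(N, K, n, k, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L || length(k) != 1L) {
    stop("hypergeom_tail takes scalar arguments")
  }
  if (N < 1 || K < 0 || n < 0 || K > N || n > N) {
    stop("invalid hypergeometric parameters: need 0 <= K, n <= N")
  }
  lo <- max(0, n - (N - K))   # support lower bound
  hi <- min(K, n)             # support upper bound
  if (k < 0 || k > hi) stop(sprintf("k = %s outside [0, min(K, n) = %s]", k, hi))
  if (direction == "under" && k >= hi) return(1)
  if (direction == "over" && k <= lo) return(1)
  if (direction == "under" && k < lo) return(0)  # below the support: impossible observation
  ii <- if (direction == "over") seq.int(k, hi) else seq.int(lo, k)
  logt <- lchoose(K, ii) + lchoose(N - K, n - ii) - lchoose(N, n)
  m <- max(logt)
  p <- exp(m) * sum(exp(logt - m))
  min(p, 1)
}

#' Expected two-set overlap under independence
#'
#' The number of genes expected by chance in the intersection of a size-nA set
#' and a size-nB set drawn from a shared universe of N genes: nA * nB / N.
#'
#' @param N Universe size (>= 1).
#' @param nA,nB Set sizes, each in `[0, N]`.
#' @return The expected overlap, at full floating precision.
#' @export
expected_overlap <- function(N, nA, nB) {
  if (N < 1) stop("universe size must be >= 1")
  if (nA < 0 || nB < 0 || nA > N || nB > N) {
    stop("set sizes must lie in [0, N]")
  }
  nA * nB / N
}

#' Over/under-representation fold of an observed overlap
#'
#' Compares the observed overlap k to the overlap expected by chance
#' e = nA * nB / N. When k >= e the overlap is over-represented with fold
#' k / e; when k < e it is under-represented with the reciprocal fold e / k.
#' A zero overlap below expectation yields an infinite under-representation
#' fold (flagged, not an error). Ties (k exactly equal to e) classify as
#' "over" with fold 1.
#'
#' @inheritParams expected_overlap
#' @param k Observed overlap, `0 <= k <= min(nA, nB)`.
#' @return A list with elements `direction` (`"over"` or `"under"`) and
#'   `fold` (>= 1; `Inf` when k = 0 under expectation). Full precision;
#'   display-round to 2 decimals to match conventional reporting.
#' @examples
#' fold_representation(17, 13964, 45, 442)   # over, 11.94 to 2 dp
#' @export
fold_representation <- function(k, N, nA, nB) {
  if (k < 0 || k > min(nA, nB)) stop("overlap k must lie in [0, min(nA, nB)]")
  e <- expected_overlap(N, nA, nB)
  if (e == 0) stop("expected overlap is zero; fold undefined")
  if (k >= e) {
    list(direction = "over", fold = k / e)
  } else if (k > 0) {
    list(direction = "under", fold = e / k)
  } else {
    list(direction = "under", fold = Inf)
  }
}

#' Two-set overlap statistics table
#'
#' For each row (label, N, nA, nB, k) computes the expected overlap, the
#' over/under-representation direction and fold, and the one-sided
#' hypergeometric tail probability in that direction. Also reports the
#' Bonferroni family-wise significance threshold alpha / m for the m rows.
#'
#' The tail is one-sided in the direction of the observed deviation: upper
#' tail P(X >= k) for over-represented overlaps, lower tail P(X <= k) for
#' under-represented ones.
#'
#' @param rows A data.frame with columns `label`, `total`, `n_a`, `n_b`,
#'   `overlap`.
#' @param alpha Family-wise error rate for the threshold (default 0.05).
#' @return A data.frame of class `overlap_table` with columns `label`, `total`,
#'   `n_a`, `n_b`, `overlap`, `expected`, `direction`, `fold`, `p_hyper`;
#'   attributes `threshold` (alpha / m, full precision) and `alpha`.
#' @export
overlap_table <- function(rows, alpha = 0.05) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  need <- c("label", "total", "n_a", "n_b", "overlap")
  if (!all(need %in% names(rows))) {
    stop(sprintf("overlap rows need columns %s", paste(need, collapse = ", ")))
  }
  m <- nrow(rows)
  out <- data.frame(label = as.character(rows$label),
                    total = as.integer(rows$total),
                    n_a = as.integer(rows$n_a),
                    n_b = as.integer(rows$n_b),
                    overlap = as.integer(rows$overlap),
                    stringsAsFactors = FALSE)
  out$expected <- mapply(expected_overlap, out$total, out$n_a, out$n_b)
  fr <- mapply(function(k, N, nA, nB) fold_representation(k, N, nA, nB),
               out$overlap, out$total, out$n_a, out$n_b, SIMPLIFY = FALSE)
  out$direction <- vapply(fr, `[[`, character(1L), "direction")
  out$fold <- vapply(fr, `[[`, numeric(1L), "fold")
  out$p_hyper <- mapply(function(N, K, n, k, d) hypergeom_tail(N, K, n, k, d),
                        out$total, out$n_b, out$n_a, out$overlap, out$direction)
  structure(out, class = c("overlap_table", "data.frame"),
            threshold = alpha / m, alpha = alpha)
}

#' @export
print.overlap_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$fold <- round(df$fold, 2)
  df$expected <- round(df$expected, 2)
  df$p_hyper <- signif(df$p_hyper, 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Family-wise threshold (alpha = %g, m = %d comparisons): %s\n",
              attr(x, "alpha"), nrow(x), format_threshold(attr(x, "threshold"))))
  invisible(x)
}

#' Venn-partition counts for 2-4 gene sets
#'
#' Counts the members of every non-empty membership pattern (Venn region)
#' over the union of the given sets. With s sets there are 2^s - 1 regions
#' and the counts sum to the size of the union.
#'
#' @param sets A named list of 2-4 [gene_set] objects (or bare character
#'   vectors, which are wrapped using their list names).
#' @return A data.frame with one row per region: logical membership columns
#'   (one per set), a `region` label like `"A&B"`, and `count`.
#' @export
venn_partition <- function(sets) {
  s <- length(sets)
  if (s < 2L || s > 4L) stop("venn_partition supports 2 to 4 sets")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(seq_len(s), function(i) {
      if (inherits(sets[[i]], "gene_set")) sets[[i]]$name else LETTERS[i]
    }, character(1L))
  }
  members <- lapply(sets, function(x) {
    if (inherits(x, "gene_set")) x$members else unique(as.character(x))
  })
  pool <- unique(unlist(members, use.names = FALSE))
  memb <- vapply(members, function(m) pool %in% m, logical(length(pool)))
  if (length(pool) == 1L) memb <- matrix(memb, nrow = 1L)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), s))[-1L, , drop = FALSE])
  colnames(patterns) <- nm
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(memb, 1L, function(row) all(row == p)))
  })
  region <- apply(patterns, 1L, function(p) paste(nm[p], collapse = "&"))
  out <- as.data.frame(patterns)
  out$region <- region
  out$count <- as.integer(counts)
  rownames(out) <- NULL
  out
}
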