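# Contingency statistics used by the reporting layer: equal-probability
# chi-square goodness of fit, the continuity-corrected 2x2 chi-square,
# the two-sided Fisher exact test (minimum-likelihood rule) and
# Benjamini-Hochberg adjustment. These are validated wrappers over the
# base stats implementations.

#' Chi-square goodness-of-fit statistic
#'
#' `sum((O - E)^2 / E)` with `E = N * p`, no continuity correction,
#' `df = k - 1`. By default all groups share the same expected
#' probability.
#'
#' @param observed Non-negative integer counts (k >= 2).
#' @param expected_probs Probabilities summing to 1; default equal.
#' @return `list(statistic, df, p_value)`.
#' @examples
#' chisq_gof(c(51, 26, 22, 21))$statistic  # 20.067
#' @export
chisq_gof <- function(observed,
                      expected_probs = rep(1 / length(observed),
                                           length(observed))) {
  if (length(observed) < 2L) stop("need at least 2 groups")
  if (any(observed < 0) || anyNA(observed)) stop("counts must be >= 0")
  if (sum(observed) <= 0) stop("total observed count must be positive")
  if (abs(sum(expected_probs) - 1) > 1e-9)
    stop("expected probabilities must sum to 1")
  if (any(expected_probs <= 0)) stop("zero expected cell")
  ct <- suppressWarnings(stats::chisq.test(observed, p = expected_probs))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Continuity-corrected 2x2 chi-square statistic
#'
#' Yates-corrected statistic `sum((|O - E| - 0.5)^2 / E)` on expected
#' counts from the table margins (the correction is clamped at `|O - E|`
#' for near-degenerate cells, as in base R).
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @return `list(statistic, df, p_value)`.
#' @examples
#' chisq_2x2_corrected(matrix(c(162, 1, 648, 809), 2))$statistic  # 174.63
#' @export
chisq_2x2_corrected <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || anyNA(table)) stop("counts must be >= 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(77, 73, 43, 47), 2))  # 0.689
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || anyNA(table)) stop("counts must be >= 0")
  if (sum(table) > 1e6) stop("table total too large for exact computation")
  if (sum(table) == 0) return(1)
  unname(stats::fisher.test(table)$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals P-values in \[0, 1\].
#' @return Adjusted p-values (each >= raw, capped at 1), in input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise equal-probability GOF comparisons with BH adjustment
#'
#' The post-hoc pattern used for scenario count tables: every pair of
#' groups is compared by a 2-cell equal-probability goodness-of-fit test
#' and the p-values are BH-adjusted.
#'
#' @param counts Named non-negative counts.
#' @return Data frame `a`, `b`, `statistic`, `p_raw`, `p_adj`.
#' @export
posthoc_pairwise_gof <- function(counts) {
  stopifnot(length(counts) >= 2L)
  nm <- names(counts) %||% as.character(seq_along(counts))
  pairs <- utils::combn(length(counts), 2L)
  res <- apply(pairs, 2L, function(ij) {
    g <- chisq_gof(counts[ij])
    c(statistic = g$statistic, p_raw = g$p_value)
  })
  out <- data.frame(a = nm[pairs[1L, ]], b = nm[pairs[2L, ]],
                    statistic = res["statistic", ],
                    p_raw = res["p_raw", ])
  out$p_adj <- bh_adjust(out$p_raw)
  out
}
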