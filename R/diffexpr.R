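#' Audic-Claverie tag-count probability
#'
#' Probability of observing `y` copies of a tag (or gene) in a library
#' of size `n2` given `x` copies in a library of size `n1`, under the
#' exact model for unreplicated count libraries:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}}
#' Evaluated in log space through `lgamma`, so it is finite and accurate
#' for counts up to millions; the naive factorial route would overflow
#' beyond x+y of about 170.
#'
#' @param y observed count in the second library.
#' @param x observed count in the first library.
#' @param n1,n2 clean library sizes (totals) of the first and second
#'   library.
#' @return probability in (0, 1]; vectorized over `x`, `y`.
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 0.5
#' @export
ac_probability <- function(y, x, n1, n2) {
  if (any(x < 0) || any(y < 0) || any(n1 <= 0) || any(n2 <= 0)) {
    stop("counts must be >= 0 and library sizes > 0", call. = FALSE)
  }
  log_r <- log(n2) - log(n1)
  exp(y * log_r + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(exp(log_r)))
}

#' Audic-Claverie two-sided p-value
#'
#' Exact two-library test of equal relative abundance. For fixed `x`,
#' `p(y | x)` is the negative-binomial density with size `x + 1` and
#' success probability `n1 / (n1 + n2)`, so the tail sums are
#' regularized incomplete beta functions; this keeps the test exact and
#' fast at library-scale counts. The two-sided p-value doubles the
#' smaller of the lower tail \eqn{P(Y \le y)} and the upper tail
#' \eqn{P(Y \ge y)}, capped at 1.
#'
#' @inheritParams ac_probability
#' @return two-sided p-value(s) in (0, 1]; vectorized.
#' @examples
#' ac_pvalue(100, 0, 1e6, 1e6)  # strong evidence of change
#' ac_pvalue(10, 10, 1e6, 1e6)  # exactly 1
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0) || any(n1 <= 0) || any(n2 <= 0)) {
    stop("counts must be >= 0 and library sizes > 0", call. = FALSE)
  }
  if (length(x) == 0L || length(y) == 0L) return(numeric(0))
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  p0 <- n1 / (n1 + n2)
  lower <- pbeta(p0, x + 1, y + 1)          # P(Y <= y)
  upper <- ifelse(y == 0, 1, 1 - pbeta(p0, x + 1, pmax(y, 1)))  # P(Y >= y)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, returned in the input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (q-values) in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' Implements the standard unreplicated DGE contrast: genes whose
#' combined copy number across the two libraries reaches `min_combined`
#' are tested with the exact Audic-Claverie statistic; BH-FDR is
#' computed over the tested set only; a gene is called significant when
#' `p < p_max`, `FDR < fdr_max` and `|log2 ratio| > min_abs_log2`.
#' The ratio is `library B / library A` on TPM by default (identical to
#' the count ratio when library sizes are equal). Zero TPM values are
#' floored at `max(TPM) / fold_cap` so an expressed-versus-absent gene
#' reports a large but finite fold, and `|log2 ratio|` is capped at
#' `log2(fold_cap)`.
#'
#' @param records_a,records_b per-gene record data frames from
#'   [map_library()] for condition A and condition B.
#' @param n1,n2 clean library totals; taken from the records'
#'   `clean_total` attribute when omitted.
#' @param min_combined minimum combined copy number `x + y` for a gene
#'   to be tested (default 200).
#' @param p_max,fdr_max significance cutoffs (default 0.05 each).
#' @param min_abs_log2 minimum absolute log2 ratio (default 0.5).
#' @param strand which counts to test: `"sense"` (default) or
#'   `"antisense"`.
#' @param ratio_scale `"tpm"` (default) or `"count"`.
#' @param fold_cap cap on the reported fold change (default 1e4).
#' @return data frame of class `diff_expr_result`, one row per tested
#'   gene: `gene_id`, `x`, `y`, `tpm_a`, `tpm_b`, `log2_ratio`,
#'   `p_value`, `fdr`, `direction` (`up`/`down`/`unchanged`),
#'   `significant`, `fold_bin` (highest fold threshold reached among
#'   1.5/2/5, or `"none"`). Parameters are carried as attributes.
#' @export
call_differential <- function(records_a, records_b, n1 = NULL, n2 = NULL,
                              min_combined = 200, p_max = 0.05,
                              fdr_max = 0.05, min_abs_log2 = 0.5,
                              strand = c("sense", "antisense"),
                              ratio_scale = c("tpm", "count"),
                              fold_cap = 1e4) {
  strand <- match.arg(strand)
  ratio_scale <- match.arg(ratio_scale)
  if (is.null(n1)) n1 <- attr(records_a, "clean_total")
  if (is.null(n2)) n2 <- attr(records_b, "clean_total")
  if (is.null(n1) || is.null(n2)) {
    stop("library totals n1 and n2 are required", call. = FALSE)
  }
  col <- paste0(strand, "_count")
  genes <- union(records_a$gene_id, records_b$gene_id)
  xa <- setNames(rep(0, length(genes)), genes)
  xb <- xa
  xa[records_a$gene_id] <- records_a[[col]]
  xb[records_b$gene_id] <- records_b[[col]]

  keep <- (xa + xb) >= min_combined
  if (!any(keep)) {
    warning("no genes pass the combined copy-number filter",
            call. = FALSE)
  }
  x <- as.numeric(xa[keep]); y <- as.numeric(xb[keep])
  tpm_a <- tpm(x, n1); tpm_b <- tpm(y, n2)
  va <- if (ratio_scale == "tpm") tpm_a else x
  vb <- if (ratio_scale == "tpm") tpm_b else y
  eps <- max(c(va, vb, 0)) / fold_cap
  if (eps <= 0) eps <- .Machine$double.eps
  log2_ratio <- log2(pmax(vb, eps) / pmax(va, eps))
  log2_ratio <- sign(log2_ratio) * pmin(abs(log2_ratio), log2(fold_cap))

  p <- ac_pvalue(x, y, n1, n2)
  q <- bh_fdr(p)
  significant <- p < p_max & q < fdr_max & abs(log2_ratio) > min_abs_log2
  direction <- ifelse(!significant, "unchanged",
                      ifelse(log2_ratio > 0, "up", "down"))
  # closed thresholds with a relative tolerance so that e.g. a count
  # ratio of exactly 5 lands in the >=5 bin despite the 2^log2 round trip
  fold <- 2^abs(log2_ratio)
  at_least <- function(f, t) f >= t * (1 - 1e-9)
  fold_bin <- ifelse(at_least(fold, 5), ">=5",
                     ifelse(at_least(fold, 2), ">=2",
                            ifelse(at_least(fold, 1.5), ">=1.5",
                                   "none")))

  out <- data.frame(
    gene_id = genes[keep], x = x, y = y, tpm_a = tpm_a, tpm_b = tpm_b,
    log2_ratio = log2_ratio, p_value = p, fdr = q,
    direction = direction, significant = significant,
    fold_bin = fold_bin, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "params") <- list(
    n1 = n1, n2 = n2, min_combined = min_combined, p_max = p_max,
    fdr_max = fdr_max, min_abs_log2 = min_abs_log2, strand = strand,
    ratio_scale = ratio_scale, fold_cap = fold_cap)
  class(out) <- c("diff_expr_result", "data.frame")
  out
}

#' Cumulative fold-change bins of differential calls
#'
#' Counts up- and down-regulated genes at each fold threshold; bins are
#' cumulative (a 6-fold gene is counted at 1.5, 2 and 5).
#'
#' @param results a `diff_expr_result` data frame.
#' @param thresholds ascending fold thresholds (default 1.5, 2, 5).
#' @param significant_only count only genes flagged significant
#'   (default `TRUE`).
#' @return data frame with columns `threshold`, `up`, `down`.
#' @export
fold_change_bins <- function(results, thresholds = c(1.5, 2, 5),
                             significant_only = TRUE) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending", call. = FALSE)
  }
  r <- results
  if (significant_only && nrow(r) > 0L) {
    r <- r[r$significant, , drop = FALSE]
  }
  fold <- 2^abs(r$log2_ratio)
  up <- r$log2_ratio > 0
  data.frame(
    threshold = thresholds,
    up = vapply(thresholds,
                function(t) sum(fold >= t * (1 - 1e-9) & up), numeric(1)),
    down = vapply(thresholds,
                  function(t) sum(fold >= t * (1 - 1e-9) & !up),
                  numeric(1))
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' qPCR fold change of a condition relative to a reference from their
#' housekeeping-normalized delta-Ct values:
#' `2^-(delta_ct_condition - delta_ct_reference)`.
#'
#' @param delta_ct_condition,delta_ct_reference delta-Ct values (target
#'   Ct minus housekeeping Ct) for the condition and the reference.
#' @return fold change(s); 1 means no change.
#' @examples
#' ddct_fold(-1, 0)  # 2-fold up
#' @export
ddct_fold <- function(delta_ct_condition, delta_ct_reference) {
  if (any(!is.finite(delta_ct_condition)) ||
      any(!is.finite(delta_ct_reference))) {
    stop("delta-Ct inputs must be finite", call. = FALSE)
  }
  2^(-(delta_ct_condition - delta_ct_reference))
}
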