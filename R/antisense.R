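#' Sense/antisense expression pairs per gene
#'
#' Projects a mapped library onto one row per gene carrying both
#' strands, for genes with any sense or antisense signal. The antisense
#' to sense TPM ratio is `NA` (flagged `antisense_only`) when the gene
#' has no sense expression.
#'
#' @param records per-gene record data frame from [map_library()].
#' @return data frame with columns `gene_id`, `sense_count`,
#'   `antisense_count`, `sense_tpm`, `antisense_tpm`, `as_ratio`,
#'   `antisense_only`; the library `clean_total` attribute is carried
#'   over.
#' @export
antisense_table <- function(records) {
  keep <- records$sense_count > 0 | records$antisense_count > 0
  out <- records[keep, c("gene_id", "sense_count", "antisense_count",
                         "sense_tpm", "antisense_tpm"), drop = FALSE]
  out$as_ratio <- ifelse(out$sense_count > 0,
                         out$antisense_tpm / out$sense_tpm, NA_real_)
  out$antisense_only <- out$sense_count == 0
  rownames(out) <- NULL
  attr(out, "clean_total") <- attr(records, "clean_total")
  attr(out, "sample_id") <- attr(records, "sample_id")
  out
}

#' Correlation between sense and antisense expression
#'
#' Pearson correlation of per-gene sense and antisense counts on a
#' chosen scale. Raw counts put nearly all the weight on the most
#' abundant genes; `log10p1` (default) is the conventional display
#' scale; `binned` correlates bin means after grouping genes into
#' equal-size sense-abundance bins.
#'
#' @param pairs data frame from [antisense_table()].
#' @param scale `"log10p1"` (default), `"raw"` or `"binned"`.
#' @param n_bins number of abundance bins for `scale = "binned"`.
#' @return Pearson correlation coefficient.
#' @export
sense_antisense_correlation <- function(pairs,
                                        scale = c("log10p1", "raw",
                                                  "binned"),
                                        n_bins = 20) {
  scale <- match.arg(scale)
  s <- pairs$sense_count
  a <- pairs$antisense_count
  if (scale == "log10p1") {
    s <- log10(s + 1); a <- log10(a + 1)
  } else if (scale == "binned") {
    ord <- order(pairs$sense_count)
    bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
    s <- as.numeric(tapply(log10(s[ord] + 1), bin, mean))
    a <- as.numeric(tapply(log10(a[ord] + 1), bin, mean))
  }
  if (length(s) < 3L) {
    stop("need at least 3 pairs to correlate", call. = FALSE)
  }
  if (sd(s) == 0 || sd(a) == 0) {
    stop("correlation undefined: zero variance in sense or antisense",
         call. = FALSE)
  }
  cor(s, a)
}

#' Average antisense-to-sense expression ratio
#'
#' Two estimators of how much antisense transcription accompanies sense
#' transcription: the ratio of totals (sum of antisense counts over sum
#' of sense counts, the library-level rate) and the mean of per-gene
#' ratios.
#'
#' @param pairs data frame from [antisense_table()].
#' @param min_sense minimum sense copy number for a pair to be eligible
#'   (default 1).
#' @return list with `ratio_of_totals`, `mean_of_ratios`, `n_pairs`.
#' @export
mean_antisense_ratio <- function(pairs, min_sense = 1) {
  ok <- pairs$sense_count >= min_sense
  if (!any(ok)) stop("no eligible sense/antisense pairs", call. = FALSE)
  list(
    ratio_of_totals = sum(pairs$antisense_count[ok]) /
      sum(pairs$sense_count[ok]),
    mean_of_ratios = mean(pairs$antisense_count[ok] /
                            pairs$sense_count[ok]),
    n_pairs = sum(ok)
  )
}

#' Differentially expressed antisense transcripts
#'
#' Two-condition comparison of antisense expression: genes whose
#' antisense copy number reaches `min_copy` in either library are
#' tested with the Audic-Claverie statistic (BH-FDR over the tested
#' set) and binned cumulatively by fold change.
#'
#' @param records_a,records_b per-gene record data frames from
#'   [map_library()].
#' @param n1,n2 clean library totals; taken from attributes when
#'   omitted.
#' @param min_copy antisense copy-number filter, applied to the
#'   antisense count in either library (default 100).
#' @param fold_bins cumulative fold thresholds (default 1.5, 2, 3).
#' @param significant_only bin only significant calls (default
#'   `FALSE`: the bins count all tested genes reaching each fold, the
#'   convention used for antisense regulation tallies).
#' @param ... further arguments passed to [call_differential()]
#'   (`p_max`, `fdr_max`, `min_abs_log2`, ...).
#' @return list with `results` (a `diff_expr_result` on antisense
#'   counts) and `bins` (data frame `threshold`, `up`, `down`).
#' @export
differential_antisense <- function(records_a, records_b, n1 = NULL,
                                   n2 = NULL, min_copy = 100,
                                   fold_bins = c(1.5, 2, 3),
                                   significant_only = FALSE, ...) {
  if (is.null(n1)) n1 <- attr(records_a, "clean_total")
  if (is.null(n2)) n2 <- attr(records_b, "clean_total")
  a <- setNames(records_a$antisense_count, records_a$gene_id)
  b <- setNames(records_b$antisense_count, records_b$gene_id)
  genes <- union(names(a), names(b))
  av <- setNames(rep(0, length(genes)), genes); av[names(a)] <- a
  bv <- setNames(rep(0, length(genes)), genes); bv[names(b)] <- b
  keep <- av >= min_copy | bv >= min_copy

  ra <- data.frame(gene_id = genes[keep], antisense_count = av[keep],
                   stringsAsFactors = FALSE)
  rb <- data.frame(gene_id = genes[keep], antisense_count = bv[keep],
                   stringsAsFactors = FALSE)
  results <- call_differential(ra, rb, n1 = n1, n2 = n2,
                               min_combined = 0, strand = "antisense",
                               ...)
  bins <- fold_change_bins(results, thresholds = fold_bins,
                           significant_only = significant_only)
  list(results = results, bins = bins)
}
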