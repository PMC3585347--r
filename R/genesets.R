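#' Meaningfully expressed genes of one library
#'
#' Genes whose copy number reaches the expression cutoff (default 100
#' copies, the conventional threshold separating meaningful expression
#' from background in DGE libraries).
#'
#' @param records per-gene record data frame from [map_library()].
#' @param min_count minimum copy number (default 100).
#' @param strand which count to threshold (default `"sense"`).
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(records, min_count = 100,
                            strand = c("sense", "antisense")) {
  strand <- match.arg(strand)
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  records$gene_id[records[[paste0(strand, "_count")]] >= min_count]
}

#' Classify genes by copy-number class
#'
#' Partitions expressed genes into copy-number intervals (default
#' 2-99, 100-499, >=500) and reports per-class counts and fractions.
#' The class bounds must tile `[lowest, Inf)` without gap or overlap.
#'
#' @inheritParams expressed_genes
#' @param bounds list of `c(lower, upper)` count intervals, inclusive
#'   on both ends, the last upper bound being `Inf`.
#' @return data frame of class `expression_class_table` with columns
#'   `class`, `lower`, `upper`, `n_genes`, `fraction`.
#' @export
copy_number_classes <- function(records,
                                bounds = list(c(2, 99), c(100, 499),
                                              c(500, Inf)),
                                strand = c("sense", "antisense")) {
  strand <- match.arg(strand)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(hi < lo) || is.unsorted(lo, strictly = TRUE) ||
      any(lo[-1L] != hi[-length(hi)] + 1) || !is.infinite(hi[length(hi)])) {
    stop("bounds must tile [lowest, Inf) without gap or overlap",
         call. = FALSE)
  }
  cnt <- records[[paste0(strand, "_count")]]
  cnt <- cnt[cnt >= lo[1L]]
  n <- vapply(seq_along(bounds),
              function(i) sum(cnt >= lo[i] & cnt <= hi[i]), numeric(1))
  out <- data.frame(
    class = paste0(lo, ifelse(is.infinite(hi), "+", paste0("-", hi))),
    lower = lo, upper = hi, n_genes = n,
    fraction = if (sum(n) > 0) n / sum(n) else rep(0, length(n))
  )
  class(out) <- c("expression_class_table", "data.frame")
  out
}

#' Construct a tissue expression set
#'
#' Thresholds a per-gene count table of one tissue at an expression
#' cutoff, yielding the tissue's expressed gene set.
#'
#' @param tissue tissue name.
#' @param counts named numeric vector gene -> count, or a data frame
#'   with columns `gene_id` and a count column (first numeric column
#'   used), or a per-gene record data frame from [map_library()].
#' @param min_count expression cutoff (default 100; applied to
#'   `sense_count` for mapped records).
#' @return object of class `tissue_expression_set`: list with `tissue`,
#'   `genes`, `cutoff`.
#' @export
tissue_expression_set <- function(tissue, counts, min_count = 100) {
  if (is.data.frame(counts)) {
    if ("sense_count" %in% names(counts)) {
      v <- setNames(counts$sense_count, counts$gene_id)
    } else {
      num <- which(vapply(counts, is.numeric, logical(1)))[1L]
      if (is.na(num) || !"gene_id" %in% names(counts)) {
        stop("counts data frame needs gene_id and a numeric column",
             call. = FALSE)
      }
      v <- setNames(counts[[num]], counts$gene_id)
    }
  } else {
    v <- counts
  }
  structure(list(tissue = tissue,
                 genes = sort(names(v)[v >= min_count]),
                 cutoff = min_count),
            class = "tissue_expression_set")
}

#' Tissue-specific genes by set difference
#'
#' Genes expressed in the target tissue and in none of the comparison
#' tissues.
#'
#' @param target a `tissue_expression_set` for the tissue of interest.
#' @param others list of `tissue_expression_set` objects to subtract.
#' @return character vector of tissue-specific gene ids.
#' @export
tissue_specific <- function(target, others) {
  stopifnot(inherits(target, "tissue_expression_set"))
  if (length(others) == 0L) {
    warning("no comparison tissues supplied; returning the target set",
            call. = FALSE)
    return(target$genes)
  }
  other_genes <- unique(unlist(lapply(others, function(o) {
    stopifnot(inherits(o, "tissue_expression_set"))
    o$genes
  })))
  setdiff(target$genes, other_genes)
}

#' Library saturation curve
#'
#' Detected-gene count as a function of sequencing depth. At each depth
#' the clean library is subsampled without replacement (multivariate
#' hypergeometric on the tag counts), mapped against the index, and the
#' number of genes with at least `min_tags` unambiguously assigned tag
#' occurrences is recorded; replicate subsamples give a mean and sd.
#'
#' @param lib a `tag_library`.
#' @param index a `reference_tag_index`.
#' @param depths subsample sizes; each must be `<= lib$clean_total`.
#' @param replicates subsamples per depth (default 3).
#' @param seed integer seed for the subsampling RNG.
#' @param min_tags detection threshold in unambiguous tag occurrences
#'   (default 1).
#' @return data frame with columns `depth`, `mean_genes`, `sd_genes`.
#' @export
saturation_curve <- function(lib, index, depths, replicates = 3,
                             seed = NULL, min_tags = 1) {
  stopifnot(inherits(lib, "tag_library"),
            inherits(index, "reference_tag_index"))
  depths <- as.numeric(depths)
  if (any(depths < 0) || any(depths > lib$clean_total)) {
    stop("depths must lie in [0, clean_total]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  # Resolve each library tag to a gene once; subsamples then only need a
  # tabulation, not a re-mapping.
  res <- index$resolution
  hit <- match(names(lib$counts), res$tag)
  gene <- ifelse(!is.na(hit) & !res$ambiguous[hit], res$gene_id[hit],
                 NA_character_)
  gene_f <- factor(gene)
  expanded <- rep.int(seq_along(lib$counts), lib$counts)

  rows <- lapply(depths, function(d) {
    detected <- vapply(seq_len(replicates), function(r) {
      if (d == 0) return(0)
      idx <- sample(expanded, d)
      per_tag <- tabulate(idx, nbins = length(lib$counts))
      per_gene <- rowsum(per_tag[!is.na(gene)],
                         gene_f[!is.na(gene)], reorder = FALSE)
      sum(per_gene >= min_tags)
    }, numeric(1))
    data.frame(depth = d, mean_genes = mean(detected),
               sd_genes = if (replicates > 1) sd(detected) else 0)
  })
  do.call(rbind, rows)
}
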