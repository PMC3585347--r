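#' Read tag reads from FASTQ
#'
#' Thin wrapper over Biostrings returning plain vectors: read sequences
#' and per-read mean/minimum Phred qualities, which is all the tag
#' extractor needs.
#'
#' @param path FASTQ file (gzipped allowed).
#' @return list with `sequences` (character), `mean_quality` and
#'   `min_quality` (numeric, `NA` when the file carries no qualities).
#' @export
read_fastq_tags <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
  qual <- S4Vectors::mcols(reads)$qualities
  if (is.null(qual)) {
    mq <- rep(NA_real_, length(reads))
    minq <- mq
  } else {
    # Phred scores are the quality characters' code points minus 33
    stats_m <- vapply(as.character(qual), function(z) {
      v <- utf8ToInt(z) - 33L
      c(mean(v), min(v))
    }, numeric(2), USE.NAMES = FALSE)
    mq <- stats_m[1L, ]
    minq <- stats_m[2L, ]
  }
  list(sequences = unname(as.character(reads)), mean_quality = mq,
       min_quality = minq)
}

#' Extract and count anchored tags from raw reads
#'
#' Each read contributes at most one tag: the first
#' `nchar(anchor) + tag_len` bases, accepted only when the read starts
#' with the anchor, the tag contains no ambiguous base, and (when
#' qualities are supplied) the read passes the quality floor. Rejected
#' reads are tallied by reason.
#'
#' @param reads character vector of read sequences (or the list returned
#'   by [read_fastq_tags()]).
#' @param anchor,tag_len tag geometry; see [build_reference_index()].
#' @param mean_quality,min_quality optional per-read quality summaries
#'   aligned with `reads`.
#' @param quality_floor minimum acceptable mean Phred quality
#'   (default 20).
#' @param min_base_quality minimum acceptable per-read minimum base
#'   quality (default 10).
#' @return list with `counts` (named integer vector tag -> copy number)
#'   and `rejected` (named integer vector with categories `too_short`,
#'   `no_anchor`, `ambiguous_base`, `low_quality`).
#' @export
count_raw_tags <- function(reads, anchor = "CATG", tag_len = 17,
                           mean_quality = NULL, min_quality = NULL,
                           quality_floor = 20, min_base_quality = 10) {
  assert_acgt(anchor, "anchor")
  if (is.list(reads) && !is.null(reads$sequences)) {
    if (is.null(mean_quality)) mean_quality <- reads$mean_quality
    if (is.null(min_quality)) min_quality <- reads$min_quality
    reads <- reads$sequences
  }
  width <- nchar(anchor) + as.integer(tag_len)
  rejected <- c(too_short = 0L, no_anchor = 0L, ambiguous_base = 0L,
                low_quality = 0L)
  if (length(reads) == 0L) {
    return(list(counts = setNames(integer(0), character(0)),
                rejected = rejected))
  }

  ok <- rep(TRUE, length(reads))
  short <- nchar(reads) < width
  rejected["too_short"] <- sum(short)
  ok[short] <- FALSE

  if (!is.null(mean_quality)) {
    lowq <- ok & !is.na(mean_quality) & mean_quality < quality_floor
    if (!is.null(min_quality)) {
      lowq <- lowq | (ok & !is.na(min_quality) &
                        min_quality < min_base_quality)
    }
    rejected["low_quality"] <- sum(lowq)
    ok[lowq] <- FALSE
  }

  noanchor <- ok & !startsWith(reads, anchor)
  rejected["no_anchor"] <- sum(noanchor)
  ok[noanchor] <- FALSE

  tags <- substr(reads[ok], 1L, width)
  bad <- grepl("[^ACGT]", tags)
  rejected["ambiguous_base"] <- sum(bad)
  list(counts = count_strings(tags[!bad]), rejected = rejected)
}

#' Clean a raw tag count table
#'
#' Applies the standard DGE cleaning filters in a fixed order so the
#' report categories are disjoint: (1) tags matching an adaptor sequence
#' are removed (adaptor-only); (2) low-quality read occurrences, removed
#' upstream during extraction, are carried into the report via
#' `n_low_quality`; (3) tags with copy number below `min_copy`
#' (default 2, i.e. singletons) are removed. What remains is the clean
#' tag library.
#'
#' @param raw_counts named integer vector tag -> copy number (the
#'   `counts` element of [count_raw_tags()]), or a `tag_library`.
#' @param adaptor_seqs character vector of adaptor sequences; a tag is
#'   adaptor-only when it is a prefix of, or prefixed by, one of them.
#' @param min_copy minimum copy number retained (default 2).
#' @param n_low_quality count of read occurrences already rejected for
#'   quality upstream, folded into the cleaning report.
#' @param sample_id label stored in the library.
#' @return list with `library` (a `tag_library`: `sample_id`, `counts`,
#'   `clean_total`, `clean_distinct`) and `report` (a `cleaning_report`:
#'   `raw_total`, `removed_adaptor_only`, `removed_low_quality`,
#'   `removed_singleton`, `clean_total`, `clean_distinct`,
#'   `percent_retained`).
#' @examples
#' raw <- c(CATGAAAAAAAAAAAAAAAAA = 5L, CATGCCCCCCCCCCCCCCCCC = 1L)
#' clean_tags(raw)$report$removed_singleton
#' @export
clean_tags <- function(raw_counts, adaptor_seqs = character(),
                       min_copy = 2, n_low_quality = 0,
                       sample_id = "sample") {
  if (inherits(raw_counts, "tag_library")) {
    if (missing(sample_id)) sample_id <- raw_counts$sample_id
    raw_counts <- raw_counts$counts
  }
  if (min_copy < 1) stop("min_copy must be >= 1", call. = FALSE)
  counts <- raw_counts[raw_counts > 0L]
  raw_total <- sum(counts) + n_low_quality

  is_adaptor <- rep(FALSE, length(counts))
  for (ad in adaptor_seqs) {
    is_adaptor <- is_adaptor | startsWith(names(counts), ad) |
      startsWith(ad, names(counts))
  }
  removed_adaptor <- sum(counts[is_adaptor])
  counts <- counts[!is_adaptor]

  singleton <- counts < min_copy
  removed_singleton <- sum(counts[singleton])
  counts <- counts[!singleton]

  clean_total <- sum(counts)
  lib <- structure(list(
    sample_id = sample_id,
    counts = counts,
    clean_total = as.numeric(clean_total),
    clean_distinct = length(counts)
  ), class = "tag_library")
  report <- structure(list(
    raw_total = as.numeric(raw_total),
    removed_adaptor_only = as.numeric(removed_adaptor),
    removed_low_quality = as.numeric(n_low_quality),
    removed_singleton = as.numeric(removed_singleton),
    clean_total = as.numeric(clean_total),
    clean_distinct = length(counts),
    percent_retained = if (raw_total > 0) clean_total / raw_total else 0
  ), class = "cleaning_report")
  list(library = lib, report = report)
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library", x$sample_id, ":", x$clean_distinct, "distinct /",
      format(x$clean_total, big.mark = ","), "total clean tags\n")
  invisible(x)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "cleaning_report: raw %s -> clean %s (%.2f%% retained)\n",
    format(x$raw_total, big.mark = ","),
    format(x$clean_total, big.mark = ","), 100 * x$percent_retained))
  cat(sprintf("  adaptor-only %s | low-quality %s | copy<min %s\n",
              x$removed_adaptor_only, x$removed_low_quality,
              x$removed_singleton))
  invisible(x)
}

#' Transcripts-per-million normalization
#'
#' `count / clean_total * 1e6`. Refuses a zero library size rather than
#' returning NaN.
#'
#' @param count tag or gene copy number(s).
#' @param clean_total clean library size the counts come from.
#' @return numeric TPM value(s).
#' @examples
#' tpm(100, 1e6)
#' @export
tpm <- function(count, clean_total) {
  if (length(clean_total) != 1L || !is.finite(clean_total) ||
      clean_total <= 0) {
    stop("clean_total must be a single positive number", call. = FALSE)
  }
  if (any(count < 0 | count > clean_total)) {
    stop("counts must lie in [0, clean_total]", call. = FALSE)
  }
  count / clean_total * 1e6
}

#' Read / write a tag library as TSV
#'
#' Two tab-separated columns, `tag` and `count`.
#'
#' @param lib a `tag_library`.
#' @param path file path.
#' @export
write_tag_library <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  write.table(
    data.frame(tag = names(lib$counts), count = as.integer(lib$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_library
#' @param sample_id label for the library read back.
#' @export
read_tag_library <- function(path, sample_id = basename(path)) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("tag", "count") %in% names(d))) {
    stop("tag library TSV needs columns tag and count", call. = FALSE)
  }
  counts <- setNames(as.integer(d$count), d$tag)
  structure(list(
    sample_id = sample_id,
    counts = counts,
    clean_total = as.numeric(sum(counts)),
    clean_distinct = length(counts)
  ), class = "tag_library")
}
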