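#' Map a clean tag library to a reference tag index
#'
#' Each distinct tag is looked up in the index. A tag assigned to
#' exactly one gene contributes its copy number to that gene on the
#' matched strand; a tag matching more than one gene is mapped but
#' ambiguous and contributes to no gene; a tag absent from the index is
#' unknown. With `max_mismatch = 1`, exact matches take precedence and a
#' one-mismatch hit is used only when it resolves to a single gene.
#'
#' @param lib a `tag_library` (see [clean_tags()]).
#' @param index a `reference_tag_index` (see [build_reference_index()]).
#' @param max_mismatch 0 (default, exact matching) or 1.
#' @return list with `records` (data frame `gene_id`, `sense_count`,
#'   `antisense_count`, `sense_tpm`, `antisense_tpm`, one row per gene
#'   in the index, carrying the library's `clean_total` and `sample_id`
#'   as attributes) and `summary` (a `mapping_summary`).
#' @export
map_library <- function(lib, index, max_mismatch = 0) {
  stopifnot(inherits(lib, "tag_library"),
            inherits(index, "reference_tag_index"))
  if (index$n_distinct_tags == 0L) {
    stop("reference index is empty", call. = FALSE)
  }
  if (!max_mismatch %in% c(0, 1)) {
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  }
  tags <- names(lib$counts)
  n <- as.numeric(lib$counts)
  res <- index$resolution

  hit <- match(tags, res$tag)
  gene <- ifelse(is.na(hit), NA_character_, res$gene_id[hit])
  strand <- ifelse(is.na(hit), NA_character_, res$strand[hit])
  ambiguous <- !is.na(hit) & res$ambiguous[hit]

  if (max_mismatch == 1 && any(is.na(hit))) {
    mm <- match_one_mismatch(tags[is.na(hit)], res)
    gene[is.na(hit)] <- mm$gene_id
    strand[is.na(hit)] <- mm$strand
    ambiguous[which(is.na(hit))[mm$ambiguous]] <- TRUE
  }

  mapped <- ambiguous | !is.na(gene)
  unique_hit <- mapped & !ambiguous

  genes <- sort(unique(index$entries$gene_id))
  sense <- setNames(numeric(length(genes)), genes)
  anti <- sense
  if (any(unique_hit)) {
    g <- gene[unique_hit]
    s <- strand[unique_hit]
    cnt <- n[unique_hit]
    add_s <- rowsum(cnt[s == "sense"], g[s == "sense"])
    add_a <- rowsum(cnt[s == "antisense"], g[s == "antisense"])
    sense[rownames(add_s)] <- add_s[, 1L]
    anti[rownames(add_a)] <- add_a[, 1L]
  }
  records <- data.frame(
    gene_id = genes,
    sense_count = as.numeric(sense),
    antisense_count = as.numeric(anti),
    sense_tpm = tpm(as.numeric(sense), lib$clean_total),
    antisense_tpm = tpm(as.numeric(anti), lib$clean_total),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(records, "clean_total") <- lib$clean_total
  attr(records, "sample_id") <- lib$sample_id

  summary <- structure(list(
    clean_total = lib$clean_total,
    clean_distinct = lib$clean_distinct,
    mapped_total = sum(n[mapped]),
    mapped_distinct = sum(mapped),
    unambiguous_total = sum(n[unique_hit]),
    unambiguous_distinct = sum(unique_hit),
    ambiguous_total = sum(n[ambiguous]),
    ambiguous_distinct = sum(ambiguous),
    unknown_total = sum(n[!mapped]),
    unknown_distinct = sum(!mapped)
  ), class = "mapping_summary")

  list(records = records, summary = summary)
}

# Internal: resolve unmatched tags allowing exactly one mismatch.
# Returns, per tag, the unique gene/strand if all one-mismatch hits agree
# on a single gene, ambiguous if they touch >1 gene (or an ambiguous
# index tag), and NA/unknown otherwise.
match_one_mismatch <- function(tags, res) {
  out <- list(gene_id = rep(NA_character_, length(tags)),
              strand = rep(NA_character_, length(tags)),
              ambiguous = rep(FALSE, length(tags)))
  if (length(tags) == 0L) return(out)
  width <- nchar(tags[1L])
  for (i in seq_along(tags)) {
    variants <- character(0)
    for (pos in seq_len(width)) {
      base <- substr(tags[i], pos, pos)
      for (b in setdiff(DNA_BASES, base)) {
        v <- tags[i]
        substr(v, pos, pos) <- b
        variants <- c(variants, v)
      }
    }
    hit <- match(variants, res$tag)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) next
    if (any(res$ambiguous[hit])) {
      out$ambiguous[i] <- TRUE
      next
    }
    g <- unique(res$gene_id[hit])
    if (length(g) > 1L) {
      out$ambiguous[i] <- TRUE
    } else {
      out$gene_id[i] <- g
      s <- res$strand[hit]
      out$strand[i] <- if ("sense" %in% s) "sense" else "antisense"
    }
  }
  out
}

#' Tabulate a mapping summary with percentages
#'
#' Expands a `mapping_summary` into report rows giving, for total tag
#' occurrences and for distinct tags, the mapped, unambiguously mapped,
#' ambiguous and unknown counts with percentages of the clean library.
#'
#' @param summary a `mapping_summary` from [map_library()].
#' @return data frame with columns `category`, `total_count`,
#'   `total_pct`, `distinct_count`, `distinct_pct`.
#' @export
summarize_mapping <- function(summary) {
  stopifnot(inherits(summary, "mapping_summary"))
  cats <- c("clean", "mapped", "unambiguous", "ambiguous", "unknown")
  tot <- c(summary$clean_total, summary$mapped_total,
           summary$unambiguous_total, summary$ambiguous_total,
           summary$unknown_total)
  dis <- c(summary$clean_distinct, summary$mapped_distinct,
           summary$unambiguous_distinct, summary$ambiguous_distinct,
           summary$unknown_distinct)
  pct <- function(x, d) if (d > 0) 100 * x / d else rep(0, length(x))
  data.frame(
    category = cats,
    total_count = tot,
    total_pct = pct(tot, summary$clean_total),
    distinct_count = dis,
    distinct_pct = pct(dis, summary$clean_distinct),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mapping_summary <- function(x, ...) {
  print(summarize_mapping(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write per-gene expression records as TSV
#'
#' @param records the `records` data frame from [map_library()].
#' @param path file path.
#' @export
write_gene_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
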