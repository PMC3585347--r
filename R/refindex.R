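#' Read transcript sequences from FASTA
#'
#' Loads a transcript FASTA into the plain data frame the indexer
#' consumes. Gene assignment comes from a `gene=` attribute on the
#' description line when present, from a two-column side table
#' (`transcript_id`, `gene_id`) when supplied, and otherwise defaults to
#' the transcript id itself (one transcript per gene).
#'
#' @param fasta path to a FASTA file of transcript sequences.
#' @param gene_map optional path to a tab-separated file with columns
#'   `transcript_id` and `gene_id`, or a data frame with those columns.
#' @return data frame with columns `transcript_id`, `gene_id`,
#'   `sequence`.
#' @export
read_transcripts <- function(fasta, gene_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  gene <- ids
  has_attr <- grepl("gene=", names(seqs), fixed = TRUE)
  gene[has_attr] <- sub(".*gene=([^ \t]+).*", "\\1", names(seqs)[has_attr])
  tr <- data.frame(
    transcript_id = ids,
    gene_id = gene,
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  if (!is.null(gene_map)) {
    gm <- if (is.character(gene_map)) {
      read.delim(gene_map, header = TRUE, stringsAsFactors = FALSE)
    } else {
      as.data.frame(gene_map, stringsAsFactors = FALSE)
    }
    if (!all(c("transcript_id", "gene_id") %in% names(gm))) {
      stop("gene_map needs columns transcript_id and gene_id", call. = FALSE)
    }
    hit <- match(tr$transcript_id, gm$transcript_id)
    tr$gene_id[!is.na(hit)] <- gm$gene_id[hit[!is.na(hit)]]
  }
  validate_transcripts(tr)
  tr
}

validate_transcripts <- function(transcripts) {
  req <- c("transcript_id", "gene_id", "sequence")
  if (!is.data.frame(transcripts) || !all(req %in% names(transcripts))) {
    stop("transcripts must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("transcript_id values must be unique", call. = FALSE)
  }
  if (any(nchar(transcripts$sequence) < 1L)) {
    stop("every transcript sequence must be non-empty", call. = FALSE)
  }
  invisible(transcripts)
}

# Internal: scan one strand of a set of sequences for anchored tag sites.
# Returns data frame (tag, gene_id, strand, site_rank); site_rank 1 is the
# 3'-most complete site on that strand. Tags containing N are dropped.
scan_strand <- function(sequences, gene_ids, anchor, tag_len, strand) {
  width <- nchar(anchor) + tag_len
  hits <- gregexpr(anchor, sequences, fixed = TRUE)
  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    pos <- hits[[i]]
    if (pos[1L] == -1L) next
    pos <- pos[pos + width - 1L <= nchar(sequences[i])]
    if (length(pos) == 0L) next
    pos <- sort(pos, decreasing = TRUE)  # 3'-most first -> rank 1
    out[[i]] <- data.frame(
      tag = substring(sequences[i], pos, pos + width - 1L),
      gene_id = gene_ids[i],
      strand = strand,
      site_rank = seq_along(pos),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(tag = character(0), gene_id = character(0),
                      strand = character(0), site_rank = integer(0),
                      stringsAsFactors = FALSE)
  }
  res[!grepl("N", res$tag, fixed = TRUE), , drop = FALSE]
}

#' Build a reference tag index from transcript sequences
#'
#' Scans every transcript and its reverse complement for occurrences of
#' the anchor (restriction site) followed by at least `tag_len` bases.
#' Each complete site yields a reference tag of `nchar(anchor) + tag_len`
#' bases; sites are ranked from the 3' end of their strand (rank 1 is the
#' site closest to the 3' end, the canonical site of the classical
#' NlaIII DGE protocol). Tags from multiple transcripts of the same gene
#' are collapsed under the gene id; a tag shared by more than one gene is
#' ambiguous and is excluded from unique gene assignment downstream.
#'
#' @param transcripts data frame with columns `transcript_id`,
#'   `gene_id`, `sequence` (see [read_transcripts()]).
#' @param anchor anchor (restriction-site) sequence; default the NlaIII
#'   site `"CATG"`.
#' @param tag_len number of bases retained downstream of the anchor
#'   (default 17, giving 21-base tags).
#' @param all_sites if `TRUE` (default) all complete anchored sites on
#'   both strands are indexed; if `FALSE` only the rank-1 (3'-most) site
#'   per strand and gene is kept.
#' @return object of class `reference_tag_index`: a list with `entries`
#'   (data frame `tag`, `gene_id`, `strand`, `site_rank`), `resolution`
#'   (per-distinct-tag unique-gene assignment), `ambiguous_tags`,
#'   `anchor`, `tag_len`, `n_transcripts`, `n_genes`, `n_distinct_tags`.
#' @examples
#' tr <- data.frame(transcript_id = "t1", gene_id = "g1",
#'                  sequence = "AACATGTTTTTTTTTTTTTTTTTGG")
#' idx <- build_reference_index(tr)
#' idx$entries
#' @export
build_reference_index <- function(transcripts, anchor = "CATG",
                                  tag_len = 17, all_sites = TRUE) {
  assert_acgt(anchor, "anchor")
  if (!is.numeric(tag_len) || tag_len < 1) {
    stop("tag_len must be >= 1", call. = FALSE)
  }
  validate_transcripts(transcripts)
  if (nrow(transcripts) == 0L) {
    stop("cannot build an index from an empty transcript set", call. = FALSE)
  }
  tag_len <- as.integer(tag_len)

  sense <- scan_strand(transcripts$sequence, transcripts$gene_id,
                       anchor, tag_len, "sense")
  anti <- scan_strand(revcomp(transcripts$sequence), transcripts$gene_id,
                      anchor, tag_len, "antisense")
  entries <- rbind(sense, anti)

  # Collapse transcripts of the same gene: keep one row per
  # (tag, gene, strand), at the best (lowest) site rank.
  if (nrow(entries) > 0L) {
    key <- paste(entries$tag, entries$gene_id, entries$strand, sep = "\r")
    ord <- order(key, entries$site_rank)
    entries <- entries[ord, , drop = FALSE]
    entries <- entries[!duplicated(key[ord]), , drop = FALSE]
    if (!all_sites) {
      entries <- entries[entries$site_rank == 1L, , drop = FALSE]
    }
    rownames(entries) <- NULL
  }

  res <- resolve_tags(entries)
  structure(list(
    entries = entries,
    resolution = res,
    ambiguous_tags = res$tag[res$ambiguous],
    anchor = anchor,
    tag_len = tag_len,
    n_transcripts = nrow(transcripts),
    n_genes = length(unique(transcripts$gene_id)),
    n_distinct_tags = nrow(res)
  ), class = "reference_tag_index")
}

# Internal: per distinct tag, decide the unique gene/strand assignment.
# >1 gene -> ambiguous; one gene on both strands -> sense (avoids double
# counting while keeping antisense signal from strand-unique tags).
resolve_tags <- function(entries) {
  if (nrow(entries) == 0L) {
    return(data.frame(tag = character(0), gene_id = character(0),
                      strand = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  }
  split_idx <- split(seq_len(nrow(entries)), entries$tag)
  tag <- names(split_idx)
  gene <- character(length(tag))
  strand <- character(length(tag))
  amb <- logical(length(tag))
  for (i in seq_along(split_idx)) {
    rows <- split_idx[[i]]
    g <- unique(entries$gene_id[rows])
    if (length(g) > 1L) {
      amb[i] <- TRUE
      gene[i] <- NA_character_
      strand[i] <- NA_character_
    } else {
      gene[i] <- g
      s <- entries$strand[rows]
      strand[i] <- if ("sense" %in% s) "sense" else "antisense"
    }
  }
  data.frame(tag = tag, gene_id = gene, strand = strand, ambiguous = amb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Canonical (3'-most) sense tag of one transcript
#'
#' Convenience accessor for the rank-1 sense tag: the tag at the
#' anchored site closest to the transcript's 3' end with a complete
#' `tag_len` bases downstream.
#'
#' @inheritParams build_reference_index
#' @param transcript a single sequence string, or a one-row data frame
#'   with a `sequence` column.
#' @return the tag string, or `NA_character_` if the transcript has no
#'   complete anchored site.
#' @export
canonical_sense_tag <- function(transcript, anchor = "CATG", tag_len = 17) {
  assert_acgt(anchor, "anchor")
  seq <- if (is.data.frame(transcript)) transcript$sequence[1L] else transcript
  hits <- scan_strand(seq, "g", anchor, as.integer(tag_len), "sense")
  if (nrow(hits) == 0L) NA_character_ else hits$tag[hits$site_rank == 1L]
}

#' @export
print.reference_tag_index <- function(x, ...) {
  cat("reference_tag_index:", x$n_distinct_tags, "distinct tags (",
      x$anchor, "+", x$tag_len, "nt ) from", x$n_transcripts,
      "transcripts /", x$n_genes, "genes;",
      length(x$ambiguous_tags), "ambiguous\n")
  invisible(x)
}

#' Serialize / load a reference tag index
#'
#' The index is written as a tag table (TSV: `tag`, `gene_id`, `strand`,
#' `site_rank`) plus a small JSON stats block holding the tag geometry.
#'
#' @param index a `reference_tag_index`.
#' @param tsv path for the tag table.
#' @param json optional path for the stats block.
#' @return `write_reference_index` returns the paths invisibly;
#'   `read_reference_index` returns a rebuilt `reference_tag_index`.
#' @export
write_reference_index <- function(index, tsv, json = NULL) {
  stopifnot(inherits(index, "reference_tag_index"))
  write.table(index$entries, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(json)) {
    stats <- index[c("anchor", "tag_len", "n_transcripts", "n_genes",
                     "n_distinct_tags")]
    stats$n_ambiguous_tags <- length(index$ambiguous_tags)
    jsonlite::write_json(stats, json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_reference_index
#' @param anchor,tag_len geometry to record when reading back.
#' @export
read_reference_index <- function(tsv, anchor = "CATG", tag_len = 17) {
  entries <- read.delim(tsv, header = TRUE, stringsAsFactors = FALSE)
  entries$site_rank <- as.integer(entries$site_rank)
  res <- resolve_tags(entries)
  structure(list(
    entries = entries,
    resolution = res,
    ambiguous_tags = res$tag[res$ambiguous],
    anchor = anchor,
    tag_len = as.integer(tag_len),
    n_transcripts = NA_integer_,
    n_genes = length(unique(entries$gene_id)),
    n_distinct_tags = nrow(res)
  ), class = "reference_tag_index")
}
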