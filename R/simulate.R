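#' Configuration for the synthetic tag-library generator
#'
#' Collects every knob of the two-condition DGE simulation. The
#' defaults emulate the structure of a typical deep mouse-tissue tag
#' experiment: tens of thousands of genes with log-normally skewed
#' abundances sequenced to several million raw tags per condition, a
#' small planted fraction of differentially expressed genes, antisense
#' transcription at about a tenth of sense output, a few percent of
#' adaptor-only and un-indexed reads, and a per-read single-base error
#' rate that mostly produces singleton tags.
#'
#' @param n_genes number of genes (one transcript each).
#' @param meanlog,sdlog log-normal abundance parameters.
#' @param library_size_a,library_size_b raw reads per condition.
#' @param de_fraction fraction of genes with a planted fold change.
#' @param de_fold planted fold (> 1), applied up or down with equal
#'   probability in condition B.
#' @param antisense_rho expected antisense/sense read rate per gene.
#' @param adaptor_fraction fraction of raw reads that are adaptor-only.
#' @param error_rate per-read probability of one random base error.
#' @param unknown_fraction fraction of reads from un-indexed sequence.
#' @param n_unknown_tags size of the un-indexed tag pool.
#' @param n_collisions number of gene pairs forced to share their
#'   canonical tag (creates that many ambiguous tags).
#' @param transcript_length transcript length in bases (>= 38 so both a
#'   canonical sense and an antisense site fit).
#' @param anchor,tag_len tag geometry (see [build_reference_index()]).
#' @param seed integer RNG seed; every draw in the generator derives
#'   from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 20000, meanlog = 3, sdlog = 1.5,
                              library_size_a = 6e6,
                              library_size_b = 6e6,
                              de_fraction = 0.02, de_fold = 4,
                              antisense_rho = 0.10,
                              adaptor_fraction = 0.01,
                              error_rate = 0.01,
                              unknown_fraction = 0.065,
                              n_unknown_tags = max(100, n_genes %/% 10),
                              n_collisions = 0,
                              transcript_length = 300,
                              anchor = "CATG", tag_len = 17, seed = 1) {
  assert_acgt(anchor, "anchor")
  fracs <- c(de_fraction, antisense_rho, adaptor_fraction, error_rate,
             unknown_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (adaptor_fraction + unknown_fraction >= 1) {
    stop("adaptor_fraction + unknown_fraction must be < 1", call. = FALSE)
  }
  if (de_fold <= 1) stop("de_fold must be > 1", call. = FALSE)
  if (n_genes < 1 || library_size_a < 1 || library_size_b < 1) {
    stop("n_genes and library sizes must be positive", call. = FALSE)
  }
  if (transcript_length < nchar(anchor) + 2 * tag_len) {
    stop("transcript_length too short for a sense and an antisense site",
         call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), meanlog = meanlog, sdlog = sdlog,
    library_size_a = as.integer(library_size_a),
    library_size_b = as.integer(library_size_b),
    de_fraction = de_fraction, de_fold = de_fold,
    antisense_rho = antisense_rho,
    adaptor_fraction = adaptor_fraction, error_rate = error_rate,
    unknown_fraction = unknown_fraction,
    n_unknown_tags = as.integer(n_unknown_tags),
    n_collisions = as.integer(n_collisions),
    transcript_length = as.integer(transcript_length),
    anchor = anchor, tag_len = as.integer(tag_len),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Internal: n random DNA strings of the given width.
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# Internal: n random, mutually distinct k-mers, none present in `avoid`.
random_unique_kmers <- function(n, width, avoid = character(0)) {
  out <- random_dna(n, width)
  repeat {
    bad <- duplicated(out) | out %in% avoid
    if (!any(bad)) return(out)
    out[bad] <- random_dna(sum(bad), width)
  }
}

#' Simulate a transcriptome with controlled tag structure
#'
#' Generates one transcript per gene: uniform random background with a
#' canonical anchored site planted at the 3' end so every gene carries
#' a rank-1 sense tag (unique across genes) and, because the anchor is
#' palindromic, an antisense site immediately upstream of it. Random
#' internal anchor occurrences contribute additional sites exactly as
#' in real transcripts. `n_collisions` gene pairs are forced to share
#' their canonical tag, which makes those tags ambiguous in the index.
#'
#' @param config a `simulation_config`.
#' @return data frame with columns `transcript_id`, `gene_id`,
#'   `sequence`, byte-identical across runs for a fixed config.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g <- config$n_genes
  len <- config$transcript_length
  alen <- nchar(config$anchor)
  body_len <- len - alen - config$tag_len

  body <- random_dna(g, body_len)
  tail17 <- random_unique_kmers(g, config$tag_len)
  if (config$n_collisions > 0L) {
    if (2L * config$n_collisions > g) {
      stop("not enough genes for the requested collisions", call. = FALSE)
    }
    for (i in seq_len(config$n_collisions)) {
      tail17[2L * i] <- tail17[2L * i - 1L]
    }
  }
  data.frame(
    transcript_id = sprintf("tx%05d", seq_len(g)),
    gene_id = sprintf("gene%05d", seq_len(g)),
    sequence = paste0(body, config$anchor, tail17),
    stringsAsFactors = FALSE
  )
}

#' Simulate two-condition raw tag libraries with ground truth
#'
#' Draws the configured number of raw reads per condition from a
#' multinomial over adaptor-only reads, a pool of un-indexed tags, and
#' each gene's canonical sense and antisense tags. Condition B
#' multiplies a planted subset of gene abundances by the configured
#' fold (up or down with equal probability) before renormalization.
#' Antisense reads are emitted at rate `antisense_rho` of each gene's
#' sense probability, which couples antisense to sense output across
#' genes. A per-read single-base error mutates a random tag position,
#' producing mostly singleton tags (and anchor-less reads when the
#' error falls in the anchor). Everything derives from `config$seed`.
#'
#' @param config a `simulation_config`.
#' @param transcriptome the transcript set from
#'   [simulate_transcriptome()] built with the same config.
#' @return list of class `dge_simulation` with `reads_a`, `reads_b`
#'   (character vectors of raw read sequences, lengths exactly the
#'   configured library sizes), `truth` (per-gene data frame:
#'   `gene_id`, `abundance`, `multiplier_b`, `de`, `direction`,
#'   `expected_log2fc`, `sense_tag`, `antisense_tag`), `adaptor`,
#'   `unknown_tags`, and the `config`.
#' @export
simulate_libraries <- function(config, transcriptome) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$n_genes
  if (!is.data.frame(transcriptome) || nrow(transcriptome) != g) {
    stop("transcriptome does not match the configuration", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  len <- config$transcript_length
  alen <- nchar(config$anchor)
  width <- alen + config$tag_len

  sense_tag <- substring(transcriptome$sequence, len - width + 1L, len)
  if (any(substr(sense_tag, 1L, alen) != config$anchor)) {
    stop("transcriptome does not match the configuration", call. = FALSE)
  }
  # Palindromic anchor: the site upstream of the canonical one read on
  # the reverse strand.
  anti_tag <- revcomp(substring(transcriptome$sequence,
                                len - width - config$tag_len + 1L,
                                len - config$tag_len))

  abund <- rlnorm(g, config$meanlog, config$sdlog)
  n_de <- round(config$de_fraction * g)
  de_idx <- sort(sample.int(g, n_de))
  up <- runif(n_de) < 0.5
  mult <- rep(1, g)
  mult[de_idx] <- ifelse(up, config$de_fold, 1 / config$de_fold)

  q_a <- abund / sum(abund)
  q_b <- abund * mult / sum(abund * mult)
  renorm <- sum(abund) / sum(abund * mult)

  unknown_tags <- paste0(
    config$anchor,
    random_unique_kmers(config$n_unknown_tags, config$tag_len))
  unknown_w <- rlnorm(config$n_unknown_tags, config$meanlog,
                      config$sdlog)
  unknown_w <- unknown_w / sum(unknown_w)
  adaptor <- substr(paste0(config$anchor, "TCGGACTGTAGAACTCTGAAC"),
                    1L, width)

  draw_library <- function(size, q) {
    gene_budget <- 1 - config$adaptor_fraction - config$unknown_fraction
    probs <- c(config$adaptor_fraction,
               config$unknown_fraction * unknown_w,
               gene_budget * q / (1 + config$antisense_rho),
               gene_budget * q * config$antisense_rho /
                 (1 + config$antisense_rho))
    counts <- as.vector(rmultinom(1L, size, probs))
    n_unk <- config$n_unknown_tags
    reads <- c(
      rep.int(adaptor, counts[1L]),
      rep.int(unknown_tags, counts[1L + seq_len(n_unk)]),
      rep.int(sense_tag, counts[1L + n_unk + seq_len(g)]),
      rep.int(anti_tag, counts[1L + n_unk + g + seq_len(g)])
    )
    # Single-base errors on gene-derived reads.
    first_gene <- counts[1L] + sum(counts[1L + seq_len(n_unk)]) + 1L
    n_gene_reads <- length(reads) - first_gene + 1L
    n_err <- rbinom(1L, n_gene_reads, config$error_rate)
    if (n_err > 0L) {
      at <- sample(seq.int(first_gene, length(reads)), n_err)
      pos <- sample.int(width, n_err, replace = TRUE)
      for (j in seq_len(n_err)) {
        old <- substr(reads[at[j]], pos[j], pos[j])
        new <- sample(setdiff(DNA_BASES, old), 1L)
        substr(reads[at[j]], pos[j], pos[j]) <- new
      }
    }
    reads
  }

  reads_a <- draw_library(config$library_size_a, q_a)
  reads_b <- draw_library(config$library_size_b, q_b)

  truth <- data.frame(
    gene_id = transcriptome$gene_id,
    abundance = abund,
    multiplier_b = mult,
    de = mult != 1,
    direction = ifelse(mult > 1, "up", ifelse(mult < 1, "down", "none")),
    expected_log2fc = log2(mult * renorm),
    sense_tag = sense_tag,
    antisense_tag = anti_tag,
    stringsAsFactors = FALSE
  )
  structure(list(reads_a = reads_a, reads_b = reads_b, truth = truth,
                 adaptor = adaptor, unknown_tags = unknown_tags,
                 config = config),
            class = "dge_simulation")
}

#' Score differential calls against the planted truth
#'
#' Compares a differential result table with the generator's ground
#' truth: recall over the planted genes that entered testing, realized
#' false discovery proportion over the significant set, and the
#' per-gene log2 fold-estimation error.
#'
#' @param diff_results a `diff_expr_result` from [call_differential()].
#' @param truth the `truth` data frame of a `dge_simulation`.
#' @return list with `n_planted`, `n_planted_tested`, `n_significant`,
#'   `recall`, `precision`, `realized_fdr` (NA when no gene is called),
#'   and `fold_errors`: data frame `gene_id`, `combined`,
#'   `log2_estimated`, `log2_planted`, `error` over all tested genes.
#' @export
evaluate_recovery <- function(diff_results, truth) {
  common <- intersect(diff_results$gene_id, truth$gene_id)
  if (length(common) == 0L) {
    stop("results and truth share no gene ids", call. = FALSE)
  }
  planted <- truth$gene_id[truth$de]
  tested <- diff_results$gene_id
  sig <- diff_results$gene_id[diff_results$significant]
  planted_tested <- intersect(planted, tested)

  recall <- if (length(planted_tested) > 0L) {
    length(intersect(sig, planted_tested)) / length(planted_tested)
  } else NA_real_
  precision <- if (length(sig) > 0L) {
    length(intersect(sig, planted)) / length(sig)
  } else NA_real_
  realized_fdr <- if (length(sig) > 0L) 1 - precision else NA_real_

  m <- match(tested, truth$gene_id)
  fold_errors <- data.frame(
    gene_id = tested,
    combined = diff_results$x + diff_results$y,
    log2_estimated = diff_results$log2_ratio,
    log2_planted = truth$expected_log2fc[m],
    stringsAsFactors = FALSE
  )
  fold_errors$error <- fold_errors$log2_estimated -
    fold_errors$log2_planted

  list(n_planted = length(planted),
       n_planted_tested = length(planted_tested),
       n_significant = length(sig),
       recall = recall, precision = precision,
       realized_fdr = realized_fdr,
       fold_errors = fold_errors)
}

#' Write reads as FASTQ
#'
#' Plain-text FASTQ writer for simulated reads with a flat quality
#' profile.
#'
#' @param reads character vector of read sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param quality_char quality character applied to every base
#'   (default `"I"`, Phred 40).
#' @param id_prefix read-name prefix.
#' @export
write_fastq <- function(reads, path, quality_char = "I",
                        id_prefix = "read") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  lines <- character(4L * length(reads))
  lines[seq(1L, by = 4L, length.out = length(reads))] <-
    paste0("@", id_prefix, seq_along(reads))
  lines[seq(2L, by = 4L, length.out = length(reads))] <- reads
  lines[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(reads))] <-
    strrep(quality_char, nchar(reads))
  writeLines(lines, con)
  invisible(path)
}

#' Write a transcriptome as FASTA
#'
#' @param transcriptome data frame from [simulate_transcriptome()] (or
#'   any transcript table with `transcript_id`, `gene_id`, `sequence`).
#' @param path output FASTA path.
#' @export
write_transcripts_fasta <- function(transcriptome, path) {
  validate_transcripts(transcriptome)
  seqs <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(seqs) <- paste0(transcriptome$transcript_id, " gene=",
                        transcriptome$gene_id)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
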