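test_that("anchored sites yield tags exactly as defined", {
  # no anchor site anywhere
  tr <- data.frame(transcript_id = "t1", gene_id = "g1",
                   sequence = "AAATTTGGGCCC")
  # revcomp also has no CATG, but an index needs >= 1 tag somewhere;
  # pair it with a real transcript so the build succeeds
  tr2 <- rbind(tr, data.frame(transcript_id = "t2", gene_id = "g2",
                              sequence = "AACATGTTTTTTTTTTTTTTTTTGG"))
  idx <- build_reference_index(tr2)
  expect_false("g1" %in% idx$entries$gene_id)

  # single complete sense site, rank 1; the reverse strand site is
  # incomplete (only 2 bases downstream) so exactly one entry exists
  e <- idx$entries[idx$entries$gene_id == "g2", ]
  expect_identical(e$tag, "CATGTTTTTTTTTTTTTTTTT")
  expect_identical(e$strand, "sense")
  expect_identical(e$site_rank, 1L)
})

test_that("site ranking counts from the 3' end and all_sites toggles", {
  seq2 <- paste0("CATG", strrep("A", 17), "CATG", strrep("C", 17))
  tr <- data.frame(transcript_id = "t", gene_id = "g", sequence = seq2)
  idx <- build_reference_index(tr)
  sense <- idx$entries[idx$entries$strand == "sense", ]
  expect_identical(sense$tag[sense$site_rank == 1L],
                   paste0("CATG", strrep("C", 17)))
  expect_identical(sense$tag[sense$site_rank == 2L],
                   paste0("CATG", strrep("A", 17), collapse = ""))

  idx1 <- build_reference_index(tr, all_sites = FALSE)
  expect_true(all(idx1$entries$site_rank == 1L))
})

test_that("cross-gene shared tags are ambiguous, shared within a gene are not", {
  shared_tail <- paste0("CATG", strrep("G", 17))
  tr <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g2", "g1"),
    sequence = c(paste0(strrep("A", 30), shared_tail),
                 paste0(strrep("T", 30), shared_tail),
                 paste0(strrep("C", 30), shared_tail))
  )
  idx <- build_reference_index(tr)
  expect_identical(idx$ambiguous_tags, shared_tail)
  # t1/t3 collapse under g1: one entry per (tag, gene, strand)
  e <- idx$entries[idx$entries$tag == shared_tail, ]
  expect_identical(sort(unique(e$gene_id)), c("g1", "g2"))
})

test_that("emitted tags always have anchor prefix and full length", {
  cfg <- simulation_config(n_genes = 40, library_size_a = 1000,
                           library_size_b = 1000, seed = 5)
  tx <- simulate_transcriptome(cfg)
  idx <- build_reference_index(tx)
  expect_true(all(nchar(idx$entries$tag) == 21L))
  expect_true(all(startsWith(idx$entries$tag, "CATG")))
  expect_false(any(grepl("N", idx$entries$tag)))
})

test_that("strand labels swap under reverse complementation of input", {
  cfg <- simulation_config(n_genes = 25, library_size_a = 1000,
                           library_size_b = 1000, seed = 9)
  tx <- simulate_transcriptome(cfg)
  idx <- build_reference_index(tx)
  tx_rc <- tx
  tx_rc$sequence <- revcomp(tx$sequence)
  idx_rc <- build_reference_index(tx_rc)
  key <- function(e, flip = FALSE) {
    s <- if (flip) c(sense = "antisense", antisense = "sense")[e$strand]
    else e$strand
    sort(paste(e$tag, e$gene_id, s, e$site_rank))
  }
  expect_identical(key(idx$entries), key(idx_rc$entries, flip = TRUE))
})

test_that("index construction is deterministic", {
  cfg <- simulation_config(n_genes = 30, library_size_a = 1000,
                           library_size_b = 1000, seed = 3)
  tx <- simulate_transcriptome(cfg)
  expect_identical(build_reference_index(tx), build_reference_index(tx))
})

test_that("canonical_sense_tag handles boundaries", {
  expect_identical(canonical_sense_tag(paste0("CATG", strrep("A", 10))),
                   NA_character_)
  two <- paste0("CATG", strrep("A", 17), "CATG", strrep("C", 17))
  expect_identical(canonical_sense_tag(two),
                   paste0("CATG", strrep("C", 17)))
  exact <- paste0("CATG", strrep("T", 17))
  expect_identical(canonical_sense_tag(exact), exact)
})

test_that("invalid inputs are rejected explicitly", {
  empty <- data.frame(transcript_id = character(0),
                      gene_id = character(0), sequence = character(0))
  expect_error(build_reference_index(empty), "empty")
  tr <- data.frame(transcript_id = "t", gene_id = "g",
                   sequence = "CATGAAAAAAAAAAAAAAAAA")
  expect_error(build_reference_index(tr, anchor = "CAXG"), "A,C,G,T")
  expect_error(build_reference_index(tr, tag_len = 0), "tag_len")
})

test_that("FASTA and TSV round trips preserve the index", {
  cfg <- simulation_config(n_genes = 20, library_size_a = 1000,
                           library_size_b = 1000, seed = 12)
  tx <- simulate_transcriptome(cfg)
  fa <- tempfile(fileext = ".fa")
  write_transcripts_fasta(tx, fa)
  tx2 <- read_transcripts(fa)
  expect_identical(tx2$gene_id, tx$gene_id)
  expect_identical(tx2$sequence, tx$sequence)

  idx <- build_reference_index(tx)
  tsv <- tempfile(fileext = ".tsv")
  write_reference_index(idx, tsv)
  idx2 <- read_reference_index(tsv)
  expect_identical(idx2$entries$tag, idx$entries$tag)
  expect_identical(idx2$ambiguous_tags, idx$ambiguous_tags)
  expect_identical(idx2$resolution, idx$resolution)
})
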