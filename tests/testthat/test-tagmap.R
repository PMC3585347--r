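tagA <- paste0("CATG", strrep("A", 17))
tagC <- paste0("CATG", strrep("C", 17))
tagG <- paste0("CATG", strrep("G", 17))

# Two genes plus one shared (ambiguous) tag. Homopolymer bodies are
# chosen so the antisense junction tags coincide with each gene's own
# sense tag (resolved to sense) and add no cross-gene ambiguity beyond
# tagG; t3 additionally contributes the antisense tag CATG+T17 to g1.
toy_index <- build_reference_index(data.frame(
  transcript_id = c("t1", "t2", "t3", "t4"),
  gene_id = c("g1", "g2", "g1", "g2"),
  sequence = c(paste0(strrep("T", 25), tagA),
               paste0(strrep("G", 25), tagC),
               paste0(strrep("A", 25), tagG),
               paste0(strrep("C", 25), tagG))
))

make_lib <- function(counts, id = "S") {
  structure(list(sample_id = id, counts = counts,
                 clean_total = as.numeric(sum(counts)),
                 clean_distinct = length(counts)),
            class = "tag_library")
}

test_that("unique, ambiguous and unknown tags land in the right buckets", {
  unknown <- paste0("CATG", "ACGTACGTACGTACGTA")
  lib <- make_lib(setNames(c(50L, 10L, 7L, 3L),
                           c(tagA, tagC, tagG, unknown)))
  m <- map_library(lib, toy_index)
  rec <- m$records
  expect_identical(rec$sense_count[rec$gene_id == "g1"], 50)
  expect_identical(rec$sense_count[rec$gene_id == "g2"], 10)
  # ambiguous: mapped but assigned to no gene
  expect_identical(m$summary$ambiguous_total, 7)
  expect_identical(m$summary$mapped_total, 67)
  expect_identical(m$summary$unknown_total, 3)
  # conservation across categories
  expect_identical(
    sum(rec$sense_count) + sum(rec$antisense_count) +
      m$summary$ambiguous_total + m$summary$unknown_total,
    lib$clean_total)
})

test_that("sense and antisense hits to the same gene resolve to sense", {
  tail_tag <- paste0("CATG", "AAGGTTCCAAGGTTCCA")
  # transcript carries revcomp(tail_tag) internally, so its reverse
  # strand also contains tail_tag as an anchored antisense site
  seqs <- paste0(strrep("T", 20), revcomp(tail_tag), strrep("G", 20),
                 tail_tag)
  idx <- build_reference_index(data.frame(
    transcript_id = "t", gene_id = "g", sequence = seqs))
  res <- idx$resolution[idx$resolution$tag == tail_tag, ]
  expect_false(res$ambiguous)
  expect_identical(res$strand, "sense")
  m <- map_library(make_lib(setNames(8L, tail_tag)), idx)
  expect_identical(m$records$sense_count[m$records$gene_id == "g"], 8)
  expect_identical(m$records$antisense_count[m$records$gene_id == "g"], 0)
})

test_that("mapping percentages cover the boundary cases", {
  all_map <- make_lib(setNames(c(5L, 5L), c(tagA, tagC)))
  s <- summarize_mapping(map_library(all_map, toy_index)$summary)
  expect_equal(s$total_pct[s$category == "mapped"], 100)
  expect_equal(s$total_pct[s$category == "unambiguous"], 100)

  none <- make_lib(setNames(4L, paste0("CATG", "ACGTACGTACGTACGTA")))
  s0 <- summarize_mapping(map_library(none, toy_index)$summary)
  expect_equal(s0$total_pct[s0$category == "mapped"], 0)
  expect_equal(s0$total_pct[s0$category == "unknown"], 100)
})

test_that("count conservation holds on simulated libraries", {
  exp <- small_experiment(seed = 41, n_genes = 150, library_size = 8000)
  m <- exp$map_a
  expect_equal(
    sum(m$records$sense_count) + sum(m$records$antisense_count) +
      m$summary$ambiguous_total + m$summary$unknown_total,
    exp$clean_a$library$clean_total)
  # planted unknown fraction recovered within sampling error:
  # unknown tags surviving the copy filter stay near the configured rate
  expect_lt(abs(m$summary$unknown_total / m$summary$clean_total -
                  exp$cfg$unknown_fraction), 0.02)
  # mapping twice gives identical output
  m2 <- map_library(exp$clean_a$library, exp$idx)
  expect_identical(m2$records, m$records)
})

test_that("one-mismatch mode rescues unique near-matches only", {
  near_A <- paste0("CATG", "T", strrep("A", 16))  # 1 mismatch from tagA
  lib <- make_lib(setNames(c(9L, 4L), c(tagA, near_A)))
  exact <- map_library(lib, toy_index, max_mismatch = 0)
  expect_identical(exact$summary$unknown_total, 4)
  mm <- map_library(lib, toy_index, max_mismatch = 1)
  expect_identical(mm$summary$unknown_total, 0)
  rec <- mm$records
  expect_identical(rec$sense_count[rec$gene_id == "g1"], 13)

  # a variant reaching two genes is ambiguous, not assigned
  between <- paste0("CATG", strrep("A", 16), "C")
  near_two <- build_reference_index(data.frame(
    transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
    sequence = c(paste0(strrep("T", 25), tagA),
                 paste0(strrep("G", 25), paste0("CATG", strrep("A", 15),
                                                "CC")))
  ))
  m2 <- map_library(make_lib(setNames(5L, between)), near_two,
                    max_mismatch = 1)
  expect_identical(m2$summary$ambiguous_total, 5)
  expect_identical(m2$summary$mapped_total, 5)
})

test_that("an empty index is refused", {
  lib <- make_lib(setNames(1L, tagA))
  idx <- toy_index
  idx$resolution <- idx$resolution[0, ]
  idx$n_distinct_tags <- 0L
  expect_error(map_library(lib, idx), "empty")
})
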