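# Small in-code fixtures shared across test files.

# A compact two-condition simulated experiment, mapped and ready for
# downstream tests. Sized for speed, not power.
small_experiment <- function(seed = 101, n_genes = 300,
                             library_size = 3e4, de_fraction = 0.1,
                             de_fold = 4, antisense_rho = 0.1, ...) {
  cfg <- simulation_config(
    n_genes = n_genes, library_size_a = library_size,
    library_size_b = library_size, de_fraction = de_fraction,
    de_fold = de_fold, antisense_rho = antisense_rho, seed = seed, ...)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_libraries(cfg, tx)
  idx <- build_reference_index(tx)
  lib <- function(reads, id) {
    clean_tags(count_raw_tags(reads)$counts,
               adaptor_seqs = sim$adaptor, sample_id = id)
  }
  cla <- lib(sim$reads_a, "A")
  clb <- lib(sim$reads_b, "B")
  list(cfg = cfg, tx = tx, sim = sim, idx = idx,
       clean_a = cla, clean_b = clb,
       map_a = map_library(cla$library, idx),
       map_b = map_library(clb$library, idx))
}

# Hand-built per-gene record frames for the differential tests.
make_records <- function(counts, clean_total,
                         antisense = rep(0, length(counts))) {
  rec <- data.frame(
    gene_id = if (is.null(names(counts))) character(0) else names(counts),
    sense_count = as.numeric(counts),
    antisense_count = as.numeric(antisense),
    sense_tpm = as.numeric(counts) / clean_total * 1e6,
    antisense_tpm = as.numeric(antisense) / clean_total * 1e6,
    stringsAsFactors = FALSE
  )
  attr(rec, "clean_total") <- clean_total
  rec
}
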