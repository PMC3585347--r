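# dgetag

Digital gene expression (DGE) tag profiling in R: from raw
restriction-anchored sequence tags to differentially expressed genes and
antisense transcripts.

## The problem

Classical Solexa/Illumina DGE (SAGE-style) experiments sequence short
cDNA tags anchored at an NlaIII restriction site: each tag is the
`CATG` anchor plus the next 17 bases of the transcript, and the number
of times a tag is sequenced measures the abundance of its transcript.
One library is sequenced per condition — typically millions of tags,
no replicates — so the analysis rests on exact count statistics rather
than dispersion models. `dgetag` implements the complete analysis for
such data:

* **Reference tag indexing** — every anchored site on both strands of a
  transcript set becomes a reference tag, ranked from the 3' end (rank 1
  is the canonical NlaIII site). Tags shared by multiple genes are
  ambiguous and never assigned.
* **Tag extraction and cleaning** — adaptor-only tags, low-quality
  reads, and tags with copy number below 2 are removed; the cleaning
  report partitions every raw tag into exactly one category.
* **Mapping** — clean tags are assigned to genes with sense/antisense
  resolution; counts are normalized to transcripts per million
  (TPM = count / clean total × 10⁶).
* **Differential expression** — the exact Audic–Claverie test for a
  count *y* in a library of size *N₂* given *x* in a library of size
  *N₁*:

  p(y | x) = (N₂/N₁)ʸ · (x+y)! / ( x! · y! · (1 + N₂/N₁)^(x+y+1) )

  evaluated in log space; two-sided p-values double the smaller tail,
  Benjamini–Hochberg FDR is computed over the tested set, and genes are
  called at the conventional cutoffs (combined copy number ≥ 200,
  P < 0.05, FDR < 0.05, |log₂ ratio| > 0.5).
* **Downstream summaries** — copy-number classes (2–99 / 100–499 /
  ≥ 500), expressed (≥ 100 copies) and tissue-specific gene sets,
  sense–antisense coupling (correlation and antisense/sense ratio),
  differential antisense transcripts, gene-set enrichment
  (Re = (n_f/n)/(N_f/N), two-sided Fisher exact and χ² tests), and
  library saturation curves.
* **Synthetic data with ground truth** — a fully seeded generator
  producing transcriptomes and two-condition raw tag libraries with
  planted fold changes, antisense transcription, adaptor contamination
  and sequencing errors, so every stage is testable end to end.

## Worked example

Simulate a two-condition experiment (2,000 genes, 5×10⁵ tags per
library, 2% of genes planted at 4-fold) and run the pipeline:

```r
library(dgetag)

cfg <- simulation_config(n_genes = 2000, library_size_a = 5e5,
                         library_size_b = 5e5, de_fraction = 0.02,
                         de_fold = 4, seed = 7)
tx  <- simulate_transcriptome(cfg)
sim <- simulate_libraries(cfg, tx)

idx <- build_reference_index(tx)
#> reference_tag_index: 8152 distinct tags ( CATG + 17 nt ) from 2000
#> transcripts / 2000 genes; 0 ambiguous

cl <- lapply(list(A = sim$reads_a, B = sim$reads_b), function(r)
  clean_tags(count_raw_tags(r)$counts, adaptor_seqs = sim$adaptor))
cl$A$report
#> cleaning_report: raw 499,131 -> clean 490,660 (98.30% retained)
#>   adaptor-only 5009 | low-quality 0 | copy<min 3462

maps <- lapply(cl, function(x) map_library(x$library, idx))
maps$A$summary
#>     category total_count total_pct distinct_count distinct_pct
#>        clean      490660   100.000           4021       100.00
#>       mapped      457334    93.208           3574        88.88
#>  unambiguous      457334    93.208           3574        88.88
#>    ambiguous           0     0.000              0         0.00
#>      unknown       33326     6.792            447        11.12

de <- call_differential(maps$A$records, maps$B$records)
sum(de$significant)   # 15 of 799 tested genes
fold_change_bins(de)
#>   threshold up down
#> 1       1.5 14    1
#> 2       2.0 14    1
#> 3       5.0  0    0

evaluate_recovery(de, sim$truth)[c("recall", "realized_fdr")]
#> $recall       [1] 1
#> $realized_fdr [1] 0

pairs <- antisense_table(maps$A$records)
mean_antisense_ratio(pairs)$ratio_of_totals   # 0.100
sense_antisense_correlation(pairs)            # 0.940 (log10 scale)
```

The cleaning report shows ~98% of raw tags surviving the filters; ~93%
of clean tags map to the reference, ~7% come from un-indexed sequence.
Of the planted 4-fold genes abundant enough to pass the combined ≥ 200
filter, all are recovered with no false calls, and the planted
antisense rate (10% of sense) and tight sense–antisense coupling are
both measured back from the reads.

File-based orchestration of the same stages (FASTA/FASTQ in, TSV/JSON
out, with a run manifest) is available through `pipeline_config()` and
`run_pipeline()`; see the methods vignette in `vignettes/` for the
statistical background and design choices.

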