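#' Pipeline configuration
#'
#' Consolidates input paths and every stage cutoff of the end-to-end
#' tag-profiling analysis. Defaults are the conventional DGE cutoffs:
#' clean tags need copy number >= 2, meaningful expression >= 100
#' copies, differential testing needs a combined copy number >= 200
#' with `P < 0.05`, `FDR < 0.05` and `|log2 ratio| > 0.5`, and
#' antisense analysis uses antisense copy number >= 100.
#'
#' @param transcript_fasta path to the reference transcript FASTA.
#' @param library_a,library_b per-sample inputs: FASTQ files of raw
#'   reads, or pre-counted tag TSVs (`tag`, `count`; detected by a
#'   `.tsv`/`.txt` suffix).
#' @param sample_a,sample_b sample labels.
#' @param annotation_gmt optional GMT/TSV annotation file for
#'   enrichment of the differential gene set.
#' @param tissue_tables optional named character vector of per-tissue
#'   count TSVs (`gene_id`, `count`) for tissue-specificity analysis.
#' @param out_dir output directory (created if missing).
#' @param anchor,tag_len tag geometry.
#' @param adaptor_seqs adaptor sequences removed during cleaning.
#' @param min_copy,expressed_min,min_combined,min_abs_log2,p_max,fdr_max,antisense_min
#'   stage cutoffs (see Description).
#' @param fold_bins cumulative fold thresholds for the differential
#'   summary.
#' @param saturation_depths optional depths for a saturation curve on
#'   library A.
#' @param seed RNG seed used by the saturation subsampler.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(transcript_fasta, library_a, library_b,
                            sample_a = "A", sample_b = "B",
                            annotation_gmt = NULL, tissue_tables = NULL,
                            out_dir = "dgetag-out",
                            anchor = "CATG", tag_len = 17,
                            adaptor_seqs = character(),
                            min_copy = 2, expressed_min = 100,
                            min_combined = 200, min_abs_log2 = 0.5,
                            p_max = 0.05, fdr_max = 0.05,
                            antisense_min = 100,
                            fold_bins = c(1.5, 2, 5),
                            saturation_depths = NULL, seed = 1) {
  if (any(c(min_copy, expressed_min, min_combined, antisense_min) <= 0)) {
    stop("count cutoffs must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

# Internal: read one sample input (FASTQ or pre-counted TSV) into raw
# counts + quality rejection tally.
load_sample <- function(path, anchor, tag_len) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    lib <- read_tag_library(path)
    list(counts = lib$counts, rejected = c(low_quality = 0L))
  } else {
    reads <- read_fastq_tags(path)
    count_raw_tags(reads, anchor = anchor, tag_len = tag_len)
  }
}

#' Run the full tag-profiling pipeline
#'
#' Executes, in order: reference indexing, tag counting and cleaning
#' for both samples, mapping, differential expression with fold bins,
#' copy-number classification, expressed and tissue-specific gene
#' derivation, the antisense analysis (table, correlation, mean ratio,
#' differential antisense), optional enrichment of the significant
#' genes, and an optional saturation curve. Every stage writes its TSV
#' output under `config$out_dir` and contributes its filter counts to
#' the run manifest, which is also written as JSON.
#'
#' @param config a `pipeline_config`.
#' @return the manifest: a nested list with parameter echo, per-stage
#'   gene/tag counts, and the paths of all written files. The full
#'   stage results are attached as the `"results"` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(parameters = unclass(config)[
    !vapply(unclass(config), is.null, logical(1))])
  stage <- "refindex"
  results <- list()

  tryCatch({
    transcripts <- read_transcripts(config$transcript_fasta)
    index <- build_reference_index(transcripts, anchor = config$anchor,
                                   tag_len = config$tag_len)
    write_reference_index(index, out("reference_index.tsv"),
                          out("reference_index.json"))
    manifest$refindex <- list(
      n_transcripts = index$n_transcripts, n_genes = index$n_genes,
      n_distinct_tags = index$n_distinct_tags,
      n_ambiguous_tags = length(index$ambiguous_tags))

    stage <- "taglib"
    libs <- list()
    for (s in c("a", "b")) {
      id <- config[[paste0("sample_", s)]]
      raw <- load_sample(config[[paste0("library_", s)]],
                         config$anchor, config$tag_len)
      cl <- clean_tags(raw$counts, adaptor_seqs = config$adaptor_seqs,
                       min_copy = config$min_copy,
                       n_low_quality = unname(raw$rejected["low_quality"]),
                       sample_id = id)
      write_tag_library(cl$library, out(paste0("clean_tags_", id, ".tsv")))
      jsonlite::write_json(unclass(cl$report),
                           out(paste0("cleaning_report_", id, ".json")),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest[[paste0("cleaning_", s)]] <- unclass(cl$report)
      libs[[s]] <- cl$library
    }

    stage <- "tagmap"
    maps <- lapply(libs, map_library, index = index)
    for (s in c("a", "b")) {
      id <- config[[paste0("sample_", s)]]
      write_gene_records(maps[[s]]$records,
                         out(paste0("gene_expression_", id, ".tsv")))
      jsonlite::write_json(unclass(maps[[s]]$summary),
                           out(paste0("mapping_summary_", id, ".json")),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest[[paste0("mapping_", s)]] <- unclass(maps[[s]]$summary)
    }

    stage <- "diffexpr"
    de <- call_differential(maps$a$records, maps$b$records,
                            min_combined = config$min_combined,
                            p_max = config$p_max,
                            fdr_max = config$fdr_max,
                            min_abs_log2 = config$min_abs_log2)
    write.table(de, out("differential_expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bins <- fold_change_bins(de, thresholds = config$fold_bins)
    jsonlite::write_json(bins, out("fold_change_bins.json"),
                         pretty = TRUE)
    manifest$diffexpr <- list(
      n_tested = nrow(de), n_significant = sum(de$significant),
      n_up = sum(de$direction == "up"),
      n_down = sum(de$direction == "down"),
      fold_bins = bins)
    results$differential <- de

    stage <- "genesets"
    expressed <- expressed_genes(maps$a$records,
                                 min_count = config$expressed_min)
    classes <- lapply(maps, function(m) copy_number_classes(m$records))
    manifest$genesets <- list(
      n_expressed_a = length(expressed),
      classes_a = as.data.frame(classes$a),
      classes_b = as.data.frame(classes$b))
    writeLines(expressed, out("expressed_genes_a.txt"))

    if (!is.null(config$tissue_tables)) {
      target <- tissue_expression_set(config$sample_a, maps$a$records,
                                      min_count = config$expressed_min)
      others <- lapply(names(config$tissue_tables), function(tn) {
        d <- read.delim(config$tissue_tables[[tn]], header = TRUE,
                        stringsAsFactors = FALSE)
        tissue_expression_set(tn, d, min_count = config$expressed_min)
      })
      specific <- tissue_specific(target, others)
      writeLines(specific, out("tissue_specific_genes.txt"))
      manifest$genesets$n_tissue_specific <- length(specific)
    }

    stage <- "antisense"
    pairs <- lapply(maps, function(m) antisense_table(m$records))
    write.table(pairs$a, out("antisense_table_a.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    da <- differential_antisense(maps$a$records, maps$b$records,
                                 min_copy = config$antisense_min,
                                 p_max = config$p_max,
                                 fdr_max = config$fdr_max,
                                 min_abs_log2 = config$min_abs_log2)
    write.table(da$results, out("differential_antisense.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$antisense <- list(
      n_pairs_a = nrow(pairs$a), n_pairs_b = nrow(pairs$b),
      correlation_log10_a = sense_antisense_correlation(pairs$a),
      mean_ratio_a = mean_antisense_ratio(pairs$a)$ratio_of_totals,
      n_tested = nrow(da$results), bins = da$bins)
    results$antisense <- da

    if (!is.null(config$annotation_gmt)) {
      stage <- "enrichment"
      ann <- read_gmt(config$annotation_gmt,
                      universe = maps$a$records$gene_id)
      flagged <- de$gene_id[de$significant]
      if (length(flagged) > 0L) {
        er <- enrich(intersect(flagged, ann$universe), ann,
                     p_max = config$p_max, fdr_max = config$fdr_max)
        write.table(er, out("enrichment.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        manifest$enrichment <- list(n_terms = nrow(er),
                                    n_selected = sum(er$selected))
        results$enrichment <- er
      }
    }

    if (!is.null(config$saturation_depths)) {
      stage <- "saturation"
      sat <- saturation_curve(libs$a, index,
                              depths = config$saturation_depths,
                              seed = config$seed)
      write.table(sat, out("saturation_a.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$saturation <- sat
    }
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  attr(manifest, "results") <- results
  manifest
}
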