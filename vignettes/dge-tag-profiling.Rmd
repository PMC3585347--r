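---
title: "Methods: digital gene expression tag profiling with dgetag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital gene expression tag profiling with dgetag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Restriction-anchored digital gene expression (DGE) sequencing reduces
each transcript to one or a few short tags: the NlaIII recognition site
`CATG` plus the next 17 bases, 21 nt in total. Because NlaIII cuts at
the 3'-most site ahead of the poly(A) tail, the canonical tag of a
transcript is the anchored site closest to its 3' end; internal sites
and sites on the reverse strand produce additional tags, which is what
makes antisense transcription visible in the same library. A library is
then simply a multiset of tags, and a gene's expression is the summed
copy number of the tags assigned to it.

`dgetag` models this chain explicitly:

* `build_reference_index()` scans transcripts and their reverse
  complements for complete anchored sites, ranking sites from the 3'
  end per strand. The tag chemistry is not hard-wired: `anchor` and
  `tag_len` are arguments, with the NlaIII 4+17 geometry as default
  because that is the convention of the classical DGE protocol. All
  sites on both strands are indexed by default (`all_sites = TRUE`);
  antisense expression arises mostly from internal sites, so indexing
  only canonical sites would silence it. A canonical-only mode is
  provided for sensitivity analyses; neither mode is claimed to be the
  only defensible choice.
* Tags occurring in more than one gene are *ambiguous*: they are
  counted as mapped but assigned to no gene. A tag hitting the same
  gene on both strands is assigned to the sense strand — this prevents
  double counting while preserving antisense signal from strand-unique
  tags.

# Cleaning

Three filters produce the clean library, applied in a fixed order so
the report categories are disjoint and partition the raw total exactly:

1. adaptor-only tags (tag equal to, or prefixed by, a supplied adaptor
   sequence);
2. low-quality reads — the convention here is mean Phred < 20 or any
   base < 10, both configurable, since short-tag protocols did not
   standardize this;
3. tags with copy number < 2 (`min_copy = 2`), the singleton filter
   that serves as the protocol's only error control. Counting is exact
   on tag strings; no near-identical-tag collapsing is attempted,
   because the singleton filter already absorbs the vast majority of
   single-base sequencing errors.

Normalization is transcripts per million: `count / clean_total * 1e6`.
A zero library size is an error, never a silent `NaN`, and the TPM
vector of a library sums to 10⁶ by construction (asserted in the test
suite to 10⁻⁶ relative).

# The exact two-library test

With one library per condition there is no replication, so testing
relies on the exact Audic–Claverie statistic. Given `x` occurrences in
a library of size `N1`, the probability of `y` occurrences in a library
of size `N2` under equal relative abundance is

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}}.$$

Numerically this is evaluated in log space via `lgamma`; the naive
factorial route overflows beyond `x + y` ≈ 170, whereas the log-space
form is finite and accurate for counts in the millions. For the tail
sums the package uses the fact that, for fixed `x`, $p(\cdot \mid x)$
is a negative binomial density with size $x+1$ and success probability
$N_1/(N_1+N_2)$, so cumulative probabilities are regularized incomplete
beta functions (`pbeta`) — exact, and constant-time in the counts. The
test suite verifies this path against an independent term-by-term
recurrence summation to below 10⁻⁹ absolute over all `x, y ≤ 100` at
library-size ratios 0.5, 1 and 2.

The two-sided p-value doubles the smaller of $P(Y \le y)$ and
$P(Y \ge y)$, capped at 1. The direction of a call is treated
symmetrically; the doubled-tail construction is *almost* invariant
under swapping the libraries, the discrepancy being bounded by the
point masses at the observed counts (a discreteness effect, tested
explicitly). At `x = y` with equal library sizes the p-value is exactly
1.

Multiple testing uses Benjamini–Hochberg step-up FDR (`p.adjust`),
computed over the tested set only — genes are filtered to combined copy
number `x + y ≥ 200` *before* testing, and separately for the sense and
antisense analysis universes, since those are reported separately.

A gene is called differential when `P < 0.05`, `FDR < 0.05` and
`|log₂ ratio| > 0.5` (all configurable). The ratio is computed on TPM
by default; on raw counts as an option (identical when library sizes
are equal — which of the two the classical pipelines used is not
documented, so both are supported). Zero values are floored at
`max(TPM)/10⁴` and the reported fold is capped at 10⁴, so an
expressed-versus-absent gene reports a large but finite fold rather
than infinity. Fold-change bins (≥ 1.5, ≥ 2, ≥ 5 by default) are
cumulative, and the closed thresholds are evaluated with a 10⁻⁹
relative tolerance so that an exact count ratio of 2 or 5 lands in its
bin despite the `2^log2` floating-point round trip.

`ddct_fold()` is the companion qPCR utility (2^−ΔΔCt), included because
tag-profiling studies conventionally validate calls by qPCR.

# Gene-set summaries

* *Expressed genes*: sense copy number ≥ 100, the conventional
  threshold separating meaningful expression from background in
  million-tag libraries.
* *Copy-number classes*: default bounds 2–99, 100–499, ≥ 500; the
  bounds must tile the count range without gap or overlap, and class
  fractions sum to one.
* *Tissue specificity* is a set difference: genes expressed in the
  target tissue and in none of the comparison tissues. The same
  ≥ 100-copy cutoff is applied to every tissue by default — the
  symmetric choice; per-tissue overrides exist because published
  comparison tables come from heterogeneous platforms.
* *Saturation curves* subsample the clean library without replacement
  (multivariate hypergeometric on tag counts), re-tally genes with at
  least one unambiguously assigned tag (configurable to ≥ 2), and
  average over seeded replicates. Detection is monotone non-decreasing
  in depth in expectation and equals the full-library gene count at
  full depth.

# Antisense analysis

Each gene's sense and antisense counts are paired;
`mean_antisense_ratio()` reports both the ratio of totals
(Σ antisense / Σ sense — the library-level rate) and the mean of
per-gene ratios, which differ under skewed abundances.
`sense_antisense_correlation()` defaults to the `log10(count + 1)`
scale: a raw-count Pearson coefficient on log-skewed abundances is
dominated by the few most abundant genes and can approach 1 with
little per-gene coupling, so raw and abundance-binned modes are
offered alongside for transparency rather than silently choosing one.
Differential antisense testing filters on the antisense count (≥ 100
in either library — the filter applies to the antisense transcript,
not its sense partner), then reuses the exact test machinery.

# Enrichment

For a flagged gene set, each annotation term gets the enrichment ratio

$$R_e = \frac{n_f / n}{N_f / N}$$

(`n_f` flagged in the category, `n` category size, `N_f` flagged in
the universe, `N` universe size), a two-sided Fisher exact p-value
(hypergeometric enumeration of tables no more probable than the
observed one, with the customary 10⁻⁷ tie tolerance), a Pearson χ²
p-value (1 df, continuity correction off by default; refused when an
expected cell is zero), and BH-FDR across terms. Selection uses the
Fisher p-value by default because it is exact at small category
counts. The background universe is supplied by the caller; the natural
default in this pipeline is the set of genes detected in the clean
library, and the choice matters — a genome-wide universe inflates
enrichment of anything expressed.

No ontology-graph propagation is attempted: the statistics operate on
whatever term → gene map is supplied (GMT or two-column TSV).

# The synthetic data generator

`simulate_transcriptome()` and `simulate_libraries()` exist so that
every stage of the pipeline can be validated against planted truth
without any external data. The generator emulates:

* log-normally skewed gene abundances (`meanlog = 3`, `sdlog = 1.5`),
  chosen so that at multi-million-tag depth a majority of genes fall
  under 100 copies and roughly a tenth exceed 500 — the qualitative
  copy-number profile of deep mouse-tissue DGE libraries (no claim of
  matching any particular table numerically);
* library sizes of 6×10⁶ raw tags per condition by default, the scale
  of a deep single-lane DGE run;
* planted differential expression: a configurable fraction of genes
  multiplied by `de_fold` (up or down with equal probability) in
  condition B, with the renormalized expected log₂ fold stored per
  gene;
* antisense transcription at rate `antisense_rho` (default 0.10) of
  each gene's sense output. Antisense reads are drawn as additional
  multinomial cells at rate ρ/(1+ρ) of the gene's sense probability —
  this keeps the total read count exactly equal to the configured
  library size while coupling antisense to sense across genes through
  the shared abundance, which is what produces the strong
  sense–antisense correlation;
* contamination: adaptor-only reads (1%; the simulated adaptor begins
  with the anchor, as a restriction site ligated to an adaptor would,
  so these flow into the tag table and are caught by the adaptor
  filter), reads from un-indexed transcripts (6.5%, emulating
  incomplete reference annotation), and single-base errors at 1% per
  read, which mostly create singleton tags (or anchor-less reads when
  the error hits the anchor) and exercise the cleaning filters.

Everything derives from one integer seed; identical configurations
produce byte-identical libraries and truth tables.

What the generator does **not** emulate: positional quality decay and
miscalibrated quality strings, PCR duplication, partial digestion
(tags from non-canonical sites in proportions other than what random
internal anchors give), 3'-biased fragmentation, and any biological
correlation structure between genes. Passing recovery tests on this
generator therefore demonstrates that the statistics and bookkeeping
are correct under the stated sampling model — not that the pipeline is
robust to every artifact of real libraries.

`evaluate_recovery()` closes the loop: recall over planted genes that
entered testing, realized false-discovery proportion over the
significant set, and per-gene log₂ fold-estimation error.

# Validation sizes and numerical choices

The packaged validation (test suite and `scripts/acceptance.R`) runs
the planted-truth experiment at 5,000 genes and two 10⁶-tag libraries
with 100 genes planted at 4-fold — large enough that genes passing the
combined ≥ 200 filter carry real statistical power, small enough to
re-run routinely. At these sizes the exact test recovers essentially
all eligible planted genes with realized FDR under the nominal 0.05,
and log₂ fold estimates for genes with combined counts ≥ 500 land
within ±0.2 of the planted value for ≈ 95% of genes — that bound is
the sampling-noise limit of a count ratio at a few hundred counts, not
an implementation artifact (the standard error of a log₂ ratio at
`x = y = 250` is ≈ 0.13).

Degenerate inputs are handled explicitly rather than propagated:
empty transcript sets, empty flagged sets, zero library totals and
zero-variance correlations raise errors; an empty tested set returns
an empty, well-formed result with a warning; `NA` never silently
enters a p-value vector.

# Limitations

* No replicate-aware or dispersion-modeling inference: the exact test
  assumes pure counting noise, which understates biological
  variability. With replicated designs, use a count-model package
  (e.g. edgeR/DESeq2) instead; `dgetag` targets the unreplicated
  tag-library design.
* Tag-to-gene assignment is exact string matching (optionally one
  mismatch); no positional or genomic alignment, and no proportional
  rescue of ambiguous tags.
* Enrichment treats terms independently; no hierarchy-aware
  correction.
* The one-mismatch mode enumerates 3×21 variants per unknown tag and
  is intended for moderate libraries, not for error correction at
  scale.
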