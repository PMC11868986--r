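---
title: "From GWAS risk loci to regulatory mechanism: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS risk loci to regulatory mechanism: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Most risk variants found by genome-wide association studies sit in
non-coding DNA, where their most plausible mode of action is to change how
strongly a transcription factor (TF) binds a regulatory element, and
thereby how much of some target gene is made. regsnap implements the
standard functional-genomics funnel that turns a list of index SNPs into a
ranked list of candidate regulatory variants:

1. **LD expansion** — each index SNP tags a haplotype block; every variant
   in linkage disequilibrium (r² at or above a threshold, default 0.3)
   within a window (default ±500 kb) is a candidate.
2. **Motif discovery** — the top ChIP-seq peaks (default 500, ±20 bp
   around the summit, ranked by peak height) for each TF are searched for
   enriched sequence motifs against a dinucleotide-shuffled background,
   keeping motifs at ≤5% FDR, and the discovered matrices are matched to a
   motif database (PWMs).
3. **Allele-specific scoring** — each candidate variant is scored against
   each matched PWM with both alleles substituted; a variant is called
   *TF binding-disrupting* when at least one allele shows a significant
   binding likelihood (affinity p < 0.001) and the two alleles differ
   significantly (rank p < 0.05 after Bonferroni correction over all
   scored SNP × motif pairs).
4. **eQTL integration** — called variants must associate with gene
   expression in brain eQTL datasets (Benjamini–Hochberg q < 0.001 within
   each dataset); association with the same gene in ≥2 datasets is flagged
   as replicated.
5. **Prioritization** — survivors need a RegulomeDB category-1
   annotation; ranking is by an additive 0–4 evidence score (promoter
   histone marks, enhancer histone marks, DNase protein binding, motif
   change), then rank p-value, then variant id.

Every input can be generated by the synthetic-data module with planted
ground truth, so the full pipeline is testable end to end without any
external download.

# The statistics

## PWM scoring

A PWM stores per-position base probabilities. Scores are log-odds sums in
log2 units: `log2(((p + c) / (1 + 4c)) / bg)` with pseudocount
`c = 1e-4` — small enough to preserve strong penalties for
zero-probability bases, large enough to avoid −∞. For a variant, the
sequence ±20 bases (the scoring half-window) is extracted, each allele is
substituted at the focal base, and every motif window overlapping the
focal base is scored on both strands; the best window per allele is kept.
Ties break to the smaller window start, then the plus strand, making
results deterministic.

## Affinity p-value

`P(best score of a random background sequence of the same scan length ≥
observed)`. Exact by full enumeration when the scan length is ≤10 bases
(4^len sequences, weighted by the background law), Monte Carlo otherwise.
The default `n_mc = 1e5` puts the binomial standard error at p = 0.001
near 1e-4.

## Rank p-value (allelic difference)

The null pairs both alleles on identical random flanks. The tested
statistic is the *change in binding-likelihood rank*:
`|log p_aff(S_ref) − log p_aff(S_alt)|`, where `p_aff` is the marginal
survival function of the same null.

Two numerical facts forced this design, and both are worth recording:

* The raw score difference `|S_ref − S_alt|` is useless as a statistic
  here: because the best window is a maximum over windows whose focal
  column differs, each allele's argmax migrates to a window whose focal
  column favors it, and the null difference saturates at the maximum
  attainable column contrast in 40–65% of draws. No real variant could
  ever pass a Bonferroni threshold against that null. The log-rank
  transform restores power while leaving every degenerate contract intact
  (identical alleles give p = 1; an allele-blind motif gives p = 1).
* A strong planted site pushes *both* alleles beyond the resolvable tail
  of a plain background sample of size 1e5. The batch scorer therefore
  mixes half of its Monte-Carlo draws from motif-planted sequences
  (uniform window and strand) with self-normalized importance weights
  that restore the background law — the same idea the field's standard
  scoring package uses. The standalone p-value functions keep pure
  background sampling (`site_frac = 0`) so exact-versus-Monte-Carlo
  oracle comparisons test the plain estimator.

Survival lookups use a 1e-9 score tolerance so floating-point jitter
between scoring code paths cannot flip tie inclusion, and the survival
function is floored at half its smallest atom so logs stay finite.

## Multiple testing

The affinity gate is `min(p_ref, p_alt) < 0.001`. The rank gate is
Bonferroni: `p_rank < 0.05 / N` with `N` the number of scored SNP × motif
pairs (global by default, configurable per TF — the underlying study does
not state its denominator). eQTL q-values are Benjamini–Hochberg within
each dataset; the threshold `q < 0.001` is applied strictly.

# Motif discovery: a documented stand-in

The discovery module exposes the published parameters (`nmotifs = 5`,
`minw = 6`, `maxw = 20`) but is deliberately a simplified seed-and-refine
scheme rather than a reimplementation of the published tool: positives
are split 50/50; k-mer seeds (k = min(w, 8)) are scored by one-sided
Fisher presence enrichment against per-sequence dinucleotide shuffles
(an exact Eulerian-path shuffle preserving dinucleotide counts); the best
seed per width is refined into a PWM by one EM pass over best-site
alignments; up to `nmotifs` motifs are accepted greedily with site
masking; and each accepted motif's reported enrichment p-value comes from
the held-out half only, which keeps it honest despite seed selection.
Widths are enumerated up to 12 (`width_cap`); an optional EM-driven
extension to wider motifs was considered and dropped, because every
planted-recovery and calibration target is met within the cap at a
fraction of the runtime — wider enumeration only inflates the seed space
(k-mer seeds are capped at 8 anyway).

"FDR > 5% excluded" is read as *motifs* (not peaks) with discovery FDR
above 5% being excluded, matching how discovery tools report per-motif
significance.

# The synthetic world

The generator's defaults are the package's stated test conditions, chosen
once:

* **Reference**: 50 kb, GC 0.41 (human-like), i.i.d. bases.
* **Generating motif**: a 12-bp GC-rich palindromic consensus (an
  NRF1-like response element) with dominant-base probability 0.95 per
  column (≈19.6 bits; allelic contrast ≈5.8 log2 units at the most
  informative column) — a realistic strong TF.
* **Peaks**: 100 peaks of 61 bp, 80% planted with one sampled motif
  instance at the summit; log-normal heights with a +1σ shift (log scale)
  for planted peaks so height ranking is meaningful.
* **LD panel**: 200 haplotypes, four blocks. Blocks with an r² profile
  plant proxies by the flip construction `eps = (1 − sqrt(r²))/2` around
  a frequency-0.5 index SNP, whose expected r² is exactly the target;
  founder blocks resample from founder haplotypes plus the ancestral
  haplotype (a single founder gives perfect within-block LD). Blocks are
  independent, so across-block r² has expectation 0.
* **Variants**: 5 causal (inside planted sites, at the PWM column of
  maximal information, alternate allele = least probable base) + 200 null
  (≥100 bases from any planted site). Each causal variant's
  `true_delta_score` is recomputed from the emitted reference with the
  scoring module, so the round trip is exact by construction.
* **eQTL**: 3 datasets; planted pairs get p ~ 1e-8..1e-12 (surviving
  BH q < 0.001 everywhere) with direction-consistent effects in
  |β| ∈ [0.2, 0.8]; everything else is uniform.
* **Annotations**: causal variants get category 1a–1f and all four
  evidence flags, each flag flipped with probability 0.05; others get
  categories ≥2 and sparse (15%) flags.

What the generator does *not* emulate: coalescent demography and
recombination gradients, read-level ChIP-seq noise, correlated eQTL
datasets (sample overlap), annotation errors correlated across features,
and multi-variant haplotype effects on a single motif window. A green
test therefore establishes the pipeline's internal correctness and
calibration, not performance on real cohort data.

# Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; VCF and FASTA
  interfaces convert at the boundary (VCF positions 1-based).
* Variants near contig ends are scored with truncated scans and get their
  own null geometry.
* Multiallelic VCF records are skipped with a log message by default
  (split on request, one pseudo-variant per alternate allele); indels are
  excluded by default.
* r² uses pairwise-complete haplotypes; pairs with fewer than 20 complete
  haplotypes return NA with a warning. Unphased input uses EM over double
  heterozygotes (tolerance 1e-8, ≤100 iterations).
* The LD threshold is inclusive (r² ≥ 0.3): the source study prints both
  a strict and an inclusive form in different places; the threshold is a
  parameter, so the choice is cosmetic.
* The motif-database similarity is the Pearson correlation of aligned
  probability columns over all ungapped offsets and both strands
  (minimum overlap 4), threshold 0.75 — a reduced form of standard
  motif-comparison statistics; the underlying study does not state its
  criterion.
* The composite ranking (evidence score desc, rank p asc, id lexicographic)
  is a documented reconstruction; the study says only that candidates
  were "scored and ranked".
* Genomic context collapses to exonic > intronic > intergenic.
* eQTL tables join on variant id (rsID-style); no positional fallback is
  attempted — the synthetic world and the exported schema always carry
  ids, and a positional join would need allele harmonization this module
  deliberately leaves out.

# Known limitations

* The rank test's Monte-Carlo resolution is bounded by the importance
  mixture; p-values below ~1e-8 are reported as 0.
* Discovery assumes one dominant motif per experiment; co-factor motifs
  surface only if `nmotifs` allows and masking leaves signal.
* The LD module is single-population; no stratification or imputation.
* eQTL integration treats dataset labels as independent replicates; no
  colocalization.
* The 21,300-SNP LD expansion of the source study needs 1000 Genomes EAS
  haplotypes and is hours of download away; `expand_ld()` implements the
  operation, but no desk-scale test asserts that count.
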