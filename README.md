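# regsnap

Map GWAS risk loci to candidate regulatory mechanisms. regsnap implements
the functional-genomics funnel used to find transcription-factor (TF)
binding-disrupting SNPs at psychiatric-disorder risk loci, end to end and
fully testable on synthetic data with planted ground truth:

1. **LD expansion** — index SNPs grow into candidate sets of variants with
   r² ≥ 0.3 (configurable) within ±500 kb, from a phased or unphased VCF
   panel (unphased r² via EM haplotype-frequency estimation).
2. **Motif discovery** — enriched PWMs from the top ChIP-seq peaks
   (default top 500, summit ±20 bp, ranked by height) against
   dinucleotide-shuffled backgrounds, with per-motif held-out enrichment
   p-values and Benjamini–Hochberg FDR ≤ 5%.
3. **Database matching** — discovered motifs matched to a MEME-format PWM
   database by column correlation (Pearson ≥ 0.75 over the best ungapped
   alignment, both strands).
4. **Allele-specific disruption calling** — for each SNP × motif pair,
   best-match log-odds scores for both alleles on ±20 bp scans;
   *affinity* p-values (is either allele a credible site?) and *rank*
   p-values (did the binding-likelihood rank change?) from exact
   enumeration or importance-sampled Monte Carlo. A SNP is called
   disrupting when `min(p_ref, p_alt) < 0.001` and
   `p_rank < 0.05 / n_tests` (Bonferroni over all scored pairs).
5. **eQTL integration** — BH q-values within each brain eQTL dataset;
   gate `q < 0.001`; replication flagged at ≥2 datasets.
6. **Prioritization** — RegulomeDB category-1 gate, additive 0–4 evidence
   score (promoter marks, enhancer marks, DNase binding, motif change),
   deterministic tie-breaks, per-TF and co-disruption summaries.

The core statistic: writing `S(a)` for the best log2 PWM match with allele
`a` substituted at the focal base, the affinity p-value is
`P(S_bg ≥ S(a))` under a background-sequence null, and the rank p-value
tests `|log P(S_bg ≥ S(ref)) − log P(S_bg ≥ S(alt))|` against the paired
null with both alleles substituted into identical random flanks. See the
methods vignette (`vignettes/regsnap-methods.Rmd`) for why the rank
transform and the importance-sampling mixture are there.

## Worked example

Generate a fully synthetic world (reference, ChIP-seq peaks with a planted
NRF1-like motif, LD panel, 5 causal + 200 null variants, 3 brain eQTL
datasets, annotations) and run the whole pipeline:

```r
library(regsnap)
sc  <- simulate_scenario(outdir = "scenario", seed = 1)
run <- run_pipeline(sc$paths$config, outdir = "run1")
rep <- make_report("run1")
```

Output printed by this exact session:

```
--- funnel ---
  pairs_scored     410
  variants_called  2
  eqtl_pass        2
  regulome_pass    2
  ranked           2
--- top ranked ---
 variant_id evidence_score       p_rank  tf_hits rank
  causal_01              4 5.015314e-07 TFA:loss  1
  causal_04              3 2.837782e-05 TFA:loss  2
```

Reading it: 205 variants were scored against 2 matched database motifs
(410 pairs). Two planted causal variants cleared both significance gates
at this Monte-Carlo seed — every ranked variant is a planted causal one
and the direction (`loss`) matches the planted disruption; the remaining
planted variants sit just above the Bonferroni threshold
`0.05/410 ≈ 1.2e-4` here (perfect-consensus sites give a rank shift close
to that boundary; across the 20-seed acceptance study 82% of causal
variants are called, with essentially no false calls). The funnel is
monotone: called → eQTL-replicated → category-1 → ranked.

The single-SNP worked example (NRF1 response element, G→A loss):

```r
pwm <- from_consensus("YGCGCAYGCGCR")
best_match_score(pwm, "GGCGCAGCCGCAGC", 9L, "G")$score  # -16.87
best_match_score(pwm, "GGCGCAGCCGCAGC", 9L, "A")$score  # -30.16
```

(The consensus-PWM zero-probability columns make absolute scores strongly
negative for any imperfect site; the direction — G above A — is what the
worked example asserts.)

## Command line

```sh
Rscript -e 'regsnap::regsnap_main()' simulate --outdir scenario --seed 1
Rscript -e 'regsnap::regsnap_main()' run --config scenario/config.txt --outdir run1
Rscript -e 'regsnap::regsnap_main()' report run1
```

(Subcommands: `simulate`, `ld-expand`, `discover`, `match-motifs`,
`score`, `eqtl`, `prioritize`, `run`, `report`; `inst/cli/regsnap` is a
ready launcher.)

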