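---
title: "Mapping a recessive mutation from two phenotype-selected bulks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive mutation from two phenotype-selected bulks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkseg)
```

## The genetic model

`bulkseg` targets the simplest and most common mapping situation in induced
mutant libraries: a single recessive mutation in a selfed line. A family
derived from a heterozygous parent segregates genotypes 1:2:1
(hom-ref : het : hom-alt), hence phenotypes 3:1 wild-type : mutant. The
`cross_design()` object carries this prior and the inheritance mode; every
expectation downstream is derived from it rather than hard-coded, so a
dominant mutation or a distorted prior can be analysed with the same code.

Bulked segregant analysis pools plants by phenotype and sequences each pool.
Genotype frequencies conditioned on phenotype translate into expected pool
allele frequencies (`expected_bulk_af()`):

* mutant-selected bulk, recessive design: every plant is hom-alt, expected
  mutant-allele frequency **1**;
* wild-type-selected bulk: plants are 1/3 hom-ref : 2/3 het, expected
  frequency **1/3**.

At an unlinked variant the two bulks look alike; at the causal locus they
diverge maximally. This is the signal the pipeline scores.

## The pipeline

`run_bvf_pipeline()` chains five stages.

1. **Record filtering** (`filter_records()`). Thresholds follow the
   Picard-FilterVcf-style convention: total depth ≥ 6 reads, genotype
   quality ≥ 0, quality-by-depth ≥ 2 (derived as `QUAL/DP` when the caller
   wrote no `QD`), and an allele-balance floor of 0.8 applied to homozygous
   calls — a hom-alt call supported by fewer than 80% of its reads is more
   plausibly a mis-genotyped het and is dropped. Heterozygous calls are
   exempt from the allele-balance floor: their defining property is
   intermediate balance, and the information they carry (a segregating pool)
   is used at the ranking stage instead. All thresholds are inclusive;
   records missing a tested field fail conservatively; a threshold of zero
   disables its test.

2. **Effect restriction** (`select_effect_classes()`). Only variants
   annotated missense or frameshift (any-match over a record's annotations)
   enter the first screening round; the parser accepts both the SnpEff `ANN`
   sub-field layout and a simplified `class|gene` dialect and collapses term
   synonyms onto one enum.

3. **Bulk consensus and subtraction** (`subtract_common()`). Each bulk's
   variant set is its homozygous-alt calls — a pooled sample called het means
   the pool segregates at that site, which is evidence, not a fixed bulk
   variant. Variants present in both bulks' sets are background differences
   from the reference and are removed; identity is the full
   `(chrom, pos, ref, alt)` key after multi-allelic splitting (stricter than
   position-only identity, and documented as such). This is what lets the
   causal locus survive: the mutant bulk carries it as a clean homozygous
   call, while the wild-type bulk shows a ~1/3 heterozygous pattern and so
   does not cancel it.

4. **Consistency ranking** (`rank_candidates()`). Each mutant-specific
   candidate is tested in both bulks with the exact two-sided binomial test
   (`binom_consistency()`, minimum-likelihood rule) against the design's
   expected frequencies, and scored as the product `p_mut * p_wt`. The
   product was preferred to Fisher combination because both factors are
   interpretable consistency probabilities and the product is monotone in
   each. The binomial test operates on *reads*, so expectations are folded
   with a per-read miscall rate (`read_error`, default 0.001): a bulk fixed
   for the mutant allele is expected at read frequency `1 - 0.001`, not
   exactly 1 — under the degenerate `p0 = 1` distribution a single miscalled
   read would otherwise send an ideal candidate's p-value to zero. Sites
   with no wild-type coverage are flagged `wt_untestable` with `p_wt = 1`
   rather than treated as support. Ties are broken by the deviation of the
   observed SNP-index difference from its expectation (2/3 under the
   recessive design), then genomic position, giving a deterministic total
   order.

5. **IGV review** (`igv_batch_script()`). Ranking replaces eyeballing for
   triage, but visual confirmation remains the field's practice; the emitted
   batch script (`new`/`genome`/`load`/`goto`/`snapshot`) spans each
   candidate's affected interval — for a VCF-style deletion record the bases
   after the anchor base — plus a configurable flank (default 500 bp,
   clamped at position 1).

One deliberate asymmetry: the expected wild-type bulk frequency is 1/3 (the
dosage-weighted mean over 1 hom-ref : 2 het), even though one sometimes sees
such pools described as "half heterozygous"; the conditional 1:2 composition
is the Mendelian expectation and is what the simulator reproduces.

## What the simulator emulates — and what it does not

`simulate_bulk_experiment()` regenerates the study conditions as defaults,
fixed once: a 120-plant family genotyped before bulking, a 12-plant mutant
bulk and a 28-plant wild-type bulk, Poisson site depth with mean 30 (floor 1,
the standard shotgun assumption), symmetric per-read miscall probability
0.001, and 500 unlinked background induced variants. Plants are drawn without
replacement from their phenotype class, so each replicate's bulk composition
— and hence its true allele frequency — varies as it does in a real 28-plant
bulk. Background variants model homozygous sub-lineage differences: 40%
specific to the mutant bulk, 40% to the wild-type bulk, 20% shared (shared
ones vanish at subtraction by construction), with effect classes uniform
over missense, frameshift, synonymous, intron, intergenic, so 2/5 survive the
effect restriction. The 500-per-bulk order of magnitude mirrors the scale of
bulk-specific loci reported for gamma-ray libraries; the true density of such
libraries is not well constrained and this is an explicitly free parameter.

The simulator does **not** model linkage along chromosomes (every background
variant is unlinked), alignment artifacts, indel-realignment noise, or
coverage biases; passing the recovery property therefore shows the ranking
logic is sound under the assumed sampling model, not that real libraries are
free of linked passenger mutations — in real data the causal region carries
a block of linked candidates that IGV review and cosegregation testing must
separate.

Simulated spectrophotometer readings invert the pigment equations exactly
(2×2 linear solve plus a direct carotenoid back-calculation) before adding
Gaussian absorbance noise, so quantification round-trips are exact at zero
noise. Haplotype-matrix simulation plants allele tuples with stated carrier
counts plus unique singletons, guaranteeing the classifier can be checked
against its construction.

## Numerical and statistical choices

* `binom_consistency()` implements the two-sided minimum-likelihood rule
  (sum of pmf values not exceeding the observed one) with the conventional
  `1 + 1e-7` relative guard against floating-point ties; degenerate
  expectations (`p0` of 0 or 1) admit a single outcome and return 1 on it,
  0 elsewhere.
* `chi2_gof()` computes the Pearson statistic directly (ratio weights are
  normalised, so 1:3 and 0.25:0.75 agree) with no continuity correction by
  default — class counts in segregation tables are large — and optional
  Yates correction for two classes.
* `two_sample_t()` defaults to the pooled-variance Student form
  (`df = n_a + n_b - 2`), with Welch behind a flag; zero-pooled-variance
  inputs return `t = 0, p = 1` (equal means) or a flagged degenerate
  `p = 0`.
* Pigment concentrations are returned unclamped with a warning when noisy
  absorbances drive them negative, keeping simulation/quantification round
  trips exact. The extract volume is a required argument of the mg/L → mg/g
  conversion; no default is assumed.
* `diff_proteins()` trims the longest common prefix and suffix and compares
  the cores — exact for a single indel with local substitutions and fully
  deterministic; it is validated against hand-constructed pairs rather than
  a general aligner, and is not meant for multi-indel comparisons. A 10 bp
  deletion is classified as a frameshift (length not divisible by 3); note
  that a frameshift generally rewrites the entire downstream protein, so a
  reported small N-terminal change implies transcript-specific context
  (e.g. an alternative start) that coordinate-free CDS arithmetic cannot
  reconstruct.
* Missing haplotype calls are their own tuple symbol — never imputed — and
  haplotype labels (`Hap_1`, ...) are assigned by descending carrier count
  with lexicographic tie-breaks, so classification is invariant to row
  order.
* All simulators take explicit seeds, use one private RNG stream, and
  restore the caller's RNG state; identical seeds give byte-identical
  output.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run at the sizes the analyses are
stated for: 10,000 replicates for the depth-27 wild-type bulk read-count
simulation and for each type-I-error calibration (both tests land at the
nominal 5% within Monte-Carlo noise), 200 seeded end-to-end pipeline runs
for the causal-recovery property, 400 pooled replicates (aggregate depth
above 10,000 reads) for the 1/3 frequency-recovery check, and the full
`alt ≤ n ≤ 30` grid for the binomial-oracle equivalence.

## Known limitations

Variant calling itself (and annotation) is out of scope: the package consumes
VCFs with `AD` depths and SnpEff-style annotations. BCF input, genotype
re-calling, sliding-window SNP-index plots, haplotype network layout,
phasing and imputation are deliberately not provided. The subtraction step
assumes the two bulks were called against the same reference with consistent
normalisation of indel representation.
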