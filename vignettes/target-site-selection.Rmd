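---
title: "Detecting selection against microRNA target sites in maternal transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection against microRNA target sites in maternal transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miravoid)
```

## The question and the model

Before zygotic transcription starts, a *Drosophila* egg runs on maternally
deposited gene products, among them mature microRNAs. If those maternal
microRNAs are active, maternal protein-coding transcripts that should *not*
be silenced are under pressure to avoid carrying target sites for them.
`miravoid` implements a mutation model of microRNA target sites and the
population-genetic statistics that detect that pressure in a panel of
sequenced inbred lines.

The mutation model is deliberately minimal:

* A **target site** for a mature microRNA is the 3' UTR sixmer exactly
  complementary to its canonical seed, nucleotides 2–7 of the mature
  sequence (`extract_seed()`). One match type only; no wobble pairing, no
  7mer/8mer grades. A single site definition keeps the mutation model
  closed under single substitutions.
* Every target sixmer has exactly **18 one-nucleotide neighbors**
  (6 positions × 3 substitutions, `mutant_neighbors()`), which are by
  definition non-targets for that microRNA.
* A biallelic SNP whose two alleles turn one UTR window into a target and
  a neighbor, respectively, is a **polymorphic target site**. Its
  **target-allele frequency** *p* is the fraction of genotyped lines
  carrying the target allele (`classify_site()`, `build_site_table()`).

Selection leaves a footprint in the distribution of *p* across sites:
under neutrality a pair of alleles drifts to a characteristic equilibrium
shape; selection against the target allele shifts mass toward low *p*.
Because mutation bias and background selection also distort the shape, the
analysis never interprets the maternal distribution in isolation — it is
always compared against the empirical distribution at target sites in
zygotic transcripts, where maternal microRNAs have little or no influence.

## The statistics

For each seed (or seed family, since mature products sharing positions 2–7
target identical sites, `collapse_seed_families()`):

* **Target avoidance** = log2 of the ratio of maternal to zygotic site
  counts with *p* < 0.1. Positive values mean maternal transcripts are
  enriched for the non-target allele. **Target conservation** is the
  mirror statistic for *p* > 0.9. When exactly one of the two counts is
  zero, 0.5 is added to both and the result is flagged rather than
  silently dropped; when both are zero the statistic is `NA` and excluded
  from class summaries.
* A **one-sided Kolmogorov–Smirnov test** (`ks_left_shift()`) asks whether
  the maternal frequency distribution lies to the left of the zygotic one:
  D⁺ = sup [F̂~mat~ − F̂~zyg~], p = exp(−2 D⁺² mn/(m+n)), clamped to (0, 1].
  The asymptotic exponential form is used because the site counts involved
  are in the hundreds; with heavily tied discrete frequencies it is
  mildly conservative (measured type-I error ≈ 3.3% at α = 0.05 with 200
  sites per class), which is the safe direction for claiming selection.
  Ties are handled by evaluating the CDF difference only at the end of
  each tie group, exactly as `stats::ks.test()` does.
* Per-microRNA statistics are summarized by **egg abundance class**
  (`NULL` undetected, `LOW` < 0.1% of microRNA-mapped reads, `MID`
  0.1–1%, `HIGH` ≥ 1%; boundaries half-open upward) with unweighted means,
  SEMs and pairwise Welch t-tests (`summarize_by_class()`). Means are
  unweighted across microRNAs because the maternal/zygotic transcript
  sets, not the per-microRNA site counts, are the fixed frame of
  comparison.
* **Derived allele frequencies.** Sites whose outgroup base equals the
  non-target allele are polarized: the target allele is taken as derived
  and its frequency is the DAF (`polarize()`). The DAF distributions of
  maternal versus nonmaternal microRNA targets (in maternal transcripts)
  are compared with a two-sample KS test (`daf_compare()`), and the
  **singleton excess** — derived alleles seen in exactly one line — with a
  Pearson χ² test on the 2×2 table, 1 df, no continuity correction
  (`singleton_chisq()`). The singleton is defined on the *derived* allele
  count to stay inside the unfolded DAF frame. The outgroup table must be
  in the same sense orientation as the site table.
* **MZT enrichment.** For each seed family, transcripts destabilized
  across the maternal-to-zygotic transition among its targeted maternal
  transcripts are tested against the genome-wide unstable proportion
  (default 0.146) with an exact upper-tail binomial P(X ≥ k)
  (`binomial_enrichment()`), and Benjamini–Hochberg q-values across
  families (`fdr_qvalues()`; Storey's λ = 0.5 estimator is available
  behind a flag). "Targeted" means ≥ 1 sixmer occurrence; counting is per
  transcript.

## Coordinates, strands, degenerate inputs

Internally every interval is 0-based half-open; VCF positions are 1-based
and BED intervals 0-based at the file boundary. Minus-strand UTRs are
stored sense-oriented and SNP alleles are complemented on projection, so
classification happens entirely in sense space and a fully mirrored
dataset yields an identical site table. UTRs containing introns are
discarded (splicing would break the linear window model). Multiallelic
records and indels are skipped; missing genotypes leave both numerator and
denominator of *p*; sites genotyped in fewer than 20 lines (configurable)
are dropped — the source panels do not state a floor, and 10% of a
~200-line panel is a conservative default. When several windows around one
SNP qualify for the same seed, the leftmost is kept — an arbitrary but
deterministic, order-independent tie-break. Isoforms sharing a genomic
site collapse to one record per (chromosome, position, seed), maternal if
any carrying transcript is maternal. Inbred isogenic lines contribute one
allele each (the first genotype allele); this treats the panel as haploid,
which is how reference panels of inbred lines are normally consumed.
Neighbors that happen to be targets of a *different* microRNA remain valid
non-target alleles for the focal microRNA: the neighbor definition is
per-microRNA.

## What the synthetic generator emulates

`simulate_dataset()` builds a complete miniature study: mature microRNAs,
single-exon UTRs (half maternal, half on the minus strand, each on its own
chromosome), and planted biallelic SNPs whose alleles form target/neighbor
pairs. Target-allele counts are drawn from the stationary
diffusion/Poisson-random-field spectrum

f(x) ∝ (1 − e^(−2γ(1−x))) / ((1 − e^(−2γ)) · x · (1−x)),

discretized at x = i/n and reducing to the classical 1/i law at γ = 0,
with γ = 2Ns acting on the target allele; separate coefficients apply to
sites in maternal and zygotic transcripts. Defaults are 200 lines (the
scale of the reference panel), γ = 0 for both classes, a UTR GC content of
0.38 (typical for *Drosophila* 3' UTRs), and an unstable-transcript rate
of 0.146 (the genome-wide proportion used as the enrichment null).
Sampling from the equilibrium spectrum rather than forward-simulating
matches the equilibrium reasoning behind the frequency-shift statistics
and is fast at desk scale.

Modeling choices worth knowing about:

* The target allele is always the **derived** allele (ancestral state =
  non-target), so with a perfect outgroup, polarization recovers every
  planted site; a `mispolarization_rate` flips the emitted outgroup base.
  A consequence is that the *unpolarized* neutral target-frequency
  spectrum in the synthetic data follows the decreasing 1/i law; the
  textbook symmetric U-shape describes a neutral allele *pair* where
  either member may be derived, and tests construct that condition by
  symmetrizing (p ↦ 1−p with probability ½).
* Planted windows are kept ≥ 12 bp apart so no sixmer window spans two
  planted SNPs and the ground truth is unambiguous. The ground-truth site
  table is still computed by full enumeration of every planted SNP against
  every seed, so target/neighbor pairs that background sequence happens to
  create for a non-focal seed are part of the truth, not a discrepancy.
* No recombination, linkage, demography or background selection is
  modeled; in the real analysis the empirical zygotic baseline absorbs
  those forces, and the generator inherits that logic. Passing tests on
  synthetic data therefore demonstrate correctness of the bookkeeping and
  calibration of the statistics under the stated model — not robustness
  to demographic confounding in real panels.

## Calibration and problem sizes

The test suite and the acceptance script verify, at fixed problem sizes
chosen to make Monte-Carlo error small relative to the quantities checked:

* the neutral sampler against its 1/i law (χ² goodness of fit, 10⁵ draws);
* type-I error of the KS left-shift test with both classes neutral at 200
  sites per class — 20,000 replicates, which pins the rejection rate to
  ±0.4 percentage points;
* power: γ = −5 maternal vs neutral zygotic at 200 sites per class gives
  positive avoidance and KS p < 0.05 in ≥ 95% of 200 replicates (in
  practice ~100%);
* the exact binomial tail against direct pmf summation, and the χ² p
  against a 10⁵-draw label-permutation estimate. For a discrete 2×2
  permutation null the comparable permutation quantity is the **mid-p**
  estimate (P(stat > obs) + ½·P(stat = obs)); the plain "≥" permutation p
  exceeds the asymptotic χ² p by half a hypergeometric lattice step per
  tail, a gap that dwarfs Monte-Carlo error for tables with a few hundred
  entries. The comparison is run at a 2,000-sites-per-group table, where
  the mid-p lattice bias is a fraction of the Monte-Carlo standard error.

## A worked miniature analysis

```{r example, eval = FALSE}
cfg <- sim_config(n_lines = 200, gamma_maternal = -5, gamma_zygotic = 0,
                  n_mirs = 6, n_utrs = 60, utr_length = 600,
                  sites_per_class = 40, rng_seed = 1)
paths <- write_dataset(simulate_dataset(cfg), "sim_out")

res <- run_selection(list(
  utr_bed = paths[["utr_bed"]], genome_fasta = paths[["genome"]],
  maternal_labels = paths[["maternal_labels"]], vcf = paths[["vcf"]],
  mir_fasta = paths[["mir_fasta"]], mir_counts = paths[["mir_counts"]],
  outgroup = paths[["outgroup"]], out_dir = "sim_out/reports"
))
res$stats[, c("seed_target", "avoidance", "conservation", "ks_p")]
```

With selection against maternal target sites, avoidance values come out
positive and the per-seed KS p-values small, while rerunning with
`gamma_maternal = 0` centers avoidance on zero.

## Known limitations

* One match type (seed sixmer) means sites created or destroyed by
  non-seed pairing are invisible, as are wobble-mediated targets.
* Scanning is edge-complete: sixmers flush against UTR boundaries count.
* Read counts are consumed as given; multimapping weighting is upstream.
* The model treats sites independently: linked selection among nearby
  polymorphic sites is ignored.
* The one-sided KS p is asymptotic and mildly conservative under heavy
  ties; an exact variant would require a permutation scheme conditioned
  on the tie pattern and is not implemented.
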