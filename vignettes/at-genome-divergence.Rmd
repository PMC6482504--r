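---
title: "Base composition as a genome phenotype: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base composition as a genome phenotype: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Domesticated plant populations carry systematically more A and T alleles at
polymorphic sites than their wild relatives. This package treats that
observation as a measurable *genome phenotype*: for an accession with
genotype calls at a set of bi-allelic SNPs, resolve each non-missing call to
its base and compute

$$[\mathrm{AT}] = \frac{\#\{\text{carried alleles that are A or T}\}}
                      {\#\{\text{non-missing sites}\}}.$$

Because parity rule 2 (PR2) holds across SNP sites — within one strand
$[A] \approx [T]$ and $[G] \approx [C]$ — the single number $[\mathrm{AT}]
= [A] + [T]$ captures the strand-symmetric part of base composition, and
the wild-vs-domesticated contrast $\Delta[\mathrm{AT}] =
\overline{[\mathrm{AT}]}_{dom} - \overline{[\mathrm{AT}]}_{wild}$ is the
quantity every downstream stratification decomposes: by substitution type,
by genomic annotation (genic vs non-genic), by region (pericentromere, TE,
selective sweep, CG-methylation state) and along the chromosome in moving
windows.

Two further layers ask *why* the difference exists:

* **Motif enrichment.** Each SNP contributes a trinucleotide motif (its
  reference-strand flanking bases around the polymorphic site) crossed with
  its unordered substitution type: $16 \times 6 = 96$ classes. Observed
  class frequencies are compared with an empirical null in which, for every
  SNP, one position is resampled uniformly from its ±1 kb flank; the
  per-class 95th percentile over 100 such replicates is the threshold, and
  a motif is *enriched* when observed/threshold exceeds 1 and the observed
  frequency exceeds 1/96. The four classes C[C/T]G, T[C/T]G, C[A/G]G and
  C[A/G]A — two reverse-complement pairs — constitute the solar-UV
  signature: UV-induced cyclobutane pyrimidine dimers cause C→T transitions
  preferentially at 5'-Py-mCG-3' sites, more so when the cytosine is
  methylated.
* **Private-variant spectra.** SNPs segregating in exactly one population
  while all others are fixed for the ancestral allele (PW, PD, PL, PI for
  wild, domesticated, landrace, improved) are recent mutations on that
  lineage. After polarizing with an outgroup allele, each is typed as
  ancestral→derived with both flanking bases, strand-collapsed so the
  ancestral base is a pyrimidine (96 classes, e.g. TCG>TTG). Spectra of two
  sets are compared per class with the Pearson $\chi^2$ on the 2×2
  count table (no continuity correction) and the fold frequency difference
  $(f_1 - f_2)/f_2$. Raw $\chi^2$ values are reported rather than p-values
  because interesting classes reach values where the p-value underflows.

A final layer connects the phenotype back to genes: given per-SNP
association p-values for $[\mathrm{AT}]$, SNPs passing the Bonferroni
threshold define windows; a gene *tagged* by ≥ 2 significant SNPs is
counted, and a one-sided pooled two-proportion z-test asks whether
UV-damage-repair genes are tagged more often than annotated genes at large.
The mixed-model scan itself is out of scope — association p-values are an
input; a plain single-marker scan (`naive_scan()`) is included only so the
pipeline runs end-to-end on synthetic data.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `maf_min`, `missing_max` | 0.05 / 0.20 | fraction | the common-panel filter; both boundaries inclusive-keep |
| window / step | 5 Mb / 4 Mb | bp | moving-average $[\mathrm{AT}]$ track (scaled to 0.5 Mb / 0.4 Mb on the 10-Mb synthetic genome) |
| `min_snps` | 100 | SNPs | windows below this are emitted masked, not dropped |
| gene-proximal distance | 5,000 | bp | upstream (5', strand-aware) of the TSS only |
| pericentromere flank | 40 Mb | bp | centromere ± flank, clipped; pre-computed coordinates may be supplied instead |
| methylation cutoff | 40 | % mCG per 100-bp window | strictly greater than; windows without CG count as unmethylated |
| motif null | 100 reps, ±1 kb | — | per-class 95th percentile; one random site per SNP per replicate |
| `min_call_rate` | 0.8 | fraction | call-rate floor for the "fixed ancestral" check in private-set calling |
| tagging rule | ≥ 2 SNPs, window = total width centred on SNP | — | a gene overlapping the windows of ≥ 2 significant SNPs is counted |
| proportion-test floor | 10 tagged UV genes | — | below it the test result is flagged invalid and no p-value is reported |

## The synthetic study

The generator (`sim_config()` + `simulate_genome()` +
`simulate_common_panel()` + `simulate_private_sets()`) emulates the
*statistical* structure the analyses consume, not population history. The
default study is two 5-Mb chromosomes, 50 accessions per group, 50,000
common SNPs and 20,000 SNPs per private set.

* **Genome and annotation.** I.i.d. sequence at GC 0.47; non-overlapping
  coding gene models (~10% inside the pericentromere, mirroring its low
  gene density); TE intervals concentrated (~70% of the budget) in the
  pericentromere; mCG per 100-bp window elevated inside pericentromere and
  TEs (0.85 vs 0.25 probability of a methylated window); recombination-rate
  windows drawn from disjoint ranges so the pericentromere is strictly
  colder.
* **Common panel.** Sites take group-specific frequencies for their A/T
  allele. At sites where exactly one allele is A/T, the domesticated groups
  get a frequency shift; its genome-wide average is calibrated so the mean
  planted contrast equals `delta_at` (default 0.034, the magnitude of the
  maize wild-vs-landrace difference), with the shift doubled in the
  pericentromere and halved in genic sequence (region multipliers are
  renormalised so the overall mean stays at `delta_at`). Substitution types
  are drawn conditionally on the reference base so A/G and C/T transitions
  each land at ~34%. Every emitted site is guaranteed to pass the
  MAF ≥ 0.05 / missing ≤ 0.20 filter (the guarantee is waived when
  `missing_rate` is configured above the filterable range, e.g. in
  missing-data experiments).
* **Private sets.** Each SNP's ancestral allele is the genome base; the
  focal group segregates for the derived allele while other groups are
  fixed ancestral with call rate ≥ 0.8 — enforced per site, so
  `call_private()` provably recovers every planted SNP. A fraction
  `uv_base_rate` (default 0.08) of mutations are planted UV events: C→T at
  PyCG contexts (on either strand), placed in methylated 100-bp windows
  with probability 0.8; domesticated-private sets get `uv_enrichment`
  (default 1.5) times that rate. The baseline rate was chosen once so that,
  at the 1.5-fold enrichment and 20,000 SNPs per set, the TCG>TTG class is
  a clear $\chi^2$ outlier while UV events remain a small minority of all
  mutations; the remainder are background mutations with a 68% transition
  share.

What the generator does **not** emulate — and what passing tests therefore
do not certify on real data: linkage disequilibrium and haplotype
structure, demography and drift, selection at linked sites, ascertainment
bias of SNP discovery, sequencing error, non-uniform local base
composition (isochores), and outgroup misalignment beyond a simple
misassignment rate. Recovery results on synthetic data validate the
*estimators*, not the biology.

## Numerical and design choices

* **Coordinates.** VCF/GFF3 are 1-based inclusive; BED and all internal
  interval math 0-based half-open; a SNP at position $p$ is inside
  $[s, e)$ iff $p - 1 \in [s, e)$.
* **Heterozygous calls are set to missing.** Both motivating panels are
  inbred lines; the $[\mathrm{AT}]$ definition counts one nucleotide per
  accession per site. Multi-allelic records are dropped, never split.
* **One canonical transcript per gene** (longest CDS, ties to the
  lexicographically smallest id). A SNP covered by several genes takes the
  highest-severity label (missense > other_genic > synonymous > UTR >
  intronic); `other_genic` absorbs stop gain/loss, start loss, splice
  sites (first/last 2 bp of an intron) and phase-trimmed coding edges.
  Genes whose phase-adjusted CDS length is not a multiple of 3 are flagged
  and classified by exon/intron structure only.
* **Gene-proximal attaches upstream only**, and genic takes precedence
  over gene-proximal for SNPs upstream of one gene but inside another.
* **Motif null.** The random site keeps the SNP's substitution type and
  contributes its own flanks, making the null a pure local-sequence-
  composition null — the only reading under which per-motif SNP-site and
  random-site frequencies are comparable. One draw per SNP per replicate;
  other SNP positions are not excluded from the flank. A zero null
  threshold yields an infinite ratio; enrichment then still requires an
  observed frequency above 1/96. Percentiles use R's default (type 7)
  quantile.
* **Private-set definitions are applied independently.** PD (segregating
  in landrace *or* improved, wild fixed ancestral) is not the union of PL
  and PI: a SNP segregating in both domesticated groups is PD only, while
  PL/PI members typically also satisfy PD; the three-way overlap is
  reported. Sites where any group is entirely missing are unassignable.
* **Group separation** uses Welch's unequal-variance t by default
  (rank-based alternative available); the separation itself, not the exact
  p-value, is the reproducible quantity.
* **Rate correlations** use non-overlapping window tiles so window pairs
  are independent; overlapping tiles would shift r slightly.
* **Windows for gene tagging** have total width `window_size` centred on
  the SNP ("within the window" = any overlap of the gene body).
* **Degenerate inputs.** Accessions with zero non-missing calls,
  substitution types with zero sites, empty strata and windows with too
  few SNPs are flagged, not silently dropped; an all-sites-removed filter
  result warns and returns an empty panel.

## Problem sizes

The shipped analysis scripts and the test suite run the full pipeline at a
10-Mb genome, 150 accessions, 50,000 common SNPs and 4 × 20,000 private
SNPs; calibration properties use 10–50 replicate seeds (e.g. the
SNP-site/random-site motif ratio is averaged over 10 seeds × 20,000 SNPs,
and UV-signature detection power over 20 seeds). These sizes give
recovery of the planted $\Delta[\mathrm{AT}] = 0.034$ to within ±0.005 and
detection of the 1.5-fold UV excess with $\chi^2 \approx 50$, while the
whole suite stays desk-scale.

## Limitations

* The single-marker scan ignores structure and kinship; with the planted
  frequency shifts, population stratification *is* the signal, so its
  p-values on synthetic data are a mechanical demonstration only.
* $\chi^2$ spectrum comparisons treat sets as independent samples;
  overlapping sets (PL ⊂ PD) should not be compared against each other.
* Strand-collapsed mutation classes assume no strand asymmetry of
  mutation; the motif layer, which reads flanks from the reference strand
  without collapsing, is the place where asymmetry would surface.
* The UV-gene list is an input; nothing in the package curates repair
  pathways.

## A worked run

```{r, eval = FALSE}
library(atgenome)
cfg <- sim_config(seed = 1)
sim <- simulate_genome(cfg)
panel <- simulate_common_panel(cfg, sim)
at <- compute_at(panel$geno, panel$snps)
group_separation(at$at, panel$groups)

priv <- simulate_private_sets(cfg, sim)
cmp <- compare_spectra(mutation_spectrum96(priv$PL$snps, sim$genome),
                       mutation_spectrum96(priv$PW$snps, sim$genome))
head(cmp[order(-cmp$chisq), ])
```

The numbered scripts under `analysis/` run the same steps against files on
disk (VCF/FASTA/GFF3/BED/TSV) and write summary tables under `results/`.
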