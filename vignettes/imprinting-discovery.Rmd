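---
title: "Methods: discovering imprinted loci from phased methylation, allelic expression and duos"
author: "imprintscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering imprinted loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

# The inference chain

Imprinted genes are expressed from one parental allele because an imprint
control region (ICR) carries parent-specific DNA methylation that
silences the other allele in *cis*. In an outbred cohort without sampled
fathers, `imprintscan` assembles four independent lines of evidence and
requires them to converge:

1. within one deeply sequenced individual, the two haplotypes differ in
   methylation at a locus (allele-specific methylation, ASM);
2. heterozygous SNPs near that locus show monoallelic RNA expression
   across tissues;
3. in mother–offspring duos where the mother is homozygous, the expressed
   allele of a heterozygous offspring has a determinable parent; and
4. in the germline, the locus behaves like an ICR: ~50% methylated in
   soma (one allele), erased in primordial germ cells (PGCs), and either
   absent from or complete in sperm depending on which parent carries the
   mark.

The package's claim is conditional, not absolute: a gene is called
imprinted only when duo evidence is unanimous, and the
heterozygote-deficiency test and germline screen are attached as support,
never as gates.

# Phasing and ASM

## Read-backed phasing

Heterozygous SNPs are phased from the long reads themselves. Adjacent
SNPs co-covered by at least `min_link_reads = 2` reads share a phase
block; single-read linkage is not trusted because one chimeric or
misassigned read would silently join unrelated blocks. Within a block the
orientation is built greedily left-to-right by majority linkage between
neighbouring SNPs, then refined by coordinate descent on the
minimum-error-correction (MEC) objective — alternately assigning each
read to its closer haplotype and re-orienting each SNP by majority — and
finally by a switch-move scan (flip the suffix at each position) that
escapes the characteristic local optimum of phasing, the switch error.
The switch scan runs on blocks of at most 300 SNPs; longer blocks at
realistic depth do not produce switch errors that coordinate descent
cannot fix, and the scan is quadratic in block length. On random blocks
of up to 12 SNPs the result is verified against exhaustive enumeration of
all `2^(n-1)` orientations; the test suite requires exact agreement of
the MEC cost.

Haplotype labels are arbitrary per block, so they are canonicalised
(hap1 carries the reference allele at the block's first SNP) and —
crucially — per-CpG methylation tallies never mix reads across blocks:
at a block boundary the block contributing more reads at that CpG wins.
Parental identity is *not* claimed at this stage; it only becomes
available later, from duos.

## Calling ASM sites

Each CpG with at least `min_depth_per_hap = 5` assigned reads on both
haplotypes is tested with a conditional exact test on the 2×2 table
(methylated/unmethylated × haplotype) at `alpha = 0.01`. No
multiple-testing correction is applied per CpG: the false-positive
control is regional, exactly as in region-level methylation callers — a
spurious CpG is harmless unless twenty of them cluster. Differential
CpGs are clustered by single linkage with gap ≤ 5 kb (CpG-island scale:
keeps one island together without bridging distinct loci), and a cluster
becomes an ASM site iff it holds ≥ 20 differential CpGs with ≥ 90%
direction agreement. The 20-CpG filter is interpreted as differential
CpGs per clustered site (ASM sites are multi-CpG regions); the
direction-consistency requirement discards clusters whose sign flips
midway, which is the signature of a phase-switch artefact rather than
biology. Sites are annotated with the nearest gene within ±20 kb of the
site midpoint, ties broken to the lexicographically smaller gene id so
annotation is reproducible.

# Monoallelic expression

Per-SNP allelic counts are tested only at sites where the screened
sample is DNA-heterozygous (a homozygote's one-sided counts carry no
allelic information). The observed `(ref, alt)` counts are compared with
the expected 1:1 counts `(⌈d/2⌉, ⌊d/2⌋)` by a two-sided Fisher exact
test; odd depths split the expectation deterministically. This
observed-vs-expected construction is unusual — an exact binomial test
against 0.5 is the textbook alternative and is available via
`method = "binomial"` — but it is retained as the primary method because
it is the analysis the evidence chain was designed around, and at the
effect sizes of interest (minor fraction 0 vs 0.5) the two agree on
every verdict. Depth < 10 is reported as `underpowered`, never as
biallelic.

Bonferroni correction uses the family of all depth-qualified SNPs per
sample × tissue screen. Each tissue of each individual is one screen:
this matches a design where one reference animal's tissues are screened
separately, and it is also the choice that keeps per-SNP power at
moderate RNA depth (a pooled family across 40 individuals would demand
p below ~1e-6, unreachable at 30× except for perfect monoallelic
counts). A flag (`by =`) pools tissues or samples for sensitivity
analysis.

Significant SNPs are kept only within ±1 Mb of an ASM site midpoint —
imprinted expression without a nearby methylation asymmetry is treated
as unexplained. The gene screen then applies the biallelic-exclusion
rule: per sample, per-SNP counts pooled across that sample's tissues;
any SNP reaching depth ≥ 10 with minor fraction ≥ 0.2 contradicts the
gene *in that sample*. A gene survives iff at least one sample both
supplies a linked monoallelic SNP and shows no contradiction. Pooling
within (never across) individuals matters: the expressed parental allele
is `ref` in some individuals and `alt` in others, so cross-individual
pooling would average a perfectly imprinted gene to 50/50 and destroy
the signal.

# Parent of origin

A duo is informative iff the mother is homozygous and the offspring
heterozygous; the offspring's expressed allele is then maternal or
paternal by elimination. Genotype combinations sharing no allele are
flagged `inconsistent` (a pedigree-error signal) rather than silently
dropped. A gene needs `min_duos = 2` agreeing informative duos for a
parental call; a single duo is reported as provisional, never as
confirmed. Any disagreement yields `conflicting` — the package does not
vote between duos, because a single genuine discordant duo falsifies
strict imprinting.

The population-level support statistic is an exact one-sided
heterozygote-deficiency test conditional on allele counts,

$$P(n_{AB}) = \frac{N!}{n_{AA}!\,n_{AB}!\,n_{BB}!}\;
2^{n_{AB}}\;\frac{n_A!\,n_B!}{(2N)!},$$

summed over configurations with at most the observed heterozygote count.
It is applied to *expressed* genotypes: under imprinting every individual
appears homozygous in RNA, so expressed heterozygotes are deficient
relative to Hardy–Weinberg even though DNA genotypes are not. It is
reported as evidence, not used as a gate, because selection and
population structure also violate Hardy–Weinberg.

# Germline reprogramming

Global methylation of a bisulfite library is the proportion of
methylated CG calls; conversion efficiency is estimated from residual
non-CpG methylation (`100 − non-CG%`). Libraries with < 400 CG calls or
< 35% mapping efficiency fail QC. PGC libraries are grouped `pre`
(< 10 dpp), `demethylated` (13–16 dpp) and `remethylated` (> 16 dpp);
ages in the 10–13 dpp gap, which the bands do not tile, are surfaced as
`unclassified` rather than assigned — group membership is by age rule,
never by methylation value, to avoid circular stage definitions. Stage
contrasts use Welch's unequal-variance t-test.

ASM sites are screened for ICR behaviour on three thresholds: somatic
methylation within 30–57% (inclusive on both ends — the boundary
convention is stated because the band's source leaves it open), sperm
≤ 20% ⇒ maternal ICR, sperm ≥ 80% ⇒ paternal ICR. The sperm thresholds
interpolate between the observed extremes of known germline ICRs
(~1–2% erased vs ~94–96% complete) and are exposed as arguments.
Uncovered sites get missing values, never zeros — an unmeasured site is
not an unmethylated site.

# Cohort metrics

Variant filtering keeps records with quality ≥ 30, mean depth ≥ 10 and
≤ 5% missing calls (all inclusive). sMLH divides a sample's heterozygous
locus count by the sum of across-sample heterozygote frequencies over the
loci typed in that sample; with complete data the cohort mean is exactly
1, an identity the tests assert. Group comparison uses the Wilcoxon
rank-sum test (exact for combined n ≤ 20 without ties, normal
approximation with continuity correction otherwise); the test choice is
a package decision, made for robustness at small group sizes, since no
canonical test attaches to this comparison. The weaning screen uses
log2 RPKM (`count·1e9 / (length·library size)`, pseudocount 1 read), a
galactase-minus-CYP mean difference as the signature ratio (a log-scale
ratio; high = pre-weaning), and Spearman correlation for the
genome-wide screen so the ranking is invariant to the expression
transform; Pearson is available by flag. Gene-set membership is
user-supplied input.

# The synthetic cohort generator

The generator is first-class, tested code and defines the study
conditions under which the pipeline's guarantees are stated.

What it emulates, with defaults and units:

* **Genome**: 2 chromosomes × 1.5 Mb; 500 genes of 1.5 kb on jittered
  non-overlapping slots, each with a 1.2 kb promoter CpG island of 60
  CpGs (5 CpGs/100 bp, the dinucleotide density that defines CpG
  islands); background CpGs at 8/kb. Genes keep one read length clear of
  chromosome ends, where uniformly placed reads cannot reach full
  coverage.
* **Variation**: panel SNPs at 7/kb with allele frequencies uniform on
  (0.2, 0.8), giving ~3.4 heterozygous SNPs per kb per individual —
  matching the ~0.35% heterozygosity of a highly admixed reference
  animal. At least 2 exonic SNPs per gene are guaranteed so expressed
  genes are testable.
* **Cohort**: 40 individuals; 50% have their mother in the cohort.
  Founders draw haplotypes from the panel frequencies; a child inherits
  one complete maternal chromosome haplotype (no recombination — duo
  inference uses single SNPs, so within-chromosome recombination would
  not change any result) and a population paternal haplotype.
* **Imprinting truth**: 10 ICRs (the islands of 10 sampled genes, kept
  ≥ 25 kb apart — closer imprinted genes share one ICR in real genomes,
  which the truth model represents as a single ICR); 70% maternally
  methylated; the expressed parent is always the opposite of the
  methylated parent. 20% of imprinted genes are leaky with minor-allele
  expression fraction 0.15, deliberately below the 0.2
  detection/exclusion threshold: leaky genes are detectable as
  monoallelic yet must not be discarded as biallelic.
* **Reads**: 30× coverage, 8 kb reads, haplotype of origin fair-coin;
  SNP allele flipped with probability 0.01, per-CpG state flipped with
  probability 0.01. Methylation is Bernoulli per CpG per haplotype
  around a regional mean with no spatial autocorrelation — the simplest
  model that exercises the downstream tests; ICR levels are 1/0 so that
  with zero call error the parental states are deterministic and every
  noise path flows through the error knob.
* **RNA**: three tissues as i.i.d. replicates of the same allelic
  regime; per-SNP depth Poisson(30).
* **Germline**: 16 PGC libraries (7–106 dpp) with stage means 0.697 /
  0.411 / 0.65, matched soma (0.70) and sperm (0.65); ~20k CG calls per
  library; non-CpG methylation 1%. Deep per-CpG calls over ICRs for two
  PGC, two soma and the sperm libraries: soma at the allelic average,
  PGCs at 0.12 erasure residue, sperm at the paternal allele's state.

What it does **not** emulate — and what passing tests therefore do not
show about real data: mapping and reference bias, spatially correlated
methylation and partially methylated domains, recombination,
tissue-specific or polymorphic imprinting, X inactivation, sequencing
quality variation, and genotyping error in the DNA genotypes (the duo
logic consumes true genotypes; with array or exome genotypes the
`inconsistent` rate becomes informative). Every RNG stream is sub-seeded
from the master seed by label (`subseed(seed, "reads")` etc.), so adding
an output never perturbs the others and identical configurations are
byte-identical.

# Numerical and testing choices

Exact p-values (Fisher 2×2, Hardy–Weinberg) are computed in log-factorial
space and compared in the suite against independent enumeration oracles
written by a different route (`lchoose` sums; a sequential allele-pairing
recursion; exhaustive `2^(n-1)` phasings), to 1e-9 and 1e-12. The
two-sided Fisher tail uses the standard `p ≤ p_obs·(1+1e-7)` guard
against floating-point equality. Ties are deterministic everywhere:
hap1 carries ref at a block's first SNP, equidistant genes resolve
lexicographically, tied votes mean unassigned, an exactly balanced count
reports `ref` as the majority allele with minor fraction 0.5.

Validation problem sizes, chosen as the package's own test conditions:
the end-to-end recovery runs 20 seeded default cohorts (40 individuals,
500 genes, 10 ICRs, 30×); ASM accuracy runs 20 single-chromosome cohorts
at nominal 20× with 5% call error, with recall measured over ICRs whose
achieved coverage meets the 20× condition (fold coverage is a per-locus
random variable; an island that happened to draw 16 reads is not at
20×); the germline/expression concordance runs 20 noise-free cohorts;
calibration uses 10,000 null SNPs at depth 50 and 100 replicate screens.

# Known limitations

* The biallelic-exclusion rule keys on a fixed 0.2 minor fraction;
  strongly leaky imprinting (minor fraction near 0.2) will be excluded
  in deep samples and missed.
* Phase blocks end at heterozygosity deserts longer than the read
  length; ASM inside such a desert is undetectable by design, and in
  low-heterozygosity genomes this is the binding constraint on recall.
* The duo logic supports mother–offspring pairs only; trios and
  paternal-line pedigrees are out of scope.
* The HWE support statistic assumes independent sampled individuals;
  duo structure within the cohort mildly violates this, which is one
  more reason it is never used as a gate.
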