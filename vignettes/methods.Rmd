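---
title: "Detecting and dating a sex chromosome turnover: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating a sex chromosome turnover: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xyturnover)
```

## The problem

When a lineage replaces its ancestral sex chromosome pair with a new one,
three independent genomic signatures appear.  First, the old X becomes
indistinguishable from an autosome: males and females show the same read
depth and balanced expression over it.  Second, a previously autosomal
chromosome pair starts behaving like an XY pair: males show half the
female read depth over the X-specific region (one X versus two), except in
pseudoautosomal segments (PAR) that still recombine, and male-limited
(Y-derived) transcripts appear that have no counterpart in the female
genome.  Third, the X and Y copies of genes caught on the non-recombining
region — gametologues — diverge from the moment recombination stopped, so
their synonymous divergence (dS) dates the arrest, and blocks of genes
that stopped recombining together form strata of similar age.

`xyturnover` implements the full analysis chain for this situation —
coverage-based sex-linkage detection, k-mer subtraction discovery of
Y-specific transcripts, dS-based strata assignment and calibrated dating,
and dosage-compensation statistics — together with a synthetic-data
generator that produces inputs with known ground truth, so that every
stage can be scored for parameter recovery rather than merely exercised.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_genome_pair()`,
`simulate_reads()`, `simulate_gametologues()` and `simulate_expression()`
are pure functions of the configuration and a seed.

**Genome.**  The female genome is two autosomes plus an X; the male genome
shares the autosomes and X and adds a Y.  The default X (500 kb) carries
two PAR segments (60 kb and 60 kb at the ends) and two strata
(recombination arrest 62 and 20 Ma).  Within the PAR the Y is copied
verbatim from the X — the recombining proxy.  Elsewhere the Y is an
independently decayed copy: point substitutions at the neutral rate
(`2 * syn_rate * arrest_time` expected substitutions per site, applied at
the Jukes–Cantor observed-difference probability), small insertions and
deletions at `y_indel_rate` (default 0.001 per site per Myr, tracts of
1–8 nt), and outright deletion of the gene bodies that are not retained
(`y_gene_retention` per stratum, default 20% and 15%).

The indel component deserves a comment because it is the one place where
the generator deliberately goes beyond a pure substitution model.  A
non-recombining Y accumulates structural change — indels, repeat
expansions, rearrangements — much faster than point substitutions alone
would suggest, and after tens of Myr its male-specific sequence is largely
unalignable to the X.  Without that structural component, a young
stratum's retained Y genes (arrest 20 Ma, roughly 8% nucleotide
divergence) would still align to the female X copy at ~92% identity and
could never be called "absent from the female genome", contradicting the
empirical observation that even low-dS gametologues are recovered as
genome-level male-specific.  With it, both strata's retained Y copies are
genuinely male-specific at the sequence level, and the ground truth
`y_transcript_ids` is simply the set of retained Y gene copies.

**Reads.**  `simulate_reads()` draws uniform reads (default 100 nt) with
placeholder qualities and no errors by default — the downstream filters
assume near-exact matching, and an error-rate knob exists for sensitivity
checks.  An individual's total depth is split evenly over its two
haplotypes (`simulate_sex_reads()`), so a 6x female yields 6x autosomes
and 6x X, while a 6x male yields 6x autosomes, 3x X-specific region, and
6x PAR (X copy plus identical Y copy).  RNA-seq reads are strand-specific
(sense strand only) and shred the transcript set — transcripts equal gene
bodies; no splicing is modelled.

**Gametologue alignments.**  Codon sequences evolve along a fixed
time-calibrated species tree (eight taxa; the focal split from the anole
lineage at 85.7 Ma, *Xenopus* rooting the tree at 352 Ma).  The mutation
model is codon-level Jukes–Cantor with separate synonymous and
nonsynonymous acceptance: synonymous events arrive at `syn_rate` (default
0.002 per synonymous site per Myr — chosen so the older stratum's expected
dS of 0.25 matches the magnitude of published corytophanid values) and
pick uniformly among synonymous single-nucleotide neighbours; mutations
creating stop codons are never proposed.  The X and Y tips duplicate at
the stratum's arrest time, so E[dS(X,Y)] = 2 x `syn_rate` x arrest.  This
is the simplest model whose dS expectation is closed-form; measured bias
of the estimator against that expectation is below 1% up to dS = 0.5.

**Expression.**  Per-gene baseline diploid means are log-normal
(median 30 TPM, sdlog 1); observed TPM multiplies the expected mean by
log-normal noise with sigma `tpm_dispersion` (default 0.5 on the natural
log — dispersion typical of between-sample variation in bulk RNA-seq; the
generator models no count noise, batch structure, or mean–variance
trend).  Females express two alleles everywhere.  The single male X allele
in the hemizygous region is scaled by the tissue's dosage factor: full
compensation 2, none 1, partial *c* in (1, 2); the default is partial with
c = 1.5, the intermediate regime the analyses are designed to resolve.
Genes with a retained Y copy express both alleles at the per-allele level
without upregulation, so male X+Y output balances the female X output.

## Coverage analysis

Reads are mapped back to the female-assembled reference by full-length
exact matching on both strands (`map_reads_exact()`); this stands in for a
short-read aligner and is exact for error-free simulated reads — real data
would substitute an external aligner behind the same hit-table interface.
Depth is averaged in 100 kb windows on autosomes and 10 kb windows on the
candidate X (`coverage_scan()`), and each window is classified from
log2(male/female): within ±0.25 of −1 is hemizygous (`X_HEMI`), within
±0.25 of 0 is `AUTOSOMAL` (or `PAR` on the candidate X), anything else is
`UNASSIGNED`, and windows below 1x in either sex are `NO_DATA`.  The ±0.25
band was chosen once from the noise model: Poisson depth at 6x over 10 kb
windows gives a log-ratio standard deviation of about 0.12, so the band
misclassifies well under 1% of windows while cleanly separating the
half-coverage signature.  No GC-bias correction, mappability masking, or
CNV logic is attempted.

Scaffold selection against a reference genome (`select_scaffolds()`)
retains scaffolds aligning over 50% of their length at above 80% identity
for a close reference (the `anolis` preset) or over 40% at above 70% for a
distant one (`chicken`), and orders them along the reference.  The
built-in aligner is exact 31-mer seeding with ungapped X-drop extension;
its identity estimates are exact on substitution-only divergence and it
deliberately fragments across indels — which is precisely the behaviour
the male-specificity validation relies on.

## Subtraction discovery of Y transcripts

The pipeline follows the classic sex-specific read subtraction: (1) drop
reads with ambiguous bases; (2) keep male RNA-seq reads that do not map to
the female genome (full-length exact matching); (3) build the abundant
k-mer signature of the female transcriptome — 35-mers at frequency >= 10,
rarer k-mers being noise rather than signature — and discard any surviving
read sharing one indexed k-mer exactly, in either orientation (the
libraries are strand-specific, the genome is not, so screening both
orientations is the conservative choice); (4) assemble the few survivors
with a deterministic greedy overlap assembler (longest exact
suffix–prefix overlap first, ties broken lexicographically, contained
reads absorbed — a desk-scale replacement for a de novo assembler, which
would be overkill for a few hundred reads); (5) validate each contig:
accepted iff 100% identity over >= 90% of its length in the male genome
and no female hit at >= 80% identity over >= 50% of the contig.  The
female-hit thresholds operationalise "no significant alignment", which
has no standard numeric definition; both are arguments.  Running the
same pipeline with the sexes swapped is the W-chromosome control: on an
XY system it must accept nothing, because every female sequence is
present in the male genome.

The k-mer frequency cutoff is applied over the pooled opposite-sex read
set (per-library application would be stricter); coding-potential
classification of accepted transcripts is out of scope.

## Strata and dating

`pairwise_ds()` implements Nei–Gojobori counting: per-codon synonymous
site fractions averaged over the two sequences, per-codon-pair difference
counts averaged over all mutational pathways that avoid stop-codon
intermediates, and a Jukes–Cantor correction
dS = −(3/4) log(1 − 4 pS / 3), with an explicit saturation error at
pS >= 0.75.  Ambiguous or gap codons are excluded pairwise.  This is a
deliberate, documented stand-in for maximum-likelihood pairwise dS; the
discrepancies grow with divergence but the strata decisions hinge on a
0.2 threshold, not third-decimal precision.  The implementation is tested
codon-by-codon against an independent enumeration oracle.

`classify_stratum()` makes outgroup presence authoritative: a Y copy
detected in the second corytophanid clade predates that species split
(stratum 1); absence places the gene in stratum 2; the dS threshold 0.2
only decides when presence evidence is missing.

Dating proceeds as: concatenate stratum-1 alignments; resample codon
columns with replacement to the original length, 100 rounds (codon-wise
rather than nucleotide-wise, because nucleotide resampling would destroy
the reading frame dS needs); for each replicate compute the pairwise dS
matrix and fit non-negative least-squares branch lengths on the fixed
species topology (`phangorn::nnls.tree`); average the replicate branch
lengths, make the tree ultrametric with a mean-path-length clock (each
node's age is the mean path length to its descendant tips, clamped for
parent/child monotonicity), anchor the focal/anole split at the published
calibration age, and read off the X/Y split age.  The 95% CI is the
2.5th/97.5th percentile of the age over the 100 replicates.  The strict
clock is a modelling choice replacing penalized-likelihood rate smoothing;
on clock-like simulated data it is exact, and `rescale_age()` exposes the
exact linearity of ages in the calibration (61.05 Ma under an 85.7 Ma
calibration is 62.69 Ma under 88 Ma).

## Dosage compensation

`median_scale_normalize()` rescales every sample so the median TPM of a
shared always-expressed orthologue set equals the grand median of those
medians — idempotent by construction.  Ancestral (proto-sex-chromosome)
per-allele expression is the median of autosomal outgroup orthologue
values divided by two.  Male/female log2 ratios of X genes (0.1 TPM
pseudocount per side; genes under 1 TPM in both sexes excluded as an
expression floor) are tested per tissue against fixed medians 0 and −1
with a one-sample Wilcoxon signed-rank test — the published "rank test
against a distribution with fixed median" is degenerate as a literal
two-sample test against a constant, so the one-sample form is the
operational reading — and Benjamini–Hochberg correction is applied across
the whole tissue-by-reference family.  The per-tissue call is
`INTERMEDIATE` iff both references are rejected at 0.05, `BALANCED` when
only −1 is rejected, `UNCOMPENSATED` when only 0 is, `INCONCLUSIVE`
otherwise.

A dataset-level consensus is reported as the modal tissue call.  This is
deliberate: each true-null reference test still rejects at the nominal 5%
rate, so with several tissues a single-tissue miscall is expected
occasionally even under a clean regime; the modal call across six tissues
is the robust dataset-level summary, the same way the published analyses
read the compensation state off the pattern across tissues rather than
any single one.

`gametologue_balance()` is log2((X_male + Y_male + p)/(X_female + p)) with
the pseudocount added once per side, and `tsi()` is max/sum over tissues
(1/T for uniform expression, 1 for single-tissue; 0.7 is the conventional
specificity threshold).

## Problem sizes and what passing does not show

The packaged study conditions are desk-scale by design: 1 Mb haploid
genome (two 250 kb autosomes, 500 kb X), 40 genes of 300 codons per
chromosome, 6x depth per sex, 30x transcript coverage, 100 bootstrap
rounds, 500 X genes and six tissues per expression dataset, and 20
repetitions for the dating-coverage experiment.  These sizes make the
whole chain — and its acceptance checks — reproducible in minutes while
keeping every per-window, per-read and per-codon computation identical to
what larger inputs would use.

The generator emulates the statistical structure the analyses assume, not
real data: no sequencing error, GC or mappability structure in reads; no
splicing, paralogy, or incomplete assembly; clock-like rates with no
lineage effects; independent log-normal expression noise.  Passing the
recovery tests therefore shows the implementation is correct and
internally consistent under the stated model — it does not show the
thresholds would be optimal on real short-read data, where aligner
sensitivity, assembly gaps, and count noise dominate the error budget.
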