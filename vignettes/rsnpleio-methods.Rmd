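---
title: "Methods: regulatory-SNP pleiotropy from multi-omics data"
author: "rsnpleio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-SNP pleiotropy from multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`rsnpleio` implements a four-phase analysis for discovering *pleiotropic
regulatory SNPs* (rSNPs) in panels of inbred lines — variants in gene
promoters whose alleles create or destroy predicted transcription factor
binding sites (TFBSs) and that are associated with two or more
quantitative phenotypes. The four phases are:

1. **rSNP identification.** Promoter SNPs are scanned allele by allele
   against a position weight matrix (PWM) library; each (SNP, TF) pair is
   classified as *Gain*, *Loss*, or *NoStrongEffect*.
2. **Phenotype association.** For each phenotype, rSNPs are ranked by a
   shadow-feature (Boruta-style) wrapper around random-forest regression,
   and the optimal number of top-ranked rSNPs is chosen by incremental
   feature selection (IFS) on out-of-bag R².
3. **Pleiotropy clustering.** A binary profile matrix over phenotypes and
   TFs is converted to a Proportional Similarity Index (PSI) association
   matrix and clustered with Markov clustering (MCL); rSNPs associated
   with fewer than two phenotypes are pruned.
4. **Expression validation.** For each pleiotropic rSNP, lines are split
   by allele and the promoter's gene expression (median-of-ratios
   normalized counts) is compared between groups with the Wilcoxon
   rank-sum test; rSNPs without a significant shift are pruned from the
   three-layer TF → rSNP(gene) → phenotype network models.

A synthetic-data generator produces all inputs with known ground truth,
so the whole pipeline is testable as a parameter-recovery exercise.

## Phase 1: allele-aware TFBS scanning

For every biallelic SNP with minor allele frequency (MAF) ≥ 0.05 that
falls in a promoter window — transcription-direction offsets in
[−500, +100] bp around the TSS (feature start on the plus strand, feature
end on the minus strand) — two 51-base windows are extracted (±25 bp,
SNP central), one per allele. Each window is scanned on both strands with
every PWM using MATCH-style information-weighted scoring:

- per-position information \(I(i) = \sum_b f(i,b)\,\ln 4 f(i,b)\),
- matrix similarity score
  \(\mathrm{mss} = (\mathrm{Current} - \mathrm{Min})/(\mathrm{Max} - \mathrm{Min})\)
  with \(\mathrm{Current} = \sum_i I(i) f(i, s_i)\), and the core score
  computed identically over the five consecutive positions of maximal
  summed information.

A TFBS is *present* when at least one hit anywhere in the window passes
both cutoffs (defaults `mss_cutoff = 0.95`, `core_cutoff = 0.90`). The
consequence is *Loss* when only the reference-allele window has a site,
*Gain* when only the alternate does. A SNP is an rSNP when it has at
least one Gain or Loss. Because a hit whose span does not overlap the SNP
scores identically in both windows, only SNP-overlapping sites can
produce Gain/Loss — the window-level definition and the site-level one
coincide.

**Numerical choices.** Score cutoffs are global and configurable; the
underlying scanning literature uses per-matrix cutoff profiles, which we
deliberately do not model (the defaults sit in the conservative range of
published minimum-false-positive profiles). Matrices whose positions are
all uniform have Max = Min and are excluded from scanning with a warning.
Windows containing ambiguous bases are skipped. Multi-allelic VCF records
are split into biallelic records on load. Coordinates are 1-based
inclusive in VCF/GFF3 and converted internally to 0-based arithmetic.

## Phase 2: Boruta ranking and incremental feature selection

Dosage coding is 0/1/2 alternate-allele copies; missing calls are imputed
by the per-SNP mode. Each Boruta iteration appends a column-permuted
shadow copy of every feature still in play, fits a regression forest
(`ranger`, 500 trees, features-per-split p/3, single thread, seeded), and
records a *hit* for features whose impurity importance exceeds the
maximum shadow importance. Hit counts are tested after every iteration
against Binomial(iterations, ½), two-sided, Bonferroni-corrected over the
currently undecided features (α = 0.01): significantly many hits confirm,
significantly few reject (and remove) a feature; survivors at
`max_iter = 100` remain Tentative. All features are ranked by the median
of \(Z = (\text{importance} - \mu_{\text{shadow}})/\sigma_{\text{shadow}}\)
over their active iterations, with ties broken by feature id.

IFS then refits the forest on the top-k ranked features for
k = 1, 2, …, recording out-of-bag R² and taking the smallest k that
attains the maximum. Out-of-bag R² was chosen over cross-validation
because it is deterministic given the seed and costs a single fit per k.

**Design decision (gatekeeping).** The IFS prefix search uses the full
median-Z ranking *order*, but only as deep as the number of features that
Boruta did not reject, and a phenotype with no Confirmed feature (or no
positive out-of-bag R²) is assigned an *empty* optimal set. Without this
gate, phenotypes with no genetic signal acquire sizeable "optimal" sets
through feature-selection bias — ranking and refitting on the same data
produces positive-looking out-of-bag R² for prefixes of chance-correlated
features — and those spurious memberships flood the Phase-3 profile
matrix and merge genuine clusters. Gatekeeping is the purpose Boruta was
designed for; the search-depth bound follows from it.

**Known limitation.** With many candidate features, the shadow-feature
procedure does not control the per-feature false-confirmation rate at its
nominal α under a complete null: a null feature's chance in-sample
correlation is fixed across iterations while shadows are re-permuted
every iteration, so the few luckiest features have hit probability above
½ and are eventually confirmed once mass rejections shrink the Bonferroni
denominator. At n = 300 with 100 null features we measure ≈ 3–4 false
confirmations per run rather than the nominal 1. Downstream this is
tolerable — falsely confirmed rSNPs rarely recur across two phenotypes
and are pruned by the pleiotropy rule — but Boruta's Confirmed set should
not be read as a family-wise-error-controlled discovery list.

## Phase 3: PSI and Markov clustering

The profile matrix M has one row per rSNP appearing in at least one
optimal set; phenotype columns mark optimal-set membership, TF columns
mark Gain/Loss consequences. The association matrix is the pairwise
Proportional Similarity Index
\(A_{kl} = 2\sum_j \min(M_{kj}, M_{lj}) / \sum_j (M_{kj} + M_{lj})\),
defined as 0 for two all-zero rows. MCL runs on A with self-loops equal
to each row's maximum (a standard stabilization; the all-zero row gets a
unit loop), column normalization, expansion power 2, inflation 2.0
(MCL's canonical default, configurable), entry pruning at 1e-6 and
convergence tolerance 1e-8 on the maximum change. Attractors are rows of
the limit with positive diagonal mass; nodes join the attractor holding
the largest weight in their column, ties going to the lexicographically
smallest attractor, and overlapping attractor systems are merged, so the
output is a deterministic partition. Finally, rSNPs with fewer than two
phenotype-column entries are removed (TF columns confer no pleiotropy)
and emptied clusters are dropped.

## Phase 4: allele-split expression validation

Counts are normalized by median-of-ratios: each line's size factor is the
median, over genes with all-positive counts, of the count divided by the
gene's geometric mean across lines. (The median is taken on the ratio
scale; log-scale interpolation of even-count medians differs by ~1e-4.)
For each (pleiotropic rSNP, gene) pair, lines are split into reference
(dosage 0) and alternate (dosage 2) groups — heterozygotes are excluded
by default, fitting an inbred panel, with an option to pool them with the
alternate group — and expression is compared with a Wilcoxon rank-sum
test: exact when both groups have ≤ 10 lines and no ties, otherwise a
tie-corrected normal approximation with continuity correction. Groups
smaller than 3 are skipped. Significance defaults to raw p < 0.05,
mirroring the single-test-per-rSNP procedure; Benjamini–Hochberg
correction across records is available as an option because whether the
original procedure corrected for multiple testing is unstated. rSNPs
without a significant shift are removed from the network models along
with any orphaned TFs and phenotypes.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with machine-readable ground truth:

- **PWMs** with mostly informative positions (dominant base 0.8–0.97)
  and a forced high-information central anchor so consensus sites are
  plantable and a central mismatch is score-relevant.
- **Genome and annotation**: genes in fixed 2-kb slots on one contig,
  alternating strand; for each planted rSNP an exact consensus site of
  its designated PWM is written into the promoter overlapping the SNP at
  the motif's most discriminating position, with the alternate allele
  chosen to break the site (Loss) or the reference to lack it (Gain);
  every planted site is verified against the Phase-1 classifier at
  default cutoffs before acceptance.
- **Genotypes**: per-SNP alternate-allele frequency uniform on
  [0.05, 0.5], homozygous 0/2 calls (heterozygosity rate 0 by default,
  emulating inbred lines), redrawn until the realized folded frequency
  respects the MAF floor.
- **Phenotypes**: each planted cluster assigns the same additive dosage
  signal (effect 0.5 per dosage unit) to its phenotypes; Gaussian noise
  contributes a fixed fraction (default 0.4) of the total variance;
  remaining phenotypes are standard-normal noise. Effects are additive
  with no epistasis and no linkage disequilibrium, population structure
  or kinship; with inbred 0/2 dosages the marginal variance contribution
  of one SNP is \(4p(1-p)\beta^2\).
- **Expression**: gamma-Poisson counts with log-normal baselines and
  per-line size factors; each planted cis effect multiplies the mean of
  alternate-homozygous lines by `exp(±shift)` (default |shift| = 1.5
  natural-log units, sign up for Gain and down for Loss).

**Default study conditions** (used by the recovery tests and the
acceptance script): 400 lines, 60 genes, 2,000 SNPs, 20 phenotypes, a
20-motif PWM library, 3 planted clusters of 6 rSNPs × 3 phenotypes with
disjoint rSNP and phenotype sets, effect 0.5, noise fraction 0.4, cis
shift 1.5. These sizes make the marginal per-SNP R² ≈ 0.1, comfortably
detectable at n = 400 yet far from trivial, and keep a full pipeline run
within a few minutes on one CPU.

**What passing recovery tests do and do not show.** The generator plants
clean, disjoint, additive structure with no linkage disequilibrium,
relatedness, environment or shared TF usage between clusters. Recovery
of that structure demonstrates the pipeline's internal consistency —
each phase's output feeds the next correctly and the planted parameters
are identifiable — not performance on real panels, where LD, kinship and
correlated phenotypes will blur all four phases.

## Reproducibility

Every stochastic stage derives its own seed from the single run seed
through a fixed integer map, so reruns with the same inputs, parameters
and seed reproduce the consequence table, rankings, clusters and
networks exactly. The run manifest records package and R versions, seed,
all parameters and per-stage record counts.
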