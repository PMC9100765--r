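# rsnpleio

Pleiotropic signatures of regulatory SNPs from multi-omics data.

## The problem

In dense genotype panels of inbred crop lines, some promoter variants do
double duty: a single SNP changes a transcription factor binding site
(TFBS) in a gene's promoter *and* is associated with several quantitative
phenotypes at once. Finding these **pleiotropic regulatory SNPs (rSNPs)**
— and the transcription factors and genes they act through — points to
breeding targets that move multiple traits simultaneously. `rsnpleio` is
for quantitative geneticists and breeding informaticians who have a
genotype matrix (VCF), a genome and gene annotation (FASTA + GFF3), a TF
motif library (TRANSFAC-style PWMs), phenotypes and RNA-seq counts for
the same lines, and want a tested, reproducible implementation of the
whole chain from motifs to validated networks.

## The method

Four phases, each exposed as ordinary functions and orchestrated by
`run_pipeline()`:

1. **rSNP identification.** SNPs with MAF ≥ 0.05 inside promoter windows
   ([−500, +100] bp around the TSS in transcription direction) are
   expanded into two 51-base windows (±25 bp, SNP central), one per
   allele, and scanned on both strands against every PWM with
   MATCH-style scoring: mss = (Current − Min)/(Max − Min) with
   Current = Σᵢ I(i)·f(i, sᵢ) and I(i) = Σ_b f(i,b)·ln 4f(i,b), plus a
   core score over the 5 most informative consecutive positions. A
   (SNP, TF) pair is a **Loss** if only the reference window carries a
   passing hit, a **Gain** if only the alternate does; SNPs with ≥ 1
   Gain/Loss are the rSNPs.
2. **Association.** Per phenotype, rSNP dosages (0/1/2) are ranked by a
   Boruta-style shadow-feature wrapper around random-forest regression
   (hits against the max shadow importance, binomial decisions, median-Z
   ranking), then incremental feature selection refits the forest on
   growing top-k prefixes and picks the k maximizing out-of-bag R².
3. **Pleiotropy clustering.** The binary rSNP × (phenotype ∪ TF) profile
   matrix M becomes an association matrix via the Proportional
   Similarity Index A_kl = 2·Σⱼ min(M_kj, M_lj) / Σⱼ (M_kj + M_lj),
   which Markov clustering (expansion 2, inflation 2.0) cuts into
   clusters; rSNPs associated with < 2 phenotypes are pruned.
4. **Expression validation.** For each pleiotropic rSNP, lines split by
   allele (dosage 0 vs 2) and the promoter gene's median-of-ratios
   normalized expression is compared with a Wilcoxon rank-sum test;
   non-significant rSNPs (and orphaned TFs/phenotypes) are pruned from
   the three-layer TF → rSNP(gene) → phenotype networks.

A synthetic-data generator (`simulate_dataset()`) produces genomes with
planted consensus sites, inbred genotypes, clustered phenotypes and
cis-shifted expression counts together with ground truth, so the full
pipeline is testable as parameter recovery.

## Worked example

```r
library(rsnpleio)

cfg <- sim_config(n_lines = 200, n_genes = 20, n_snps = 400, n_pwms = 10,
                  n_planted_clusters = 2, phenotypes_per_cluster = 2,
                  rsnps_per_cluster = 4, n_phenotypes = 10, seed = 42)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim, seed = 42)
print(res)
#> Four-phase rSNP pleiotropy pipeline
#>   snps_after_maf               400
#>   consequences                 11
#>   rsnps                        10
#>   phenotypes_analyzed          10
#>   optimal_set_sizes            19
#>   profile_rows                 8
#>   clusters                     2
#>   pleiotropic_rsnps            8
#>   validations                  8
#>   significant_validations      8
#>   rsnps_surviving_expression   8
res$summary
#>   cluster n_rsnps n_genes                         phenotypes
#> 1       1       4       4 trait01, trait02, trait03, trait06
#> 2       2       4       4          trait02, trait09, trait10
str(evaluate_recovery(res, sim$truth))
#> List of 5
#>  $ rsnp_detection_rate : num 1
#>  $ optimal_set_recovery: num 1
#>  $ cluster_ari         : num 1
#>  $ cis_pruning_survival: num 1
#>  $ n_clusters          : int 2
```

Reading the output: all 400 SNPs pass the MAF filter (the generator
enforces the floor); scanning finds 11 Gain/Loss consequences across 10
rSNPs (8 planted plus background); association yields 19 optimal-set
memberships over 10 phenotypes; the profile matrix keeps 8 rSNPs, MCL
splits them into the 2 planted clusters, and all 8 pleiotropic rSNPs
show the planted cis expression shift, so the pruned networks retain
them. The recovery metrics compare everything against the generator's
ground truth: detection, optimal-set recovery and Adjusted Rand Index of
the clustering are all perfect on this panel.

A thin CLI with subcommands `simulate`, `call-rsnps`, `associate`,
`cluster`, `network` and `run-all` is installed at
`inst/scripts/rsnpleio`.

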