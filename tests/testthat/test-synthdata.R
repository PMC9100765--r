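# Synthetic-data generator: config validation, determinism, genotype
# spectrum, phenotype variance decomposition and expression model.

test_that("simulation config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.3, 0.2)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(phenotypes_per_cluster = 1), ">= 2")
  expect_error(sim_config(n_lines = 0), "> 0")
  expect_error(sim_config(heritability_like_noise = 1), "heritability")
  expect_error(sim_config(n_planted_clusters = 10, phenotypes_per_cluster = 3,
                          n_phenotypes = 20), "phenotypes")
})

test_that("generators are pure functions of config and seed", {
  cfg <- small_sim_config(seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$genotypes$snps, s2$genotypes$snps)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$counts, s2$counts)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$planted_rsnps, s2$truth$planted_rsnps)
})

test_that("genotypes respect the MAF floor and inbred coding", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_dataset(cfg)
  dos <- sim$genotypes$dosages
  expect_true(all(dos %in% c(0L, 2L)))  # het rate 0: homozygous calls only
  mafs <- apply(dos, 2, compute_maf)
  expect_true(all(mafs >= cfg$maf_range[1]))
  expect_true(all(mafs <= 0.5))
})

test_that("planted ground truth has promoter rSNPs and >= 2 phenotypes per cluster", {
  sim <- simulate_dataset(small_sim_config(seed = 5))
  sel <- select_promoter_snps(sim$genotypes$snps, sim$annotations)
  for (i in seq_len(nrow(sim$truth$planted_rsnps))) {
    pr <- sim$truth$planted_rsnps[i, ]
    expect_true(any(sel$snp_id == pr$snp & sel$gene_id == pr$gene),
                label = sprintf("%s in promoter of %s", pr$snp, pr$gene))
  }
  for (cl in sim$truth$planted_clusters)
    expect_gte(length(cl$phenotypes), 2)
  # cluster rSNP sets are disjoint
  all_rsnps <- unlist(lapply(sim$truth$planted_clusters, `[[`, "rsnps"))
  expect_equal(anyDuplicated(all_rsnps), 0)
})

test_that("phenotypes decompose as planted additive dosage effects plus noise", {
  # noiseless limit: phenotype is an affine function of dosage
  cfg0 <- sim_config(n_lines = 60, n_genes = 10, n_snps = 40, n_pwms = 4,
                     n_planted_clusters = 1, phenotypes_per_cluster = 2,
                     rsnps_per_cluster = 1, heritability_like_noise = 1e-12,
                     n_phenotypes = 4, seed = 2)
  sim0 <- simulate_dataset(cfg0)
  cl <- sim0$truth$planted_clusters[[1]]
  d <- sim0$genotypes$dosages[, cl$rsnps[1]]
  y <- sim0$phenotypes[, cl$phenotypes[1]]
  expect_gte(summary(stats::lm(y ~ d))$r.squared, 0.999)

  # zero effect: no phenotype-genotype correlation beyond Monte-Carlo noise
  cfg_null <- sim_config(n_lines = 200, n_genes = 10, n_snps = 40, n_pwms = 4,
                         n_planted_clusters = 1, phenotypes_per_cluster = 2,
                         rsnps_per_cluster = 2, effect_size = 0,
                         n_phenotypes = 4, seed = 8)
  simn <- simulate_dataset(cfg_null)
  cln <- simn$truth$planted_clusters[[1]]
  for (s in cln$rsnps) for (tr in cln$phenotypes)
    expect_lt(abs(stats::cor(simn$genotypes$dosages[, s],
                             simn$phenotypes[, tr])), 0.2)

  # closed-form variance decomposition of the marginal per-SNP R2:
  # with inbred 0/2 dosages, Var(d) = 4 p (1 - p)
  cfg <- sim_config(n_lines = 400, n_genes = 14, n_snps = 60, n_pwms = 5,
                    n_planted_clusters = 2, phenotypes_per_cluster = 2,
                    rsnps_per_cluster = 3, effect_size = 0.5,
                    n_phenotypes = 6, seed = 4)
  sim <- simulate_dataset(cfg)
  obs <- c(); expct <- c()
  for (cl in sim$truth$planted_clusters) {
    tr <- cl$phenotypes[1]
    y <- sim$phenotypes[, tr]
    for (s in cl$rsnps) {
      d <- sim$genotypes$dosages[, s]
      p <- mean(d) / 2
      obs <- c(obs, stats::cor(d, y)^2)
      expct <- c(expct, cfg$effect_size^2 * 4 * p * (1 - p) / stats::var(y))
    }
  }
  expect_lt(abs(mean(obs) - mean(expct)), 0.05)
})

test_that("expression shifts follow the planted cis effects", {
  # type-I error at nominal level over null genes
  n_l <- 300; n_g <- 200
  cfg <- sim_config(n_lines = n_l, n_genes = n_g, n_snps = 10, n_pwms = 3,
                    n_planted_clusters = 1, phenotypes_per_cluster = 2,
                    rsnps_per_cluster = 1, n_phenotypes = 4, seed = 6)
  geno <- structure(list(
    snps = data.frame(id = "s1", chrom = "chr1", pos = 100, ref = "A",
                      alt = "G", stringsAsFactors = FALSE),
    dosages = matrix(rep(c(0L, 2L), each = n_l / 2), ncol = 1,
                     dimnames = list(sprintf("L%03d", 1:n_l), "s1")),
    lines = sprintf("L%03d", 1:n_l)), class = "geno_set")
  ann <- data.frame(gene_id = sprintf("g%03d", 1:n_g))
  null_truth <- structure(list(
    planted_rsnps = data.frame(), planted_clusters = list(),
    planted_cis_effects = data.frame(snp = character(0), gene = character(0),
                                     sign = integer(0))), class = "ground_truth")
  counts <- generate_expression(geno, null_truth, cfg, ann, seed = 11)
  norm <- median_of_ratios(counts)$normalized
  grp <- split_lines_by_allele(geno$dosages[, 1])
  pvals <- apply(norm, 1, function(ev)
    wilcoxon_rank_sum(ev[grp$ref], ev[grp$alt])$p.value)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.10)

  # power: large shift, 150 vs 150 lines
  cis_truth <- structure(list(
    planted_rsnps = data.frame(), planted_clusters = list(),
    planted_cis_effects = data.frame(snp = "s1", gene = sprintf("g%03d", 1:100),
                                     sign = rep(c(1L, -1L), 50),
                                     stringsAsFactors = FALSE)),
    class = "ground_truth")
  counts2 <- generate_expression(geno, cis_truth, cfg, ann, seed = 12)
  norm2 <- median_of_ratios(counts2)$normalized
  p2 <- apply(norm2[1:100, ], 1, function(ev)
    wilcoxon_rank_sum(ev[grp$ref], ev[grp$alt])$p.value)
  expect_gte(mean(p2 < 0.05), 0.95)
  # direction matches the planted sign
  med_diff <- apply(norm2[1:100, ], 1, function(ev)
    stats::median(ev[grp$alt]) - stats::median(ev[grp$ref]))
  expect_true(all(sign(med_diff[1:10]) == rep(c(1, -1), 5)[1:10]))

  # determinism
  counts3 <- generate_expression(geno, cis_truth, cfg, ann, seed = 12)
  expect_identical(counts2, counts3)
})

test_that("written artifacts exist and the VCF/truth round-trip", {
  outdir <- tempfile("simout")
  sim <- simulate_dataset(small_sim_config(seed = 9), outdir = outdir)
  expect_true(all(file.exists(unlist(sim$paths))))
  back <- read_vcf(sim$paths$vcf)
  expect_identical(back$dosages[sim$genotypes$lines, sim$genotypes$snps$id],
                   sim$genotypes$dosages[, sim$genotypes$snps$id])
  expect_equal(back$snps$pos[match(sim$genotypes$snps$id, back$snps$id)],
               sim$genotypes$snps$pos)
  truth2 <- read_ground_truth(sim$paths$truth)
  expect_equal(truth2$planted_rsnps$snp, sim$truth$planted_rsnps$snp)
  expect_equal(length(truth2$planted_clusters), length(sim$truth$planted_clusters))
  expect_setequal(truth2$planted_clusters[[1]]$rsnps,
                  sim$truth$planted_clusters[[1]]$rsnps)
  unlink(outdir, recursive = TRUE)
})
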