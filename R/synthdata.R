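# Synthetic multi-omics generator: genome with promoter-planted motif
# sites, inbred genotypes, clustered quantitative phenotypes, and
# expression counts with cis-allelic shifts, plus machine-readable ground
# truth for recovery tests.

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator.
#' Defaults describe the study conditions the package's recovery tests
#' run under: a 400-line inbred panel, 2,000 biallelic SNPs with MAF in
#' \[0.05, 0.5\], 20 quantitative phenotypes of which 3 disjoint clusters
#' of 3 phenotypes carry planted additive effects from 6 regulatory SNPs
#' each, and expression counts with large cis-allelic shifts at every
#' planted rSNP.
#'
#' @param n_lines Number of inbred lines.
#' @param n_genes Number of annotated genes.
#' @param n_snps Total number of biallelic SNPs (planted rSNPs included).
#' @param maf_range Alternate-allele frequency range `c(low, high)`,
#'   0 < low <= high <= 0.5.
#' @param n_phenotypes Number of quantitative phenotypes (default 20).
#' @param n_pwms Number of motifs in the PWM library.
#' @param pwm_length_range Motif length range, minimum >= 6.
#' @param n_planted_clusters Number of planted pleiotropy clusters.
#' @param phenotypes_per_cluster Phenotypes per cluster (>= 2; pleiotropy
#'   requires at least two phenotypes).
#' @param rsnps_per_cluster Planted regulatory SNPs per cluster.
#' @param effect_size Additive allele-dosage effect (per dosage unit) of
#'   each planted rSNP on each of its cluster's phenotypes.
#' @param heritability_like_noise Fraction of the total phenotypic
#'   variance contributed by Gaussian noise, in \[0, 1).
#' @param cis_expression_shift Natural-log fold change of expression in
#'   alternate-homozygous lines at planted cis effects.
#' @param het_rate Per-line heterozygosity rate (default 0: fully inbred).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 400, n_genes = 60, n_snps = 2000,
                       maf_range = c(0.05, 0.5), n_phenotypes = 20,
                       n_pwms = 20, pwm_length_range = c(8, 12),
                       n_planted_clusters = 3, phenotypes_per_cluster = 3,
                       rsnps_per_cluster = 6, effect_size = 0.5,
                       heritability_like_noise = 0.4,
                       cis_expression_shift = 1.5, het_rate = 0, seed = 1) {
  cfg <- list(n_lines = n_lines, n_genes = n_genes, n_snps = n_snps,
              maf_range = maf_range, n_phenotypes = n_phenotypes,
              n_pwms = n_pwms, pwm_length_range = pwm_length_range,
              n_planted_clusters = n_planted_clusters,
              phenotypes_per_cluster = phenotypes_per_cluster,
              rsnps_per_cluster = rsnps_per_cluster,
              effect_size = effect_size,
              heritability_like_noise = heritability_like_noise,
              cis_expression_shift = cis_expression_shift,
              het_rate = het_rate, seed = as.integer(seed))
  counts <- c("n_lines", "n_genes", "n_snps", "n_phenotypes", "n_pwms",
              "n_planted_clusters", "phenotypes_per_cluster", "rsnps_per_cluster")
  for (f in counts) if (cfg[[f]] < 1) stop(sprintf("%s must be > 0", f))
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] <= 0.5))
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  if (phenotypes_per_cluster < 2)
    stop("phenotypes_per_cluster must be >= 2 (pleiotropy needs >= 2 phenotypes)")
  if (n_planted_clusters * phenotypes_per_cluster > n_phenotypes)
    stop("planted clusters require more phenotypes than available")
  if (n_planted_clusters * rsnps_per_cluster > n_genes)
    stop("planted rSNPs require more promoters (genes) than available")
  if (heritability_like_noise < 0 || heritability_like_noise >= 1)
    stop("heritability_like_noise must be in [0, 1)")
  if (het_rate < 0 || het_rate > 1) stop("het_rate must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

# Derive a bounded per-stage seed from the master seed.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k) %% 2147483629)
}

GENE_SLOT <- 2000L  # bp of genome reserved per gene

# Plan the planted ground truth: cluster -> phenotypes, rSNPs -> genes,
# one TF and a Gain/Loss effect per planted rSNP, cis sign from effect.
plan_ground_truth <- function(config, pwm_library, seed) {
  set.seed(seed)
  n_planted <- config$n_planted_clusters * config$rsnps_per_cluster
  genes <- sprintf("gene%04d", sample.int(config$n_genes, n_planted))
  phen_pool <- sample.int(config$n_phenotypes,
                          config$n_planted_clusters * config$phenotypes_per_cluster)
  tfs <- names(pwm_library)[1 + (seq_len(n_planted) - 1L) %% length(pwm_library)]
  effects <- rep(c("Loss", "Gain"), length.out = n_planted)
  planted <- data.frame(
    snp = sprintf("rsnp%03d", seq_len(n_planted)),
    gene = genes, tf = tfs, effect = effects,
    cluster = rep(seq_len(config$n_planted_clusters),
                  each = config$rsnps_per_cluster),
    stringsAsFactors = FALSE)
  clusters <- lapply(seq_len(config$n_planted_clusters), function(k) {
    idx <- (k - 1L) * config$phenotypes_per_cluster +
      seq_len(config$phenotypes_per_cluster)
    list(rsnps = planted$snp[planted$cluster == k],
         phenotypes = sprintf("trait%02d", sort(phen_pool[idx])))
  })
  cis <- data.frame(snp = planted$snp, gene = planted$gene,
                    sign = ifelse(planted$effect == "Gain", 1L, -1L),
                    stringsAsFactors = FALSE)
  structure(list(planted_rsnps = planted, planted_clusters = clusters,
                 planted_cis_effects = cis), class = "ground_truth")
}

#' Generate a genome with promoter-planted TF binding sites
#'
#' Lays out `n_genes` genes (alternating strand) on a single chromosome in
#' fixed 2-kb slots so that promoter windows never overlap contig ends, and
#' plants one consensus motif site per planned regulatory SNP: for a Loss
#' the reference sequence carries an exact consensus of the designated PWM
#' overlapping the SNP and the alternate allele destroys it; for a Gain the
#' roles are reversed. Every planted site is verified against the Phase-1
#' classifier at the default cutoffs before being accepted.
#'
#' @param config A `sim_config`.
#' @param pwm_library Named list of `pwm` objects.
#' @param plan A `ground_truth` plan from the internal planner (the planted
#'   rSNP table drives site placement).
#' @param seed Integer seed.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `annotations`
#'   (data.frame gene_id, chrom, start, end, strand, tss) and
#'   `planted_snps` (data.frame id, chrom, pos, ref, alt, gene, tf, effect).
#' @export
generate_genome_with_promoters <- function(config, pwm_library, plan, seed) {
  set.seed(seed)
  planted <- plan$planted_rsnps
  if (nrow(planted) > config$n_genes)
    stop("plan requests more planted sites than available promoters")
  chrom <- "chr1"
  glen <- config$n_genes * GENE_SLOT + 1000L
  genome_chars <- sample(DNA_BASES, glen, replace = TRUE)
  ann <- data.frame(gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
                    chrom = chrom, start = 0L, end = 0L,
                    strand = rep(c("+", "-"), length.out = config$n_genes),
                    tss = 0L, stringsAsFactors = FALSE)
  for (g in seq_len(config$n_genes)) {
    s0 <- (g - 1L) * GENE_SLOT
    if (ann$strand[g] == "+") {
      ann$tss[g] <- s0 + 700L
      ann$start[g] <- ann$tss[g]; ann$end[g] <- ann$tss[g] + 800L
    } else {
      ann$tss[g] <- s0 + 1300L
      ann$start[g] <- ann$tss[g] - 800L; ann$end[g] <- ann$tss[g]
    }
  }
  planted_out <- planted
  planted_out$chrom <- chrom
  planted_out$pos <- NA_integer_
  planted_out$ref <- NA_character_
  planted_out$alt <- NA_character_
  for (i in seq_len(nrow(planted))) {
    p <- pwm_library[[planted$tf[i]]]
    gi <- match(planted$gene[i], ann$gene_id)
    res <- plant_site(genome_chars, ann[gi, ], p, planted$effect[i])
    genome_chars <- res$genome_chars
    planted_out$pos[i] <- res$pos
    planted_out$ref[i] <- res$ref
    planted_out$alt[i] <- res$alt
  }
  genome <- Biostrings::DNAStringSet(structure(paste(genome_chars, collapse = ""),
                                               names = chrom))
  list(genome = genome,
       annotations = ann,
       planted_snps = data.frame(id = planted_out$snp, chrom = planted_out$chrom,
                                 pos = planted_out$pos, ref = planted_out$ref,
                                 alt = planted_out$alt, gene = planted_out$gene,
                                 tf = planted_out$tf, effect = planted_out$effect,
                                 stringsAsFactors = FALSE))
}

# Plant one consensus site for `p` in the promoter of `ann` (one row),
# verified to classify as the requested effect at default cutoffs.
plant_site <- function(genome_chars, ann, p, effect,
                       upstream = 500, downstream = 100, flank = 25) {
  L <- p$length
  cons <- strsplit(consensus_string(p), "")[[1L]]
  # SNP goes at the most discriminating motif position
  jstar <- which.max(p$info * (apply(p$freq, 1, max) - apply(p$freq, 1, min)))
  lo <- if (ann$strand == "+") ann$tss - upstream else ann$tss - downstream
  hi <- if (ann$strand == "+") ann$tss + downstream else ann$tss + upstream
  for (attempt in 1:50) {
    pos <- sample(seq(lo + flank, hi - flank), 1L)      # SNP genomic position
    mstart <- pos - jstar + 1L                          # motif genomic start
    region <- (pos - flank):(pos + flank)
    cand <- genome_chars
    cand[region] <- sample(DNA_BASES, length(region), replace = TRUE)
    cand[mstart:(mstart + L - 1L)] <- cons
    cons_base <- cons[jstar]
    break_base <- DNA_BASES[which.min(p$freq[jstar, ])]
    if (break_base == cons_base) break_base <- DNA_BASES[order(p$freq[jstar, ])][2L]
    if (effect == "Loss") { ref <- cons_base; alt <- break_base }
    else { ref <- break_base; alt <- cons_base; cand[pos] <- break_base }
    win <- paste(cand[(pos - flank):(pos + flank)], collapse = "")
    alt_win <- win; substr(alt_win, flank + 1L, flank + 1L) <- alt
    pair <- structure(list(snp_id = "planted", ref_seq = win, alt_seq = alt_win,
                           snp_index = flank + 1L), class = "flanking_pair")
    cc <- classify_consequence(pair, p)
    if (cc$effect == effect)
      return(list(genome_chars = cand, pos = pos, ref = ref, alt = alt))
  }
  stop(sprintf("could not plant a verifiable %s site for %s in %s",
               effect, p$name, ann$gene_id))
}

#' Generate inbred genotypes
#'
#' Draws a per-SNP alternate-allele frequency inside `maf_range` and
#' samples homozygous 0/2 dosages per line (heterozygotes at the configured
#' rate, default 0). Genotype vectors are redrawn until the realized folded
#' frequency respects the lower MAF bound, so every emitted SNP survives
#' the MAF filter at that floor. Planted rSNPs are included at their
#' planned positions; the remaining SNPs get random positions (with 25 bp
#' of context) and alleles matching the reference genome.
#'
#' @param config A `sim_config`.
#' @param planted_snps Planted SNP table from
#'   [generate_genome_with_promoters()] (NULL for none).
#' @param genome The reference [Biostrings::DNAStringSet].
#' @param seed Integer seed.
#' @return A `geno_set`: list with `snps` (data.frame id, chrom, pos, ref,
#'   alt), `dosages` (lines x SNPs integer matrix) and `lines`.
#' @export
generate_genotypes <- function(config, planted_snps, genome, seed) {
  set.seed(seed)
  lines <- sprintf("line%04d", seq_len(config$n_lines))
  chrom <- names(genome)[1L]
  glen <- length(genome[[1L]])
  n_extra <- config$n_snps - if (is.null(planted_snps)) 0L else nrow(planted_snps)
  if (n_extra < 0) stop("n_snps smaller than the number of planted rSNPs")
  taken <- if (is.null(planted_snps)) integer(0) else planted_snps$pos
  avail <- setdiff(seq(26L, glen - 26L), taken)
  pos_extra <- sort(sample(avail, n_extra))
  genome_chars <- strsplit(as.character(genome[[1L]]), "")[[1L]]
  extra <- data.frame(id = sprintf("snp%05d", seq_len(n_extra)),
                      chrom = chrom, pos = pos_extra,
                      ref = genome_chars[pos_extra],
                      alt = NA_character_, stringsAsFactors = FALSE)
  if (n_extra > 0)
    extra$alt <- vapply(extra$ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "")
  snps <- rbind(
    if (!is.null(planted_snps))
      planted_snps[, c("id", "chrom", "pos", "ref", "alt")] else NULL,
    extra)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  dos <- matrix(0L, config$n_lines, nrow(snps),
                dimnames = list(lines, snps$id))
  for (j in seq_len(nrow(snps))) {
    for (try in 1:100) {
      p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      is_het <- stats::runif(config$n_lines) < config$het_rate
      d <- ifelse(is_het, 1L, 2L * (stats::runif(config$n_lines) < p))
      realized <- sum(d) / (2 * config$n_lines)
      if (min(realized, 1 - realized) >= config$maf_range[1]) break
    }
    dos[, j] <- as.integer(d)
  }
  structure(list(snps = snps, dosages = dos, lines = lines), class = "geno_set")
}

#' Generate clustered quantitative phenotypes
#'
#' Each phenotype belonging to a planted cluster is the sum of additive
#' allele-dosage effects of the cluster's planted rSNPs plus Gaussian noise
#' whose variance is set so that noise contributes the configured fraction
#' of the total phenotypic variance. Phenotypes outside every cluster are
#' pure standard-normal noise.
#'
#' @param genotypes A `geno_set` containing the planted rSNPs.
#' @param ground_truth A `ground_truth` object.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return Numeric matrix, lines x phenotypes, with dimnames.
#' @export
generate_phenotypes <- function(genotypes, ground_truth, config, seed) {
  set.seed(seed)
  traits <- sprintf("trait%02d", seq_len(config$n_phenotypes))
  Y <- matrix(stats::rnorm(config$n_lines * config$n_phenotypes),
              config$n_lines, config$n_phenotypes,
              dimnames = list(genotypes$lines, traits))
  for (cl in ground_truth$planted_clusters) {
    miss <- setdiff(cl$rsnps, colnames(genotypes$dosages))
    if (length(miss))
      stop(sprintf("ground-truth cluster references unknown SNP(s): %s",
                   paste(miss, collapse = ", ")))
    g <- genotypes$dosages[, cl$rsnps, drop = FALSE] %*%
      rep(config$effect_size, length(cl$rsnps))
    vg <- stats::var(as.vector(g))
    f <- config$heritability_like_noise
    ve <- if (vg > 0) f / (1 - f) * vg else 1
    for (tr in cl$phenotypes)
      Y[, tr] <- as.vector(g) + stats::rnorm(config$n_lines, sd = sqrt(ve))
  }
  Y
}

#' Generate expression counts with planted cis-allelic shifts
#'
#' Counts follow a gamma-Poisson (negative binomial) model with
#' log-normal baseline means per gene and log-normal library size factors
#' per line. For each planted cis effect the expected count of
#' alternate-allele lines is multiplied by `exp(sign * shift * dosage/2)`,
#' i.e. the full natural-log shift in alternate homozygotes.
#'
#' @param genotypes A `geno_set`.
#' @param ground_truth A `ground_truth` object.
#' @param config A `sim_config`.
#' @param annotations Gene annotation data.frame (supplies gene ids).
#' @param seed Integer seed.
#' @return Integer matrix, genes x lines, with dimnames.
#' @export
generate_expression <- function(genotypes, ground_truth, config, annotations, seed) {
  set.seed(seed)
  genes <- annotations$gene_id
  n_g <- length(genes); n_l <- config$n_lines
  base_mu <- exp(stats::rnorm(n_g, log(200), 0.7))
  size_factors <- exp(stats::rnorm(n_l, 0, 0.2))
  logfc <- matrix(0, n_g, n_l, dimnames = list(genes, genotypes$lines))
  cis <- ground_truth$planted_cis_effects
  for (i in seq_len(nrow(cis))) {
    g <- cis$gene[i]
    if (!(g %in% genes) || !(cis$snp[i] %in% colnames(genotypes$dosages))) next
    d <- genotypes$dosages[, cis$snp[i]]
    logfc[g, ] <- logfc[g, ] + cis$sign[i] * config$cis_expression_shift * d / 2
  }
  mu <- outer(base_mu, size_factors) * exp(logfc)
  counts <- matrix(stats::rnbinom(n_g * n_l, mu = as.vector(mu), size = 10),
                   n_g, n_l, dimnames = list(genes, genotypes$lines))
  counts
}

#' Simulate a complete synthetic multi-omics dataset
#'
#' Runs every generator in order with per-stage seeds derived from the
#' config seed and optionally writes all artifacts (TRANSFAC PWMs, FASTA
#' genome, GFF3 annotation, VCF genotypes, phenotype and count TSVs,
#' ground-truth JSON) to a directory.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory (created if needed), or NULL to skip
#'   writing files.
#' @return List with `config`, `pwms`, `genome`, `annotations`,
#'   `genotypes`, `phenotypes`, `counts`, `truth` and (if written) `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  pwms <- generate_pwm_library(config$n_pwms, config$pwm_length_range,
                               stage_seed(seed, 1L))
  truth <- plan_ground_truth(config, pwms, stage_seed(seed, 2L))
  gen <- generate_genome_with_promoters(config, pwms, truth, stage_seed(seed, 3L))
  genotypes <- generate_genotypes(config, gen$planted_snps, gen$genome,
                                  stage_seed(seed, 4L))
  phenotypes <- generate_phenotypes(genotypes, truth, config, stage_seed(seed, 5L))
  counts <- generate_expression(genotypes, truth, config, gen$annotations,
                                stage_seed(seed, 6L))
  out <- list(config = config, pwms = pwms, genome = gen$genome,
              annotations = gen$annotations, genotypes = genotypes,
              phenotypes = phenotypes, counts = counts, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      pwms = file.path(outdir, "pwms.transfac"),
      genome = file.path(outdir, "genome.fa"),
      gff = file.path(outdir, "genes.gff3"),
      vcf = file.path(outdir, "genotypes.vcf"),
      phenotypes = file.path(outdir, "phenotypes.tsv"),
      counts = file.path(outdir, "counts.tsv"),
      truth = file.path(outdir, "ground_truth.json"))
    write_transfac(pwms, paths$pwms)
    Biostrings::writeXStringSet(gen$genome, paths$genome)
    write_gff3(gen$annotations, paths$gff)
    write_vcf(genotypes, paths$vcf)
    write_phenotypes(phenotypes, paths$phenotypes)
    write_counts(counts, paths$counts)
    write_ground_truth(truth, paths$truth)
    out$paths <- paths
  }
  out
}
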