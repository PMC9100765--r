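# Phase 1: MAF handling, promoter windows, flanking pairs, consequence
# classification and rSNP identification.

test_that("compute_maf counts, folds and handles missing values", {
  expect_equal(compute_maf(rep(0, 5)), 0)
  expect_equal(compute_maf(c(rep(2, 3), rep(0, 7))), 0.3)
  expect_equal(compute_maf(c(rep(2, 8), rep(0, 2))), 0.2)  # folded from 0.8
  expect_equal(compute_maf(c(2, 2, NA, 0)), 1 / 3)          # NA excluded
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("MAF filtering keeps the boundary and drops below it", {
  d <- cbind(a = c(rep(2, 4), rep(0, 96)),    # maf 0.04
             b = c(rep(2, 5), rep(0, 95)),    # maf 0.05
             c = c(rep(2, 30), rep(0, 70)))   # maf 0.30
  g <- toy_geno(d)
  mafs <- apply(g$dosages, 2, compute_maf)
  expect_equal(unname(mafs), c(0.04, 0.05, 0.30))
  kept <- filter_snps_by_maf(g, 0.05)
  expect_setequal(colnames(kept$dosages), c("b", "c"))  # 0.05 boundary retained
  expect_equal(ncol(filter_snps_by_maf(g, 0)$dosages), 3)
  empty <- g
  empty$dosages <- g$dosages[, 0, drop = FALSE]
  empty$snps <- g$snps[0, ]
  expect_equal(ncol(filter_snps_by_maf(empty, 0.05)$dosages), 0)
})

test_that("promoter window is [-500, +100] in transcription direction", {
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(10000, 10000),
                    stringsAsFactors = FALSE)
  snps <- data.frame(id = sprintf("s%d", 1:8), chrom = "chr1",
                     pos = c(9500, 9499, 10100, 10101,   # plus-strand probes
                             10500, 10501, 9900, 9899),  # minus-strand probes
                     stringsAsFactors = FALSE)
  sel <- select_promoter_snps(snps, ann)
  plus <- sel$snp_id[sel$gene_id == "gp"]
  minus <- sel$snp_id[sel$gene_id == "gm"]
  expect_true(all(c("s1", "s3") %in% plus))        # offsets -500 and +100
  expect_false(any(c("s2", "s4") %in% plus))       # -501 and +101
  # minus strand: genomic [tss - 100, tss + 500]
  expect_true(all(c("s5", "s7") %in% minus))       # offsets -500 and +100
  expect_false(any(c("s6", "s8") %in% minus))
  bad <- ann; bad$strand <- c("+", "*")
  expect_warning(sel2 <- select_promoter_snps(snps, bad), "unknown strand")
  expect_false("gm" %in% sel2$gene_id)
})

test_that("flanking pairs are 51 bases with the SNP exactly central", {
  chars <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  chars[26] <- "A"
  genome <- Biostrings::DNAStringSet(structure(paste(chars, collapse = ""),
                                               names = "chr1"))
  snp <- data.frame(id = "s1", chrom = "chr1", pos = 26, ref = "A", alt = "T",
                    stringsAsFactors = FALSE)
  fp <- extract_allele_sequences(snp, genome)
  expect_equal(nchar(fp$ref_seq), 51)
  expect_equal(nchar(fp$alt_seq), 51)
  expect_equal(fp$snp_index, 26)
  expect_equal(fp$ref_seq, paste(chars[1:51], collapse = ""))
  expect_equal(substr(fp$alt_seq, 26, 26), "T")
  expect_equal(substr(fp$ref_seq, 26, 26), "A")
  # identical except at the centre
  expect_equal(substr(fp$ref_seq, 27, 51), substr(fp$alt_seq, 27, 51))
  expect_equal(substr(fp$ref_seq, 1, 25), substr(fp$alt_seq, 1, 25))
})

test_that("flanking extraction skips short context and catches ref mismatches", {
  chars <- rep("A", 100)
  genome <- Biostrings::DNAStringSet(structure(paste(chars, collapse = ""),
                                               names = "chr1"))
  near_edge <- data.frame(id = "s1", chrom = "chr1", pos = 10, ref = "A",
                          alt = "T", stringsAsFactors = FALSE)
  expect_warning(fp <- extract_allele_sequences(near_edge, genome), "context")
  expect_null(fp)
  mismatch <- data.frame(id = "s2", chrom = "chr1", pos = 50, ref = "G",
                         alt = "T", stringsAsFactors = FALSE)
  expect_error(extract_allele_sequences(mismatch, genome), "s2")
})

test_that("consequence classification follows the gain/loss definitions", {
  p <- sharp_pwm()
  make_pair <- function(ref_center, alt_center) {
    # plant the consensus so its 5th position sits at the window centre
    left <- paste0(strrep("C", 21), "ACGT")
    right <- paste0("CGT", strrep("C", 22))
    ref <- paste0(left, ref_center, right)
    alt <- paste0(left, alt_center, right)
    structure(list(snp_id = "s", ref_seq = ref, alt_seq = alt, snp_index = 26),
              class = "flanking_pair")
  }
  loss <- classify_consequence(make_pair("A", "C"), p)
  expect_equal(loss$effect, "Loss")
  gain <- classify_consequence(make_pair("C", "A"), p)
  expect_equal(gain$effect, "Gain")
  none <- classify_consequence(make_pair("C", "G"), p)
  expect_equal(none$effect, "NoStrongEffect")
})

test_that("classification is antisymmetric under allele swap", {
  set.seed(21)
  lib <- generate_pwm_library(4, c(7, 10), seed = 3)
  flip <- c(Gain = "Loss", Loss = "Gain", NoStrongEffect = "NoStrongEffect")
  for (rep in 1:20) {
    chars <- sample(c("A", "C", "G", "T"), 51, replace = TRUE)
    ref <- paste(chars, collapse = "")
    alt_chars <- chars
    alt_chars[26] <- sample(setdiff(c("A", "C", "G", "T"), chars[26]), 1)
    alt <- paste(alt_chars, collapse = "")
    pair <- structure(list(snp_id = "s", ref_seq = ref, alt_seq = alt,
                           snp_index = 26), class = "flanking_pair")
    swapped <- structure(list(snp_id = "s", ref_seq = alt, alt_seq = ref,
                              snp_index = 26), class = "flanking_pair")
    for (p in lib) {
      e1 <- classify_consequence(pair, p, 0.85, 0.8)$effect
      e2 <- classify_consequence(swapped, p, 0.85, 0.8)$effect
      expect_equal(e2, unname(flip[e1]))
    }
  }
})

test_that("hits whose span avoids the SNP score identically in both alleles", {
  set.seed(31)
  p <- sharp_pwm()
  L <- p$length
  for (rep in 1:10) {
    chars <- sample(c("A", "C", "G", "T"), 51, replace = TRUE)
    alt_chars <- chars
    alt_chars[26] <- sample(setdiff(c("A", "C", "G", "T"), chars[26]), 1)
    h_ref <- scan_sequence(paste(chars, collapse = ""), p, 0, 0)
    h_alt <- scan_sequence(paste(alt_chars, collapse = ""), p, 0, 0)
    # offsets (0-based) whose span [o, o+L-1] misses index 25
    away <- function(h) h[h$offset + L - 1 < 25 | h$offset > 25, ]
    a <- away(h_ref); b <- away(h_alt)
    expect_equal(a$mss, b$mss, tolerance = 1e-12)
    expect_equal(a$offset, b$offset)
  }
})

test_that("identify_rsnps recovers every planted gain/loss and only gain/loss", {
  sim <- simulate_dataset(small_sim_config())
  geno <- filter_snps_by_maf(sim$genotypes)
  cons <- identify_rsnps(geno, sim$genome, sim$annotations, sim$pwms)
  expect_true(all(cons$effect %in% c("Gain", "Loss")))
  planted <- sim$truth$planted_rsnps
  for (i in seq_len(nrow(planted))) {
    hit <- cons$snp == planted$snp[i] & cons$tf == planted$tf[i] &
      cons$effect == planted$effect[i]
    expect_true(any(hit),
                label = sprintf("planted %s/%s recovered", planted$snp[i],
                                planted$tf[i]))
  }
  # deterministic ordering by snp, gene, tf
  expect_false(is.unsorted(cons$snp))
  # empty library -> empty output
  empty <- identify_rsnps(geno, sim$genome, sim$annotations, list())
  expect_equal(nrow(empty), 0)
})
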