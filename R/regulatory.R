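# Phase 1: promoter SNP selection, allele-specific flanking sequences,
# PWM scanning, and Gain / Loss / NoStrongEffect classification.

#' Minor allele frequency from a dosage vector
#'
#' Computes the alternate-allele frequency p from 0/1/2 dosages (missing
#' values excluded from the denominator) and folds it to `min(p, 1 - p)`.
#'
#' @param dosages Integer/numeric vector of alternate-allele dosages in
#'   {0, 1, 2}, NA for missing.
#' @return Folded frequency in \[0, 0.5\].
#' @export
#' @examples
#' compute_maf(c(2, 2, 2, 0, 0, 0, 0, 0, 0, 0))  # 0.3
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages are missing")
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

#' Drop SNPs below a minor-allele-frequency floor
#'
#' Retains exactly the SNPs with MAF >= `floor`; the boundary is kept
#' because only variants strictly below the floor are discarded.
#'
#' @param genotypes A `geno_set` (see [read_vcf()] / [generate_genotypes()]).
#' @param floor MAF floor, default 0.05.
#' @return The filtered `geno_set`.
#' @export
filter_snps_by_maf <- function(genotypes, floor = 0.05) {
  stopifnot(inherits(genotypes, "geno_set"))
  mafs <- apply(genotypes$dosages, 2L, compute_maf)
  keep <- which(mafs >= floor)
  genotypes$snps <- genotypes$snps[genotypes$snps$id %in% colnames(genotypes$dosages)[keep], , drop = FALSE]
  genotypes$dosages <- genotypes$dosages[, keep, drop = FALSE]
  genotypes
}

#' Assign SNPs to gene promoter windows
#'
#' A SNP is assigned to a gene when its transcription-direction offset from
#' the TSS lies in `[-upstream, +downstream]`. On the minus strand this
#' maps to the genomic interval `[TSS - downstream, TSS + upstream]`. A SNP
#' may pair with several genes.
#'
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based).
#' @param annotations data.frame with columns `gene_id`, `chrom`, `strand`
#'   ("+" or "-") and `tss` (1-based genomic TSS coordinate).
#' @param upstream,downstream Window extent in bp (defaults 500 / 100).
#' @return data.frame with columns `snp_id`, `gene_id`, `offset`
#'   (transcription-direction offset, negative = upstream).
#' @export
select_promoter_snps <- function(snps, annotations, upstream = 500, downstream = 100) {
  bad <- !(annotations$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sprintf("%d annotation record(s) with unknown strand skipped", sum(bad)))
    annotations <- annotations[!bad, , drop = FALSE]
  }
  out <- vector("list", nrow(annotations))
  for (g in seq_len(nrow(annotations))) {
    ann <- annotations[g, ]
    on_chrom <- snps$chrom == ann$chrom
    offset <- if (ann$strand == "+") snps$pos - ann$tss else ann$tss - snps$pos
    hit <- on_chrom & offset >= -upstream & offset <= downstream
    if (any(hit))
      out[[g]] <- data.frame(snp_id = snps$id[hit], gene_id = ann$gene_id,
                             offset = offset[hit], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$snp_id, res$gene_id), , drop = FALSE]
}

#' Extract the allele-specific flanking sequence pair of a SNP
#'
#' Returns two copies of the +/- `flank` bp window centred on the SNP: one
#' carrying the reference allele and one the alternate. With the default
#' flank of 25 both sequences are 51 bases and the SNP sits at (1-based)
#' index 26.
#'
#' @param snp One-row data.frame (or list) with `id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param flank Flank size in bp (default 25).
#' @return List of class `flanking_pair` with `snp_id`, `ref_seq`,
#'   `alt_seq`, `snp_index`, or NULL (with a warning) when the SNP lacks
#'   context or the window contains ambiguous bases.
#' @export
extract_allele_sequences <- function(snp, genome, flank = 25) {
  if (!(snp$chrom %in% names(genome)))
    stop(sprintf("SNP %s: chromosome '%s' not in genome", snp$id, snp$chrom))
  chrom_seq <- genome[[snp$chrom]]
  n <- length(chrom_seq)
  if (snp$pos - flank < 1 || snp$pos + flank > n) {
    warning(sprintf("SNP %s skipped: fewer than %d bases of context", snp$id, flank))
    return(NULL)
  }
  win <- as.character(Biostrings::subseq(chrom_seq, snp$pos - flank, snp$pos + flank))
  idx <- flank + 1L
  genome_base <- substr(win, idx, idx)
  if (genome_base != snp$ref)
    stop(sprintf("SNP %s: genome base '%s' does not match VCF ref allele '%s'",
                 snp$id, genome_base, snp$ref))
  if (grepl("[^ACGT]", win)) {
    warning(sprintf("SNP %s skipped: ambiguous base in flanking window", snp$id))
    return(NULL)
  }
  alt_win <- win
  substr(alt_win, idx, idx) <- snp$alt
  structure(list(snp_id = snp$id, ref_seq = win, alt_seq = alt_win,
                 snp_index = idx), class = "flanking_pair")
}

#' Classify the regulatory consequence of a SNP for one TF
#'
#' A TF binding site counts as present when at least one hit passes both
#' score cutoffs anywhere in the 51-base window. The consequence is `Loss`
#' when only the reference-allele sequence contains a site, `Gain` when
#' only the alternate-allele sequence does, and `NoStrongEffect` otherwise.
#'
#' @param pair A `flanking_pair` from [extract_allele_sequences()].
#' @param pwm A `pwm` object.
#' @param mss_cutoff,core_cutoff Score cutoffs (defaults 0.95 / 0.90).
#' @return List with `effect` ("Gain", "Loss" or "NoStrongEffect"),
#'   `n_ref_hits`, `n_alt_hits`, `best_ref_mss`, `best_alt_mss`.
#' @export
classify_consequence <- function(pair, pwm, mss_cutoff = 0.95, core_cutoff = 0.90) {
  ref_codes <- encode_dna(pair$ref_seq)
  alt_codes <- encode_dna(pair$alt_seq)
  ref_hits <- scan_codes(ref_codes, pwm, mss_cutoff, core_cutoff)
  alt_hits <- scan_codes(alt_codes, pwm, mss_cutoff, core_cutoff)
  effect <- if (nrow(ref_hits) > 0 && nrow(alt_hits) == 0) "Loss"
    else if (nrow(ref_hits) == 0 && nrow(alt_hits) > 0) "Gain"
    else "NoStrongEffect"
  list(effect = effect, n_ref_hits = nrow(ref_hits), n_alt_hits = nrow(alt_hits),
       best_ref_mss = best_mss(ref_codes, pwm),
       best_alt_mss = best_mss(alt_codes, pwm))
}

#' Identify regulatory SNPs (Phase 1)
#'
#' Runs the full first phase: promoter-window SNP selection, allele-specific
#' flanking-sequence extraction, PWM scanning on both strands, and
#' consequence classification, keeping only SNPs with at least one Gain or
#' Loss of a TF binding site.
#'
#' @param genotypes A `geno_set`.
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param annotations Gene annotation data.frame (see
#'   [select_promoter_snps()]).
#' @param pwm_library List of `pwm` objects.
#' @param mss_cutoff,core_cutoff Score cutoffs (defaults 0.95 / 0.90).
#' @param upstream,downstream Promoter window extent (defaults 500 / 100).
#' @return data.frame of class `consequences` with columns `snp`, `gene`,
#'   `tf`, `effect` ("Gain"/"Loss" only), `best_ref_mss`, `best_alt_mss`,
#'   ordered by snp, gene, tf.
#' @export
identify_rsnps <- function(genotypes, genome, annotations, pwm_library,
                           mss_cutoff = 0.95, core_cutoff = 0.90,
                           upstream = 500, downstream = 100) {
  stopifnot(inherits(genotypes, "geno_set"))
  scorable <- vapply(pwm_library, is_scorable, TRUE)
  if (any(!scorable))
    warning(sprintf("%d unscorable PWM(s) excluded from scanning", sum(!scorable)))
  pwm_library <- pwm_library[scorable]
  empty <- data.frame(snp = character(0), gene = character(0), tf = character(0),
                      effect = character(0), best_ref_mss = numeric(0),
                      best_alt_mss = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("consequences", "data.frame")
  if (!length(pwm_library)) return(empty)
  pairs <- select_promoter_snps(genotypes$snps, annotations, upstream, downstream)
  if (!nrow(pairs)) return(empty)
  snp_ids <- unique(pairs$snp_id)
  snp_tab <- genotypes$snps[match(snp_ids, genotypes$snps$id), , drop = FALSE]
  flanks <- list()
  for (i in seq_len(nrow(snp_tab))) {
    fp <- extract_allele_sequences(snp_tab[i, ], genome)
    if (!is.null(fp)) flanks[[fp$snp_id]] <- fp
  }
  rows <- list()
  for (snp_id in names(flanks)) {
    fp <- flanks[[snp_id]]
    genes <- pairs$gene_id[pairs$snp_id == snp_id]
    per_tf <- lapply(pwm_library, function(p)
      classify_consequence(fp, p, mss_cutoff, core_cutoff))
    keep <- vapply(per_tf, function(x) x$effect != "NoStrongEffect", TRUE)
    if (!any(keep)) next
    for (tf in names(per_tf)[keep]) {
      cc <- per_tf[[tf]]
      for (g in genes)
        rows[[length(rows) + 1L]] <- data.frame(
          snp = snp_id, gene = g, tf = tf, effect = cc$effect,
          best_ref_mss = cc$best_ref_mss, best_alt_mss = cc$best_alt_mss,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$snp, res$gene, res$tf), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("consequences", "data.frame")
  res
}
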