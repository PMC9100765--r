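# Shared fixtures: tiny PWMs, genotype sets and simulation configs built
# in code at test time.

toy_pwm <- function(rows, name = "TOY") {
  pwm(name, matrix(rows, ncol = 4, byrow = TRUE))
}

# A sharply informative 8-mer whose consensus is ACGTACGT.
sharp_pwm <- function(name = "SHARP", dom = 0.91) {
  rest <- (1 - dom) / 3
  cons <- c(1, 2, 3, 4, 1, 2, 3, 4)
  rows <- t(vapply(cons, function(b) {
    r <- rep(rest, 4); r[b] <- dom; r
  }, numeric(4)))
  pwm(name, rows)
}

# Build a geno_set directly from a dosage matrix (lines x snps).
toy_geno <- function(dosages, chrom = "chr1", pos = NULL,
                     ref = "A", alt = "G") {
  n_snp <- ncol(dosages)
  if (is.null(colnames(dosages))) colnames(dosages) <- sprintf("s%03d", seq_len(n_snp))
  if (is.null(rownames(dosages))) rownames(dosages) <- sprintf("L%03d", seq_len(nrow(dosages)))
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n_snp)
  snps <- data.frame(id = colnames(dosages), chrom = chrom, pos = pos,
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  structure(list(snps = snps, dosages = dosages, lines = rownames(dosages)),
            class = "geno_set")
}

# Small but complete simulation for integration tests.
small_sim_config <- function(seed = 42) {
  sim_config(n_lines = 80, n_genes = 14, n_snps = 120, n_pwms = 6,
             n_planted_clusters = 2, phenotypes_per_cluster = 2,
             rsnps_per_cluster = 3, n_phenotypes = 6, seed = seed)
}

# Independent straight-line MCL fixed-point iteration used as oracle.
mcl_fixed_point_oracle <- function(A, inflation = 2) {
  A <- as.matrix(A)
  diag(A) <- 0
  sl <- apply(A, 1, max); sl[sl == 0] <- 1
  diag(A) <- sl
  M <- sweep(A, 2, colSums(A), "/")
  for (i in 1:1000) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, pmax(colSums(M2), 1e-300), "/")
    if (max(abs(M2 - M)) < 1e-12) { M <- M2; break }
    M <- M2
  }
  # clusters = connected components of the limit support
  supp <- (M > 1e-6) | t(M > 1e-6)
  n <- nrow(supp)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (supp[i, j] && lab[j] != lab[i]) {
        new <- min(lab[i], lab[j]); lab[lab == lab[i] | lab == lab[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ids <- rownames(A) %||% as.character(seq_len(n))
  unname(lapply(split(ids, lab), sort))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided rank-sum p-value by full enumeration of labelings.
wilcoxon_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= W), mean(ws >= W)))
}

as_cluster_sets <- function(clusters) {
  unname(lapply(clusters, sort))
}

expect_same_partition <- function(a, b) {
  expect_setequal(vapply(as_cluster_sets(a), paste, "", collapse = ","),
                  vapply(as_cluster_sets(b), paste, "", collapse = ","))
}
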