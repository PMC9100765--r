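# Phase 4: normalization, allele splits, Wilcoxon test, expression
# validation and hierarchical network models.

test_that("median-of-ratios reproduces hand-computed size factors", {
  m1 <- matrix(c(10, 100, 30, 10, 100, 30), 3, 2)
  expect_equal(unname(median_of_ratios(m1)$size_factors), c(1, 1))
  m2 <- cbind(a = c(10, 100, 30), b = 2 * c(10, 100, 30))
  sf <- median_of_ratios(m2)$size_factors
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  norm <- median_of_ratios(m2)$normalized
  expect_equal(norm[, "a"] * sqrt(2), norm[, "b"] / sqrt(2) * 2,
               tolerance = 1e-12)
})

test_that("genes containing zeros are excluded from the size-factor median", {
  # the zero-containing gene would drag column-2's median far from sqrt(2)
  m <- rbind(c(10, 20), c(100, 200), c(30, 60), c(0, 5000))
  sf <- median_of_ratios(m)$size_factors
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  all_zero <- rbind(c(0, 1), c(2, 0))
  expect_error(median_of_ratios(all_zero), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(14)
  m <- matrix(rnbinom(200 * 8, mu = 150, size = 5), 200, 8) + 1
  sf <- median_of_ratios(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # DESeq2 interpolates the even-count median on the log scale, this
  # implementation on the ratio scale: agreement to ~1e-4, not machine eps
  expect_equal(unname(sf), unname(ref), tolerance = 1e-3)
})

test_that("allele splits follow dosage groups and the het flag", {
  d <- c(L1 = 0, L2 = 0, L3 = 2, L4 = 2, L5 = 1)
  g <- split_lines_by_allele(d, min_n = 2)
  expect_setequal(g$ref, c("L1", "L2"))
  expect_setequal(g$alt, c("L3", "L4"))           # heterozygote excluded
  g2 <- split_lines_by_allele(d, het = "alt", min_n = 2)
  expect_setequal(g2$alt, c("L3", "L4", "L5"))
  g3 <- split_lines_by_allele(c(a = 0, b = 0, c = 0, d = 0))
  expect_false(g3$ok)                             # empty alternate group
  expect_match(g3$reason, "too small")
})

test_that("Wilcoxon worked example and degenerate cases", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p.value, 0.1)                    # 2 of 20 labelings as extreme
  expect_equal(w$statistic, 6)
  expect_equal(w$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_gte(same$p.value, 0.99)
})

test_that("exact Wilcoxon matches enumeration and the stats reference", {
  set.seed(15)
  for (rep in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- runif(n1); y <- runif(n2)
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p.value, wilcoxon_enumeration_oracle(x, y),
                 tolerance = 1e-12)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact tail at moderate sizes", {
  set.seed(16)
  for (rep in 1:10) {
    x <- rnorm(10); y <- rnorm(10, mean = runif(1, 0, 1.5))
    approx_p <- wilcoxon_rank_sum(c(x, 0.123456), y)  # n1 = 11 forces normal path
    exact_p <- stats::wilcox.test(c(x, 0.123456), y, exact = TRUE)$p.value
    expect_equal(approx_p$method, "normal")
    expect_lt(abs(approx_p$p.value - exact_p), 0.02)
  }
})

make_validation_fixture <- function(shift = 3, n = 60, seed = 17) {
  set.seed(seed)
  lines <- sprintf("L%03d", 1:n)
  dos <- cbind(r1 = rep(c(0L, 2L), each = n / 2),
               r2 = rep(c(0L, 2L), times = n / 2))
  rownames(dos) <- lines
  geno <- toy_geno(dos)
  expr <- rbind(g1 = exp(rnorm(n) + shift * (dos[, "r1"] / 2)),
                g2 = exp(rnorm(n)))
  colnames(expr) <- lines
  cons <- data.frame(snp = c("r1", "r2"), gene = c("g1", "g2"),
                     tf = c("M1", "M2"), effect = c("Gain", "Loss"),
                     stringsAsFactors = FALSE)
  class(cons) <- c("consequences", "data.frame")
  list(geno = geno, expr = expr, cons = cons,
       clusters = structure(list(c("r1", "r2")), class = "mcl_clusters"))
}

test_that("expression validation flags planted shifts with the right direction", {
  fx <- make_validation_fixture()
  val <- validate_expression(fx$clusters, fx$cons, fx$geno, fx$expr)
  expect_equal(nrow(val), 2)
  v1 <- val[val$snp == "r1", ]
  expect_true(v1$significant)
  expect_equal(v1$direction, "up")
  expect_true(v1$p_value < 0.05)
  # direction invariant under positive scaling of expression
  val_scaled <- validate_expression(fx$clusters, fx$cons, fx$geno, 1000 * fx$expr)
  expect_equal(val$direction, val_scaled$direction)
  expect_equal(val$p_value, val_scaled$p_value, tolerance = 1e-12)
})

test_that("expression validation skips missing genes and small groups", {
  fx <- make_validation_fixture()
  expr_missing <- fx$expr["g1", , drop = FALSE]
  expect_warning(val <- validate_expression(fx$clusters, fx$cons, fx$geno,
                                            expr_missing), "absent")
  expect_equal(val$snp, "r1")
  geno_mono <- fx$geno
  geno_mono$dosages[, "r2"] <- 0L
  expect_warning(val2 <- validate_expression(fx$clusters, fx$cons, geno_mono,
                                             fx$expr), "too small")
  expect_false("r2" %in% val2$snp)
})

test_that("BH adjustment is applied across validation records when requested", {
  fx <- make_validation_fixture()
  raw <- validate_expression(fx$clusters, fx$cons, fx$geno, fx$expr)
  bh <- validate_expression(fx$clusters, fx$cons, fx$geno, fx$expr,
                            adjust = "BH")
  expect_equal(raw$p_value, bh$p_value)
  expect_equal(bh$significant,
               stats::p.adjust(raw$p_value, "BH") < 0.05)
})

network_fixture <- function() {
  cons <- data.frame(
    snp = c("r1", "r1", "r1", "r2", "r3"),
    gene = c("g1", "g1", "g1", "g2", "g3"),
    tf = c("M1", "M2", "M3", "M1", "M4"),
    effect = c("Loss", "Loss", "Gain", "Gain", "Loss"),
    stringsAsFactors = FALSE)
  class(cons) <- c("consequences", "data.frame")
  sets <- list(P1 = c("r1", "r2", "r3"), P2 = c("r1", "r2"), P3 = c("r3"))
  list(cons = cons, sets = sets)
}

test_that("hierarchical networks are tripartite with labeled TF edges", {
  fx <- network_fixture()
  nw <- build_hierarchical_network(c("r1", "r2", "r3"), fx$cons, fx$sets,
                                   cluster_id = 1)
  expect_s3_class(nw, "hier_network")
  expect_equal(nrow(nw$rsnps), 3)
  expect_setequal(nw$tfs, c("M1", "M2", "M3", "M4"))
  expect_setequal(nw$phenotypes, c("P1", "P2", "P3"))
  # r1 has three labeled layer-1 edges: Loss, Loss, Gain
  r1_edges <- nw$tf_edges[nw$tf_edges$snp == "r1", ]
  expect_equal(sort(r1_edges$effect), c("Gain", "Loss", "Loss"))
  # tripartite: every edge joins adjacent layers only
  expect_true(all(nw$tf_edges$tf %in% nw$tfs))
  expect_true(all(nw$tf_edges$snp %in% nw$rsnps$snp))
  expect_true(all(nw$ph_edges$snp %in% nw$rsnps$snp))
  expect_true(all(nw$ph_edges$phenotype %in% nw$phenotypes))
  # every layer-2 node touches both adjacent layers
  expect_setequal(unique(nw$tf_edges$snp), nw$rsnps$snp)
  expect_setequal(unique(nw$ph_edges$snp), nw$rsnps$snp)
  g <- as_igraph(nw)
  expect_equal(igraph::vcount(g), 4 + 3 + 3)
  # an rSNP without TF consequences cannot occupy layer 2
  sets2 <- c(fx$sets, list(P9 = "r9"))
  expect_warning(nw2 <- build_hierarchical_network(c("r1", "r9"), fx$cons, sets2),
                 "excluded")
  expect_false("r9" %in% nw2$rsnps$snp)
  empty <- build_hierarchical_network(character(0), fx$cons, fx$sets)
  expect_equal(nrow(empty$rsnps), 0)
})

test_that("expression pruning removes non-significant rSNPs and orphans", {
  fx <- network_fixture()
  nw <- build_hierarchical_network(c("r1", "r2", "r3"), fx$cons, fx$sets)
  val_all <- data.frame(snp = c("r1", "r2", "r3"), significant = TRUE)
  expect_equal(prune_network_by_expression(nw, val_all)$rsnps, nw$rsnps)
  val_partial <- data.frame(snp = c("r1", "r2", "r3"),
                            significant = c(TRUE, TRUE, FALSE))
  pruned <- prune_network_by_expression(nw, val_partial)
  expect_setequal(pruned$rsnps$snp, c("r1", "r2"))
  expect_false("M4" %in% pruned$tfs)              # orphaned TF removed
  expect_false("P3" %in% pruned$phenotypes)       # orphaned phenotype removed
  # tripartite invariant still holds after pruning
  expect_true(all(pruned$tf_edges$snp %in% pruned$rsnps$snp))
  expect_true(all(pruned$ph_edges$snp %in% pruned$rsnps$snp))
  none <- prune_network_by_expression(nw, data.frame(snp = character(0),
                                                     significant = logical(0)))
  expect_equal(nrow(none$rsnps), 0)
  expect_length(none$tfs, 0)
})
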