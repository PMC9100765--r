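# Phase 4: median-of-ratios normalization, allele-split Wilcoxon
# expression validation, and three-layer TF -> rSNP(gene) -> phenotype
# network models with expression-based pruning.

#' Median-of-ratios normalization
#'
#' Computes per-sample size factors as the median, over genes with
#' all-positive counts, of the ratio of the count to the gene's geometric
#' mean across samples, then divides each column by its factor.
#'
#' @param counts Nonnegative numeric matrix, genes x samples.
#' @return List with `size_factors` (per sample) and `normalized` (matrix
#'   of the same shape).
#' @export
#' @examples
#' m <- matrix(c(10, 100, 20, 200), 2, 2)   # column 2 = 2 x column 1
#' median_of_ratios(m)$size_factors          # 1/sqrt(2), sqrt(2)
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene with all-positive counts: size factors undefined")
  logc <- log(counts[pos, , drop = FALSE])
  log_geomean <- rowMeans(logc)
  size_factors <- apply(exp(logc - log_geomean), 2L, stats::median)
  list(size_factors = size_factors,
       normalized = sweep(counts, 2L, size_factors, `/`))
}

#' Split lines into reference and alternate allele groups
#'
#' Reference group = dosage 0, alternate group = dosage 2; heterozygotes
#' and missing calls are excluded by default (`het = "alt"` pools dosage-1
#' lines with the alternate group, mirroring the inbred-panel design where
#' heterozygotes are rare).
#'
#' @param dosages Named (by line) dosage vector in {0, 1, 2, NA}.
#' @param het Either "exclude" (default) or "alt".
#' @param min_n Minimum size required of each group (default 3).
#' @return List with `ref`, `alt` (line names), `ok` (logical) and
#'   `reason` (string when not ok).
#' @export
split_lines_by_allele <- function(dosages, het = c("exclude", "alt"), min_n = 3) {
  het <- match.arg(het)
  ref <- names(dosages)[!is.na(dosages) & dosages == 0]
  alt_d <- if (het == "alt") c(1, 2) else 2
  alt <- names(dosages)[!is.na(dosages) & dosages %in% alt_d]
  ok <- length(ref) >= min_n && length(alt) >= min_n
  list(ref = ref, alt = alt, ok = ok,
       reason = if (ok) NA_character_ else
         sprintf("group too small (ref %d, alt %d, need >= %d)",
                 length(ref), length(alt), min_n))
}

#' Wilcoxon rank-sum test
#'
#' Computes the rank-sum statistic of `x` on pooled mid-ranks. The
#' two-sided p-value is exact (from the null rank-sum distribution) when
#' both samples have at most 10 observations and there are no ties;
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x,y Numeric samples (each nonempty).
#' @return List with `statistic` (rank sum of `x`), `p.value`, and
#'   `method` ("exact" or "normal").
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  has_ties <- anyDuplicated(pooled) > 0
  U <- W - n1 * (n1 + 1) / 2
  if (n1 <= 10 && n2 <= 10 && !has_ties) {
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = W, p.value = 1, method = "normal"))
    z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
    if (U == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p.value = p, method = method)
}

#' Allele-split expression validation of pleiotropic rSNPs
#'
#' For every (rSNP, gene) pair with a Gain/Loss consequence where the rSNP
#' belongs to a cluster, splits the lines by allele and compares the
#' gene's normalized expression between the groups with the Wilcoxon
#' rank-sum test. Direction is that of the alternate-group median relative
#' to the reference group.
#'
#' @param clusters Cluster list (pleiotropy-pruned).
#' @param consequences A `consequences` data.frame.
#' @param genotypes A `geno_set`.
#' @param expression Normalized expression matrix, genes x lines.
#' @param alpha Significance level (default 0.05).
#' @param adjust "none" (default, raw p < alpha) or "BH"
#'   (Benjamini-Hochberg across all records).
#' @param het,min_n Forwarded to [split_lines_by_allele()].
#' @return data.frame of class `expression_validation` with columns `snp`,
#'   `gene`, `n_ref`, `n_alt`, `statistic`, `p_value`, `direction`
#'   ("up"/"down"), `significant`.
#' @export
validate_expression <- function(clusters, consequences, genotypes, expression,
                                alpha = 0.05, adjust = c("none", "BH"),
                                het = "exclude", min_n = 3) {
  adjust <- match.arg(adjust)
  cluster_snps <- unique(unlist(clusters, use.names = FALSE))
  pairs <- unique(consequences[consequences$snp %in% cluster_snps,
                               c("snp", "gene"), drop = FALSE])
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    snp <- pairs$snp[i]; gene <- pairs$gene[i]
    if (!(gene %in% rownames(expression))) {
      warning(sprintf("gene %s absent from expression matrix; record skipped", gene))
      next
    }
    d <- genotypes$dosages[, snp]
    grp <- split_lines_by_allele(d, het = het, min_n = min_n)
    if (!grp$ok) {
      warning(sprintf("rSNP %s: %s; validation skipped", snp, grp$reason))
      next
    }
    ev <- expression[gene, ]
    wt <- wilcoxon_rank_sum(ev[grp$ref], ev[grp$alt])
    dir <- if (stats::median(ev[grp$alt]) >= stats::median(ev[grp$ref]))
      "up" else "down"
    rows[[length(rows) + 1L]] <- data.frame(
      snp = snp, gene = gene, n_ref = length(grp$ref), n_alt = length(grp$alt),
      statistic = wt$statistic, p_value = wt$p.value, direction = dir,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(0), gene = character(0), n_ref = integer(0),
               n_alt = integer(0), statistic = numeric(0), p_value = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  p_use <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$significant <- p_use < alpha
  rownames(res) <- NULL
  class(res) <- c("expression_validation", "data.frame")
  res
}

#' Build a three-layer TF -> rSNP(gene) -> phenotype network
#'
#' Layer 1 holds the TFs whose binding sites are gained or lost, layer 2
#' the cluster's rSNPs (annotated with their genes), layer 3 the
#' phenotypes from the optimal sets; edges exist only between adjacent
#' layers. rSNPs lacking either a TF consequence or a phenotype
#' association cannot occupy layer 2 and are excluded with a warning.
#'
#' @param cluster Character vector of rSNP ids (already pleiotropy-pruned).
#' @param consequences A `consequences` data.frame.
#' @param optimal_sets Named list (phenotype -> rSNP ids).
#' @param cluster_id Optional identifier stored on the network.
#' @return Object of class `hier_network` with elements `cluster_id`,
#'   `tfs`, `rsnps` (data.frame snp, gene), `phenotypes`, `tf_edges`
#'   (tf, snp, effect), `ph_edges` (snp, phenotype).
#' @export
build_hierarchical_network <- function(cluster, consequences, optimal_sets,
                                       cluster_id = NULL) {
  tf_edges <- consequences[consequences$snp %in% cluster &
                             consequences$effect %in% c("Gain", "Loss"),
                           c("tf", "snp", "effect"), drop = FALSE]
  tf_edges <- unique(tf_edges)
  ph_rows <- list()
  for (ph in names(optimal_sets)) {
    hit <- intersect(optimal_sets[[ph]], cluster)
    if (length(hit))
      ph_rows[[ph]] <- data.frame(snp = hit, phenotype = ph,
                                  stringsAsFactors = FALSE)
  }
  ph_edges <- if (length(ph_rows)) do.call(rbind, ph_rows) else
    data.frame(snp = character(0), phenotype = character(0),
               stringsAsFactors = FALSE)
  ok_snps <- intersect(unique(tf_edges$snp), unique(ph_edges$snp))
  dropped <- setdiff(cluster, ok_snps)
  if (length(dropped))
    warning(sprintf("rSNP(s) without both TF and phenotype edges excluded: %s",
                    paste(dropped, collapse = ", ")))
  tf_edges <- tf_edges[tf_edges$snp %in% ok_snps, , drop = FALSE]
  ph_edges <- ph_edges[ph_edges$snp %in% ok_snps, , drop = FALSE]
  snp_gene <- unique(consequences[consequences$snp %in% ok_snps,
                                  c("snp", "gene"), drop = FALSE])
  rownames(tf_edges) <- rownames(ph_edges) <- rownames(snp_gene) <- NULL
  structure(list(cluster_id = cluster_id,
                 tfs = sort(unique(tf_edges$tf)),
                 rsnps = snp_gene[order(snp_gene$snp), , drop = FALSE],
                 phenotypes = sort(unique(ph_edges$phenotype)),
                 tf_edges = tf_edges, ph_edges = ph_edges),
            class = "hier_network")
}

#' Prune a hierarchical network by expression validation
#'
#' Removes layer-2 rSNP nodes (and their edges) lacking a significant
#' allele-split expression validation, then drops layer-1 TFs and layer-3
#' phenotypes left without edges. rSNPs absent from the validation table
#' are treated as non-significant.
#'
#' @param network A `hier_network`.
#' @param validations An `expression_validation` data.frame.
#' @return The pruned `hier_network`.
#' @export
prune_network_by_expression <- function(network, validations) {
  sig_snps <- unique(validations$snp[validations$significant])
  keep <- intersect(network$rsnps$snp, sig_snps)
  network$tf_edges <- network$tf_edges[network$tf_edges$snp %in% keep, , drop = FALSE]
  network$ph_edges <- network$ph_edges[network$ph_edges$snp %in% keep, , drop = FALSE]
  network$rsnps <- network$rsnps[network$rsnps$snp %in% keep, , drop = FALSE]
  network$tfs <- sort(unique(network$tf_edges$tf))
  network$phenotypes <- sort(unique(network$ph_edges$phenotype))
  network
}

#' Convert a hierarchical network to an igraph object
#'
#' Nodes carry a `layer` attribute ("tf", "rsnp", "phenotype") and rSNP
#' nodes a `gene` attribute; TF edges carry their Gain/Loss label.
#'
#' @param network A `hier_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "hier_network"))
  snps <- network$rsnps$snp
  nodes <- data.frame(
    name = c(network$tfs, snps, network$phenotypes),
    layer = c(rep("tf", length(network$tfs)), rep("rsnp", length(snps)),
              rep("phenotype", length(network$phenotypes))),
    gene = c(rep(NA_character_, length(network$tfs)), network$rsnps$gene,
             rep(NA_character_, length(network$phenotypes))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = network$tf_edges$tf, to = network$tf_edges$snp,
               label = network$tf_edges$effect, stringsAsFactors = FALSE),
    data.frame(from = network$ph_edges$snp, to = network$ph_edges$phenotype,
               label = "association", stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Print method for hierarchical networks
#' @param x A `hier_network`.
#' @param ... Ignored.
#' @export
print.hier_network <- function(x, ...) {
  cat(sprintf("Hierarchical network%s: %d TF(s) -> %d rSNP(s)/%d gene(s) -> %d phenotype(s)\n",
              if (is.null(x$cluster_id)) "" else paste0(" [cluster ", x$cluster_id, "]"),
              length(x$tfs), nrow(x$rsnps), length(unique(x$rsnps$gene)),
              length(x$phenotypes)))
  invisible(x)
}
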