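# Phase 3: binary rSNP profile matrix over phenotypes and TFs,
# Proportional Similarity Index association matrix, Markov clustering,
# and single-phenotype pruning.

#' Build the binary rSNP profile matrix
#'
#' Rows are rSNPs appearing in at least one phenotype's optimal set;
#' columns are phenotype names followed by TF names (each block
#' lexicographic). An entry is 1 in a phenotype column when the rSNP
#' belongs to that phenotype's optimal set, and 1 in a TF column when the
#' rSNP has a Gain or Loss consequence for that TF.
#'
#' @param optimal_sets Named list (phenotype -> character vector of rSNP
#'   ids), e.g. from [associate_all()].
#' @param consequences A `consequences` data.frame from [identify_rsnps()].
#' @return Binary matrix of class `profile_matrix` with attribute
#'   `col_type` ("phenotype"/"tf" per column).
#' @export
build_profile_matrix <- function(optimal_sets, consequences) {
  rsnps <- sort(unique(unlist(optimal_sets, use.names = FALSE)))
  phen <- sort(names(optimal_sets))
  tfs <- sort(unique(consequences$tf))
  M <- matrix(0L, length(rsnps), length(phen) + length(tfs),
              dimnames = list(rsnps, c(phen, tfs)))
  for (ph in phen) M[intersect(optimal_sets[[ph]], rsnps), ph] <- 1L
  cons <- consequences[consequences$effect %in% c("Gain", "Loss") &
                         consequences$snp %in% rsnps, , drop = FALSE]
  if (nrow(cons)) M[cbind(cons$snp, cons$tf)] <- 1L
  attr(M, "col_type") <- c(rep("phenotype", length(phen)), rep("tf", length(tfs)))
  class(M) <- c("profile_matrix", class(M))
  M
}

#' Proportional Similarity Index between two profile rows
#'
#' `2 * sum(min(x, y)) / sum(x + y)`, a \[0, 1\] overlap measure; defined
#' as 0 when both rows are all zero (0/0 case).
#'
#' @param row_k,row_l Equal-length nonnegative numeric vectors.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' psi(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
psi <- function(row_k, row_l) {
  if (length(row_k) != length(row_l)) stop("rows must have equal length")
  s <- sum(row_k + row_l)
  if (s == 0) return(0)
  2 * sum(pmin(row_k, row_l)) / s
}

#' PSI association matrix of a profile matrix
#'
#' Computes all pairwise Proportional Similarity Index values between the
#' rows of a binary profile matrix. Symmetric, with unit diagonal for rows
#' with at least one nonzero entry and zero rows yielding zero everywhere.
#'
#' @param M Binary matrix (rows = rSNPs).
#' @return n x n numeric matrix of class `assoc_matrix`.
#' @export
psi_matrix <- function(M) {
  M <- unclass(M)
  if (!all(M %in% c(0, 1))) stop("profile matrix entries must be 0/1")
  storage.mode(M) <- "double"
  cross <- tcrossprod(M)                 # sum_j min(Mkj, Mlj) for binary rows
  r <- rowSums(M)
  denom <- outer(r, r, `+`)
  A <- 2 * cross / denom
  A[denom == 0] <- 0
  dimnames(A) <- list(rownames(M), rownames(M))
  class(A) <- c("assoc_matrix", class(A))
  A
}

#' Markov clustering of a similarity matrix
#'
#' Adds self-loops equal to each row's maximum, column-normalizes to a
#' stochastic matrix, and alternates expansion (matrix power) with
#' inflation (entrywise power followed by renormalization), pruning
#' entries below `prune_eps`, until the maximum column-wise change drops
#' below `tol` or `max_iter` is reached. Rows of the limit with positive
#' diagonal mass are attractors; every node joins the attractor holding
#' the largest limit weight in its column (ties to the lexicographically
#' smallest attractor) and overlapping attractor systems are merged.
#'
#' @param A Square, symmetric, nonnegative similarity matrix with row
#'   names.
#' @param inflation Inflation exponent (default 2).
#' @param expansion Expansion power (default 2).
#' @param max_iter Iteration limit (default 200).
#' @param tol Convergence tolerance on the max absolute change.
#' @param prune_eps Entries below this are zeroed each iteration.
#' @return List of character vectors (clusters, size-descending) of class
#'   `mcl_clusters`, with attributes `converged` and `iterations`.
#' @export
mcl <- function(A, inflation = 2.0, expansion = 2, max_iter = 200,
                tol = 1e-8, prune_eps = 1e-6) {
  A <- unclass(as.matrix(A))
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (any(A < 0)) stop("A must be nonnegative")
  if (is.null(rownames(A))) rownames(A) <- colnames(A) <- as.character(seq_len(nrow(A)))
  ids <- rownames(A)
  n <- nrow(A)
  if (n == 1L) {
    out <- list(ids)
    return(structure(out, class = "mcl_clusters", converged = TRUE, iterations = 0L))
  }
  diag(A) <- 0
  loops <- apply(A, 1L, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- normalize_cols(A)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune_eps] <- 0
    Mnew <- normalize_cols(Minf)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations", max_iter))
  clusters <- interpret_mcl_limit(M, ids, prune_eps)
  structure(clusters, class = "mcl_clusters", converged = converged,
            iterations = it)
}

normalize_cols <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2L, cs, `/`)
}

# Attractor interpretation of the MCL limit matrix.
interpret_mcl_limit <- function(M, ids, eps) {
  n <- length(ids)
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate fallback
  # assign each node to the attractor with largest limit weight in its column
  assign_attr <- integer(n)
  for (j in seq_len(n)) {
    w <- M[attractors, j]
    best <- max(w)
    if (best <= eps && j %in% attractors) {
      assign_attr[j] <- j
    } else {
      cand <- attractors[w >= best - 1e-15]
      assign_attr[j] <- min(cand)                   # lexicographically smallest
    }
  }
  # merge overlapping attractor systems: attractors connected through the
  # limit matrix support belong to one cluster
  B <- M[attractors, attractors, drop = FALSE] > eps
  att_graph <- igraph::graph_from_adjacency_matrix((B | t(B)) * 1,
                                                   mode = "undirected",
                                                   diag = FALSE)
  comp <- igraph::components(att_graph)$membership
  names(comp) <- as.character(attractors)
  cluster_of <- comp[as.character(assign_attr)]
  groups <- split(ids, cluster_of)
  groups <- lapply(groups, function(g) sort(g))
  ord <- order(-vapply(groups, length, 0L),
               vapply(groups, function(g) g[1L], ""))
  unname(groups[ord])
}

#' Remove rSNPs associated with fewer than two phenotypes
#'
#' Pleiotropy requires at least two phenotype associations: any rSNP whose
#' profile row has fewer than two ones among the phenotype columns (TF
#' columns are ignored) is removed from every cluster, and emptied
#' clusters are dropped.
#'
#' @param clusters An `mcl_clusters` list (or plain list of id vectors).
#' @param M A `profile_matrix`.
#' @return Pruned cluster list of class `mcl_clusters`.
#' @export
prune_non_pleiotropic <- function(clusters, M) {
  phen_cols <- attr(M, "col_type") == "phenotype"
  counts <- rowSums(unclass(M)[, phen_cols, drop = FALSE])
  keep_ids <- rownames(M)[counts >= 2]
  pruned <- lapply(clusters, function(g) intersect(g, keep_ids))
  pruned <- pruned[vapply(pruned, length, 0L) > 0]
  structure(pruned, class = "mcl_clusters",
            converged = attr(clusters, "converged"),
            iterations = attr(clusters, "iterations"))
}

#' Summarize clusters
#'
#' One row per cluster with its rSNP count, the number of distinct genes
#' its rSNPs sit in, and the union of associated phenotypes; ordered by
#' cluster size descending (ties by first member id).
#'
#' @param clusters Cluster list.
#' @param M A `profile_matrix`.
#' @param consequences A `consequences` data.frame (maps rSNPs to genes).
#' @return data.frame with columns `cluster`, `n_rsnps`, `n_genes`,
#'   `phenotypes` (comma-separated union).
#' @export
cluster_summary <- function(clusters, M, consequences) {
  if (!length(clusters))
    return(data.frame(cluster = integer(0), n_rsnps = integer(0),
                      n_genes = integer(0), phenotypes = character(0),
                      stringsAsFactors = FALSE))
  phen_cols <- which(attr(M, "col_type") == "phenotype")
  ord <- order(-vapply(clusters, length, 0L),
               vapply(clusters, function(g) sort(g)[1L], ""))
  clusters <- clusters[ord]
  rows <- lapply(seq_along(clusters), function(k) {
    g <- clusters[[k]]
    genes <- unique(consequences$gene[consequences$snp %in% g])
    sub <- unclass(M)[intersect(g, rownames(M)), phen_cols, drop = FALSE]
    phs <- colnames(sub)[colSums(sub) > 0]
    data.frame(cluster = k, n_rsnps = length(g), n_genes = length(genes),
               phenotypes = paste(phs, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Print method for MCL cluster sets
#' @param x An `mcl_clusters` object.
#' @param ... Ignored.
#' @export
print.mcl_clusters <- function(x, ...) {
  cat(sprintf("MCL clustering: %d cluster(s), %d node(s)%s\n",
              length(x), length(unlist(x)),
              if (isTRUE(attr(x, "converged"))) "" else " [not converged]"))
  for (k in seq_along(x))
    cat(sprintf("  cluster %d (%d): %s\n", k, length(x[[k]]),
                paste(utils::head(x[[k]], 8L), collapse = ", ")))
  invisible(x)
}
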