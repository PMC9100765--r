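# Phase 2: dosage encoding, random-forest importance, Boruta-style shadow
# feature selection, and incremental feature selection on OOB R-squared.

#' Encode genotypes as a complete dosage feature matrix
#'
#' Builds the lines x rSNPs matrix of alternate-allele dosages (0/1/2)
#' restricted to `snp_ids`, imputing missing dosages by the per-SNP mode
#' (smallest dosage on ties). Columns are ordered by rSNP id.
#'
#' @param genotypes A `geno_set`.
#' @param snp_ids SNP ids to keep (default: all).
#' @return Numeric matrix with line rownames and rSNP colnames.
#' @export
encode_genotypes <- function(genotypes, snp_ids = NULL) {
  stopifnot(inherits(genotypes, "geno_set"))
  ids <- sort(snp_ids %||% colnames(genotypes$dosages))
  missing_ids <- setdiff(ids, colnames(genotypes$dosages))
  if (length(missing_ids))
    stop(sprintf("unknown SNP id(s): %s", paste(missing_ids, collapse = ", ")))
  X <- genotypes$dosages[, ids, drop = FALSE]
  all_na <- apply(X, 2L, function(v) all(is.na(v)))
  if (any(all_na)) {
    warning(sprintf("%d SNP(s) with all-missing dosages dropped", sum(all_na)))
    X <- X[, !all_na, drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (anyNA(v)) {
      tab <- table(v[!is.na(v)])
      mode_val <- as.numeric(names(tab)[which.max(tab)])  # first max: smallest dosage
      v[is.na(v)] <- mode_val
      X[, j] <- v
    }
  }
  storage.mode(X) <- "double"
  X
}

# Internal: seeded single-thread regression forest.
fit_rf <- function(X, y, n_trees, seed) {
  df <- as.data.frame(X)
  df$..y.. <- y
  ranger::ranger(dependent.variable.name = "..y..", data = df,
                 num.trees = n_trees, importance = "impurity",
                 seed = seed, num.threads = 1, respect.unordered.factors = FALSE)
}

#' Random-forest impurity importance
#'
#' Fits a regression forest and returns the impurity-based (variance
#' reduction) importances normalized to sum to 1. Deterministic for a
#' fixed seed (single thread).
#'
#' @param X Numeric feature matrix (>= 20 rows).
#' @param y Numeric response.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return Named nonnegative numeric vector summing to 1.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1) {
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) < 20) stop("need at least 20 observations")
  if (stats::var(y) == 0) stop("constant response: importance undefined")
  imp <- fit_rf(X, y, n_trees, seed)$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) {
    warning("all importances zero; returning uniform importances")
    imp[] <- 1
  }
  imp / sum(imp)
}

#' Boruta-style shadow-feature selection and ranking
#'
#' Each iteration appends a column-wise permuted shadow copy of every
#' feature still in play, fits a regression forest, and records a hit for
#' each undecided feature whose raw importance exceeds the maximum shadow
#' importance. After every iteration, hit counts are tested against
#' Binomial(iterations, 0.5) two-sided with Bonferroni correction over the
#' undecided features: significantly many hits confirms a feature,
#' significantly few rejects it (rejected features leave the model).
#' Features undecided at `max_iter` stay Tentative. All original features
#' are ranked by their median importance Z-score
#' `(importance - mean(shadow)) / sd(shadow)` across the iterations they
#' were active in (dense ranks, ties broken by feature id).
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response.
#' @param max_iter Maximum iterations (>= 10).
#' @param alpha Significance level of the binomial decision test.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return A `boruta_result`: data.frame with columns `feature`,
#'   `decision` (Confirmed/Tentative/Rejected), `median_z`, `hits`,
#'   `n_iter`, `rank`.
#' @export
boruta_rank <- function(X, y, max_iter = 100, alpha = 0.01, n_trees = 500,
                        seed = 1) {
  if (max_iter < 10) stop("max_iter must be >= 10")
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) < 20) stop("need at least 20 observations")
  if (stats::var(y) == 0) stop("constant response")
  set.seed(seed)
  features <- colnames(X)
  p <- length(features)
  decision <- stats::setNames(rep("Tentative", p), features)
  hits <- stats::setNames(rep(0L, p), features)
  n_active <- stats::setNames(rep(0L, p), features)
  zs <- stats::setNames(vector("list", p), features)
  active <- features
  for (iter in seq_len(max_iter)) {
    Xa <- X[, active, drop = FALSE]
    shadows <- apply(Xa, 2L, sample)
    colnames(shadows) <- paste0("shadow_", active)
    fit <- fit_rf(cbind(Xa, shadows), y, n_trees, seed = stage_seed(seed, iter))
    imp <- fit$variable.importance
    sh <- imp[paste0("shadow_", active)]
    sh_max <- max(sh); sh_mean <- mean(sh); sh_sd <- stats::sd(sh)
    if (is.na(sh_sd)) sh_sd <- 0
    for (f in active) {
      z <- if (sh_sd > 0) (imp[[f]] - sh_mean) / sh_sd else 0
      zs[[f]] <- c(zs[[f]], z)
      n_active[f] <- n_active[f] + 1L
    }
    undecided <- active[decision[active] == "Tentative"]
    hits[undecided] <- hits[undecided] +
      as.integer(imp[undecided] > sh_max)
    n_und <- length(undecided)
    for (f in undecided) {
      pv <- stats::binom.test(hits[[f]], n_active[[f]], 0.5)$p.value
      if (pv * n_und < alpha) {
        decision[f] <- if (hits[[f]] > n_active[[f]] / 2) "Confirmed" else "Rejected"
      }
    }
    active <- features[decision %in% c("Confirmed", "Tentative")]
    if (!any(decision == "Tentative")) break
  }
  median_z <- vapply(features, function(f)
    if (length(zs[[f]])) stats::median(zs[[f]]) else -Inf, 0)
  ord <- order(-median_z, features)
  rank <- integer(p); rank[ord] <- seq_len(p)
  res <- data.frame(feature = features, decision = unname(decision[features]),
                    median_z = unname(median_z), hits = unname(hits[features]),
                    n_iter = unname(n_active[features]), rank = rank,
                    stringsAsFactors = FALSE)
  res <- res[order(res$rank), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("boruta_result", "data.frame")
  res
}

#' Incremental feature selection curve
#'
#' Adds ranked features from best to worst in steps of `stride`, refits a
#' regression forest on each prefix, and records the out-of-bag R-squared.
#' The optimal feature count is the smallest k attaining the maximum
#' recorded R-squared.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response.
#' @param ranking Character vector of feature names, best first (e.g. the
#'   `feature` column of a [boruta_rank()] result).
#' @param k_max Largest prefix size (clipped to the ranking length with a
#'   warning).
#' @param stride Step between successive k values (default 1).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @param phenotype Optional phenotype label stored on the curve.
#' @return An `ifs_curve`: list with `phenotype`, `k`, `r2`, `optimal_k`,
#'   `max_r2`.
#' @export
ifs_curve <- function(X, y, ranking, k_max = length(ranking), stride = 1,
                      n_trees = 500, seed = 1, phenotype = NULL) {
  if (!all(ranking %in% colnames(X)))
    stop("ranking refers to features absent from X")
  if (k_max > length(ranking)) {
    warning("k_max exceeds the number of ranked features; clipped")
    k_max <- length(ranking)
  }
  ks <- seq(1L, k_max, by = stride)
  r2 <- vapply(ks, function(k) {
    fit <- fit_rf(X[, ranking[seq_len(k)], drop = FALSE], y, n_trees,
                  seed = stage_seed(seed, k))
    fit$r.squared
  }, 0)
  optimal_k <- ks[which(r2 == max(r2))[1L]]
  structure(list(phenotype = phenotype, k = ks, r2 = r2,
                 optimal_k = optimal_k, max_r2 = max(r2)),
            class = "ifs_curve")
}

#' Plot an IFS curve
#' @param x An `ifs_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ifs_curve <- function(x, ...) {
  graphics::plot(x$k, x$r2, type = "b", pch = 16,
                 xlab = "number of top-ranked rSNPs",
                 ylab = expression(OOB ~ R^2),
                 main = x$phenotype %||% "", ...)
  graphics::abline(v = x$optimal_k, lty = 2, col = "grey40")
  invisible(x)
}

#' Print method for IFS curves
#' @param x An `ifs_curve`.
#' @param ... Ignored.
#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("IFS curve%s: %d k values, optimal k = %d (R2 = %.3f)\n",
              if (is.null(x$phenotype)) "" else paste0(" [", x$phenotype, "]"),
              length(x$k), x$optimal_k, x$max_r2))
  invisible(x)
}

#' Rank and select optimal rSNP sets for every phenotype
#'
#' For each phenotype column (with at least 20 non-missing values), runs
#' [boruta_rank()] to order the rSNPs and [ifs_curve()] to pick the
#' optimal prefix; the optimal set is the top `optimal_k` ranked rSNPs.
#'
#' @param X Dosage feature matrix from [encode_genotypes()].
#' @param phenotypes Numeric matrix or data.frame, lines x phenotypes,
#'   rownames matching `rownames(X)`.
#' @param n_trees,max_iter,alpha,stride,k_max Tuning parameters forwarded
#'   to [boruta_rank()] and [ifs_curve()]; `k_max = NULL` uses all
#'   features.
#' @param seed Integer seed (per-phenotype substreams are derived from it).
#' @return An `assoc_result`: list with `optimal_sets` (named list of rSNP
#'   id vectors), `curves`, `rankings`, and a `summary` data.frame
#'   (phenotype, max_r2, n_rsnps).
#' @export
associate_all <- function(X, phenotypes, n_trees = 500, max_iter = 100,
                          alpha = 0.01, stride = 1, k_max = NULL, seed = 1) {
  phenotypes <- as.matrix(phenotypes)
  common <- intersect(rownames(X), rownames(phenotypes))
  if (!length(common)) stop("no common line ids between X and phenotypes")
  optimal_sets <- list(); curves <- list(); rankings <- list()
  summary_rows <- list()
  for (ph in colnames(phenotypes)) {
    y_full <- phenotypes[common, ph]
    ok <- !is.na(y_full)
    if (sum(ok) < 20) {
      warning(sprintf("phenotype '%s' skipped: fewer than 20 non-missing values", ph))
      next
    }
    Xp <- X[common[ok], , drop = FALSE]
    yp <- y_full[ok]
    ph_seed <- stage_seed(seed, 1000L + match(ph, colnames(phenotypes)))
    br <- boruta_rank(Xp, yp, max_iter = max_iter, alpha = alpha,
                      n_trees = n_trees, seed = ph_seed)
    # Boruta is the gatekeeper: the IFS prefix search runs over the full
    # median-Z ranking but only as deep as the features Boruta did not
    # reject, and a phenotype with no Confirmed feature (or no positive
    # out-of-bag R2) has no credible associated set at all.
    n_keep <- sum(br$decision != "Rejected")
    km <- k_max %||% max(1L, n_keep)
    km <- min(km, nrow(br))
    cv <- ifs_curve(Xp, yp, br$feature, k_max = km, stride = stride,
                    n_trees = n_trees, seed = ph_seed, phenotype = ph)
    opt <- if (n_keep > 0 && any(br$decision == "Confirmed") && cv$max_r2 > 0)
      br$feature[seq_len(cv$optimal_k)] else character(0)
    optimal_sets[[ph]] <- opt
    curves[[ph]] <- cv
    rankings[[ph]] <- br
    summary_rows[[ph]] <- data.frame(phenotype = ph, max_r2 = cv$max_r2,
                                     n_rsnps = length(opt),
                                     stringsAsFactors = FALSE)
  }
  summary_df <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(phenotype = character(0), max_r2 = numeric(0),
               n_rsnps = integer(0), stringsAsFactors = FALSE)
  rownames(summary_df) <- NULL
  structure(list(optimal_sets = optimal_sets, curves = curves,
                 rankings = rankings, summary = summary_df),
            class = "assoc_result")
}

#' Print method for association results
#' @param x An `assoc_result`.
#' @param ... Ignored.
#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Phenotype associations: %d phenotype(s)\n", nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
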