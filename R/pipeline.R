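# End-to-end orchestration of the four phases plus run manifest and
# ground-truth recovery metrics.

#' Default pipeline parameters
#'
#' Returns the full nested parameter list the pipeline runs with:
#' Phase-1 score cutoffs and promoter window, Phase-2 forest and Boruta
#' settings, Phase-3 MCL inflation, Phase-4 significance settings, and
#' stage toggles.
#'
#' @return Nested named list.
#' @export
pipeline_params <- function() {
  list(
    regulatory = list(mss_cutoff = 0.95, core_cutoff = 0.90,
                      maf_floor = 0.05, upstream = 500, downstream = 100),
    assoc = list(n_trees = 500, max_iter = 100, alpha = 0.01,
                 stride = 1, k_max = NULL),
    pleio = list(inflation = 2.0, expansion = 2, max_iter = 200),
    netmodel = list(alpha = 0.05, adjust = "none", het = "exclude", min_n = 3),
    stages = list(phase1 = TRUE, phase2 = TRUE, phase3 = TRUE, phase4 = TRUE))
}

merge_params <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- merge_params(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' The file may override any entry of [pipeline_params()] and may carry an
#' `inputs` section of file paths (vcf, fasta, gff, pwms, phenotypes,
#' counts) and a `seed`.
#'
#' @param path YAML file.
#' @return Nested parameter list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_params(c(pipeline_params(), list(inputs = NULL, seed = 1)), cfg)
}

load_pipeline_inputs <- function(inputs) {
  for (f in c("vcf", "fasta", "gff", "pwms", "phenotypes", "counts")) {
    if (is.null(inputs[[f]]) || !file.exists(inputs[[f]]))
      stop(sprintf("pipeline input '%s' missing or not found", f))
  }
  list(genotypes = read_vcf(inputs$vcf),
       genome = Biostrings::readDNAStringSet(inputs$fasta),
       annotations = read_gff3(inputs$gff),
       pwms = read_transfac(inputs$pwms),
       phenotypes = read_phenotypes(inputs$phenotypes),
       counts = read_counts(inputs$counts))
}

#' Run the four-phase rSNP pleiotropy pipeline
#'
#' Executes, in order: Phase 1 (MAF filter, promoter scan, Gain/Loss
#' classification), Phase 2 (Boruta ranking + incremental feature
#' selection per phenotype), Phase 3 (profile matrix, PSI, Markov
#' clustering, single-phenotype pruning), and Phase 4 (median-of-ratios
#' normalization, allele-split Wilcoxon validation, network pruning).
#' Later phases can be toggled off; every intermediate is returned and,
#' when `outdir` is given, written to disk together with a JSON manifest
#' of parameters, seed and per-stage record counts.
#'
#' @param data Either the result of [simulate_dataset()] or a list with
#'   elements `genotypes`, `genome`, `annotations`, `pwms`, `phenotypes`,
#'   `counts` (e.g. from files via an `inputs` config section).
#' @param params Nested parameter list; missing entries fall back to
#'   [pipeline_params()].
#' @param seed Integer seed for the stochastic stages.
#' @param outdir Output directory or NULL.
#' @return Object of class `pleio_pipeline` with elements `consequences`,
#'   `assoc`, `profile`, `assoc_matrix`, `clusters_raw`, `clusters`,
#'   `summary`, `size_factors`, `validations`, `networks`,
#'   `networks_pruned`, `manifest`.
#' @export
run_pipeline <- function(data, params = list(), seed = 1, outdir = NULL) {
  params <- merge_params(pipeline_params(), params)
  st <- params$stages
  res <- list(params = params, seed = seed)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts_manifest <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # Phase 1 ----------------------------------------------------------------
  geno <- run_stage("phase1", filter_snps_by_maf(data$genotypes,
                                                 params$regulatory$maf_floor))
  counts_manifest$snps_after_maf <- ncol(geno$dosages)
  cons <- run_stage("phase1", identify_rsnps(
    geno, data$genome, data$annotations, data$pwms,
    mss_cutoff = params$regulatory$mss_cutoff,
    core_cutoff = params$regulatory$core_cutoff,
    upstream = params$regulatory$upstream,
    downstream = params$regulatory$downstream))
  res$consequences <- cons
  counts_manifest$consequences <- nrow(cons)
  counts_manifest$rsnps <- length(unique(cons$snp))
  if (!is.null(outdir))
    utils::write.table(cons, file.path(outdir, "consequences.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # Phase 2 ----------------------------------------------------------------
  if (isTRUE(st$phase2) && nrow(cons)) {
    X <- encode_genotypes(geno, unique(cons$snp))
    assoc <- run_stage("phase2", associate_all(
      X, data$phenotypes, n_trees = params$assoc$n_trees,
      max_iter = params$assoc$max_iter, alpha = params$assoc$alpha,
      stride = params$assoc$stride, k_max = params$assoc$k_max,
      seed = stage_seed(seed, 20L)))
    res$assoc <- assoc
    counts_manifest$phenotypes_analyzed <- nrow(assoc$summary)
    counts_manifest$optimal_set_sizes <- sum(vapply(assoc$optimal_sets, length, 0L))
    if (!is.null(outdir)) {
      utils::write.table(assoc$summary, file.path(outdir, "assoc_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      nonempty <- names(assoc$optimal_sets)[vapply(assoc$optimal_sets, length, 0L) > 0]
      opt_df <- do.call(rbind, c(list(
        data.frame(phenotype = character(0), snp = character(0),
                   stringsAsFactors = FALSE)),
        lapply(nonempty, function(ph)
          data.frame(phenotype = ph, snp = assoc$optimal_sets[[ph]],
                     stringsAsFactors = FALSE))))
      utils::write.table(opt_df, file.path(outdir, "optimal_sets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # Phase 3 ----------------------------------------------------------------
  if (isTRUE(st$phase3) && !is.null(res$assoc)) {
    M <- run_stage("phase3", build_profile_matrix(res$assoc$optimal_sets, cons))
    A <- run_stage("phase3", psi_matrix(M))
    cl_raw <- run_stage("phase3", mcl(A, inflation = params$pleio$inflation,
                                      expansion = params$pleio$expansion,
                                      max_iter = params$pleio$max_iter))
    cl <- prune_non_pleiotropic(cl_raw, M)
    res$profile <- M; res$assoc_matrix <- A
    res$clusters_raw <- cl_raw; res$clusters <- cl
    res$summary <- cluster_summary(cl, M, cons)
    counts_manifest$profile_rows <- nrow(M)
    counts_manifest$clusters <- length(cl)
    counts_manifest$pleiotropic_rsnps <- length(unlist(cl))
    if (!is.null(outdir)) {
      utils::write.table(data.frame(snp = rownames(M), unclass(M),
                                    check.names = FALSE),
                         file.path(outdir, "profile_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_clusters_json(cl, file.path(outdir, "clusters.json"))
      utils::write.table(res$summary, file.path(outdir, "cluster_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # Phase 4 ----------------------------------------------------------------
  if (isTRUE(st$phase4) && !is.null(res$clusters)) {
    nm <- run_stage("phase4", median_of_ratios(data$counts))
    res$size_factors <- nm$size_factors
    val <- run_stage("phase4", validate_expression(
      res$clusters, cons, geno, nm$normalized,
      alpha = params$netmodel$alpha, adjust = params$netmodel$adjust,
      het = params$netmodel$het, min_n = params$netmodel$min_n))
    res$validations <- val
    counts_manifest$validations <- nrow(val)
    counts_manifest$significant_validations <- sum(val$significant)
  }
  if (!is.null(res$clusters)) {
    nets <- lapply(seq_along(res$clusters), function(k)
      build_hierarchical_network(res$clusters[[k]], cons,
                                 res$assoc$optimal_sets, cluster_id = k))
    res$networks <- nets
    if (!is.null(res$validations)) {
      res$networks_pruned <- lapply(nets, prune_network_by_expression,
                                    validations = res$validations)
      counts_manifest$rsnps_surviving_expression <-
        sum(vapply(res$networks_pruned, function(nw) nrow(nw$rsnps), 0L))
    }
    if (!is.null(outdir)) {
      if (!is.null(res$validations))
        utils::write.table(res$validations, file.path(outdir, "validations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      final_nets <- res$networks_pruned %||% res$networks
      write_networks_json(final_nets, file.path(outdir, "networks.json"))
      for (k in seq_along(final_nets))
        if (nrow(final_nets[[k]]$rsnps))
          write_graphml(final_nets[[k]],
                        file.path(outdir, sprintf("network_cluster%02d.graphml", k)))
    }
  }

  res$manifest <- list(
    package = "rsnpleio",
    version = as.character(utils::packageVersion("rsnpleio")),
    r_version = as.character(getRversion()),
    seed = seed, params = params, counts = counts_manifest)
  if (!is.null(outdir))
    jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  class(res) <- "pleio_pipeline"
  res
}

#' Print method for pipeline results
#' @param x A `pleio_pipeline`.
#' @param ... Ignored.
#' @export
print.pleio_pipeline <- function(x, ...) {
  cat("Four-phase rSNP pleiotropy pipeline\n")
  cm <- x$manifest$counts
  for (nm in names(cm)) cat(sprintf("  %-28s %s\n", nm, cm[[nm]]))
  invisible(x)
}

#' Summary method for pipeline results
#' @param object A `pleio_pipeline`.
#' @param ... Ignored.
#' @export
summary.pleio_pipeline <- function(object, ...) {
  print(object)
  if (!is.null(object$summary)) {
    cat("\nClusters:\n")
    print(object$summary)
  }
  invisible(object)
}

#' Compare a pipeline run against simulation ground truth
#'
#' Computes the recovery metrics the synthetic study design is built for:
#' the fraction of planted Gain/Loss events recovered as consequences with
#' the planted TF and direction, the fraction of planted (rSNP, phenotype)
#' pairs present in the optimal sets, the Adjusted Rand Index between
#' recovered clusters and planted cluster memberships (over planted
#' rSNPs; unclustered ones count as singletons), and the fraction of
#' planted cis-effect rSNPs in recovered clusters that survive
#' expression-based network pruning.
#'
#' @param result A `pleio_pipeline`.
#' @param truth A `ground_truth` object.
#' @return Named list: `rsnp_detection_rate`, `optimal_set_recovery`,
#'   `cluster_ari`, `cis_pruning_survival`, `n_clusters`.
#' @export
evaluate_recovery <- function(result, truth) {
  planted <- truth$planted_rsnps
  cons <- result$consequences
  hit <- mapply(function(s, tf, eff)
    any(cons$snp == s & cons$tf == tf & cons$effect == eff),
    planted$snp, planted$tf, planted$effect)
  detection <- mean(hit)

  pairs_total <- 0L; pairs_hit <- 0L
  for (cl in truth$planted_clusters) {
    for (ph in cl$phenotypes) {
      pairs_total <- pairs_total + length(cl$rsnps)
      if (!is.null(result$assoc$optimal_sets[[ph]]))
        pairs_hit <- pairs_hit +
          length(intersect(cl$rsnps, result$assoc$optimal_sets[[ph]]))
    }
  }
  recovery <- if (pairs_total) pairs_hit / pairs_total else NA_real_

  truth_lab <- integer(0); names(truth_lab) <- character(0)
  for (k in seq_along(truth$planted_clusters))
    truth_lab[truth$planted_clusters[[k]]$rsnps] <- k
  rec_lab <- rep(NA_integer_, length(truth_lab))
  names(rec_lab) <- names(truth_lab)
  for (k in seq_along(result$clusters))
    rec_lab[intersect(names(rec_lab), result$clusters[[k]])] <- k
  n_cl <- length(result$clusters)
  singleton <- which(is.na(rec_lab))
  rec_lab[singleton] <- n_cl + seq_along(singleton)
  ari <- mclust::adjustedRandIndex(truth_lab, rec_lab)

  clustered_cis <- intersect(truth$planted_cis_effects$snp,
                             unlist(result$clusters))
  surviving <- unique(unlist(lapply(result$networks_pruned, function(nw)
    nw$rsnps$snp)))
  cis_survival <- if (length(clustered_cis))
    mean(clustered_cis %in% surviving) else NA_real_

  list(rsnp_detection_rate = detection,
       optimal_set_recovery = recovery,
       cluster_ari = ari,
       cis_pruning_survival = cis_survival,
       n_clusters = length(result$clusters))
}
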