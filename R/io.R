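# Readers and writers for the pipeline's file formats: VCF v4.2, FASTA,
# GFF3, phenotype/count TSVs, clusters, networks and ground-truth JSON.

#' Write genotypes as a VCF v4.2 file
#'
#' Plain-text VCF with GT-only FORMAT; dosage 0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, NA -> ./.. Positions are written 1-based as stored.
#'
#' @param genotypes A `geno_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "geno_set"))
  snps <- genotypes$snps
  gt_map <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rsnpleio",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$lines), collapse = "\t"), con)
  for (j in seq_len(nrow(snps))) {
    d <- genotypes$dosages[, snps$id[j]]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1L])
    writeLines(paste(c(snps$chrom[j], snps$pos[j], snps$id[j], snps$ref[j],
                       snps$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF file into a `geno_set`
#'
#' Parses with [vcfR::read.vcfR()]; multi-allelic records are split into
#' biallelic records (suffixing the id) before dosage extraction, and
#' genotypes are converted to alternate-allele dosages.
#'
#' @param path VCF path.
#' @return A `geno_set`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  lines <- colnames(gt_raw)
  rows <- list()
  dos_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    base_id <- if (is.na(fix$ID[i]) || fix$ID[i] == ".")
      sprintf("%s_%s", fix$CHROM[i], fix$POS[i]) else fix$ID[i]
    for (a in seq_along(alts)) {
      id <- if (length(alts) > 1L) sprintf("%s_alt%d", base_id, a) else base_id
      g <- gt_raw[i, ]
      g <- gsub("|", "/", g, fixed = TRUE)
      parts <- strsplit(g, "/", fixed = TRUE)
      d <- vapply(parts, function(pp) {
        if (length(pp) != 2L || any(pp == ".")) return(NA_integer_)
        sum(as.integer(pp) == a)
      }, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a], stringsAsFactors = FALSE)
      dos_rows[[length(dos_rows) + 1L]] <- d
    }
  }
  snps <- do.call(rbind, rows)
  dos <- do.call(cbind, dos_rows)
  dimnames(dos) <- list(lines, snps$id)
  structure(list(snps = snps, dosages = dos, lines = lines), class = "geno_set")
}

#' Write gene annotations as GFF3
#'
#' One `gene` feature per row; the TSS is the feature start on the plus
#' strand and the feature end on the minus strand.
#'
#' @param annotations data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    writeLines(paste(a$chrom, "rsnpleio", "gene", a$start, a$end, ".",
                     a$strand, ".", sprintf("ID=%s", a$gene_id), sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Imports via [rtracklayer::import()] and keeps `gene` features,
#' deriving the TSS from the strand (start on +, end on -).
#'
#' @param path GFF3 path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  strand <- as.character(GenomicRanges::strand(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  data.frame(gene_id = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end),
             stringsAsFactors = FALSE)
}

#' Write a phenotype matrix as TSV
#'
#' First column `line`, then one column per trait.
#'
#' @param phenotypes Numeric matrix, lines x traits, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(line = rownames(phenotypes), phenotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV
#' @param path TSV with a `line` id column and one column per trait.
#' @return Numeric matrix, lines x traits.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write an expression count matrix as TSV
#'
#' First column `gene`, then one column per line.
#'
#' @param counts Matrix, genes x lines, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression count TSV
#' @param path TSV with a `gene` id column and one column per line.
#' @return Numeric matrix, genes x lines.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write ground truth as JSON
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read ground truth from JSON
#' @param path JSON written by [write_ground_truth()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_clusters <- lapply(seq_len(nrow(x$planted_clusters)), function(i)
    list(rsnps = x$planted_clusters$rsnps[[i]],
         phenotypes = x$planted_clusters$phenotypes[[i]]))
  structure(x, class = "ground_truth")
}

#' Write clusters as JSON
#' @param clusters Cluster list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(clusters, path) {
  jsonlite::write_json(lapply(unclass(clusters), as.character), path,
                       pretty = TRUE)
  invisible(path)
}

#' Read clusters from JSON
#' @param path JSON written by [write_clusters_json()].
#' @return List of character vectors of class `mcl_clusters`.
#' @export
read_clusters_json <- function(path) {
  structure(lapply(jsonlite::read_json(path, simplifyVector = TRUE),
                   as.character),
            class = "mcl_clusters")
}

#' Write a hierarchical network as GraphML
#' @param network A `hier_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write hierarchical networks as JSON
#' @param networks List of `hier_network` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_networks_json <- function(networks, path) {
  if (inherits(networks, "hier_network")) networks <- list(networks)
  jsonlite::write_json(lapply(networks, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
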