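#' @name codivkit-io
#' @title Plain-text readers and writers for the pipeline formats
#' @description
#' All on-disk formats are TSV (or FASTA/JSON/Newick). Genome coordinates
#' are 0-based half-open throughout; the allele-count and gene-map writers
#' note this in a header comment line.
NULL

tsv_write <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tsv_read <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname codivkit-io
#' @param acm an [allele_counts()] object.
#' @param path file path.
#' @export
write_allele_counts <- function(acm, path) {
  stopifnot(inherits(acm, "allele_counts"))
  long <- do.call(rbind, lapply(seq_along(acm$samples), function(j) {
    data.frame(pos = acm$positions, sample = acm$samples[j],
               A = acm$counts[, j, 1], C = acm$counts[, j, 2],
               G = acm$counts[, j, 3], T = acm$counts[, j, 4])
  }))
  tsv_write(long, path, "per-position nucleotide counts; pos is 0-based")
}

#' @rdname codivkit-io
#' @export
read_allele_counts <- function(path) {
  df <- tsv_read(path)
  positions <- sort(unique(df$pos))
  samples <- unique(df$sample)
  counts <- array(0L, c(length(positions), length(samples), 4L))
  pi <- match(df$pos, positions)
  si <- match(df$sample, samples)
  for (k in 1:4) counts[cbind(pi, si, k)] <- as.integer(df[[NTS[k]]])
  allele_counts(counts, positions, samples)
}

#' @rdname codivkit-io
#' @param genes gene map with coding sequences (as from the simulator).
#' @export
write_gene_models <- function(genes, path_tsv, path_fasta) {
  tsv_write(genes[, c("gene_id", "contig", "start", "end", "strand")],
            path_tsv, "gene map; start/end are 0-based half-open")
  seqs <- Biostrings::DNAStringSet(setNames(genes$sequence, genes$gene_id))
  Biostrings::writeXStringSet(seqs, path_fasta)
  invisible(path_tsv)
}

#' @rdname codivkit-io
#' @param path_tsv,path_fasta gene map TSV and coding-sequence FASTA paths.
#' @export
read_gene_models <- function(path_tsv, path_fasta) {
  genes <- tsv_read(path_tsv)
  seqs <- Biostrings::readDNAStringSet(path_fasta)
  genes$sequence <- as.character(seqs[genes$gene_id])
  genes
}

#' @rdname codivkit-io
#' @param gl a [genotype_likelihoods()] object.
#' @export
write_genotype_likelihoods <- function(gl, path) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  long <- do.call(rbind, lapply(seq_along(gl$individuals), function(i) {
    data.frame(individual = gl$individuals[i], site = gl$sites,
               L_AA = gl$L[i, , 1], L_Aa = gl$L[i, , 2], L_aa = gl$L[i, , 3],
               missing = as.integer(gl$missing[i, ]))
  }))
  tsv_write(long, path, "per-site genotype likelihoods, normalized; missing=1 means no reads")
}

#' @rdname codivkit-io
#' @export
read_genotype_likelihoods <- function(path) {
  df <- tsv_read(path)
  individuals <- unique(df$individual)
  sites <- unique(df$site)
  L <- array(NA_real_, c(length(individuals), length(sites), 3L))
  miss <- matrix(FALSE, length(individuals), length(sites))
  ii <- match(df$individual, individuals)
  si <- match(df$site, sites)
  L[cbind(ii, si, 1L)] <- df$L_AA
  L[cbind(ii, si, 2L)] <- df$L_Aa
  L[cbind(ii, si, 3L)] <- df$L_aa
  if (!is.null(df$missing)) miss[cbind(ii, si)] <- df$missing == 1
  genotype_likelihoods(L, missing = miss, individuals = individuals,
                       sites = sites)
}

#' @rdname codivkit-io
#' @param profile an `snv_profile`.
#' @export
write_snv_profile <- function(profile, path) {
  stopifnot(inherits(profile, "snv_profile"))
  long <- do.call(rbind, lapply(seq_along(profile$samples), function(j) {
    data.frame(pos = profile$positions, sample = profile$samples[j],
               coverage = profile$coverage[, j],
               consensus = profile$consensus[, j],
               competing = profile$competing[, j],
               departure = profile$departure[, j],
               present = as.integer(profile$present[, j]))
  }))
  tsv_write(long, path, "SNV profile; pos is 0-based; departure = 1 - consensus fraction")
}

#' @rdname codivkit-io
#' @param profile an `snv_profile`.
#' @export
write_snv_matrix <- function(profile, path) {
  wide <- data.frame(sample = profile$samples,
                     t(profile$departure))
  colnames(wide)[-1] <- paste0("pos", profile$positions)
  tsv_write(wide, path, "sample x SNV departure-from-consensus matrix")
}

#' @rdname codivkit-io
#' @param d square distance matrix with labels.
#' @export
write_dist_matrix <- function(d, path) {
  d <- as_dist_matrix(d, labels = rownames(d))
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  tsv_write(df, path)
}

#' @rdname codivkit-io
#' @export
read_dist_matrix <- function(path) {
  df <- tsv_read(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- df[[1]]
  as_dist_matrix(m, labels = df[[1]])
}

#' @rdname codivkit-io
#' @param result a `parafit_result`.
#' @export
write_parafit_result <- function(result, path) {
  stopifnot(inherits(result, "parafit_result"))
  jsonlite::write_json(list(statistic = result$statistic,
                            p_value = result$p_value,
                            n_perm = result$n_perm,
                            seed = result$seed,
                            scheme = result$scheme,
                            host_correction = result$host_correction,
                            sym_correction = result$sym_correction),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname codivkit-io
#' @param truth a `holosim_truth` object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "holosim_truth"))
  jsonlite::write_json(list(
    host_cluster = as.list(truth$host_cluster),
    transmission_source = as.list(truth$transmission_source),
    snv_table = truth$snv_table,
    carried_snvs = truth$carried_snvs
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
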