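#' Per-position nucleotide allele-count matrix
#'
#' The raw substrate of all SNV/SCV work: for every genome position and
#' every sample metagenome, the number of recruited reads supporting each of
#' A, C, G, T.
#'
#' @param counts integer array, positions x samples x 4 (A, C, G, T order).
#' @param positions 0-based genome coordinates, strictly increasing.
#' @param samples unique sample identifiers.
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(counts, positions, samples) {
  counts <- as.array(counts)
  stopifnot(length(dim(counts)) == 3L, dim(counts)[3] == 4L,
            dim(counts)[1] == length(positions),
            dim(counts)[2] == length(samples))
  if (any(counts < 0)) stop("negative allele counts")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  dimnames(counts) <- list(NULL, samples, NTS)
  structure(list(positions = as.integer(positions),
                 samples = as.character(samples),
                 counts = counts),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %d positions x %d samples\n",
              length(x$positions), length(x$samples)))
  invisible(x)
}

#' Coverage per position and sample
#' @param acm an [allele_counts()] object.
#' @return Integer matrix, positions x samples.
#' @export
coverage <- function(acm) {
  stopifnot(inherits(acm, "allele_counts"))
  acm$counts[, , 1] + acm$counts[, , 2] + acm$counts[, , 3] + acm$counts[, , 4]
}

#' Host genotype likelihoods
#'
#' Per-individual, per-site likelihoods of the three diploid genotypes
#' (homRef, het, homAlt), normalized per individual and site. Sites with no
#' reads for an individual are masked missing (and carry a flat likelihood).
#'
#' @param L numeric array, individuals x sites x 3.
#' @param missing logical matrix, individuals x sites.
#' @param individuals,sites identifiers.
#' @return An object of class `genotype_likelihoods`.
#' @export
genotype_likelihoods <- function(L, missing = NULL, individuals = NULL,
                                 sites = NULL) {
  L <- as.array(L)
  stopifnot(length(dim(L)) == 3L, dim(L)[3] == 3L)
  n <- dim(L)[1]; S <- dim(L)[2]
  if (is.null(individuals)) individuals <- sprintf("ind%03d", seq_len(n))
  if (is.null(sites)) sites <- sprintf("site%05d", seq_len(S) - 1L)
  if (is.null(missing)) missing <- matrix(FALSE, n, S)
  if (any(L < 0)) stop("likelihoods must be non-negative")
  tot <- L[, , 1] + L[, , 2] + L[, , 3]
  if (any(tot[!missing] <= 0))
    stop("all-zero likelihoods at a non-missing entry")
  for (g in 1:3) L[, , g] <- L[, , g] / ifelse(tot > 0, tot, 1)
  dimnames(L) <- list(individuals, sites, c("homRef", "het", "homAlt"))
  structure(list(individuals = as.character(individuals),
                 sites = as.character(sites),
                 L = L, missing = missing),
            class = "genotype_likelihoods")
}

#' @export
print.genotype_likelihoods <- function(x, ...) {
  cat(sprintf("<genotype_likelihoods> %d individuals x %d sites (%.1f%% missing)\n",
              length(x$individuals), length(x$sites), 100 * mean(x$missing)))
  invisible(x)
}

#' @noRd
#' Validate a square distance matrix (symmetry, zero diagonal, labels).
as_dist_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (any(is.na(m))) stop("distance matrix contains NA")
  if (max(abs(m - t(m))) > 1e-10) stop("distance matrix is not symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (any(m < 0)) stop("negative distances")
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}
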