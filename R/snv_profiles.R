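#' Consensus, competing nucleotide and departure from consensus
#'
#' The per-(position, sample) variability value: `d = 1 - max_count/coverage`,
#' i.e. the fraction of recruited reads that differ from the consensus
#' nucleotide. Ties in counts are broken by the fixed order A < C < G < T,
#' both for the consensus and for the competing (second most frequent)
#' nucleotide, so results are deterministic.
#'
#' @param counts4 non-negative counts for A, C, G, T at one position in one
#'   sample; coverage (their sum) must be >= 1.
#' @return A list with `consensus`, `competing` (single letters) and
#'   `departure` in [0, 0.75].
#' @export
departure_from_consensus <- function(counts4) {
  stopifnot(length(counts4) == 4L, all(counts4 >= 0))
  cov <- sum(counts4)
  if (cov < 1) stop("coverage is zero: departure undefined")
  i1 <- which.max(counts4)
  rest <- counts4
  rest[i1] <- -1
  i2 <- which.max(rest)
  list(consensus = NTS[i1], competing = NTS[i2],
       departure = unname(1 - counts4[i1] / cov))
}

#' Call single-nucleotide variants from an allele-count matrix
#'
#' A position enters the profile when, in at least `min_prevalence` of all
#' samples, the sample has coverage >= `min_coverage` *and* its departure
#' from consensus exceeds `min_variation`. The coverage gate is applied
#' first, then the variation condition, then prevalence across samples.
#' Defaults are the standard reporting thresholds for within-population
#' metagenomic SNVs: >1% of reads off consensus, at a minimum of 20X
#' coverage, in at least 90% of the metagenomes (zero-inflation control).
#'
#' @param acm an [allele_counts()] object.
#' @param min_variation minimum departure from consensus, default 0.01.
#' @param min_coverage minimum per-sample coverage, default 20.
#' @param min_prevalence minimum fraction of samples passing both gates,
#'   default 0.90.
#' @return An object of class `snv_profile`: retained `positions`; matrices
#'   (positions x samples) `departure`, `coverage`, `consensus`, `competing`,
#'   and logical `present` (departure above threshold at adequate coverage).
#'   An empty profile (with a warning) when nothing passes.
#' @export
call_snvs <- function(acm, min_variation = 0.01, min_coverage = 20,
                      min_prevalence = 0.90) {
  stopifnot(inherits(acm, "allele_counts"))
  check_prob(min_variation, "min_variation", 0, 1, hi_open = TRUE)
  check_prob(min_prevalence, "min_prevalence", 0, 1, lo_open = TRUE)
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  if (length(acm$samples) == 0L) stop("allele-count matrix has no samples")

  P <- length(acm$positions); S <- length(acm$samples)
  cov <- coverage(acm)
  flat <- matrix(aperm(acm$counts, c(3, 1, 2)), nrow = 4L)  # 4 x (P*S)
  i1 <- max.col(t(flat), ties.method = "first")
  top <- flat[cbind(i1, seq_len(P * S))]
  flat2 <- flat
  flat2[cbind(i1, seq_len(P * S))] <- -1L
  i2 <- max.col(t(flat2), ties.method = "first")

  d <- matrix(ifelse(cov > 0, 1 - matrix(top, P, S) / cov, NA_real_), P, S)
  consensus <- matrix(NTS[i1], P, S)
  competing <- matrix(NTS[i2], P, S)
  consensus[cov == 0] <- NA_character_
  competing[cov == 0] <- NA_character_

  gate <- cov >= min_coverage
  variant <- gate & !is.na(d) & d > min_variation
  prevalence <- rowMeans(variant)
  keep <- prevalence >= min_prevalence
  if (!any(keep))
    warning("no position passed the SNV filters; returning an empty profile")

  sub <- function(m) m[keep, , drop = FALSE]
  structure(list(
    positions = acm$positions[keep],
    samples = acm$samples,
    departure = `dimnames<-`(sub(d), list(NULL, acm$samples)),
    coverage = `dimnames<-`(sub(cov), list(NULL, acm$samples)),
    consensus = sub(consensus),
    competing = sub(competing),
    present = `dimnames<-`(sub(variant), list(NULL, acm$samples)),
    config = list(min_variation = min_variation, min_coverage = min_coverage,
                  min_prevalence = min_prevalence)
  ), class = "snv_profile")
}

#' @export
print.snv_profile <- function(x, ...) {
  cat(sprintf("<snv_profile> %d SNV positions x %d samples (min_variation=%g, min_coverage=%g, min_prevalence=%g)\n",
              length(x$positions), length(x$samples),
              x$config$min_variation, x$config$min_coverage,
              x$config$min_prevalence))
  invisible(x)
}

#' Pairwise sample distances from an SNV profile
#'
#' Two complementary views of between-sample SNV structure: the Jaccard
#' distance on SNV presence/absence sets (the host--symbiont linkage
#' substrate fed to the ParaFit test), or the Euclidean distance between the
#' samples' departure-from-consensus vectors over the retained positions
#' (the variability view used for hierarchical clustering).
#'
#' @param profile an `snv_profile` from [call_snvs()].
#' @param mode `"presence_absence_jaccard"` or `"euclidean_on_d"`.
#' @return A symmetric sample x sample distance matrix with zero diagonal.
#'   For Jaccard, a pair of samples with two empty SNV sets has distance 0.
#'   For Euclidean, a departure undefined at a retained position (coverage
#'   below the gate) is imputed as 0, with a message.
#' @export
snv_distance <- function(profile,
                         mode = c("presence_absence_jaccard", "euclidean_on_d")) {
  stopifnot(inherits(profile, "snv_profile"))
  mode <- match.arg(mode)
  if (length(profile$samples) < 2L) stop("need at least 2 samples")
  if (mode == "presence_absence_jaccard") {
    P <- profile$present * 1
    inter <- crossprod(P)
    sizes <- colSums(P)
    union <- outer(sizes, sizes, "+") - inter
    d <- ifelse(union > 0, 1 - inter / union, 0)
  } else {
    D <- profile$departure
    bad <- is.na(D) | profile$coverage < profile$config$min_coverage
    if (any(bad)) {
      message(sprintf("imputing %d below-gate departure values as 0 for Euclidean distances",
                      sum(bad)))
      D[bad] <- 0
    }
    d <- as.matrix(dist(t(D)))
  }
  as_dist_matrix(d, labels = profile$samples)
}

#' Per-sample SNV presence sets
#' @param profile an `snv_profile`.
#' @return Named list of integer vectors of SNV positions per sample.
#' @export
snv_sets <- function(profile) {
  stopifnot(inherits(profile, "snv_profile"))
  lapply(setNames(seq_along(profile$samples), profile$samples),
         function(j) profile$positions[profile$present[, j]])
}
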