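#' Configuration for the synthetic hologenome generator
#'
#' Bundles every knob of the simulator: two diverged host lineages under a
#' Balding--Nichols model, and a dominant vertically transmitted symbiont
#' whose single-nucleotide variants (SNVs) partition by host lineage, with a
#' tunable horizontal-transmission rate for null calibration.
#'
#' @param n_hosts_per_cluster hosts per lineage cluster (>= 2).
#' @param n_host_sites biallelic host sites simulated.
#' @param fst Balding--Nichols differentiation parameter F, in (0, 1).
#' @param host_depth_mean mean sequencing depth per host site (Poisson).
#' @param host_error per-read error probability for host reads, in [0, 0.5).
#' @param sym_genome integer vector of symbiont gene lengths, in codons
#'   (each >= 2). Genes are contiguous, in frame, forward strand, one contig.
#' @param n_cluster_snvs length-2 integer vector: lineage-diagnostic symbiont
#'   SNVs for cluster 1 and cluster 2 (cluster 2 >= cluster 1, mirroring the
#'   excess variability observed in the southern host lineage).
#' @param sym_depth_mean mean symbiont coverage per genome position (Poisson).
#' @param sym_error symbiont per-read error probability, in [0, 0.5).
#' @param within_host_minor_freq frequency of the alternate allele within a
#'   carrier host's symbiont population, in (0, 1].
#' @param h_transmission probability that a host's symbiont is drawn from
#'   the pooled cross-cluster variant pool instead of inheriting its own
#'   lineage's set (0 = strict vertical transmission, 1 = fully horizontal
#'   null).
#' @param seed master random seed; each simulated object uses its own stream
#'   derived from it (see [stream_seed()]).
#'
#' @return A list of class `holosim_config`.
#' @export
sim_config <- function(n_hosts_per_cluster = 15L,
                       n_host_sites = 5000L,
                       fst = 0.1,
                       host_depth_mean = 20,
                       host_error = 0.01,
                       sym_genome = rep(60L, 10L),
                       n_cluster_snvs = c(8L, 16L),
                       sym_depth_mean = 100,
                       sym_error = 0.001,
                       within_host_minor_freq = 0.3,
                       h_transmission = 0,
                       seed = 1L) {
  stopifnot(n_hosts_per_cluster >= 2, n_host_sites >= 1,
            length(n_cluster_snvs) == 2, all(n_cluster_snvs >= 1),
            all(sym_genome >= 2))
  if (n_cluster_snvs[2] < n_cluster_snvs[1])
    stop("cluster 2 must carry at least as many diagnostic SNVs as cluster 1")
  check_prob(fst, "fst", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_prob(host_error, "host_error", 0, 0.5, hi_open = TRUE)
  check_prob(sym_error, "sym_error", 0, 0.5, hi_open = TRUE)
  check_prob(within_host_minor_freq, "within_host_minor_freq", 0, 1, lo_open = TRUE)
  check_prob(h_transmission, "h_transmission", 0, 1)
  if (host_depth_mean <= 0) stop("host_depth_mean must be > 0")
  if (sym_depth_mean <= 0) stop("sym_depth_mean must be > 0")
  if (sum(n_cluster_snvs) > sum(sym_genome))
    stop("more diagnostic SNVs requested than codons in the symbiont genome")
  structure(list(
    n_hosts_per_cluster = as.integer(n_hosts_per_cluster),
    n_host_sites = as.integer(n_host_sites),
    fst = fst,
    host_depth_mean = host_depth_mean,
    host_error = host_error,
    sym_genome = as.integer(sym_genome),
    n_cluster_snvs = as.integer(n_cluster_snvs),
    sym_depth_mean = sym_depth_mean,
    sym_error = sym_error,
    within_host_minor_freq = within_host_minor_freq,
    h_transmission = h_transmission,
    seed = as.integer(seed)
  ), class = "holosim_config")
}

#' Simulate host genotype likelihoods for two diverged lineages
#'
#' Per site, an ancestral allele frequency p ~ Uniform(0.05, 0.95); each
#' cluster's frequency is a Balding--Nichols draw
#' Beta(p(1-F)/F, (1-p)(1-F)/F); diploid genotypes are Binomial(2, p_cluster);
#' read depth is Poisson, and each read supports the carried allele with
#' probability 1 - host_error. Genotype likelihoods are computed from the
#' ref/alt read counts and normalized per individual per site; individuals
#' with zero reads at a site are masked missing (flat likelihood).
#'
#' @param config a [sim_config()] object.
#' @return A list: `gl`, a `genotype_likelihoods` object (see
#'   [genotype_likelihoods()]), and `truth`, a `holosim_truth` list carrying
#'   `host_cluster`, `true_host_allele_freqs` and the drawn genotypes.
#' @export
simulate_host_genotypes <- function(config) {
  stopifnot(inherits(config, "holosim_config"))
  with_stream(config$seed, "host", {
    S <- config$n_host_sites
    n_per <- config$n_hosts_per_cluster
    n <- 2L * n_per
    eps <- config$host_error
    cluster <- rep(1:2, each = n_per)
    ids <- sprintf("host%03d", seq_len(n))

    p_anc <- runif(S, 0.05, 0.95)
    Fst <- config$fst
    a <- p_anc * (1 - Fst) / Fst
    b <- (1 - p_anc) * (1 - Fst) / Fst
    p_clu <- cbind(rbeta(S, a, b), rbeta(S, a, b))  # site x cluster

    # genotypes: individuals x sites
    PM <- t(p_clu[, cluster, drop = FALSE])  # n x S cluster frequencies
    G <- matrix(rbinom(n * S, 2L, PM), nrow = n)
    depth <- matrix(rpois(n * S, config$host_depth_mean), nrow = n)
    p_alt_read <- G / 2 * (1 - eps) + (1 - G / 2) * eps
    k_alt <- matrix(rbinom(n * S, depth, p_alt_read), nrow = n)
    k_ref <- depth - k_alt

    q <- c(eps, 0.5, 1 - eps)  # P(alt read | genotype 0, 1, 2)
    L <- array(NA_real_, c(n, S, 3L),
               dimnames = list(ids, NULL, c("homRef", "het", "homAlt")))
    for (g in 0:2) {
      ll <- k_alt * log(q[g + 1]) + k_ref * log(1 - q[g + 1])
      L[, , g + 1] <- ll
    }
    mx <- pmax(L[, , 1], L[, , 2], L[, , 3])
    for (g in 1:3) L[, , g] <- exp(L[, , g] - mx)
    tot <- L[, , 1] + L[, , 2] + L[, , 3]
    for (g in 1:3) L[, , g] <- L[, , g] / tot
    missing <- depth == 0L
    for (g in 1:3) L[, , g][missing] <- 1 / 3

    gl <- genotype_likelihoods(L, missing = missing,
                               individuals = ids,
                               sites = sprintf("site%05d", seq_len(S) - 1L))
    truth <- structure(list(
      host_cluster = setNames(cluster, ids),
      true_host_allele_freqs = p_clu,
      genotypes = G,
      cluster_snv_sets = NULL,
      transmission_source = NULL,
      snv_table = NULL
    ), class = "holosim_truth")
    list(gl = gl, truth = truth)
  })
}

#' @noRd
#' Draw the symbiont reference genome: contiguous in-frame genes built from
#' sense codons (first codon ATG), single forward-strand contig, 0-based
#' half-open coordinates.
sim_genome <- function(gene_lengths) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  seqs <- vapply(gene_lengths, function(L) {
    paste(c("ATG", sample(sense, L - 1L, replace = TRUE)), collapse = "")
  }, "")
  ends <- cumsum(3L * gene_lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(gene_id = sprintf("gene%03d", seq_along(gene_lengths)),
             contig = "sym_contig", start = starts, end = ends,
             strand = "+", sequence = seqs, stringsAsFactors = FALSE)
}

#' Simulate symbiont allele-count matrices under a transmission scenario
#'
#' Each host carries a symbiont population: with probability
#' `1 - h_transmission` it inherits its own lineage's diagnostic SNV set
#' (vertical transmission), and with probability `h_transmission` it carries
#' a uniform random subset of the pooled cross-cluster variant pool
#' (horizontal acquisition). At a carried SNV position the within-host
#' alternate-allele frequency is `within_host_minor_freq`; elsewhere the
#' reference is fixed. Per position and sample, coverage is Poisson and the
#' four nucleotide counts are Multinomial given the within-host frequencies
#' with error spread evenly over the three non-true nucleotides.
#'
#' @param config a [sim_config()] object.
#' @param truth the `truth` component returned by [simulate_host_genotypes()]
#'   run with the same config (its host cluster labels are reused).
#' @return A list: `counts` (an [allele_counts()] matrix), `genes` (gene map
#'   with coding sequences), and `truth` updated with `cluster_snv_sets`,
#'   `transmission_source` and the per-SNV table.
#' @export
simulate_symbiont_counts <- function(config, truth) {
  stopifnot(inherits(config, "holosim_config"), inherits(truth, "holosim_truth"))
  with_stream(config$seed, "symbiont", {
    genes <- sim_genome(config$sym_genome)
    genome_nt <- strsplit(paste(genes$sequence, collapse = ""), "")[[1]]
    P <- length(genome_nt)
    n_codons <- P %/% 3L

    # Diagnostic SNVs: distinct codons (<= 1 variable position per codon),
    # disjoint between clusters; alternate nucleotide differs from reference.
    k <- config$n_cluster_snvs
    codon_pick <- sample(n_codons, sum(k))
    offset <- sample(0:2, sum(k), replace = TRUE)
    pos <- (codon_pick - 1L) * 3L + offset  # 0-based genome coordinate
    ref <- genome_nt[pos + 1L]
    alt <- vapply(ref, function(r) sample(setdiff(NTS, r), 1L), "")
    snv_cluster <- rep(1:2, times = k)
    snv_table <- data.frame(pos = pos, ref = ref, alt = alt,
                            cluster = snv_cluster, stringsAsFactors = FALSE)

    hosts <- names(truth$host_cluster)
    n <- length(hosts)
    horizontal <- runif(n) < config$h_transmission
    # Vertical hosts carry their own lineage's diagnostic set; horizontal
    # hosts carry a uniform random subset of the pooled cross-cluster
    # variant pool (each pooled variant independently with probability 1/2).
    carried <- lapply(seq_len(n), function(i) {
      if (horizontal[i]) {
        which(runif(nrow(snv_table)) < 0.5)
      } else {
        which(snv_table$cluster == truth$host_cluster[i])
      }
    })

    f <- config$within_host_minor_freq
    e <- config$sym_error
    counts <- array(0L, c(P, n, 4L), dimnames = list(NULL, hosts, NTS))
    ref_idx <- match(genome_nt, NTS)
    base_freq <- matrix(0, P, 4L)
    base_freq[cbind(seq_len(P), ref_idx)] <- 1
    for (i in seq_len(n)) {
      freq <- base_freq
      snvs <- snv_table[carried[[i]], , drop = FALSE]
      if (nrow(snvs)) {
        freq[cbind(snvs$pos + 1L, match(snvs$ref, NTS))] <- 1 - f
        freq[cbind(snvs$pos + 1L, match(snvs$alt, NTS))] <- f
      }
      prob <- freq * (1 - e) + (1 - freq) * e / 3
      cov <- rpois(P, config$sym_depth_mean)
      counts[, i, ] <- r_multinom_cells(cov, prob)
    }

    truth$cluster_snv_sets <- split(snv_table[, c("pos", "ref", "alt")],
                                    snv_table$cluster)
    truth$transmission_source <- setNames(
      ifelse(horizontal, "horizontal", "vertical"), hosts)
    truth$carried_snvs <- setNames(lapply(carried, function(ix)
      snv_table$pos[ix]), hosts)
    truth$snv_table <- snv_table

    acm <- allele_counts(counts, positions = seq_len(P) - 1L, samples = hosts)
    list(counts = acm, genes = genes, truth = truth)
  })
}

#' Simulate a complete synthetic hologenome
#'
#' Convenience wrapper running [simulate_host_genotypes()] then
#' [simulate_symbiont_counts()] from one configuration.
#'
#' @param config a [sim_config()] object.
#' @return A list with `gl`, `counts`, `genes`, `truth`.
#' @export
simulate_hologenome <- function(config) {
  h <- simulate_host_genotypes(config)
  s <- simulate_symbiont_counts(config, h$truth)
  list(gl = h$gl, counts = s$counts, genes = s$genes, truth = s$truth)
}
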