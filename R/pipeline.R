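#' Percentage of a count ratio, rounded half-up
#'
#' The small summary arithmetic used in reporting: `100 * numerator /
#' denominator`, rounded half-up (not banker's rounding) to `decimals`
#' places — e.g. 19 of 23 recovered genomes is 82.6.
#'
#' @param numerator,denominator non-negative counts, numerator <= denominator,
#'   denominator >= 1.
#' @param decimals decimal places, default 1.
#' @return The percentage as a number.
#' @export
percent_ratio <- function(numerator, denominator, decimals = 1L) {
  stopifnot(length(numerator) == 1L, length(denominator) == 1L)
  if (denominator < 1) stop("denominator must be >= 1")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must lie in [0, denominator]")
  x <- 100 * numerator / denominator
  scale <- 10^decimals
  floor(x * scale + 0.5) / scale
}

#' Pipeline run configuration
#'
#' All module thresholds with their standard defaults: SNV reporting
#' (min_variation 0.01, min_coverage 20, min_prevalence 0.90), host site
#' filters (snp_p 1e-6, maf 0.05, presence 0.50), ParaFit permutations
#' (n_perm 1000) and the enrichment call (q 0.05). Overrides are recorded
#' and echoed in the run report.
#'
#' @param sim a [sim_config()] for the simulated-input mode (default), or
#'   NULL to read inputs from files.
#' @param counts_tsv,genes_tsv,genes_fasta,gl_tsv input paths when `sim` is
#'   NULL.
#' @param min_variation,min_coverage,min_prevalence SNV filter thresholds.
#' @param snp_p,maf,presence host genotype-likelihood site filters.
#' @param n_perm,q ParaFit permutations and enrichment q ceiling.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory (created); NULL to skip writing files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       counts_tsv = NULL, genes_tsv = NULL,
                       genes_fasta = NULL, gl_tsv = NULL,
                       min_variation = 0.01, min_coverage = 20,
                       min_prevalence = 0.90,
                       snp_p = 1e-6, maf = 0.05, presence = 0.50,
                       n_perm = 1000L, q = 0.05,
                       seed = 1L, out_dir = NULL) {
  defaults <- list(min_variation = 0.01, min_coverage = 20,
                   min_prevalence = 0.90, snp_p = 1e-6, maf = 0.05,
                   presence = 0.50, n_perm = 1000L, q = 0.05)
  values <- list(min_variation = min_variation, min_coverage = min_coverage,
                 min_prevalence = min_prevalence, snp_p = snp_p, maf = maf,
                 presence = presence, n_perm = n_perm, q = q)
  overridden <- names(values)[!vapply(names(values), function(k)
    isTRUE(all.equal(values[[k]], defaults[[k]])), TRUE)]
  structure(c(values, list(sim = sim, counts_tsv = counts_tsv,
                           genes_tsv = genes_tsv, genes_fasta = genes_fasta,
                           gl_tsv = gl_tsv, seed = as.integer(seed),
                           out_dir = out_dir, overridden = overridden)),
            class = "run_config")
}

#' Load a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; keys under `sim:` are passed
#' to [sim_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

#' Run the full co-diversification pipeline
#'
#' Executes simulate (optional) -> SNV profiling -> codon variants
#' (pN/pS, SAAVs) -> host population structure -> ParaFit -> SAAV
#' enrichment -> summary report. All randomness derives from the config
#' seed, so a rerun with the same config reproduces every output exactly.
#' When `out_dir` is set, each stage's tables are written there as TSV
#' (plus Newick/JSON), and the report as JSON.
#'
#' @param config a [run_config()].
#' @return A list of class `summary_report`: per-stage record counts,
#'   ratios (with numerator and denominator), the `parafit` result, the
#'   host-vs-symbiont clustering `ari`, the config echo and a config hash.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message(sprintf(...))

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    log_line("stage simulate: seed %d", config$sim$seed)
    sim <- simulate_hologenome(config$sim)
    gl <- sim$gl; acm <- sim$counts; genes <- sim$genes; truth <- sim$truth
    if (!is.null(out)) {
      write_allele_counts(acm, file.path(out, "allele_counts.tsv"))
      write_gene_models(genes, file.path(out, "genes.tsv"),
                        file.path(out, "genes.fa"))
      write_genotype_likelihoods(gl, file.path(out, "genotype_likelihoods.tsv"))
      write_truth(truth, file.path(out, "truth.json"))
    }
  } else {
    log_line("stage load: reading inputs")
    acm <- read_allele_counts(config$counts_tsv)
    genes <- read_gene_models(config$genes_tsv, config$genes_fasta)
    gl <- read_genotype_likelihoods(config$gl_tsv)
    truth <- NULL
  }

  # --- symbiont SNVs --------------------------------------------------
  profile <- call_snvs(acm, min_variation = config$min_variation,
                       min_coverage = config$min_coverage,
                       min_prevalence = config$min_prevalence)
  log_line("stage snv: %d of %d positions retained",
           length(profile$positions), length(acm$positions))
  sym_dist <- snv_distance(profile, "presence_absence_jaccard")
  wardres <- ward_cluster(profile)
  if (!is.null(out)) {
    write_snv_profile(profile, file.path(out, "snv_profile.tsv"))
    write_snv_matrix(profile, file.path(out, "snv_matrix.tsv"))
    write_dist_matrix(sym_dist, file.path(out, "symbiont_distance.tsv"))
    writeLines(wardres$newick, file.path(out, "snv_dendrogram.nwk"))
  }

  # --- codon variants -------------------------------------------------
  ctab <- codon_counts_from_alleles(acm, genes,
                                    min_variation = config$min_variation)
  pnps <- pnps_table(ctab, min_variation = config$min_variation)

  # --- host structure -------------------------------------------------
  flt <- filter_sites(gl, snp_p_max = config$snp_p, maf_min = config$maf,
                      presence_min = config$presence)
  log_line("stage hostpg: %d of %d sites retained",
           length(flt$sites), length(gl$sites))
  structure_host <- genotype_covariance_pca(flt)
  host_dist <- host_distance(structure_host)
  saavs <- call_saavs(ctab, host_clusters = structure_host$clusters,
                      min_variation = config$min_variation)
  if (!is.null(out)) {
    tsv_write(pnps, file.path(out, "pnps.tsv"))
    tsv_write(saavs, file.path(out, "saavs.tsv"))
    tsv_write(data.frame(individual = names(structure_host$clusters),
                         cluster = structure_host$clusters,
                         structure_host$coordinates[, 1:2, drop = FALSE]),
              file.path(out, "host_structure.tsv"))
    write_dist_matrix(host_dist, file.path(out, "host_distance.tsv"))
  }

  # --- ParaFit --------------------------------------------------------
  pf <- parafit_global(host_dist, sym_dist, n_perm = config$n_perm,
                       seed = stream_seed(config$seed, "parafit"))
  log_line("stage parafit: statistic %.4g, p = %.4g", pf$statistic, pf$p_value)
  if (!is.null(out)) write_parafit_result(pf, file.path(out, "parafit.json"))

  # --- SAAV enrichment across host clusters ---------------------------
  enr <- NULL
  if (nrow(saavs) > 0) {
    occ <- saav_occurrence(ctab, saavs, min_variation = config$min_variation)
    enr <- enrichment_test(occ, structure_host$clusters[colnames(occ)],
                           q_max = config$q)
    if (!is.null(out)) tsv_write(enr, file.path(out, "saav_enrichment.tsv"))
  }

  # --- report ---------------------------------------------------------
  cong <- congruence(structure_host$clusters, wardres$labels_k2)
  ratios <- list(
    snv_retained = ratio_rec(length(profile$positions), length(acm$positions)),
    host_sites_retained = ratio_rec(length(flt$sites), length(gl$sites)),
    saav_enriched = if (!is.null(enr))
      ratio_rec(sum(enr$enriched), nrow(enr)) else NULL
  )
  config_echo <- config[c("min_variation", "min_coverage", "min_prevalence",
                          "snp_p", "maf", "presence", "n_perm", "q", "seed")]
  report <- structure(list(
    counts = list(positions = length(acm$positions),
                  snvs = length(profile$positions),
                  genes = nrow(genes), saavs = nrow(saavs),
                  host_sites = length(gl$sites),
                  host_sites_retained = length(flt$sites),
                  individuals = length(gl$individuals)),
    ratios = ratios,
    parafit = list(statistic = pf$statistic, p_value = pf$p_value,
                   n_perm = pf$n_perm),
    congruence_ari = cong$ari,
    truth_ari = if (!is.null(truth))
      mclust::adjustedRandIndex(structure_host$clusters,
                                truth$host_cluster[names(structure_host$clusters)])
      else NULL,
    pnps = pnps,
    config = config_echo,
    overridden = config$overridden,
    version = as.character(utils::packageVersion("codivkit")),
    config_hash = fnv1a(jsonlite::toJSON(config_echo, auto_unbox = TRUE))
  ), class = "summary_report")
  if (!is.null(out))
    jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", force = TRUE)
  report
}

#' @noRd
ratio_rec <- function(num, den) {
  list(numerator = num, denominator = den,
       percent = if (den >= 1) percent_ratio(num, den) else NA_real_)
}

#' @noRd
#' Per-sample 0/1 occurrence of each SAAV (competing amino acid above the
#' variation threshold in that sample).
saav_occurrence <- function(ctab, saavs, min_variation = 0.01) {
  samples <- sort(unique(ctab$sample))
  occ <- matrix(0L, nrow(saavs), length(samples),
                dimnames = list(paste0(saavs$gene_id, ":", saavs$codon_index),
                                samples))
  for (r in seq_len(nrow(saavs))) {
    sub <- ctab[ctab$gene_id == saavs$gene_id[r] &
                  ctab$codon_index == saavs$codon_index[r] &
                  !ctab$ambiguous & !is.na(ctab$codon), , drop = FALSE]
    for (s in unique(sub$sample)) {
      x <- sub[sub$sample == s, , drop = FALSE]
      tot <- sum(x$count)
      hit <- sum(x$count[x$aa == saavs$competing_aa[r]])
      if (tot > 0 && hit / tot > min_variation)
        occ[r, s] <- 1L
    }
  }
  occ
}

#' @export
print.summary_report <- function(x, ...) {
  cat("codivkit run report\n")
  cat(sprintf("  SNVs retained: %d/%d (%.1f%%)\n",
              x$ratios$snv_retained$numerator,
              x$ratios$snv_retained$denominator,
              x$ratios$snv_retained$percent))
  cat(sprintf("  host sites retained: %d/%d\n",
              x$ratios$host_sites_retained$numerator,
              x$ratios$host_sites_retained$denominator))
  cat(sprintf("  ParaFit: statistic %.4g, p = %.4g (%d permutations)\n",
              x$parafit$statistic, x$parafit$p_value, x$parafit$n_perm))
  cat(sprintf("  host vs symbiont clustering ARI: %.3f\n", x$congruence_ari))
  invisible(x)
}
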