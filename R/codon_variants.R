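#' Translate a codon under the standard genetic code
#' @param codon character vector of 3-mers.
#' @return Amino-acid single letters (`*` for stops).
#' @export
translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[toupper(codon)])
  if (anyNA(aa)) stop("not a valid codon: ", paste(codon[is.na(aa)], collapse = ", "))
  aa
}

#' Nei--Gojobori synonymous and non-synonymous site counts for one codon
#'
#' For each of the codon's three positions, the fraction of the three
#' possible single-nucleotide changes that are synonymous is accumulated as
#' synonymous "sites"; the remainder are non-synonymous sites. Changes that
#' create a stop codon count as non-synonymous. The two site counts always
#' sum to exactly 3.
#'
#' @param codon a sense codon (3-mer).
#' @return Named numeric vector `c(syn_sites, nonsyn_sites)`.
#' @export
ng_site_counts <- function(codon) {
  codon <- toupper(codon)
  aa0 <- translate_codon(codon)
  if (aa0 == "*") stop("stop codon has no Nei-Gojobori site counts: ", codon)
  nts <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    for (nt in setdiff(NTS, nts[p])) {
      mut <- nts
      mut[p] <- nt
      if (translate_codon(paste(mut, collapse = "")) == aa0)
        syn <- syn + 1 / 3
    }
  }
  c(syn_sites = syn, nonsyn_sites = 3 - syn)
}

#' Read a substitution matrix in NCBI flat format
#'
#' Parses the standard BLOSUM/PAM text layout: `#` comment lines, a header
#' row of one-letter codes, then one row of integer scores per residue.
#'
#' @param path file path; defaults to the BLOSUM62 matrix bundled with the
#'   package.
#' @return Integer matrix with residue dimnames.
#' @export
read_blosum <- function(path = system.file("extdata", "BLOSUM62.txt",
                                           package = "codivkit")) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  rownames(m) <- vapply(rows, `[`, "", 1L)
  colnames(m) <- header
  if (max(abs(m[header, header] - t(m[header, header]))) != 0)
    stop("substitution matrix is not symmetric")
  m
}

#' @noRd
#' Positions (1-based, genome order) of the k-th codon of a gene, in reading
#' order, together with whether counts must be complemented.
gene_codon_positions <- function(gene, k) {
  if (gene$strand == "+") {
    gene$start + 3L * (k - 1L) + 1:3
  } else {
    gene$end - 3L * (k - 1L) - (0:2)
  }
}

#' Reconstruct per-codon variant counts from nucleotide allele counts
#'
#' Single-codon variants (SCVs) are properly derived from reads spanning a
#' whole codon; absent read-level data, this reconstructs them from the
#' per-position allele counts under an independence approximation that is
#' exact when at most one of the codon's three positions is variable (the
#' synthetic generator guarantees this). Codon coverage is the minimum of
#' the three per-position coverages; positions whose departure from
#' consensus exceeds `min_variation` count as variable. Codons with two or
#' more variable positions are flagged ambiguous and excluded from all
#' downstream statistics (a message reports how many). Minus-strand genes
#' are reverse-complemented before framing.
#'
#' @param acm an [allele_counts()] object.
#' @param genes gene map data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open), `strand`; coordinates must lie within `acm` and
#'   spans must be multiples of 3.
#' @param min_variation departure threshold defining a variable position,
#'   default 0.01.
#' @return A data frame of class `codon_variants` with one row per
#'   (gene, codon_index, sample, codon): columns `gene_id`, `codon_index`
#'   (1-based), `sample`, `codon_coverage`, `codon`, `count`,
#'   `consensus_codon`, `aa`, `ambiguous`. Ambiguous codons carry NA codon
#'   and count. Counts per (gene, codon, sample) sum to the codon coverage.
#' @export
codon_counts_from_alleles <- function(acm, genes, min_variation = 0.01) {
  stopifnot(inherits(acm, "allele_counts"))
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(genes))) stop("gene map lacks columns: ",
                                         paste(setdiff(need, names(genes)), collapse = ", "))
  if (any((genes$end - genes$start) %% 3L != 0L))
    stop("gene span not a multiple of 3: frame violation")
  if (any(genes$start < min(acm$positions) | genes$end - 1L > max(acm$positions)))
    stop("gene outside the position range of the allele-count matrix")

  pos_index <- match(0:max(acm$positions), acm$positions)
  cov_all <- coverage(acm)
  n_amb <- 0L
  out <- vector("list", nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, ]
    n_codons <- (gene$end - gene$start) %/% 3L
    rows <- vector("list", n_codons)
    for (k in seq_len(n_codons)) {
      gpos <- gene_codon_positions(gene, k)       # genome order along codon
      ridx <- pos_index[gpos]
      if (anyNA(ridx)) stop("gene position absent from allele-count matrix")
      rows[[k]] <- codon_rows(acm, ridx, gene, k, min_variation)
      n_amb <- n_amb + attr(rows[[k]], "n_ambiguous")
    }
    out[[gi]] <- do.call(rbind, rows)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  if (n_amb > 0)
    message(sprintf("%d (codon, sample) entries had >= 2 variable positions: flagged ambiguous and excluded", n_amb))
  class(tab) <- c("codon_variants", class(tab))
  tab
}

#' @noRd
#' Rows of the codon-variant table for one codon of one gene, all samples.
codon_rows <- function(acm, ridx, gene, k, min_variation) {
  minus <- gene$strand == "-"
  S <- length(acm$samples)
  counts3 <- acm$counts[ridx, , , drop = FALSE]      # 3 x S x 4
  if (minus) counts3 <- counts3[, , 4:1, drop = FALSE]  # complement counts
  cov3 <- counts3[, , 1] + counts3[, , 2] + counts3[, , 3] + counts3[, , 4]
  cov3 <- matrix(cov3, nrow = 3L)
  res <- vector("list", S)
  n_amb <- 0L
  for (j in seq_len(S)) {
    ccov <- min(cov3[, j])
    cons <- character(3); dpos <- numeric(3)
    for (p in 1:3) {
      c4 <- counts3[p, j, ]
      if (cov3[p, j] == 0) { cons[p] <- NA; next }
      i1 <- which.max(c4)
      cons[p] <- NTS[i1]
      dpos[p] <- 1 - c4[i1] / cov3[p, j]
    }
    if (ccov == 0L) {
      res[[j]] <- data.frame(gene_id = gene$gene_id, codon_index = k,
                             sample = acm$samples[j], codon_coverage = 0L,
                             codon = NA_character_, count = NA_integer_,
                             consensus_codon = NA_character_,
                             aa = NA_character_, ambiguous = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    variable <- which(dpos > min_variation)
    cons_codon <- paste(cons, collapse = "")
    if (length(variable) >= 2L) {
      n_amb <- n_amb + 1L
      res[[j]] <- data.frame(gene_id = gene$gene_id, codon_index = k,
                             sample = acm$samples[j], codon_coverage = ccov,
                             codon = NA_character_, count = NA_integer_,
                             consensus_codon = cons_codon,
                             aa = NA_character_, ambiguous = TRUE,
                             stringsAsFactors = FALSE)
      next
    }
    if (length(variable) == 0L) {
      codons <- cons_codon
      cnts <- ccov
    } else {
      v <- variable
      c4 <- counts3[v, j, ]
      nz <- which(c4 > 0)
      codons <- vapply(nz, function(i) {
        trip <- cons; trip[v] <- NTS[i]; paste(trip, collapse = "")
      }, "")
      cnts <- allocate_counts(ccov, c4[nz])
      keep <- cnts > 0
      codons <- codons[keep]; cnts <- cnts[keep]
    }
    res[[j]] <- data.frame(gene_id = gene$gene_id, codon_index = k,
                           sample = acm$samples[j], codon_coverage = ccov,
                           codon = codons, count = as.integer(cnts),
                           consensus_codon = cons_codon,
                           aa = translate_codon(codons), ambiguous = FALSE,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "n_ambiguous") <- n_amb
  out
}

#' Per-gene pN/pS from codon variants
#'
#' The within-population selection statistic: observed non-synonymous and
#' synonymous polymorphisms, normalized by Nei--Gojobori expected site
#' counts over the gene's unambiguous consensus codons,
#' `pN/pS = (N_obs/N_sites) / (S_obs/S_sites)`. Every non-consensus codon
#' whose frequency exceeds `min_variation` contributes one polymorphism,
#' classified synonymous iff it encodes the consensus codon's amino acid.
#' Values above one point to positive selection pressure on the gene.
#'
#' @param tab a `codon_variants` table from [codon_counts_from_alleles()].
#' @param gene_id gene to evaluate (must occur in `tab`).
#' @param sample_scope `"pooled"` (default): codon counts are summed over
#'   samples before variants are called; `"per_sample"`: one result per
#'   sample.
#' @param min_variation variant-frequency threshold, default 0.01.
#' @return For `"pooled"`, a one-row data frame with `gene_id`, `N_obs`,
#'   `S_obs`, `N_sites`, `S_sites`, `pnps` (NA when no variants at all,
#'   `Inf` when `S_obs = 0` with `N_obs > 0`); for `"per_sample"`, one such
#'   row per sample.
#' @export
gene_pnps <- function(tab, gene_id, sample_scope = c("pooled", "per_sample"),
                      min_variation = 0.01) {
  stopifnot(inherits(tab, "codon_variants"))
  sample_scope <- match.arg(sample_scope)
  g <- tab[tab$gene_id == gene_id & !tab$ambiguous & !is.na(tab$codon), ,
           drop = FALSE]
  if (nrow(g) == 0L) stop("gene has no unambiguous codon observations: ", gene_id)
  if (sample_scope == "per_sample") {
    res <- lapply(unique(g$sample), function(s)
      cbind(sample = s, pnps_one(g[g$sample == s, , drop = FALSE],
                                 gene_id, min_variation)))
    return(do.call(rbind, res))
  }
  pnps_one(g, gene_id, min_variation)
}

#' @noRd
pnps_one <- function(g, gene_id, min_variation) {
  agg <- aggregate(count ~ codon_index + codon, data = g, FUN = sum)
  N_obs <- 0L; S_obs <- 0L; N_sites <- 0; S_sites <- 0
  for (k in sort(unique(agg$codon_index))) {
    a <- agg[agg$codon_index == k, , drop = FALSE]
    a <- a[order(a$codon), , drop = FALSE]       # deterministic tie order
    tot <- sum(a$count)
    cons <- a$codon[which.max(a$count)]
    sites <- ng_site_counts(cons)
    S_sites <- S_sites + sites[["syn_sites"]]
    N_sites <- N_sites + sites[["nonsyn_sites"]]
    vars <- a[a$codon != cons & a$count / tot > min_variation, , drop = FALSE]
    if (nrow(vars)) {
      syn <- translate_codon(vars$codon) == translate_codon(cons)
      S_obs <- S_obs + sum(syn)
      N_obs <- N_obs + sum(!syn)
    }
  }
  pnps <- if (N_obs + S_obs == 0L) NA_real_
          else if (S_obs == 0L) Inf
          else (N_obs / N_sites) / (S_obs / S_sites)
  data.frame(gene_id = gene_id, N_obs = N_obs, S_obs = S_obs,
             N_sites = N_sites, S_sites = S_sites, pnps = pnps,
             stringsAsFactors = FALSE)
}

#' pN/pS for every gene in a codon-variant table
#' @inheritParams gene_pnps
#' @return One row per gene (pooled scope).
#' @export
pnps_table <- function(tab, min_variation = 0.01) {
  do.call(rbind, lapply(unique(tab$gene_id), function(g)
    gene_pnps(tab, g, "pooled", min_variation)))
}

#' Call single amino-acid variants (SAAVs)
#'
#' Amino-acid frequency vectors are derived by translating the reconstructed
#' codon counts, pooled over samples per (gene, codon). A SAAV is emitted
#' where the most frequent non-consensus amino acid exceeds `min_variation`.
#' Each record carries the BLOSUM62 interchangeability score of the
#' (consensus, competing) pair taken verbatim from the matrix file, and the
#' per-host-cluster prevalence: the fraction of a cluster's samples in which
#' the competing amino acid's frequency exceeds `min_variation`.
#'
#' @param tab a `codon_variants` table.
#' @param blosum substitution matrix from [read_blosum()].
#' @param host_clusters named vector mapping sample id to cluster label; NULL
#'   for no prevalence columns.
#' @param min_variation amino-acid frequency threshold, default 0.01.
#' @return Data frame with one row per SAAV: `gene_id`, `codon_index`,
#'   `consensus_aa`, `competing_aa`, `departure` (1 - consensus AA
#'   frequency), `blosum62`, and `prevalence_<cluster>` columns.
#' @export
call_saavs <- function(tab, blosum = read_blosum(), host_clusters = NULL,
                       min_variation = 0.01) {
  stopifnot(inherits(tab, "codon_variants"))
  g <- tab[!tab$ambiguous & !is.na(tab$codon), , drop = FALSE]
  if (nrow(g) == 0L) return(empty_saavs(host_clusters))
  clusters <- if (is.null(host_clusters)) NULL else sort(unique(host_clusters))
  key <- paste(g$gene_id, g$codon_index)
  res <- lapply(split(g, key), function(a) {
    aa_tot <- tapply(a$count, a$aa, sum)
    aa_tot <- aa_tot[order(names(aa_tot))]
    tot <- sum(aa_tot)
    cons <- names(aa_tot)[which.max(aa_tot)]
    others <- aa_tot[names(aa_tot) != cons]
    if (length(others) == 0L) return(NULL)
    comp <- names(others)[which.max(others)]
    if (others[comp] / tot <= min_variation) return(NULL)
    if (!(cons %in% rownames(blosum)) || !(comp %in% colnames(blosum)))
      stop("amino-acid pair missing from substitution matrix: ", cons, "/", comp)
    row <- data.frame(gene_id = a$gene_id[1], codon_index = a$codon_index[1],
                      consensus_aa = cons, competing_aa = comp,
                      departure = 1 - aa_tot[[cons]] / tot,
                      blosum62 = blosum[cons, comp], stringsAsFactors = FALSE)
    if (!is.null(clusters)) {
      for (cl in clusters) {
        ss <- names(host_clusters)[host_clusters == cl]
        sub <- a[a$sample %in% ss, , drop = FALSE]
        pass <- vapply(split(sub, sub$sample), function(x) {
          xt <- sum(x$count)
          xc <- sum(x$count[x$aa == comp])
          xt > 0 && xc / xt > min_variation
        }, TRUE)
        row[[paste0("prevalence_", cl)]] <-
          if (length(ss)) sum(pass) / length(ss) else NA_real_
      }
    }
    row
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(out)) return(empty_saavs(host_clusters))
  rownames(out) <- NULL
  out[order(out$gene_id, out$codon_index), , drop = FALSE]
}

#' @noRd
empty_saavs <- function(host_clusters) {
  out <- data.frame(gene_id = character(), codon_index = integer(),
                    consensus_aa = character(), competing_aa = character(),
                    departure = numeric(), blosum62 = integer(),
                    stringsAsFactors = FALSE)
  if (!is.null(host_clusters))
    for (cl in sort(unique(host_clusters)))
      out[[paste0("prevalence_", cl)]] <- numeric()
  out
}
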