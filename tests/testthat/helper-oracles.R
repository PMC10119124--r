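# Deliberately naive, independent reimplementations used as oracles.
# These must stay ignorant of the package's internal code paths.

# Triple-gate SNV filter: explicit loops over positions and samples.
naive_snv_filter <- function(counts_arr, min_variation, min_coverage,
                             min_prevalence) {
  P <- dim(counts_arr)[1]; S <- dim(counts_arr)[2]
  keep <- logical(P)
  for (p in seq_len(P)) {
    pass <- 0L
    for (s in seq_len(S)) {
      c4 <- counts_arr[p, s, ]
      cov <- sum(c4)
      if (cov >= min_coverage && (1 - max(c4) / cov) > min_variation)
        pass <- pass + 1L
    }
    keep[p] <- pass / S >= min_prevalence
  }
  which(keep)
}

# Pairwise Jaccard distances by a double loop over sample SNV sets.
naive_jaccard <- function(sets) {
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- if (u == 0) 0 else 1 - length(intersect(sets[[i]], sets[[j]])) / u
  }
  d
}

# O(n^3) agglomerative Ward (ward.D2 Lance-Williams update on Euclidean
# distances); returns the sorted merge heights.
naive_ward_heights <- function(m) {
  d <- as.matrix(dist(m))
  n <- nrow(d)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (d[active[i], active[j]] < best[1])
        best <- c(d[active[i], active[j]], i, j)
    ai <- active[best[2]]; aj <- active[best[3]]
    heights <- c(heights, best[1])
    for (t in setdiff(active, c(ai, aj))) {
      ni <- size[ai]; nj <- size[aj]; nt <- size[t]
      d2 <- ((ni + nt) * d[ai, t]^2 + (nj + nt) * d[aj, t]^2 -
               nt * d[ai, aj]^2) / (ni + nj + nt)
      d[ai, t] <- d[t, ai] <- sqrt(d2)
    }
    size[ai] <- size[ai] + size[aj]
    active <- setdiff(active, aj)
  }
  sort(heights)
}

# Grid-search ML allele frequency (independent of the EM implementation).
grid_ml_freq <- function(L) {
  fs <- seq(0, 1, by = 0.001)
  ll <- vapply(fs, function(f)
    sum(log(L[, 1] * (1 - f)^2 + L[, 2] * 2 * f * (1 - f) + L[, 3] * f^2)),
    0)
  fs[which.max(ll)]
}

# Nei-Gojobori site counts by brute-force 9-neighbor enumeration using an
# independent translation routine (seqinr).
naive_ng <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  aa0 <- seqinr::translate(tolower(nts))
  syn <- 0
  for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), nts[p])) {
    mut <- nts; mut[p] <- nt
    if (seqinr::translate(tolower(mut)) == aa0) syn <- syn + 1 / 3
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Naive pooled pN/pS from a list of per-codon count tables
# (each element: named integer vector of codon counts for one codon index).
naive_pnps <- function(codon_counts, min_variation = 0.01) {
  N_obs <- 0; S_obs <- 0; N_sites <- 0; S_sites <- 0
  for (cc in codon_counts) {
    cc <- cc[order(names(cc))]
    cons <- names(cc)[which.max(cc)]
    ng <- naive_ng(cons)
    S_sites <- S_sites + ng[["syn"]]
    N_sites <- N_sites + ng[["nonsyn"]]
    for (cod in names(cc)) {
      if (cod == cons) next
      if (cc[[cod]] / sum(cc) > min_variation) {
        same <- seqinr::translate(tolower(strsplit(cod, "")[[1]])) ==
          seqinr::translate(tolower(strsplit(cons, "")[[1]]))
        if (same) S_obs <- S_obs + 1 else N_obs <- N_obs + 1
      }
    }
  }
  pnps <- if (N_obs + S_obs == 0) NA_real_
          else if (S_obs == 0) Inf
          else (N_obs / N_sites) / (S_obs / S_sites)
  list(N_obs = N_obs, S_obs = S_obs, N_sites = N_sites, S_sites = S_sites,
       pnps = pnps)
}

# Random allele-count fixture: mostly-reference positions with a sprinkling
# of genuinely variable ones, random coverage.
random_acm <- function(P = 40, S = 8, depth = 40, p_variable = 0.3) {
  counts <- array(0L, c(P, S, 4L))
  for (p in seq_len(P)) {
    ref <- sample(4, 1)
    alt <- sample(setdiff(1:4, ref), 1)
    f <- if (runif(1) < p_variable) runif(1, 0.02, 0.5) else 0
    for (s in seq_len(S)) {
      cov <- rpois(1, depth)
      a <- rbinom(1, cov, f)
      counts[p, s, ref] <- cov - a
      counts[p, s, alt] <- counts[p, s, alt] + a
    }
  }
  allele_counts(counts, seq_len(P) - 1L, sprintf("s%02d", seq_len(S)))
}

# Small simulated hologenome used by several tests.
small_sim <- function(seed = 5, h_transmission = 0, n_per = 8) {
  sim_config(n_hosts_per_cluster = n_per, n_host_sites = 400,
             host_depth_mean = 15, sym_genome = rep(25L, 4),
             n_cluster_snvs = c(4L, 8L), sym_depth_mean = 80,
             within_host_minor_freq = 0.3,
             h_transmission = h_transmission, seed = seed)
}

# All 24 permutations of 1:4, one per row.
gtools_permutations_4 <- function() {
  out <- NULL
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    out <- rbind(out, c(a, b, cc, setdiff(1:4, c(a, b, cc))))
  out
}

all_sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}
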