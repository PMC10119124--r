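make_acm_from_counts <- function(counts) {
  allele_counts(counts, seq_len(dim(counts)[1]) - 1L,
                sprintf("s%02d", seq_len(dim(counts)[2])))
}

one_gene <- function(n_codons, strand = "+") {
  data.frame(gene_id = "g1", contig = "c", start = 0L,
             end = 3L * n_codons, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("codon reconstruction handles fixed, single-variable and ambiguous codons", {
  nt <- function(x) match(x, c("A", "C", "G", "T"))
  counts <- array(0L, c(9, 1, 4))
  # codon 1: ATG fixed at coverage 100
  counts[1, 1, nt("A")] <- 100L
  counts[2, 1, nt("T")] <- 100L
  counts[3, 1, nt("G")] <- 100L
  # codon 2: consensus TTT with third position split T:70/C:30
  counts[4, 1, nt("T")] <- 100L
  counts[5, 1, nt("T")] <- 100L
  counts[6, 1, nt("T")] <- 70L
  counts[6, 1, nt("C")] <- 30L
  # codon 3: two variable positions -> ambiguous
  counts[7, 1, nt("G")] <- 60L; counts[7, 1, nt("A")] <- 40L
  counts[8, 1, nt("G")] <- 60L; counts[8, 1, nt("C")] <- 40L
  counts[9, 1, nt("A")] <- 100L
  acm <- make_acm_from_counts(counts)
  tab <- suppressMessages(codon_counts_from_alleles(acm, one_gene(3)))

  c1 <- tab[tab$codon_index == 1, ]
  expect_equal(c1$codon, "ATG")
  expect_equal(c1$count, 100L)
  expect_equal(c1$codon_coverage, 100L)
  expect_equal(c1$aa, "M")

  c2 <- tab[tab$codon_index == 2, ]
  expect_setequal(c2$codon, c("TTT", "TTC"))
  expect_equal(c2$count[match(c("TTT", "TTC"), c2$codon)], c(70L, 30L))
  expect_equal(unique(c2$consensus_codon), "TTT")

  c3 <- tab[tab$codon_index == 3, ]
  expect_true(all(c3$ambiguous))
  expect_true(all(is.na(c3$codon)))
})

test_that("codon counts sum to codon coverage under uneven position coverage", {
  nt <- function(x) match(x, c("A", "C", "G", "T"))
  counts <- array(0L, c(3, 1, 4))
  counts[1, 1, nt("T")] <- 95L
  counts[2, 1, nt("T")] <- 80L           # codon coverage = 80
  counts[3, 1, nt("T")] <- 70L; counts[3, 1, nt("A")] <- 30L
  acm <- make_acm_from_counts(counts)
  tab <- codon_counts_from_alleles(acm, one_gene(1))
  expect_equal(sum(tab$count), 80L)
  expect_setequal(tab$codon, c("TTT", "TTA"))
  expect_equal(sum(tab$count[tab$codon == "TTA"]), 24L)  # 0.3 * 80
})

test_that("minus-strand genes are reverse-complemented before framing", {
  nt <- function(x) match(x, c("A", "C", "G", "T"))
  # genome forward strand CAT; reverse strand reads ATG
  counts <- array(0L, c(3, 1, 4))
  counts[1, 1, nt("C")] <- 50L
  counts[2, 1, nt("A")] <- 50L
  counts[3, 1, nt("T")] <- 50L
  acm <- make_acm_from_counts(counts)
  tab <- codon_counts_from_alleles(acm, one_gene(1, strand = "-"))
  expect_equal(tab$codon, "ATG")
  expect_equal(tab$aa, "M")
})

test_that("frame violations and out-of-range genes are rejected", {
  acm <- make_acm_from_counts(array(10L, c(6, 1, 4)))
  bad <- one_gene(1); bad$end <- 4L
  expect_error(codon_counts_from_alleles(acm, bad), "frame")
  far <- one_gene(4)  # 12 nt > 6 positions
  expect_error(codon_counts_from_alleles(acm, far), "range")
})

test_that("Nei-Gojobori site counts match enumeration for canonical codons", {
  expect_equal(ng_site_counts("TTT"),
               c(syn_sites = 1 / 3, nonsyn_sites = 8 / 3))
  expect_equal(ng_site_counts("TGG"), c(syn_sites = 0, nonsyn_sites = 3))
  expect_equal(ng_site_counts("GGG"), c(syn_sites = 1, nonsyn_sites = 2))
  expect_error(ng_site_counts("TAA"), "stop")
})

test_that("site counts agree with a brute-force oracle over all 61 sense codons", {
  for (codon in all_sense_codons()) {
    got <- ng_site_counts(codon)
    oracle <- naive_ng(codon)
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12,
                 label = codon)
    expect_equal(sum(got), 3)
  }
})

test_that("single-codon genes give the textbook pN/pS outcomes", {
  nt <- function(x) match(x, c("A", "C", "G", "T"))
  base <- array(0L, c(3, 1, 4))
  base[1, 1, nt("T")] <- 100L
  base[2, 1, nt("T")] <- 100L

  syn <- base; syn[3, 1, nt("T")] <- 70L; syn[3, 1, nt("C")] <- 30L
  tab <- codon_counts_from_alleles(make_acm_from_counts(syn), one_gene(1))
  r <- gene_pnps(tab, "g1")
  expect_equal(r$N_obs, 0); expect_equal(r$S_obs, 1)
  expect_equal(r$pnps, 0)

  nonsyn <- base; nonsyn[3, 1, nt("T")] <- 70L; nonsyn[3, 1, nt("A")] <- 30L
  tab <- codon_counts_from_alleles(make_acm_from_counts(nonsyn), one_gene(1))
  r <- gene_pnps(tab, "g1")
  expect_equal(r$S_obs, 0); expect_equal(r$N_obs, 1)
  expect_true(is.infinite(r$pnps))

  fixed <- base; fixed[3, 1, nt("T")] <- 100L
  tab <- codon_counts_from_alleles(make_acm_from_counts(fixed), one_gene(1))
  expect_true(is.na(gene_pnps(tab, "g1")$pnps))
})

test_that("pN/pS matches a naive recomputation on random simulated genes", {
  withr::with_seed(404, {
    sense <- all_sense_codons()
    for (rep in 1:100) {
      n_codons <- sample(3:8, 1)
      cons <- sample(sense, n_codons, replace = TRUE)
      counts <- array(0L, c(3 * n_codons, 1, 4))
      codon_counts <- list()
      for (k in seq_len(n_codons)) {
        trip <- strsplit(cons[k], "")[[1]]
        cov <- 100L
        cc <- setNames(cov, cons[k])
        if (runif(1) < 0.6) {  # inject one single-position variant
          p <- sample(3, 1)
          alt <- sample(setdiff(c("A", "C", "G", "T"), trip[p]), 1)
          vf <- sample(c(0.005, 0.05, 0.2, 0.4), 1)
          a <- as.integer(round(cov * vf))
          mut <- trip; mut[p] <- alt
          cc <- setNames(c(cov - a, a), c(cons[k], paste(mut, collapse = "")))
          cc <- cc[cc > 0]
        }
        codon_counts[[k]] <- cc
        for (p in 1:3) {
          for (cod in names(cc)) {
            ntc <- strsplit(cod, "")[[1]][p]
            i <- match(ntc, c("A", "C", "G", "T"))
            counts[3 * (k - 1) + p, 1, i] <-
              counts[3 * (k - 1) + p, 1, i] + cc[[cod]]
          }
        }
      }
      acm <- make_acm_from_counts(counts)
      tab <- codon_counts_from_alleles(acm, one_gene(n_codons))
      got <- gene_pnps(tab, "g1")
      oracle <- naive_pnps(codon_counts)
      expect_equal(got$N_obs, oracle$N_obs)
      expect_equal(got$S_obs, oracle$S_obs)
      expect_equal(got$N_sites, oracle$N_sites, tolerance = 1e-12)
      expect_equal(got$pnps, oracle$pnps, tolerance = 1e-12)
      # exact site accounting over unambiguous codons
      expect_equal(got$N_sites + got$S_sites, 3 * n_codons, tolerance = 1e-12)
    }
  })
})

test_that("BLOSUM62 file parses and matches reference values", {
  b <- read_blosum()
  expect_equal(b["A", "A"], 4L)
  expect_equal(b["W", "W"], 11L)
  expect_equal(b["F", "L"], 0L)
  expect_equal(b["E", "Q"], 2L)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  expect_equal(b[aas, aas], t(b[aas, aas]))
  # identity always scores maximal within its row over the 20 standard AAs
  for (a in aas) expect_equal(unname(which.max(b[a, aas])), match(a, aas))
})

test_that("SAAVs are called only for amino-acid-changing splits, with scores and prevalence", {
  nt <- function(x) match(x, c("A", "C", "G", "T"))
  counts <- array(0L, c(3, 4, 4))
  counts[1, , nt("T")] <- 100L
  counts[2, , nt("T")] <- 100L
  # samples 1-2: TTT/TTA 70/30 (F -> L); samples 3-4: synonymous TTT/TTC
  counts[3, 1:2, nt("T")] <- 70L; counts[3, 1:2, nt("A")] <- 30L
  counts[3, 3:4, nt("T")] <- 70L; counts[3, 3:4, nt("C")] <- 30L
  acm <- make_acm_from_counts(counts)
  tab <- codon_counts_from_alleles(acm, one_gene(1))
  clusters <- setNames(c(1, 1, 2, 2), acm$samples)
  saavs <- call_saavs(tab, host_clusters = clusters)
  expect_equal(nrow(saavs), 1L)
  expect_equal(saavs$consensus_aa, "F")
  expect_equal(saavs$competing_aa, "L")
  expect_equal(saavs$blosum62, read_blosum()["F", "L"])
  expect_equal(saavs$prevalence_1, 1)
  expect_equal(saavs$prevalence_2, 0)

  # purely synonymous split: no SAAV
  counts[3, 1:2, nt("A")] <- 0L
  counts[3, 1:2, nt("C")] <- 30L
  tab2 <- codon_counts_from_alleles(make_acm_from_counts(counts), one_gene(1))
  expect_equal(nrow(call_saavs(tab2, host_clusters = clusters)), 0L)
})

test_that("translating reconstructed codons reproduces SAAV frequencies", {
  sim <- simulate_hologenome(small_sim(seed = 7))
  tab <- suppressMessages(
    codon_counts_from_alleles(sim$counts, sim$genes))
  saavs <- call_saavs(tab, host_clusters = sim$truth$host_cluster)
  for (r in seq_len(min(nrow(saavs), 10))) {
    sub <- tab[tab$gene_id == saavs$gene_id[r] &
                 tab$codon_index == saavs$codon_index[r] &
                 !tab$ambiguous & !is.na(tab$codon), ]
    aa_freq <- tapply(sub$count, translate_codon(sub$codon), sum)
    aa_freq <- aa_freq / sum(aa_freq)
    expect_equal(saavs$departure[r],
                 unname(1 - aa_freq[saavs$consensus_aa[r]]),
                 tolerance = 1e-12)
  }
})
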