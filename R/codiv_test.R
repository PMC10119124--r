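#' Principal coordinates analysis with optional Cailliez correction
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. With `correction = "cailliez_if_needed"`, if the smallest
#' eigenvalue is materially negative (below -1e-8 times the largest), the
#' Cailliez constant c — the largest real eigenvalue of the 2n x 2n block
#' matrix rbind(cbind(0, 2*D1), cbind(-I, -4*D2)), with D1 the centered
#' -d^2/2 and D2 the centered -d/2 — is added to every off-diagonal
#' distance and the analysis recomputed, which removes the negative
#' eigenvalues up to numerical tolerance.
#'
#' @param d square symmetric distance matrix, zero diagonal.
#' @param correction `"cailliez_if_needed"` (default) or `"none"`.
#' @return An object of class `pcoa_result`: `coordinates` (objects x axes,
#'   positive-eigenvalue axes only), `eigenvalues` (all, descending),
#'   `correction_constant` (0 when not triggered), `n_negative_pre`.
#' @export
pcoa <- function(d, correction = c("cailliez_if_needed", "none")) {
  correction <- match.arg(correction)
  d <- as_dist_matrix(d, labels = rownames(d))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 objects")
  dec <- pcoa_eigen(d)
  tol <- 1e-8 * max(abs(dec$values[1]), .Machine$double.eps)
  n_neg <- sum(dec$values < -tol)
  cc <- 0
  if (correction == "cailliez_if_needed" && min(dec$values) < -tol) {
    cc <- cailliez_constant(d)
    d2 <- d + cc
    diag(d2) <- 0
    dec <- pcoa_eigen(d2)
  }
  keep <- dec$values > 1e-8 * max(dec$values, .Machine$double.eps)
  coords <- dec$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(dec$values[keep]), sum(keep))
  rownames(coords) <- rownames(d)
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = dec$values,
                 correction_constant = cc, n_negative_pre = n_neg),
            class = "pcoa_result")
}

#' @noRd
pcoa_eigen <- function(d) {
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% (-0.5 * d^2) %*% J
  G <- (G + t(G)) / 2
  eigen(G, symmetric = TRUE)
}

#' Cailliez additive constant for a non-Euclidean distance matrix
#'
#' The smallest constant c such that d + c (off-diagonal) has a full
#' Euclidean embedding: the largest real eigenvalue of the classical
#' 2n x 2n companion block matrix.
#'
#' @param d square symmetric distance matrix.
#' @return Non-negative scalar c.
#' @export
cailliez_constant <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  D1 <- J %*% (-0.5 * d^2) %*% J
  D2 <- J %*% (-0.5 * d) %*% J
  M <- rbind(cbind(matrix(0, n, n), 2 * D1),
             cbind(-diag(n), -4 * D2))
  ev <- eigen(M, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < 1e-8 * max(1, abs(ev))])
  max(0, max(re))
}

#' Global ParaFit test of host-symbiont co-diversification
#'
#' Host and symbiont distance matrices are embedded by [pcoa()] (Cailliez
#' correction applied per matrix when needed), giving coordinate matrices B
#' (hosts) and C (symbionts). With the 0/1 association matrix A (rows =
#' symbionts, columns = hosts), the global statistic is the sum of squared
#' entries of D = t(C) A B. The null distribution permutes host links: for
#' the one-to-one associations this package produces, hosts are relabeled by
#' a single random permutation per replicate (the exact exchangeable null);
#' for general associations each symbiont's host links are shuffled
#' independently (the classical ParaFit null). The p-value uses the add-one
#' estimator (1 + b) / (1 + n_perm), so with 1000 permutations the smallest
#' attainable p is 1/1001 < 0.001.
#'
#' @param host_d host distance matrix (n_hosts x n_hosts).
#' @param sym_d symbiont distance matrix (n_sym x n_sym).
#' @param assoc 0/1 matrix, symbionts x hosts; every symbiont must link to
#'   at least one host. Default: one-to-one identity (host i carries
#'   symbiont i), valid only when dimensions agree.
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed for the permutation stream (NULL leaves the RNG
#'   state alone).
#' @param scheme `"auto"` (default), `"per_symbiont"` or `"host_labels"`.
#'   With `"auto"`, a one-to-one association uses the host-label
#'   permutation (the exact exchangeable null in that design), and any
#'   other association the per-symbiont link shuffle.
#' @return An object of class `parafit_result`: `statistic`, `p_value`,
#'   `permutations` (null statistics), `n_perm`, `seed`, `scheme`, and the
#'   two PCoA correction constants.
#' @export
parafit_global <- function(host_d, sym_d, assoc = NULL, n_perm = 1000L,
                           seed = NULL,
                           scheme = c("auto", "per_symbiont", "host_labels")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  host_d <- as_dist_matrix(host_d, labels = rownames(host_d))
  sym_d <- as_dist_matrix(sym_d, labels = rownames(sym_d))
  n_host <- nrow(host_d)
  n_sym <- nrow(sym_d)
  if (is.null(assoc)) {
    if (n_host != n_sym) stop("default one-to-one association needs equal sizes")
    assoc <- diag(1, n_sym, n_host)
  }
  assoc <- as.matrix(assoc)
  if (nrow(assoc) != n_sym || ncol(assoc) != n_host)
    stop("association matrix must be symbionts x hosts")
  if (!all(assoc %in% c(0, 1))) stop("association matrix must be 0/1")
  if (any(rowSums(assoc) < 1)) stop("every symbiont must link to >= 1 host")
  if (scheme == "auto") {
    one_to_one <- n_sym == n_host && all(rowSums(assoc) == 1) &&
      all(colSums(assoc) == 1)
    scheme <- if (one_to_one) "host_labels" else "per_symbiont"
  }

  host_pc <- pcoa(host_d, "cailliez_if_needed")
  sym_pc <- pcoa(sym_d, "cailliez_if_needed")
  B <- host_pc$coordinates
  C <- sym_pc$coordinates
  stat_fun <- function(A) {
    if (ncol(C) == 0L || ncol(B) == 0L) return(0)
    sum((t(C) %*% A %*% B)^2)
  }
  observed <- stat_fun(assoc)

  run <- function() {
    perms <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      A <- if (scheme == "per_symbiont") {
        t(apply(assoc, 1, sample))
      } else {
        assoc[, sample(n_host), drop = FALSE]
      }
      perms[i] <- stat_fun(A)
    }
    perms
  }
  perms <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  eps <- 1e-12 * max(1, observed)
  b <- sum(perms >= observed - eps)
  structure(list(statistic = observed,
                 p_value = (1 + b) / (1 + n_perm),
                 permutations = perms, n_perm = as.integer(n_perm),
                 seed = seed, scheme = scheme,
                 host_correction = host_pc$correction_constant,
                 sym_correction = sym_pc$correction_constant),
            class = "parafit_result")
}

#' @export
print.parafit_result <- function(x, ...) {
  cat(sprintf("Global ParaFit: statistic = %.6g, p = %.4g (%d permutations, %s null)\n",
              x$statistic, x$p_value, x$n_perm, x$scheme))
  invisible(x)
}

#' Ward hierarchical clustering of SNV variability profiles
#'
#' Agglomerative Ward clustering on Euclidean distances between sample
#' variability vectors — the dendrogram view of symbiont population
#' structure. Uses the Ward criterion on squared Euclidean distances
#' (Lance--Williams ward.D2 update); merge heights are the cluster
#' distances at each fusion. The dendrogram is also exported as a Newick
#' string, and a two-group partition is cut at the top merge.
#'
#' @param profile_matrix numeric matrix, samples x SNVs (departure values),
#'   with sample rownames; or an `snv_profile`, whose departure matrix is
#'   transposed and gate-imputed via [snv_distance()] conventions.
#' @return A list of class `ward_clustering`: `hclust`, `newick`,
#'   `labels_k2` (named 1/2 vector), `heights`.
#' @export
ward_cluster <- function(profile_matrix) {
  if (inherits(profile_matrix, "snv_profile")) {
    D <- profile_matrix$departure
    D[is.na(D) | profile_matrix$coverage < profile_matrix$config$min_coverage] <- 0
    profile_matrix <- t(D)
  }
  m <- as.matrix(profile_matrix)
  if (nrow(m) < 2L) stop("need at least 2 samples to cluster")
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  hc <- hclust(dist(m), method = "ward.D2")
  labels_k2 <- cutree(hc, k = 2)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc,
                 newick = ape::write.tree(phy),
                 labels_k2 = labels_k2,
                 heights = hc$height),
            class = "ward_clustering")
}

#' Congruence between two partitions
#'
#' Quantifies host-symbiont co-clustering as the adjusted Rand index between
#' the host-lineage partition and the symbiont SNV partition, with the
#' contingency table of labels.
#'
#' @param host_labels,sym_labels vectors of cluster labels over the same
#'   individuals (matched by name when both are named).
#' @return A list with `ari` and `contingency`.
#' @export
congruence <- function(host_labels, sym_labels) {
  if (!is.null(names(host_labels)) && !is.null(names(sym_labels))) {
    common <- intersect(names(host_labels), names(sym_labels))
    if (length(common) == 0L) stop("no shared individuals between label sets")
    host_labels <- host_labels[common]
    sym_labels <- sym_labels[common]
  }
  if (length(host_labels) != length(sym_labels))
    stop("label vectors differ in length")
  list(ari = mclust::adjustedRandIndex(host_labels, sym_labels),
       contingency = table(host = host_labels, symbiont = sym_labels))
}
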