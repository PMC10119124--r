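#' @noRd
#' One genotype layer of the likelihood array as an individuals x sites
#' matrix (dimension-drop safe for single-site objects).
gl_slice <- function(gl, g) {
  matrix(gl$L[, , g], dim(gl$L)[1], dim(gl$L)[2])
}

#' @noRd
#' Site-wise log-likelihood of allele frequency f under HWE:
#' l(f) = sum_ind log( L0 (1-f)^2 + L1 2f(1-f) + L2 f^2 ), missing excluded.
#' L0, L1, L2: individuals x sites matrices; f: per-site vector.
gl_loglik <- function(L0, L1, L2, miss, f) {
  fr <- matrix(f, nrow(L0), length(f), byrow = TRUE)
  lik <- L0 * (1 - fr)^2 + L1 * 2 * fr * (1 - fr) + L2 * fr^2
  ll <- log(pmax(lik, 1e-300))
  ll[miss] <- 0
  colSums(ll)
}

#' @noRd
#' EM for the ML alternate-allele frequency at every site simultaneously.
ml_allele_freqs_all <- function(gl, tol = 1e-8, max_iter = 500L) {
  L0 <- gl_slice(gl, 1); L1 <- gl_slice(gl, 2); L2 <- gl_slice(gl, 3)
  miss <- gl$missing
  n_eff <- colSums(!miss)
  if (any(n_eff == 0)) stop("site with all individuals missing")
  f <- rep(0.2, ncol(L0))
  for (it in seq_len(max_iter)) {
    fr <- matrix(f, nrow(L0), length(f), byrow = TRUE)
    w0 <- L0 * (1 - fr)^2
    w1 <- L1 * 2 * fr * (1 - fr)
    w2 <- L2 * fr^2
    tot <- w0 + w1 + w2
    dos <- (w1 + 2 * w2) / pmax(tot, 1e-300)
    dos[miss] <- 0
    f_new <- colSums(dos) / (2 * n_eff)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  f
}

#' Maximum-likelihood allele frequency at one site from genotype likelihoods
#'
#' Maximizes the marginal likelihood of the alternate-allele frequency under
#' Hardy--Weinberg genotype proportions by EM, to tolerance 1e-8. The
#' standard frequency estimator behind genotype-likelihood-based site
#' filters at low and medium coverage.
#'
#' @param L_site numeric matrix, individuals x 3 (homRef, het, homAlt
#'   likelihoods); rows of all-equal values act as missing.
#' @return The ML alternate-allele frequency in [0, 1].
#' @export
ml_allele_frequency <- function(L_site) {
  L_site <- as.matrix(L_site)
  stopifnot(ncol(L_site) == 3L, all(L_site >= 0))
  miss <- matrix(apply(L_site, 1, function(r) diff(range(r)) == 0 | sum(r) == 0),
                 ncol = 1)
  if (all(miss)) stop("all individuals missing at this site")
  gl <- genotype_likelihoods(array(L_site, c(nrow(L_site), 1L, 3L)),
                             missing = miss)
  ml_allele_freqs_all(gl)
}

#' SNP likelihood-ratio test at one site
#'
#' Tests polymorphism: 2 * (l(f_hat) - max(l(0), l(1))) against chi-square
#' with 1 df (upper tail). No boundary point-mass correction is applied,
#' which is conservative: true p-values at the boundary are smaller.
#'
#' @param L_site as in [ml_allele_frequency()].
#' @return A list with `statistic` and `p_value`.
#' @export
snp_lrt <- function(L_site) {
  L_site <- as.matrix(L_site)
  miss <- matrix(apply(L_site, 1, function(r) diff(range(r)) == 0 | sum(r) == 0),
                 ncol = 1)
  gl <- genotype_likelihoods(array(L_site, c(nrow(L_site), 1L, 3L)),
                             missing = miss)
  st <- snp_lrt_all(gl)
  list(statistic = st$statistic[1], p_value = st$p_value[1])
}

#' @noRd
snp_lrt_all <- function(gl) {
  f <- ml_allele_freqs_all(gl)
  L0 <- gl_slice(gl, 1); L1 <- gl_slice(gl, 2); L2 <- gl_slice(gl, 3)
  ll_hat <- gl_loglik(L0, L1, L2, gl$missing, f)
  ll_0 <- gl_loglik(L0, L1, L2, gl$missing, rep(0, length(f)))
  ll_1 <- gl_loglik(L0, L1, L2, gl$missing, rep(1, length(f)))
  stat <- pmax(0, 2 * (ll_hat - pmax(ll_0, ll_1)))
  data.frame(f = f, statistic = stat,
             p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Filter genotype-likelihood sites for population-structure analysis
#'
#' The three standard gates against low-coverage artefacts: the site must be
#' non-missing in at least `presence_min` of the individuals, polymorphic at
#' SNP likelihood-ratio p below `snp_p_max`, and have ML minor allele
#' frequency of at least `maf_min`. Gates are evaluated
#' presence -> LRT -> MAF; they are independent, so the surviving set does
#' not depend on the order.
#'
#' @param gl a [genotype_likelihoods()] object.
#' @param snp_p_max SNP p-value ceiling, default 1e-6.
#' @param maf_min minor-allele-frequency floor, default 0.05.
#' @param presence_min minimum fraction of non-missing individuals, default 0.50.
#' @return A `genotype_likelihoods` object restricted to surviving sites,
#'   with per-site ML frequencies in attribute `"freqs"`; empty (with a
#'   warning) when nothing survives.
#' @export
filter_sites <- function(gl, snp_p_max = 1e-6, maf_min = 0.05,
                         presence_min = 0.50) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  check_prob(snp_p_max, "snp_p_max", 0, 1, lo_open = TRUE)
  check_prob(maf_min, "maf_min", 0, 1, lo_open = TRUE)
  check_prob(presence_min, "presence_min", 0, 1, lo_open = TRUE)
  presence <- colMeans(!gl$missing)
  st <- snp_lrt_all(gl)
  maf <- pmin(st$f, 1 - st$f)
  keep <- presence >= presence_min & st$p_value < snp_p_max & maf >= maf_min
  if (!any(keep)) warning("no site passed the filters; returning empty set")
  out <- genotype_likelihoods(gl$L[, keep, , drop = FALSE],
                              missing = gl$missing[, keep, drop = FALSE],
                              individuals = gl$individuals,
                              sites = gl$sites[keep])
  attr(out, "freqs") <- st$f[keep]
  out
}

#' Host population structure by posterior-dosage covariance PCA
#'
#' Computes, per individual and site, the posterior mean genotype dosage
#' under a Hardy--Weinberg prior at the site's ML allele frequency,
#' standardizes by `sqrt(2 f (1 - f))`, forms the individual x individual
#' covariance (pairwise-complete over missing entries), and
#' eigendecomposes. Principal-coordinate positions are eigenvectors scaled
#' by the square roots of their (positive) eigenvalues. Two lineage clusters
#' are assigned by one-dimensional 2-means on PC1, deterministically
#' initialized at the two extreme individuals; cluster 1 is the cluster
#' containing the first individual.
#'
#' @param gl a (filtered) `genotype_likelihoods` object.
#' @return An object of class `host_structure`: `coordinates` (individuals x
#'   axes), `eigenvalues` (descending), `covariance`, `freqs`, `clusters`
#'   (named 1/2 labels).
#' @export
genotype_covariance_pca <- function(gl) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  if (length(gl$sites) < 2L) stop("need >= 2 filtered sites")
  if (length(gl$individuals) < 3L) stop("need >= 3 individuals")
  f <- attr(gl, "freqs")
  if (is.null(f)) f <- ml_allele_freqs_all(gl)
  sd2 <- sqrt(2 * f * (1 - f))
  if (any(sd2 == 0)) stop("monomorphic site after filtering: degenerate covariance")
  fr <- matrix(f, length(gl$individuals), length(f), byrow = TRUE)
  w0 <- gl_slice(gl, 1) * (1 - fr)^2
  w1 <- gl_slice(gl, 2) * 2 * fr * (1 - fr)
  w2 <- gl_slice(gl, 3) * fr^2
  dos <- (w1 + 2 * w2) / (w0 + w1 + w2)
  X <- sweep(dos - 2 * fr, 2, sd2, "/")
  X[gl$missing] <- NA
  X0 <- X; X0[is.na(X0)] <- 0
  M <- (!is.na(X)) * 1
  denom <- M %*% t(M)
  if (any(denom == 0)) stop("individual pair with no shared non-missing site")
  C <- (X0 %*% t(X0)) / denom
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  pos <- eig$values > 1e-12 * max(abs(eig$values))
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  dimnames(coords) <- list(gl$individuals,
                           paste0("PC", seq_len(ncol(coords))))
  clusters <- kmeans2_1d(coords[, 1])
  names(clusters) <- gl$individuals
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 covariance = C, freqs = f, clusters = clusters),
            class = "host_structure")
}

#' @noRd
#' Deterministic 1-d 2-means: centers initialized at the extremes; label 1 is
#' the first element's cluster.
kmeans2_1d <- function(x, max_iter = 100L) {
  ctr <- c(min(x), max(x))
  lab <- rep(1L, length(x))
  for (i in seq_len(max_iter)) {
    lab_new <- ifelse(abs(x - ctr[1]) <= abs(x - ctr[2]), 1L, 2L)
    if (all(lab_new == lab) && i > 1L) break
    lab <- lab_new
    for (k in 1:2) if (any(lab == k)) ctr[k] <- mean(x[lab == k])
  }
  if (lab[1] == 2L) lab <- 3L - lab
  lab
}

#' Host distance matrix in principal-component space
#'
#' Euclidean distance between individuals on the leading principal
#' components — the host-side input to the ParaFit congruence test.
#'
#' @param structure a `host_structure` from [genotype_covariance_pca()].
#' @param k_axes number of leading axes; default all retained (positive
#'   eigenvalue) axes.
#' @return Symmetric individuals x individuals distance matrix.
#' @export
host_distance <- function(structure, k_axes = NULL) {
  stopifnot(inherits(structure, "host_structure"))
  k_max <- ncol(structure$coordinates)
  if (is.null(k_axes)) k_axes <- k_max
  if (k_axes < 1 || k_axes > k_max) stop("k_axes out of range")
  as_dist_matrix(as.matrix(dist(structure$coordinates[, seq_len(k_axes),
                                                      drop = FALSE])),
                 labels = rownames(structure$coordinates))
}
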