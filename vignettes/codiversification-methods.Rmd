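---
title: "Methods: testing host-symbiont co-diversification from metagenomic variant profiles"
author: "codivkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing host-symbiont co-diversification from metagenomic variant profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codivkit)
```

## The scientific question

When a bacterial symbiont is transmitted vertically over many host
generations, the population structure of the symbiont should mirror the
population structure of its host: hosts from one genetic lineage should
carry symbiont variants that hosts from another lineage lack. The motivating
system is a dominant, vertically transmitted *Mycoplasma* symbiont in the
gut of wild Atlantic salmon, where the host species splits into two deep
Norwegian lineages and the symbiont's single-nucleotide variants (SNVs)
partition along the same boundary. `codivkit` implements the quantitative
chain needed to test this mirroring from metagenomes:

1. per-position SNV variability of the symbiont across host metagenomes
   (departure from consensus),
2. codon-level consequences (SCVs, per-gene pN/pS, SAAVs scored with
   BLOSUM62),
3. host population structure from genotype likelihoods (covariance PCA),
4. a global ParaFit permutation test of congruence between the host and
   symbiont distance structures, on Cailliez-corrected principal
   coordinates,
5. a binomial-GLM (Rao score) enrichment statistic across genome groups.

Because the raw sequencing data behind such a study cannot ship with a
package, a synthetic hologenome generator with complete ground truth drives
development and testing; every statistical claim the test suite makes is a
claim about this generator's output, a point discussed at the end.

## SNV profiling

For one genome position in one sample, with read counts
$(n_A, n_C, n_G, n_T)$ and coverage $n$, the variability value is the
departure from consensus

$$d = 1 - \max_i n_i / n,$$

the fraction of reads that disagree with the locally most frequent
nucleotide. Ties at the maximum are broken by the fixed order
A < C < G < T, for both the consensus and the competing (second) nucleotide,
so results are deterministic; $d$ is bounded by 0.75 (four-way tie). The
consensus is per (position, sample), not global: each metagenome is its own
reference point, which is what the variability-stacking view of symbiont
structure plots.

A position enters the reported profile when in at least a fraction
`min_prevalence` (default 0.90) of the samples it simultaneously has
coverage at least `min_coverage` (default 20) and $d$ above `min_variation`
(default 0.01, i.e. more than 1% of recruited reads off consensus). The
coverage gate is evaluated first, then the variation condition, then
prevalence; the prevalence denominator is all samples. The 90% prevalence
default is a zero-inflation control: positions observed variable only in a
few samples carry little co-structure information and dilute the profile
matrix. When the variants of interest are lineage-diagnostic — present in
only one host cluster — prevalence must be lowered to the cluster fraction,
and the bundled co-diversification scenario does exactly that (0.45 for two
equal clusters of 15).

Two distances summarize the profile across samples: the Jaccard distance on
SNV presence/absence sets (the linkage substrate fed to ParaFit; a pair of
samples with two empty sets is at distance 0), and the Euclidean distance on
the departure vectors (the clustering view). A departure undefined at a
retained position (sample below the coverage gate) is imputed as 0 for the
Euclidean view, with a message; it simply does not enter that sample's
presence set for the Jaccard view.

## Codon-level variation without read-level data

Proper single-codon variants require reads spanning a whole codon. The
package works from per-position allele counts, so codons are reconstructed
under an independence approximation that is exact when at most one of the
three positions is variable: codon coverage is the minimum of the three
per-position coverages, the consensus codon is assembled from per-position
consensus calls, and at a single variable position (departure above
`min_variation`) the codon coverage is split across the observed
nucleotides by the largest-remainder rule so reconstructed counts always sum
to the codon coverage. Codons with two or more variable positions are
flagged ambiguous and excluded from every downstream statistic, with a
message reporting how many; the synthetic generator places at most one
variant per codon, so on simulated data ambiguity arises only from
sequencing error. On real pileups this reconstruction is a documented
limitation, not a substitute for spanning-read counting. Minus-strand genes
are reverse-complemented before framing.

Per-gene selection pressure is summarized by the within-population pN/pS.
Expected site counts follow Nei--Gojobori accounting: for each consensus
codon, the fraction of its nine single-nucleotide neighbours that are
synonymous contributes synonymous "sites" (the two site classes always sum
to exactly 3 per codon); changes creating a stop codon count as
non-synonymous, the standard convention. Every non-consensus codon with
pooled frequency above `min_variation` contributes one observed
polymorphism, classified synonymous iff it preserves the consensus amino
acid, and

$$\mathrm{pN/pS} = \frac{N_{\mathrm{obs}} / N_{\mathrm{sites}}}
                        {S_{\mathrm{obs}} / S_{\mathrm{sites}}}.$$

With no variants at all the ratio is undefined (NA); with only
non-synonymous variants it is flagged infinite rather than silently capped.
Counts are pooled over samples by default because the population-level
statistic is the target; a per-sample scope is available. Values above one
are read as positive selection pressure on the gene.

Single amino-acid variants (SAAVs) are derived by translating the
reconstructed codon counts: a SAAV is emitted where the most frequent
non-consensus amino acid exceeds `min_variation` (the SAAV threshold
deliberately reuses the SNV variation threshold). Each record carries the
BLOSUM62 score of the (consensus, competing) pair, read verbatim from the
bundled NCBI-format matrix file — used here as an interchangeability index,
with low or negative scores marking biochemically drastic substitutions —
and the per-host-cluster prevalence: the fraction of a cluster's samples in
which the competing amino acid passes the threshold, the quantity that links
protein-level variation to host genotype.

## Host population structure from genotype likelihoods

At the 2--30X coverages typical of host reads in metagenomes, hard genotype
calls are unreliable, so all host inference works from per-site genotype
likelihoods $L(g)$, $g \in \{0, 1, 2\}$ copies of the alternate allele. The
maximum-likelihood alternate-allele frequency $\hat f$ of a site maximizes
$\sum_i \log \sum_g L_i(g)\,\mathrm{HWE}(g \mid f)$ and is found by EM to a
tolerance of 1e-8. Sites are filtered by three independent gates with the
standard defaults: presence (non-missing in at least 50% of individuals),
polymorphism (likelihood-ratio statistic
$2[\ell(\hat f) - \max(\ell(0), \ell(1))]$ against $\chi^2_1$, p below
1e-6), and minor allele frequency $\min(\hat f, 1 - \hat f) \ge 0.05$. The
boundary point-mass correction of the LRT null is deliberately omitted: the
uncorrected test is conservative (true boundary p-values are smaller), which
only strengthens a site that passes the 1e-6 gate.

Structure itself comes from a one-pass posterior-dosage covariance PCA: per
individual and site the posterior mean dosage
$E[g \mid L, \hat f]$ under the HWE prior at $\hat f$, standardized by
$\sqrt{2 \hat f (1 - \hat f)}$; the individual-by-individual covariance uses
pairwise-complete entries over missing data; eigendecomposition gives
principal components scaled by the square roots of their eigenvalues. The
iterated individual-allele-frequency refinement used by dedicated
low-coverage PCA tools is intentionally not replicated: for recovering two
diverged lineages and producing a distance matrix — the only downstream
uses here — the one-pass estimator is sufficient, and it keeps the module a
page of linear algebra. Two clusters are then forced (the two-lineage
design is an assumption, not an inference) by one-dimensional 2-means on
PC1, deterministically initialized at the two extreme individuals.

The host-side input to ParaFit is defined as the Euclidean distance between
individuals in PC space, over all positive-eigenvalue axes by default. This
was a genuinely open design point — an identity-by-state matrix or the raw
covariance would also be defensible — and the PC-space choice was made
because it is exactly the geometry in which the clusters were defined, and
because with all axes kept it equals (up to the $1/\sqrt{M}$ site scaling)
the distance between standardized dosage vectors, a property the test suite
checks algebraically.

## The ParaFit test on Cailliez-corrected coordinates

Principal coordinates analysis double-centres $-D^2/2$ (Gower) and keeps
eigenvectors scaled by the square roots of the positive eigenvalues
(positive meaning above 1e-8 times the largest eigenvalue — the axis cutoff
used everywhere). A Jaccard matrix is generally not Euclidean-embeddable
and produces negative eigenvalues; when the smallest eigenvalue is
materially negative (below −1e-8 times the largest) the Cailliez constant —
the largest real eigenvalue of the classical $2n \times 2n$ block companion
matrix — is added to every off-diagonal distance and the embedding is
recomputed. Each of the two input matrices is corrected independently and
only when it needs it; the correction constants are reported in the result.

With host coordinates $B$, symbiont coordinates $C$ and the 0/1 association
matrix $A$ (rows symbionts, columns hosts; one-to-one in this design, since
each host metagenome contributes exactly one symbiont genotype), the global
statistic is

$$\mathrm{ParaFitGlobal} = \sum_{ij} \left[ C^{\top} A B \right]_{ij}^2 ,$$

large when hosts that are close carry symbionts that are close. The null
distribution permutes the host links. Two schemes are implemented: for
one-to-one associations (the default situation) hosts are relabeled by a
single random permutation per replicate, which is the exact exchangeable
null for that design and empirically holds the 5% level (type-I rate 0.052
over 500 null datasets in the test suite); for general associations each
symbiont's links are shuffled independently, the classical formulation. The
per-symbiont shuffle applied to a one-to-one association can place several
symbionts on one host, which inflates the null statistics and makes the
test conservative — the reason the exact scheme is preferred when
available. The p-value uses the add-one estimator
$(1 + \#\{T_{\mathrm{perm}} \ge T_{\mathrm{obs}}\}) / (1 + n_{\mathrm{perm}})$:
it can never be zero, and at the default 1000 permutations the smallest
attainable value is $1/1001 < 0.001$, so "p < 0.001" is reportable exactly
when no permutation reaches the observed statistic. Permutation statistics
are compared with a relative tolerance of 1e-12 so that exact symmetric
ties count as ties rather than depending on floating-point noise.

Hierarchical views use Ward clustering on Euclidean distances (the ward.D2
criterion, i.e. the Lance--Williams update on squared distances), with the
dendrogram exported as Newick (branch lengths are merge heights) and a
two-group cut at the top merge. Host-symbiont co-clustering is quantified
as the adjusted Rand index between the host lineage partition and the
symbiont k = 2 partition — a chance-corrected scalar stand-in for what is
usually shown as stacked dendrograms.

## Enrichment across genome groups

For each binary feature across two genome groups, the score (Rao) test of
the group effect in an intercept-plus-group logistic model is computed. For
a 2 x 2 layout this statistic equals the Pearson chi-square of the
occurrence table — an algebraic identity the implementation uses directly
and the tests verify against both `chisq.test` and a fitted GLM's Rao
statistic. No continuity correction is applied (it has no place in the
score formulation); degenerate all-present or all-absent features get
statistic 0 and p = 1. P-values are adjusted by Benjamini--Hochberg, and
features with q below 0.05 are called enriched in the group where they are
more frequent. In the simulated pipeline the features are the SAAVs
themselves, scored for occurrence across the two host genotype clusters; on
real data the same routine applies to any occurrence table, e.g. functional
annotations across high- and low-abundance symbiont genomes.

## The synthetic hologenome generator

The generator's defaults are the bundled study conditions, not knobs to
revisit per run:

* **Hosts.** Two lineages of 15 individuals; 5000 biallelic sites; per site
  an ancestral frequency from Uniform(0.05, 0.95) and per-lineage
  frequencies from the Balding--Nichols beta model at F = 0.1 — a
  differentiation depth at which two salmon lineages separate cleanly on
  one PC but individual sites are far from fixed differences. Diploid
  genotypes are Binomial(2, f); depth is Poisson(20), inside the low-to-mid
  coverage band where genotype likelihoods matter; reads support the
  carried allele with probability 0.99 (1% error), and likelihoods are
  computed from the resulting read counts, so the generator produces
  exactly the uncertainty structure the host module is built for.
* **Symbiont.** A single-contig genome of ten 60-codon genes (1800 bp —
  deliberately small; coordinates are 0-based half-open, genes contiguous,
  in frame, forward strand, built from sense codons with ATG starts).
  Eight cluster-1 and sixteen cluster-2 diagnostic SNVs — the asymmetry
  mirrors the observed excess of variable SNVs in one host lineage — are
  placed in distinct codons (at most one variable position per codon, which
  is what makes the codon reconstruction exact on simulated data), each an
  alternate nucleotide at within-host frequency 0.3: an intermediate
  variability chosen because the empirical variability profiles sit well
  away from both 0 and fixation; it is exposed as a knob because the true
  within-host spectrum is not identifiable from published summaries.
  Coverage is Poisson(100) per position (within the 20--100X band), with
  errors spread uniformly over the three wrong nucleotides at rate 0.001.
* **Transmission.** With probability `1 - h_transmission` a host inherits
  its own lineage's diagnostic SNV set (vertical transmission); with
  probability `h_transmission` it instead carries a uniform random subset
  of the pooled cross-cluster variant pool — each pooled variant
  independently with probability 1/2 — modelling horizontal acquisition
  from the mixed environmental pool. At `h_transmission = 0` the
  sample-by-SNV presence matrix is block-diagonal by lineage; at 1,
  carriage is exactly independent of the host lineage, the null used for
  type-I calibration.
* **Randomness.** Every output object draws from its own RNG stream derived
  from the master seed by a fixed text label, so enlarging the host side of
  a simulation does not perturb the symbiont draws, and identical
  configurations reproduce bit-identical outputs.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: read-level artefacts (quality-score
structure, strand bias, mapping bias around indels), reference and binning
errors in the symbiont assembly, within-host symbiont strain mixtures and
recombination, relatedness structure within host lineages, and any
environmental covariate. The acceptance-level claims are that the
implemented statistics behave correctly — recover planted structure, hold
their nominal error rates, match independent oracles — under a clean
generative model, which is the appropriate desk-scale check of the
machinery, not a validation of the biological conclusions on new data.

## Numerical conventions, degenerate inputs, and problem sizes

* Ties everywhere resolve deterministically: nucleotides and codons by
  fixed alphabetical order, merge order in Ward by `hclust`'s convention,
  2-means by extreme-point initialization.
* Zero coverage yields an undefined (NA) departure, never 0; an all-zero
  profile is an empty result with a warning, not an error.
* Eigen-axis retention and "materially negative" both use relative 1e-8
  thresholds; the EM frequency tolerance is 1e-8; covariance symmetry is
  enforced by averaging with the transpose.
* Integer count allocation (codon reconstruction) uses the
  largest-remainder rule with index-order tie-breaks.
* The test suite runs the chain at reduced but non-trivial sizes: the
  co-diversification scenario at its full 30 hosts / 1800 bp / 1000
  permutations; null calibration over 500 datasets of 20 hosts with 199
  permutations each; host-structure recovery over 10 seeds at 40
  individuals and 5000 sites; oracle suites over all 61 sense codons, 100
  random genes, 100 random non-Euclidean matrices, and 200 random filter
  fixtures. These sizes were chosen to exercise every code path at
  meaningful statistical resolution while keeping a full check run in
  minutes on one core.

## Known limitations

* Codon reconstruction from per-position counts is exact only under the
  at-most-one-variable-position condition; real pileups need spanning-read
  counting, and ambiguous codons are excluded rather than resolved.
* The host PCA is the one-pass posterior-dosage estimator; very low
  coverage combined with weak differentiation would benefit from iterative
  individual-allele-frequency refinement, which is out of scope.
* Exactly two host clusters are emitted by design; a third (e.g. an
  outgroup population) must be handled upstream.
* The symbiont side enters ParaFit as a distance matrix derived from SNV
  presence/absence; no phylogeny is inferred, and per-link significance
  tests are not implemented (only the global statistic).
* `percent_ratio` rounds half-up to match conventional reporting, which
  differs from R's banker's rounding in `round()`.
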