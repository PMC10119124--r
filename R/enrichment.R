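#' Rao score test for a binary feature across two genome groups
#'
#' Score (Rao) test of the group effect in a logistic regression of the 0/1
#' feature occurrence on group membership with an intercept. For a two-group
#' comparison this statistic equals the Pearson chi-square of the 2x2
#' occurrence table (a standard algebraic identity), which is how it is
#' computed here; the p-value is the chi-square df = 1 upper tail. A
#' degenerate feature (all 0 or all 1, or an empty margin) gives statistic 0
#' and p = 1. No continuity correction is applied.
#'
#' @param x 0/1 occurrence vector.
#' @param g group labels, exactly two levels.
#' @return A list with `statistic` and `p_value`.
#' @export
rao_score_test <- function(x, g) {
  if (!all(x %in% c(0, 1))) stop("occurrence must be 0/1")
  g <- as.factor(g)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 1L)) stop("both groups must be non-empty")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  k1 <- sum(x[g == levels(g)[1]]); k2 <- sum(x[g == levels(g)[2]])
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool == 0 || p_pool == 1) {
    stat <- 0
  } else {
    # Pearson chi-square of the 2x2 table, = logistic score statistic
    e <- outer(c(n1, n2), c(p_pool, 1 - p_pool))
    o <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
    stat <- sum((o - e)^2 / e)
  }
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini--Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values.
#' @return q-values in the same order.
#' @export
bh_qvalues <- function(p) {
  p.adjust(p, method = "BH")
}

#' Group-wise feature enrichment across two genome groups
#'
#' For every feature of a 0/1 occurrence table, fits the binomial-GLM score
#' (Rao) test of a group difference, adjusts p-values by
#' Benjamini--Hochberg, and flags features with q below `q_max` as enriched
#' in the group where they are more frequent.
#'
#' @param occurrence 0/1 matrix, features x genomes, with feature rownames.
#' @param groups named (or positionally matched) group labels per genome,
#'   exactly two levels.
#' @param q_max enrichment call threshold on the q-value, default 0.05.
#' @return Data frame, one row per feature: per-group occurrence
#'   proportions, `statistic`, `p_value`, `q_value`, `enriched`,
#'   `associated_group`.
#' @export
enrichment_test <- function(occurrence, groups, q_max = 0.05) {
  occurrence <- as.matrix(occurrence)
  if (!all(occurrence %in% c(0, 1))) stop("occurrence table must be 0/1")
  if (length(groups) != ncol(occurrence))
    stop("one group label per genome column required")
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (is.null(rownames(occurrence)))
    rownames(occurrence) <- sprintf("feature%04d", seq_len(nrow(occurrence)))
  lv <- levels(g)
  tests <- apply(occurrence, 1, rao_score_test, g = g)
  stat <- vapply(tests, `[[`, 0, "statistic")
  p <- vapply(tests, `[[`, 0, "p_value")
  q <- bh_qvalues(p)
  prop1 <- rowMeans(occurrence[, g == lv[1], drop = FALSE])
  prop2 <- rowMeans(occurrence[, g == lv[2], drop = FALSE])
  data.frame(feature = rownames(occurrence),
             prop_group1 = prop1, prop_group2 = prop2,
             statistic = stat, p_value = p, q_value = q,
             enriched = q < q_max,
             associated_group = ifelse(prop1 >= prop2, lv[1], lv[2]),
             row.names = NULL, stringsAsFactors = FALSE)
}
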