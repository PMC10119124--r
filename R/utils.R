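#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Each simulated object (host genotypes, symbiont counts, permutations, ...)
#' draws from its own RNG stream so that, e.g., adding host individuals does
#' not perturb the symbiont draws. Streams are derived deterministically from
#' the master seed and a fixed text label.
#'
#' @param master integer master seed.
#' @param label character stream label.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
stream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483629 + 1)
}

with_stream <- function(master, label, code) {
  withr::with_seed(stream_seed(master, label), code)
}

#' @noRd
#' Multinomial draws for many cells at once via conditional binomial thinning.
#' n: integer vector of totals (length m); prob: m x k matrix, rows sum to 1.
r_multinom_cells <- function(n, prob) {
  m <- length(n)
  k <- ncol(prob)
  stopifnot(nrow(prob) == m)
  out <- matrix(0L, m, k)
  rem <- as.integer(n)
  pleft <- rep(1, m)
  for (j in seq_len(k - 1L)) {
    pj <- ifelse(pleft > 1e-12, pmin(1, pmax(0, prob[, j] / pleft)), 0)
    x <- rbinom(m, rem, pj)
    out[, j] <- x
    rem <- rem - x
    pleft <- pleft - prob[, j]
  }
  out[, k] <- rem
  out
}

#' @noRd
#' Allocate `total` integer counts proportionally to `freq`, deterministically
#' (largest-remainder rule; ties broken by index order).
allocate_counts <- function(total, freq) {
  freq <- freq / sum(freq)
  raw <- freq * total
  base <- floor(raw)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' @noRd
check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must lie in %s%g, %g%s", name,
                        if (lo_open) "(" else "[", lo, hi,
                        if (hi_open) ")" else "]"), call. = FALSE)
  invisible(x)
}

#' @noRd
#' FNV-1a hash of a string, as an 8-hex-digit tag (config fingerprints).
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

reverse_complement <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
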