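# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately avoid the package's own computational
# paths.

# quick genotype matrix from a sites x isolates call matrix
make_gm <- function(calls, chrom = "I", pos = NULL, samples = NULL,
                    contig_lengths = NULL, ...) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (is.null(samples)) {
    samples <- if (!is.null(colnames(calls))) colnames(calls) else
      paste0("S", seq_len(ncol(calls)))
  }
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(pos, chrom, max)
    contig_lengths <- stats::setNames(as.numeric(contig_lengths),
                                      names(contig_lengths))
  }
  genotype_matrix(chrom = chrom, pos = pos,
                  ref = rep("A", n), alt = rep("T", n),
                  calls = calls, samples = samples,
                  contig_lengths = contig_lengths, ...)
}

# mean pairwise Hamming difference per bp over all haplotype pairs
# (complete-data oracle for window pi)
oracle_pi <- function(calls, window_bp) {
  n <- ncol(calls)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(calls[, i] != calls[, j])
    }
  }
  tot / choose(n, 2) / window_bp
}

# two-sided Fisher p by full hypergeometric enumeration
# (minimum-likelihood method)
oracle_fisher <- function(k_a, n_a, k_b, n_b) {
  K <- k_a + k_b
  lo <- max(0, K - n_b)
  hi <- min(K, n_a)
  probs <- stats::dhyper(lo:hi, n_a, n_b, K)
  obs <- stats::dhyper(k_a, n_a, n_b, K)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Tajima's D evaluated constant by constant, independently of
# tajima_d()/tajima_constants()
oracle_tajima_d <- function(S, pi_sum, n) {
  harm <- function(m, pw) sum((1 / seq_len(m))^pw)
  a1 <- harm(n - 1, 1)
  a2 <- harm(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)  # degenerate variance (e.g. n = 3, S = 1)
  (pi_sum - S / a1) / sqrt(v)
}

# brute-force survivor scan mirroring the published per-call/per-site
# thresholds, record by record
oracle_filter_survivors <- function(g, t) {
  keep <- logical(n_sites(g))
  for (s in seq_len(n_sites(g))) {
    site_ok <- TRUE
    if (!is.null(g$mq) && !is.na(g$mq[s]) && g$mq[s] <= t$min_mq) {
      site_ok <- FALSE
    }
    if (!is.null(g$qual) && !is.na(g$qual[s]) && g$qual[s] <= t$min_qual) {
      site_ok <- FALSE
    }
    any_call <- FALSE
    for (i in seq_along(g$samples)) {
      if (g$calls[s, i] == 3L) next
      ok <- site_ok
      if (!is.null(g$dp) && !is.na(g$dp[s, i])) {
        ok <- ok && if (t$depth_strict) g$dp[s, i] > t$min_depth else
          g$dp[s, i] >= t$min_depth
      }
      if (!is.null(g$ad_ratio) && !is.na(g$ad_ratio[s, i])) {
        ok <- ok && g$ad_ratio[s, i] > t$min_ad_ratio
      }
      if (ok) any_call <- TRUE
    }
    keep[s] <- any_call
  }
  keep
}

# random haploid matrix with quality fields, for property tests
random_gm <- function(n_sites = 60, n_iso = 6, seed = 1,
                      p_missing = 0.05) {
  set.seed(seed)
  calls <- matrix(sample(c(0L, 1L), n_sites * n_iso, replace = TRUE),
                  n_sites, n_iso)
  calls[stats::runif(length(calls)) < p_missing] <- 3L
  make_gm(calls,
          pos = sort(sample.int(n_sites * 100, n_sites)),
          dp = matrix(sample(1:60, n_sites * n_iso, TRUE), n_sites),
          ad_ratio = matrix(stats::runif(n_sites * n_iso, 0.3, 1), n_sites),
          mq = stats::runif(n_sites, 20, 60),
          qual = stats::runif(n_sites, 5, 60))
}
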