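#' Build a sliding-window grid over chromosomes
#'
#' Windows start at 1, 1+step, 1+2*step, ...; the last window is the
#' final *full* window fitting within the chromosome. Chromosomes
#' shorter than one window contribute zero windows (logged). Interior
#' positions are covered by exactly `window_size / step` windows.
#'
#' @param contig_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Window width in bp (default 10,000).
#' @param step Step between window starts in bp (default 1,000).
#' @return A data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
make_windows <- function(contig_lengths, window_size = 10000, step = 1000) {
  stopifnot(window_size >= 1, step >= 1, step <= window_size,
            window_size == as.integer(window_size),
            step == as.integer(step))
  out <- lapply(names(contig_lengths), function(chr) {
    L <- contig_lengths[[chr]]
    if (L < window_size) {
      message("make_windows: chromosome ", chr, " (", L,
              " bp) shorter than window_size; zero windows")
      return(NULL)
    }
    starts <- seq(1, L - window_size + 1, by = step)
    data.frame(chrom = chr, start = starts, end = starts + window_size - 1)
  })
  do.call(rbind, out)
}

# Per-site allele-frequency summaries among a sample of haploid columns.
# Returns alt frequency p among non-missing haplotypes, the non-missing
# count nn, the n/(n-1)-corrected heterozygosity contribution, and the
# segregating indicator. Sites with fewer than 2 non-missing haplotypes
# (or completeness below `min_completeness`) contribute zero.
site_frequencies <- function(g, samples = NULL, min_completeness = 0.5) {
  calls <- if (is.null(samples)) g$calls else {
    cols <- match(samples, g$samples)
    if (anyNA(cols)) stop("unknown sample(s): ",
                          paste(samples[is.na(cols)], collapse = ", "),
                          call. = FALSE)
    g$calls[, cols, drop = FALSE]
  }
  n <- ncol(calls)
  n_alt <- rowSums(calls == GT_ALT)
  # HET calls are excluded from the haploid allele counts entirely
  nn <- rowSums(calls != GT_MISSING) - rowSums(calls == GT_HET)
  ok <- nn >= 2 & nn >= min_completeness * n
  p <- ifelse(nn > 0, n_alt / nn, NA_real_)
  het <- ifelse(ok, 2 * p * (1 - p) * nn / (nn - 1), 0)
  seg <- ok & n_alt > 0 & n_alt < nn
  list(p = p, nn = nn, het = het, seg = seg, n = n)
}

#' Tajima (1989) normalization constants
#'
#' The standard constants in the sample size `n` (number of haplotypes):
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i` in `1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`.
#'
#' @param n Number of haplotypes (>= 2).
#' @return A named list of the constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from window summaries
#'
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1))` where `pi_sum` is the
#' *un-normalized* window sum of per-site pairwise-difference rates (not
#' divided by window length) and `S` the segregating-site count.
#' Undefined (`NA`, never 0) when `S = 0` or `n < 3`.
#'
#' @param S Segregating sites per window (vectorized).
#' @param pi_sum Window sums of per-site heterozygosity contributions.
#' @param n Number of haplotypes in the sample.
#' @return Numeric vector of D values (`NA` where undefined).
#' @export
tajima_d <- function(S, pi_sum, n) {
  if (n < 3) return(rep(NA_real_, length(S)))
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  ifelse(S > 0 & v > 0, (pi_sum - S / k$a1) / sqrt(v), NA_real_)
}

# windowed sums of a per-site vector via prefix sums on sorted positions
window_sums <- function(pos, values, starts, ends) {
  cs <- c(0, cumsum(values))
  i0 <- findInterval(starts - 1, pos)   # sites strictly before start
  i1 <- findInterval(ends, pos)         # sites at or before end
  cs[i1 + 1] - cs[i0 + 1]
}

#' Sliding-window diversity statistics among isotypes
#'
#' For each window: the segregating-site count `S`, per-site nucleotide
#' diversity `pi` (window sum of `2 p (1-p) n/(n-1)` site contributions
#' divided by the full window size, with `p` the ALT frequency among
#' non-missing haplotypes), per-site Watterson's `theta_w`
#' (`S / a1 / window_size`), and Tajima's D. Statistics are intended to
#' be computed among isotype representatives, not isolates, on a
#' hard-filtered haploidized matrix.
#'
#' @param g A hard-filtered, haploidized [genotype_matrix()].
#' @param samples Character vector naming the sample (isotype
#'   representatives) to use; default all columns. Must have >= 2
#'   members.
#' @param window_size,step Window grid in bp (defaults 10 kb / 1 kb).
#' @param contig_lengths Chromosome lengths; default from the matrix.
#' @param min_completeness Per-site completeness floor; sites with fewer
#'   non-missing haplotypes than this fraction of the sample are skipped.
#' @return A data.frame with one row per window: `chrom`, `start`,
#'   `end`, `n`, `S`, `pi`, `theta_w`, `tajima_d`.
#' @export
window_stats <- function(g, samples = NULL, window_size = 10000,
                         step = 1000, contig_lengths = NULL,
                         min_completeness = 0.5) {
  if (is.null(contig_lengths)) contig_lengths <- g$contig_lengths
  if (is.null(contig_lengths)) {
    stop("chromosome lengths unknown: supply contig_lengths", call. = FALSE)
  }
  n_samp <- if (is.null(samples)) length(g$samples) else length(samples)
  if (n_samp < 2) stop("need at least 2 haplotypes", call. = FALSE)
  sf <- site_frequencies(g, samples, min_completeness)
  win <- make_windows(contig_lengths, window_size, step)
  if (is.null(win)) return(NULL)
  res <- lapply(split(win, win$chrom), function(w) {
    chr <- w$chrom[1]
    idx <- which(g$chrom == chr)
    pos <- g$pos[idx]
    S <- window_sums(pos, as.numeric(sf$seg[idx]), w$start, w$end)
    pi_sum <- window_sums(pos, sf$het[idx], w$start, w$end)
    data.frame(chrom = chr, start = w$start, end = w$end, n = sf$n,
               S = S, pi = pi_sum / window_size,
               theta_w = S / tajima_constants(sf$n)$a1 / window_size,
               tajima_d = tajima_d(S, pi_sum, sf$n))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(match(out$chrom, names(contig_lengths)), out$start), ]
}

#' Sliding-window Hudson's F_ST between two samples
#'
#' Per-site Hudson numerator
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)`, with allele frequencies among non-missing
#' haplotypes; the window estimate is the *ratio of sums* (not the mean
#' of per-site ratios), the standard low-bias choice for window
#' estimators. Windows with zero denominator sum are undefined (`NA`);
#' the estimator may be negative.
#'
#' @param g A hard-filtered, haploidized [genotype_matrix()].
#' @param samples_a,samples_b Character vectors naming the two samples.
#' @param window_size,step Window grid in bp.
#' @param contig_lengths Chromosome lengths; default from the matrix.
#' @param min_completeness Per-site completeness floor within each
#'   sample; sites below it (or with fewer than 2 non-missing haplotypes
#'   in either sample) are skipped.
#' @return A data.frame per window: `chrom`, `start`, `end`,
#'   `numerator`, `denominator`, `fst`.
#' @export
window_hudson_fst <- function(g, samples_a, samples_b, window_size = 10000,
                              step = 1000, contig_lengths = NULL,
                              min_completeness = 0.5) {
  if (is.null(contig_lengths)) contig_lengths <- g$contig_lengths
  if (is.null(contig_lengths)) {
    stop("chromosome lengths unknown: supply contig_lengths", call. = FALSE)
  }
  site <- hudson_site_components(g, samples_a, samples_b, min_completeness)
  win <- make_windows(contig_lengths, window_size, step)
  res <- lapply(split(win, win$chrom), function(w) {
    chr <- w$chrom[1]
    idx <- which(g$chrom == chr)
    pos <- g$pos[idx]
    num <- window_sums(pos, site$num[idx], w$start, w$end)
    den <- window_sums(pos, site$den[idx], w$start, w$end)
    data.frame(chrom = chr, start = w$start, end = w$end,
               numerator = num, denominator = den,
               fst = ifelse(den > 0, num / den, NA_real_))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(match(out$chrom, names(contig_lengths)), out$start), ]
}

# Per-site Hudson numerator/denominator; sites unusable in either sample
# contribute zero to both sums.
hudson_site_components <- function(g, samples_a, samples_b,
                                   min_completeness = 0.5) {
  fa <- site_frequencies(g, samples_a, min_completeness)
  fb <- site_frequencies(g, samples_b, min_completeness)
  ok <- fa$nn >= 2 & fb$nn >= 2 &
    fa$nn >= min_completeness * fa$n & fb$nn >= min_completeness * fb$n
  p1 <- fa$p; p2 <- fb$p; n1 <- fa$nn; n2 <- fb$nn
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- 0
  den[!ok] <- 0
  list(num = num, den = den)
}

#' Genome-wide mean diversity from window statistics
#'
#' @param stats A [window_stats()] data.frame (or any data.frame with a
#'   `pi` column).
#' @return The unweighted mean of per-window per-site `pi`.
#' @export
genome_summary <- function(stats) {
  if (is.null(stats) || nrow(stats) == 0) {
    stop("no windows to summarize", call. = FALSE)
  }
  mean(stats$pi, na.rm = TRUE)
}

#' Genome-wide nucleotide diversity
#'
#' Two normalizations are exposed: `"window_mean"` (default) averages
#' per-window per-site `pi` over the sliding-window grid;
#' `"pooled"` sums site contributions genome-wide and divides by the
#' total chromosome length.
#'
#' @param g A hard-filtered, haploidized [genotype_matrix()].
#' @param samples Sample (isotype) name list; default all columns.
#' @param mode `"window_mean"` or `"pooled"`.
#' @param ... Passed to [window_stats()] in window-mean mode.
#' @return A single per-site diversity value.
#' @export
genome_pi <- function(g, samples = NULL, mode = c("window_mean", "pooled"),
                      ...) {
  mode <- match.arg(mode)
  if (mode == "window_mean") {
    genome_summary(window_stats(g, samples, ...))
  } else {
    sf <- site_frequencies(g, samples)
    sum(sf$het) / sum(g$contig_lengths)
  }
}

#' Count SNVs segregating within a sample
#'
#' @param g A haploidized [genotype_matrix()].
#' @param samples Sample name list; default all columns.
#' @return Number of sites with both alleles present among non-missing
#'   haplotypes of the sample.
#' @export
count_segregating_sites <- function(g, samples = NULL) {
  sf <- site_frequencies(g, samples, min_completeness = 0)
  sum(sf$seg)
}

#' Greedy sliding-window LD pruning
#'
#' PLINK-style `--indep-pairwise` scan: within each window of
#' `window_sites` consecutive variants, while any retained pair has
#' squared Pearson correlation of 0/1 allele dosages above `r2_max`, one
#' member of the worst pair is removed (the site with the lower
#' minor-allele frequency; ties by later position); the window then
#' advances by `step_sites`. Optionally drops variants present in only
#' one isotype (singletons) first, as done upstream of distance-based
#' phylogenies and ancestry model fitting.
#'
#' @param g A haploidized [genotype_matrix()].
#' @param window_sites Variants per scan window (e.g. 50).
#' @param step_sites Variants to advance between windows (e.g. 10 or 1).
#' @param r2_max Maximum tolerated r-squared (e.g. 0.8 or 0.95).
#' @param drop_singletons Remove variants whose ALT allele occurs in
#'   exactly one isolate before scanning.
#' @return Sorted integer vector of retained site indices into `g`.
#' @export
ld_prune <- function(g, window_sites = 50, step_sites = 10, r2_max = 0.8,
                     drop_singletons = FALSE) {
  stopifnot(window_sites >= 2, step_sites >= 1, r2_max > 0)
  dose <- g$calls
  dose[dose == GT_HET | dose == GT_MISSING] <- NA_integer_
  active <- rep(TRUE, n_sites(g))
  if (drop_singletons) {
    n_alt <- rowSums(dose == 1L, na.rm = TRUE)
    active[n_alt == 1L] <- FALSE
  }
  maf <- {
    p <- rowMeans(dose, na.rm = TRUE)
    pmin(p, 1 - p)
  }
  for (chr in unique(g$chrom)) {
    chr_idx <- which(g$chrom == chr)
    start <- 1
    repeat {
      live <- chr_idx[active[chr_idx]]
      if (start > length(live)) break
      win <- live[start:min(start + window_sites - 1, length(live))]
      if (length(win) >= 2) {
        repeat {
          win <- win[active[win]]
          if (length(win) < 2) break
          r2 <- suppressWarnings(
            stats::cor(t(dose[win, , drop = FALSE]),
                       use = "pairwise.complete.obs")^2
          )
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[worst[1], worst[2]] <= r2_max) break
          pair <- win[c(worst[1], worst[2])]
          drop <- if (maf[pair[1]] != maf[pair[2]]) {
            pair[which.min(maf[pair])]
          } else max(pair)  # tie: later position
          active[drop] <- FALSE
        }
      }
      if (start + window_sites - 1 >= length(live)) break
      start <- start + step_sites
    }
  }
  which(active)
}
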