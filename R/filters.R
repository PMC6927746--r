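#' Filter thresholds for the two filtering regimes
#'
#' Two regimes are used on wild-isolate SNV calls. The
#' *concordance*-grade filter (used before pairwise strain comparison)
#' requires depth (`FORMAT/DP`) >= 3, mapping quality (`INFO/MQ`) > 40,
#' variant quality (`QUAL`) > 30 and allelic-depth ratio
#' (`FORMAT/AD`/`FORMAT/DP`) > 0.5. The *population*-grade filter (used
#' to build the population VCFs) requires depth > 10, mapping quality
#' > 40, variant quality > 10 and allelic-depth ratio > 0.5, and
#' additionally flags sites with > 90% missing genotypes
#' (`high_missing`) or > 10% heterozygosity (`high_heterozygosity`).
#' Inequalities are strict exactly as printed (a ratio of exactly 0.5
#' fails).
#'
#' @param mode `"concordance"` or `"population"`.
#' @param min_depth,depth_strict Depth threshold and whether the
#'   comparison is strict (`>`; population) or inclusive (`>=`;
#'   concordance).
#' @param min_mq,min_qual,min_ad_ratio Strict lower bounds for mapping
#'   quality, variant quality and allelic-depth ratio.
#' @param max_missing_fraction,max_het_fraction Site-flag thresholds
#'   (population mode), strict upper bounds.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(mode = c("concordance", "population"),
                              min_depth = NULL, depth_strict = NULL,
                              min_mq = 40, min_qual = NULL,
                              min_ad_ratio = 0.5,
                              max_missing_fraction = 0.90,
                              max_het_fraction = 0.10) {
  mode <- match.arg(mode)
  if (is.null(min_depth)) min_depth <- if (mode == "concordance") 3 else 10
  if (is.null(depth_strict)) depth_strict <- mode == "population"
  if (is.null(min_qual)) min_qual <- if (mode == "concordance") 30 else 10
  stopifnot(min_depth >= 0, min_mq >= 0, min_qual >= 0,
            min_ad_ratio >= 0, min_ad_ratio <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            max_het_fraction >= 0, max_het_fraction <= 1)
  structure(list(mode = mode, min_depth = min_depth,
                 depth_strict = depth_strict, min_mq = min_mq,
                 min_qual = min_qual, min_ad_ratio = min_ad_ratio,
                 max_missing_fraction = max_missing_fraction,
                 max_het_fraction = max_het_fraction),
            class = "filter_thresholds")
}

#' Apply per-call and per-site quality filters
#'
#' Calls failing any per-call threshold (depth, allelic-depth ratio) and
#' all calls at sites failing a per-site threshold (mapping quality,
#' variant quality) are set to MISSING. Site rows where every call
#' becomes MISSING are dropped. Quality fields absent from the input
#' (e.g. toy fixtures without `DP`/`AD`) are treated as passing, with a
#' warning counter in the attached accounting.
#'
#' Filtering is idempotent and monotone: applying the same thresholds
#' twice equals applying once, and raising any minimum never increases
#' the number of retained calls.
#'
#' @param g A [genotype_matrix()].
#' @param t A [filter_thresholds()] object.
#' @return A filtered `genotype_matrix` with a `filter_counts` attribute
#'   recording dropped sites, masked calls and fields absent from input.
#' @export
apply_call_filters <- function(g, t) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(t, "filter_thresholds"))
  absent <- character(0)
  n0 <- n_sites(g)
  if (n0 == 0) return(g)

  site_fail <- rep(FALSE, n0)
  if (is.null(g$mq)) absent <- c(absent, "INFO/MQ") else {
    site_fail <- site_fail | (!is.na(g$mq) & g$mq <= t$min_mq)
  }
  if (is.null(g$qual)) absent <- c(absent, "QUAL") else {
    site_fail <- site_fail | (!is.na(g$qual) & g$qual <= t$min_qual)
  }

  call_fail <- matrix(FALSE, nrow = n0, ncol = length(g$samples))
  if (is.null(g$dp)) absent <- c(absent, "FORMAT/DP") else {
    call_fail <- call_fail |
      (!is.na(g$dp) & (if (t$depth_strict) g$dp <= t$min_depth
                       else g$dp < t$min_depth))
  }
  if (is.null(g$ad_ratio)) absent <- c(absent, "FORMAT/AD") else {
    call_fail <- call_fail |
      (!is.na(g$ad_ratio) & g$ad_ratio <= t$min_ad_ratio)
  }
  call_fail <- call_fail | site_fail

  was_called <- g$calls != GT_MISSING
  n_masked <- sum(call_fail & was_called)
  g$calls[call_fail] <- GT_MISSING
  keep <- rowSums(g$calls != GT_MISSING) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0 || n_masked > 0) {
    message("apply_call_filters[", t$mode, "]: masked ", n_masked,
            " call(s), dropped ", n_dropped, " all-missing site(s)")
  }
  if (length(absent)) {
    warning("quality field(s) absent, treated as passing: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- subset_genotypes(g, sites = keep)
  attr(out, "filter_counts") <- list(sites_in = n0,
                                     sites_dropped = n_dropped,
                                     calls_masked = n_masked,
                                     absent_fields = absent)
  out
}

#' Flag sites with excess missingness or heterozygosity
#'
#' Population-grade site flags: `high_missing` where the fraction of
#' MISSING calls exceeds `max_missing_fraction` (default 0.90), and
#' `high_heterozygosity` where the fraction of HET calls among
#' non-missing calls exceeds `max_het_fraction` (default 0.10).
#'
#' @param g A [genotype_matrix()].
#' @param t A [filter_thresholds()] in population mode.
#' @return A list with `g` (unchanged) and `flags`, a per-site
#'   data.frame with columns `chrom`, `pos`, `missing_fraction`,
#'   `het_fraction`, `high_missing`, `high_heterozygosity`, `ft` (the
#'   combined FILTER-style string, `"PASS"` when clean).
#' @export
apply_site_flags <- function(g, t = filter_thresholds("population")) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (t$mode != "population") {
    stop("site flags are defined for population mode", call. = FALSE)
  }
  n <- length(g$samples)
  n_miss <- rowSums(g$calls == GT_MISSING)
  n_het <- rowSums(g$calls == GT_HET)
  n_called <- n - n_miss
  miss_frac <- n_miss / n
  het_frac <- ifelse(n_called > 0, n_het / n_called, 0)
  hm <- miss_frac > t$max_missing_fraction
  hh <- het_frac > t$max_het_fraction
  ft <- rep("PASS", n_sites(g))
  ft[hh] <- "high_heterozygosity"
  ft[hm] <- "high_missing"
  ft[hm & hh] <- "high_missing;high_heterozygosity"
  list(g = g,
       flags = data.frame(chrom = g$chrom, pos = g$pos,
                          missing_fraction = miss_frac,
                          het_fraction = het_frac,
                          high_missing = hm, high_heterozygosity = hh,
                          ft = ft, stringsAsFactors = FALSE))
}

#' Hard-filter a population-grade genotype matrix
#'
#' Removes sites flagged `high_missing` or `high_heterozygosity` (see
#' [apply_site_flags()]) and, for downstream population genetics among
#' essentially homozygous isotypes, sets remaining HET calls to MISSING
#' ([haploidize()]).
#'
#' @param g A [genotype_matrix()].
#' @param t A population-mode [filter_thresholds()].
#' @return A haploidized, hard-filtered `genotype_matrix`.
#' @export
hard_filter <- function(g, t = filter_thresholds("population")) {
  g <- apply_call_filters(g, t)
  fl <- apply_site_flags(g, t)$flags
  keep <- !(fl$high_missing | fl$high_heterozygosity)
  if (any(!keep)) {
    message("hard_filter: removed ", sum(!keep), " flagged site(s)")
  }
  g <- subset_genotypes(g, sites = keep)
  g <- haploidize(g)
  keep2 <- rowSums(g$calls != GT_MISSING) > 0
  subset_genotypes(g, sites = keep2)
}
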