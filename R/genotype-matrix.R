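# Integer call codes used throughout; MISSING sorts last so that
# haploid comparisons can mask on code < GT_HET.
GT_REF <- 0L
GT_ALT <- 1L
GT_HET <- 2L
GT_MISSING <- 3L

#' Construct a genotype matrix of biallelic SNVs
#'
#' The central container for all genetic computation: a sites x isolates
#' matrix of genotype calls at biallelic single-nucleotide variants, with
#' per-call depth and allelic-depth-ratio fields and per-site mapping and
#' variant quality. Selfing isolates are essentially homozygous, so calls
#' are coded `REF`/`ALT`/`HET`/`MISSING` (integers 0/1/2/3) and downstream
#' statistics treat haploidized matrices (one allele per isotype).
#'
#' @param chrom Character vector, chromosome id per site.
#' @param pos Integer vector, 1-based position per site; must be strictly
#'   increasing within each chromosome.
#' @param ref,alt Single-base reference/alternate alleles per site.
#' @param calls Integer matrix (`n_sites` x `n_isolates`) of call codes.
#' @param samples Character vector of isolate names (column order).
#' @param dp Optional matrix of per-call read depths (`FORMAT/DP`).
#' @param ad_ratio Optional matrix of per-call allelic-depth ratios:
#'   high-quality reads supporting the called allele over total
#'   high-quality reads, in `[0, 1]`.
#' @param mq,qual Optional per-site mapping quality (`INFO/MQ`) and variant
#'   quality (`QUAL`), Phred-like scores.
#' @param contig_lengths Named numeric vector of chromosome lengths in bp.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, calls, samples,
                            dp = NULL, ad_ratio = NULL, mq = NULL,
                            qual = NULL, contig_lengths = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(NULL, samples)
  g <- structure(
    list(
      chrom = as.character(chrom),
      pos = as.integer(pos),
      ref = as.character(ref),
      alt = as.character(alt),
      calls = calls,
      dp = dp,
      ad_ratio = ad_ratio,
      mq = if (is.null(mq)) NULL else as.numeric(mq),
      qual = if (is.null(qual)) NULL else as.numeric(qual),
      samples = as.character(samples),
      contig_lengths = contig_lengths
    ),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  n_sites <- length(g$pos)
  if (length(g$chrom) != n_sites || length(g$ref) != n_sites ||
      length(g$alt) != n_sites) {
    stop("chrom/pos/ref/alt lengths differ", call. = FALSE)
  }
  if (!all(dim(g$calls) == c(n_sites, length(g$samples)))) {
    stop("calls dimensions must be (n_sites, n_isolates)", call. = FALSE)
  }
  if (n_sites > 0) {
    if (any(nchar(g$ref) != 1L) || any(nchar(g$alt) != 1L)) {
      stop("all sites must be biallelic SNVs (single-base ref and alt)",
           call. = FALSE)
    }
    ord <- order(match(g$chrom, unique(g$chrom)), g$pos)
    if (is.unsorted(ord)) stop("sites must be ordered by chromosome then position",
                               call. = FALSE)
    by_chr <- split(g$pos, g$chrom)
    bad <- vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))
    if (any(bad)) {
      stop("positions must be strictly increasing within chromosome(s): ",
           paste(names(by_chr)[bad], collapse = ", "), call. = FALSE)
    }
    if (!all(g$calls %in% c(GT_REF, GT_ALT, GT_HET, GT_MISSING))) {
      stop("calls must be coded 0 (REF), 1 (ALT), 2 (HET) or 3 (MISSING)",
           call. = FALSE)
    }
  }
  for (fld in c("dp", "ad_ratio")) {
    m <- g[[fld]]
    if (!is.null(m) && !all(dim(m) == dim(g$calls))) {
      stop(fld, " must have the same dimensions as calls", call. = FALSE)
    }
  }
  for (fld in c("mq", "qual")) {
    v <- g[[fld]]
    if (!is.null(v) && length(v) != n_sites) {
      stop(fld, " must have one value per site", call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", n_sites(x), " biallelic SNV sites x ",
      length(x$samples), " isolates\n", sep = "")
  if (n_sites(x) > 0) {
    tab <- table(factor(x$calls, levels = 0:3,
                        labels = c("REF", "ALT", "HET", "MISSING")))
    cat("  chromosomes: ", paste(unique(x$chrom), collapse = ", "), "\n", sep = "")
    cat("  calls: ", paste(names(tab), tab, sep = "=", collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of SNV sites in a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Integer site count.
#' @export
n_sites <- function(g) length(g$pos)

#' Subset a genotype matrix by site index and/or sample names
#'
#' @param g A `genotype_matrix`.
#' @param sites Integer or logical index over sites (default: all).
#' @param samples Character vector of isolate names to keep (default: all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(g))
  if (is.logical(sites)) sites <- which(sites)
  cols <- seq_along(g$samples)
  if (!is.null(samples)) {
    cols <- match(samples, g$samples)
    if (anyNA(cols)) {
      stop("sample(s) not present: ",
           paste(samples[is.na(cols)], collapse = ", "), call. = FALSE)
    }
  }
  genotype_matrix(
    chrom = g$chrom[sites], pos = g$pos[sites],
    ref = g$ref[sites], alt = g$alt[sites],
    calls = g$calls[sites, cols, drop = FALSE],
    samples = g$samples[cols],
    dp = if (!is.null(g$dp)) g$dp[sites, cols, drop = FALSE],
    ad_ratio = if (!is.null(g$ad_ratio)) g$ad_ratio[sites, cols, drop = FALSE],
    mq = if (!is.null(g$mq)) g$mq[sites],
    qual = if (!is.null(g$qual)) g$qual[sites],
    contig_lengths = g$contig_lengths
  )
}

#' Set heterozygous calls to missing (haploid treatment)
#'
#' The species selfs in the wild, so isotypes are homozygous genome-wide
#' haplotypes; residual heterozygous calls are treated as missing and the
#' matrix is interpreted as haploid downstream.
#'
#' @param g A `genotype_matrix`.
#' @return A `genotype_matrix` with no HET calls.
#' @export
haploidize <- function(g) {
  g$calls[g$calls == GT_HET] <- GT_MISSING
  g
}
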