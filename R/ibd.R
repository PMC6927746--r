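#' Detect long identity-by-descent segments between haploid isolates
#'
#' A simple internal detector so synthetic bundles run end to end
#' (production analyses of the released VCFs used IBDSeq with
#' `minalleles = 0.01, ibdtrim = 0, r2max = 0.8`; its segment table is
#' accepted directly by [read_ibd_segments()]). For every pair of
#' columns, maximal runs of identical non-missing calls allowing at most
#' `max_mismatch` discordances are reported when the genomic span
#' reaches `min_length`; overlapping qualifying runs are merged.
#'
#' @param g A haploidized [genotype_matrix()].
#' @param min_length Minimum reported span in bp (default 1 Mb).
#' @param max_mismatch Maximum discordant sites tolerated inside one run
#'   (default 1).
#' @return A data.frame of segments: `isotype_a`, `isotype_b`, `chrom`,
#'   `start`, `end` (bp, 1-based inclusive), with attribute
#'   `provenance = "internal run detector"`.
#' @export
detect_ibd_segments <- function(g, min_length = 1e6, max_mismatch = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  samples <- g$samples
  n <- length(samples)
  out <- vector("list", 0)
  for (chr in unique(g$chrom)) {
    idx <- which(g$chrom == chr)
    pos <- g$pos[idx]
    calls <- g$calls[idx, , drop = FALSE]
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- calls[, i]; b <- calls[, j]
        ok <- a != GT_MISSING & b != GT_MISSING
        if (sum(ok) < 2) next
        p <- pos[ok]
        mism <- which(a[ok] != b[ok])
        segs <- runs_with_mismatches(p, mism, max_mismatch, min_length)
        if (!is.null(segs)) {
          segs$isotype_a <- samples[i]
          segs$isotype_b <- samples[j]
          segs$chrom <- chr
          out[[length(out) + 1]] <- segs
        }
      }
    }
  }
  res <- if (length(out)) {
    do.call(rbind, out)[, c("isotype_a", "isotype_b", "chrom",
                            "start", "end")]
  } else {
    data.frame(isotype_a = character(0), isotype_b = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "provenance") <- "internal run detector"
  res
}

# Maximal stretches of the jointly-called site list containing at most
# max_mismatch mismatching sites, spanning >= min_length bp; overlaps
# merged. `mism` holds indices (into p) of mismatching sites.
runs_with_mismatches <- function(p, mism, max_mismatch, min_length) {
  bounds <- c(0L, mism, length(p) + 1L)
  # candidate run t covers sites (bounds[t]+1) .. (bounds[t+max_mismatch+1]-1),
  # i.e. it may contain up to max_mismatch mismatching sites; when the
  # pair has fewer mismatches than the allowance a single run covers all
  n_runs <- max(1L, length(bounds) - max_mismatch - 1L)
  starts <- ends <- numeric(0)
  for (t in seq_len(n_runs)) {
    lo <- bounds[t] + 1L
    hi <- bounds[min(t + max_mismatch + 1L, length(bounds))] - 1L
    if (hi < lo) next
    if (p[hi] - p[lo] >= min_length) {
      starts <- c(starts, p[lo]); ends <- c(ends, p[hi])
    }
  }
  if (!length(starts)) return(NULL)
  # merge overlapping runs
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- out_e <- numeric(0)
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me) me <- max(me, ends[k]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start = out_s, end = out_e)
}

#' Read an IBD segment table
#'
#' Accepts the package's own TSV (`isotype_a`, `isotype_b`, `chrom`,
#' `start`, `end`) or IBDSeq-style columns (`sample1`, `sample2`,
#' `chrom`/`chr`, `start`, `end`); extra columns are ignored.
#'
#' @param path TSV file path.
#' @return A data.frame of segments with canonical column names.
#' @export
read_ibd_segments <- function(path) {
  if (!file.exists(path)) stop("IBD table not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  alias <- c(sample1 = "isotype_a", sample2 = "isotype_b", chr = "chrom")
  for (a in names(alias)) {
    if (a %in% names(d) && !(alias[[a]] %in% names(d))) {
      names(d)[names(d) == a] <- alias[[a]]
    }
  }
  need <- c("isotype_a", "isotype_b", "chrom", "start", "end")
  if (!all(need %in% names(d))) {
    stop("IBD table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- d[, need]
  if (any(d$start >= d$end)) stop("IBD segments must have start < end",
                                  call. = FALSE)
  d
}
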