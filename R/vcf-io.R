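#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a standard VCF v4.x (via \pkg{vcfR}) and restricts it to
#' biallelic SNVs; indels and multiallelic records are dropped with a
#' logged count. Diploid genotypes are recoded `0/0 -> REF`,
#' `1/1 -> ALT`, `0/1` or `1/0 -> HET`, `./. -> MISSING` (phased
#' separators accepted). `FORMAT/DP`, `FORMAT/AD`, `INFO/MQ` and `QUAL`
#' are carried along when present; the allelic-depth ratio is the depth
#' of reads supporting the called allele over `DP` (for heterozygous
#' calls, the larger of the two allele depths over `DP`).
#'
#' @param path Path to a VCF (optionally bgzipped) file.
#' @param sample_subset Optional character vector of sample names to keep.
#' @return A [genotype_matrix()] with contig lengths taken from the
#'   `##contig` header lines when present.
#' @export
read_vcf_genotypes <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF: ", conditionMessage(e),
                             call. = FALSE)
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    stop("malformed VCF: no variant records in ", path, call. = FALSE)
  }
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, samples)
    if (length(missing_s)) {
      stop("requested sample(s) absent from VCF: ",
           paste(missing_s, collapse = ", "), call. = FALSE)
    }
    samples <- sample_subset
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_drop <- sum(!snv)
  if (n_drop > 0) {
    message("read_vcf_genotypes: dropped ", n_drop,
            " non-SNV or multiallelic record(s)")
  }
  keep <- which(snv)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, samples, drop = FALSE]
  code <- matrix(GT_MISSING, nrow = nrow(gt), ncol = ncol(gt))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  code[gt_clean %in% c("0/0", "0")] <- GT_REF
  code[gt_clean %in% c("1/1", "1")] <- GT_ALT
  code[gt_clean %in% c("0/1", "1/0")] <- GT_HET

  fmt <- strsplit(v@gt[1, 1], ":", fixed = TRUE)[[1]]
  dp <- NULL
  if ("DP" %in% fmt) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, samples,
                                                                 drop = FALSE]
  }
  ad_ratio <- NULL
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v, element = "AD")[keep, samples, drop = FALSE]
    ad_ratio <- ad_to_ratio(ad, code)
  }

  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))[keep]
  if (all(is.na(mq))) mq <- NULL
  if (all(is.na(qual))) qual <- NULL

  genotype_matrix(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    calls = code, samples = samples,
    dp = dp, ad_ratio = ad_ratio, mq = mq, qual = qual,
    contig_lengths = contig_lengths_from_meta(v@meta)
  )
}

# AD is "ref,alt"; ratio = reads supporting the called allele / total reads.
ad_to_ratio <- function(ad, code) {
  parts <- strsplit(ad, ",", fixed = TRUE)
  a_ref <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  a_alt <- suppressWarnings(as.numeric(vapply(parts, function(x) {
    if (length(x) >= 2) x[2] else NA_character_
  }, "")))
  tot <- a_ref + a_alt
  supp <- a_alt
  supp[code == GT_REF] <- a_ref[code == GT_REF]
  supp[code == GT_HET] <- pmax(a_ref, a_alt)[code == GT_HET]
  r <- matrix(supp / tot, nrow = nrow(ad), ncol = ncol(ad))
  r[!is.finite(r)] <- NA_real_
  r
}

contig_lengths_from_meta <- function(meta) {
  contigs <- grep("^##contig=", meta, value = TRUE)
  if (!length(contigs)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contigs)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                          contigs)))
  stats::setNames(lens, ids)
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Serializes a [genotype_matrix()] as plain-text VCF with `##contig`
#' header lines carrying chromosome lengths, `GT:DP:AD` FORMAT fields
#' (when depth/ratio are present) and `INFO/MQ`. Reading the file back
#' with [read_vcf_genotypes()] reproduces the call codes exactly.
#'
#' @param g A `genotype_matrix`.
#' @param path Output file path (plain `.vcf`).
#' @param ft Optional character matrix of per-call or per-site filter
#'   annotations written to the `FILTER` column (per-site character
#'   vector), e.g. `high_missing`/`high_heterozygosity` flags.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(g, path, ft = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(g$contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(g$contig_lengths),
                       as.integer(g$contig_lengths)), con)
  }
  writeLines(c(
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FILTER=<ID=high_missing,Description="More than 90% missing genotypes">',
    '##FILTER=<ID=high_heterozygosity,Description="More than 10% heterozygosity">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"), con)
  if (n_sites(g) == 0) return(invisible(path))

  gt_str <- matrix(c("0/0", "1/1", "0/1", "./.")[g$calls + 1L],
                   nrow = n_sites(g))
  has_dp <- !is.null(g$dp)
  if (has_dp) {
    dp <- g$dp
    ratio <- if (!is.null(g$ad_ratio)) g$ad_ratio else
      matrix(1, nrow(dp), ncol(dp))
    supp <- round(dp * ratio)
    other <- dp - supp
    # place supporting depth on the called allele
    a_ref <- ifelse(g$calls == GT_ALT, other, supp)
    a_alt <- ifelse(g$calls == GT_ALT, supp, other)
    cell <- matrix(paste0(gt_str, ":", ifelse(is.na(dp), ".", dp), ":",
                          ifelse(is.na(dp), ".", paste0(a_ref, ",", a_alt))),
                   nrow = nrow(gt_str))
    fmt <- "GT:DP:AD"
  } else {
    cell <- gt_str
    fmt <- "GT"
  }
  filter_col <- if (is.null(ft)) "PASS" else ifelse(ft == "" | is.na(ft),
                                                    "PASS", ft)
  lines <- paste(
    g$chrom, g$pos, ".", g$ref, g$alt,
    if (is.null(g$qual)) "." else ifelse(is.na(g$qual), ".",
                                         format(g$qual, trim = TRUE)),
    filter_col,
    if (is.null(g$mq)) "." else ifelse(is.na(g$mq), ".",
                                       paste0("MQ=", format(g$mq, trim = TRUE))),
    fmt,
    apply(cell, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}
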