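#' Pairwise SNV concordance between isolates
#'
#' Computes, for every pair of isolates, the fraction of shared SNVs
#' over sites callable (non-missing) in both members of the pair. Two
#' readings of "fraction of shared SNVs" are supported:
#'
#' * `"agreement"` (default): the fraction of jointly-called sites at
#'   which the two calls are identical;
#' * `"jaccard"`: the Jaccard similarity of the two isolates' ALT-site
#'   sets, `|shared alt| / |union alt|`, restricted to jointly-callable
#'   sites.
#'
#' Pairs with no jointly-callable denominator are undefined (`NA`) and
#' reported; pairs whose denominator is below `min_sites` are flagged
#' low-confidence (tiny denominators make the fraction unstable).
#'
#' @param g A concordance-grade filtered [genotype_matrix()].
#' @param method `"agreement"` or `"jaccard"` (see Details).
#' @param min_sites Low-confidence flag threshold on the pair
#'   denominator (default 100).
#' @return An object of class `concordance_matrix`: a list with
#'   symmetric matrices `fraction`, `shared`, `denominator`, a logical
#'   `low_confidence` matrix, the `method`, and per-isolate missing-call
#'   counts (used downstream to pick isotype representatives).
#' @export
pairwise_concordance <- function(g, method = c("agreement", "jaccard"),
                                 min_sites = 100) {
  method <- match.arg(method)
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$samples)
  callable <- (g$calls != GT_MISSING) * 1
  if (method == "agreement") {
    denom <- crossprod(callable)
    shared <- matrix(0, n, n)
    for (code in c(GT_REF, GT_ALT, GT_HET)) {
      ind <- (g$calls == code) * 1
      shared <- shared + crossprod(ind)
    }
  } else {
    alt <- (g$calls == GT_ALT) * 1
    shared <- crossprod(alt)
    denom <- crossprod(alt, callable) + crossprod(callable, alt) - shared
  }
  frac <- ifelse(denom > 0, shared / denom, NA_real_)
  dimnames(frac) <- dimnames(shared) <- dimnames(denom) <-
    list(g$samples, g$samples)
  undef <- sum(is.na(frac[upper.tri(frac)]))
  if (undef > 0) {
    message("pairwise_concordance: ", undef,
            " pair(s) with empty denominator reported as undefined")
  }
  structure(list(fraction = frac, shared = shared, denominator = denom,
                 low_confidence = denom < min_sites, method = method,
                 n_missing = colSums(g$calls == GT_MISSING),
                 samples = g$samples),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("<concordance_matrix> ", length(x$samples), " isolates, method=",
      x$method, "\n", sep = "")
  invisible(x)
}

#' Long-format pair table from a concordance matrix
#'
#' @param cm A [pairwise_concordance()] result.
#' @return A data.frame with one row per unordered pair: `isolate_a`,
#'   `isolate_b`, `shared`, `denominator`, `fraction`, `low_confidence`.
#' @export
concordance_pairs <- function(cm) {
  idx <- which(upper.tri(cm$fraction), arr.ind = TRUE)
  data.frame(isolate_a = cm$samples[idx[, 1]],
             isolate_b = cm$samples[idx[, 2]],
             shared = cm$shared[idx],
             denominator = cm$denominator[idx],
             fraction = cm$fraction[idx],
             low_confidence = cm$low_confidence[idx],
             stringsAsFactors = FALSE)
}

#' Partition isolates into isotypes by the >99.9% concordance rule
#'
#' Isolates sharing more than `threshold` (default 0.999) of their SNVs
#' are the same isotype. Transitivity is resolved by single linkage:
#' isotypes are the connected components of the graph with an edge
#' wherever pair concordance exceeds the threshold. Isotype ids are
#' deterministic (the lexicographically smallest member name); the
#' designated representative is the member with the fewest missing
#' calls, ties broken by name.
#'
#' @param cm A [pairwise_concordance()] result.
#' @param threshold Concordance threshold; pairs must exceed it
#'   *strictly* to merge (default 0.999, i.e. ">99.9%").
#' @return An object of class `isotype_partition`: a data.frame with
#'   columns `isolate`, `isotype`, `representative`.
#' @export
assign_isotypes <- function(cm, threshold = 0.999) {
  stopifnot(inherits(cm, "concordance_matrix"),
            threshold >= 0, threshold <= 1)
  samples <- cm$samples
  n <- length(samples)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(upper.tri(cm$fraction) & !is.na(cm$fraction) &
                   cm$fraction > threshold, arr.ind = TRUE)
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_len(n), find, integer(1))
  iso_id <- vapply(split(seq_len(n), comp), function(members) {
    min(samples[members])
  }, character(1))[as.character(comp)]

  rep_flag <- logical(n)
  for (members in split(seq_len(n), iso_id)) {
    nm <- cm$n_missing[members]
    best <- members[order(nm, samples[members])][1]
    rep_flag[best] <- TRUE
  }
  structure(data.frame(isolate = samples, isotype = unname(iso_id),
                       representative = rep_flag,
                       stringsAsFactors = FALSE),
            class = c("isotype_partition", "data.frame"))
}

#' List isotypes with members and representatives
#'
#' @param part An [assign_isotypes()] partition.
#' @return A data.frame with one row per isotype: `isotype`,
#'   `n_members`, `representative`, `members` (comma-separated).
#' @export
isotype_summary <- function(part) {
  sp <- split(part, part$isotype)
  data.frame(
    isotype = names(sp),
    n_members = vapply(sp, nrow, integer(1)),
    representative = vapply(sp, function(d) d$isolate[d$representative][1],
                            character(1)),
    members = vapply(sp, function(d) paste(sort(d$isolate), collapse = ","),
                     character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
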