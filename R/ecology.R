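#' Controlled vocabularies for field-collection records
#'
#' `SUBSTRATE_CLASSES` holds the six major substrate categories;
#' `ISLANDS` the sampled islands; `CATEGORY_PRECEDENCE` the collection
#' category legend order (left to right: named Caenorhabditis species
#' first, then other PCR outcomes, tracks, and no nematode) used to
#' assign a single category to samples observed under several.
#'
#' @name field-vocabularies
#' @export
SUBSTRATE_CLASSES <- c("leaf litter", "fruit", "flower", "fungus",
                       "invertebrate", "vegetation")

#' @rdname field-vocabularies
#' @export
ISLANDS <- c("Kauai", "Oahu", "Molokai", "Maui", "Big Island")

#' @rdname field-vocabularies
#' @export
CATEGORY_PRECEDENCE <- c("C. elegans", "C. oiwi", "C. briggsae",
                         "C. tropicalis", "C. kamaaina",
                         "Other PCR-positive", "PCR-negative",
                         "Not genotyped", "Tracks", "No nematode")

#' Read a field-collection table
#'
#' Expects the source-data CSV dialect: one row per observed
#' (`c_label`, `collection_type`) pair with columns `c_label`,
#' `collection_type`, `island`, `PCR_positive`, `worms_on_sample`,
#' `Longitude`, `Latitude`, `multiple_type`, and optionally `substrate`,
#' `gridsect` (id or empty) and `gridsect_radius`. Unknown island or
#' substrate values raise a validation error listing the offenders.
#'
#' @param path CSV file path.
#' @param islands,substrates Allowed category vocabularies.
#' @return A validated data.frame of collection records.
#' @export
read_collections <- function(path, islands = ISLANDS,
                             substrates = SUBSTRATE_CLASSES) {
  if (!file.exists(path)) stop("collections file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("c_label", "collection_type", "island", "PCR_positive",
            "worms_on_sample", "Longitude", "Latitude", "multiple_type")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("collections table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad_island <- setdiff(unique(d$island), islands)
  if (length(bad_island)) stop("unknown island value(s): ",
                               paste(bad_island, collapse = ", "),
                               call. = FALSE)
  if ("substrate" %in% names(d)) {
    bad_sub <- setdiff(unique(d$substrate), substrates)
    if (length(bad_sub)) stop("unknown substrate value(s): ",
                              paste(bad_sub, collapse = ", "),
                              call. = FALSE)
  }
  bad_lat <- !is.na(d$Latitude) & abs(d$Latitude) > 90
  bad_lon <- !is.na(d$Longitude) & abs(d$Longitude) > 180
  if (any(bad_lat) || any(bad_lon)) {
    stop("coordinates out of range for c_label(s): ",
         paste(unique(d$c_label[bad_lat | bad_lon]), collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Read an isolation (S-plate) table
#'
#' One row per isolated nematode: `s_label`, `c_label`,
#' `genotype_outcome` (`PCR-positive` / `PCR-negative` /
#' `Not genotyped`), `species_or_genus`, and optionally
#' `worms_on_plate`. Every `s_label` must map to an existing `c_label`
#' when a collections table is supplied.
#'
#' @param path CSV file path.
#' @param collections Optional collections data.frame for referential
#'   validation.
#' @return A validated data.frame of isolation records.
#' @export
read_isolations <- function(path, collections = NULL) {
  if (!file.exists(path)) stop("isolations file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("s_label", "c_label", "genotype_outcome", "species_or_genus")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("isolations table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$s_label)) stop("duplicate s_label(s)", call. = FALSE)
  if (!is.null(collections)) {
    orphan <- setdiff(unique(d$c_label), unique(collections$c_label))
    if (length(orphan)) stop("isolation c_label(s) missing from collections: ",
                             paste(orphan, collapse = ", "), call. = FALSE)
  }
  d
}

#' Read a long-format environmental parameter table
#'
#' Columns `c_label`, `s_label`, `species_family`, `env_par`, `value`.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_environment <- function(path) {
  if (!file.exists(path)) stop("environment file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("c_label", "env_par", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("environment table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Collapse a sample's observed categories by legend precedence
#'
#' A sample observed under several collection categories is assigned the
#' single highest-precedence one (the category legend read left to
#' right: named species first, then other PCR outcomes, tracks, and no
#' nematode).
#'
#' @param records A collections data.frame (long: one row per
#'   c_label x category).
#' @param precedence Category order, highest first.
#' @return A data.frame with one row per `c_label` and its assigned
#'   `category` (plus `island`, and `substrate` when present).
#' @export
assign_categories <- function(records, precedence = CATEGORY_PRECEDENCE) {
  unknown <- setdiff(unique(records$collection_type), precedence)
  if (length(unknown)) stop("collection categories not in precedence list: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  rank <- match(records$collection_type, precedence)
  keep_cols <- intersect(c("c_label", "island", "substrate", "Longitude",
                           "Latitude", "gridsect"), names(records))
  sp <- split(seq_len(nrow(records)), records$c_label)
  rows <- vapply(sp, function(i) i[which.min(rank[i])], integer(1))
  out <- records[rows, keep_cols, drop = FALSE]
  out$category <- precedence[vapply(sp, function(i) min(rank[i]), integer(1))]
  rownames(out) <- NULL
  out
}

#' Tally collection categories by island and by substrate
#'
#' @param records A collections data.frame.
#' @param precedence Category precedence for multi-category samples.
#' @return A list with `by_island` and (when a substrate column is
#'   present) `by_substrate`, each a data.frame of counts and
#'   percentages per stratum x category; percentages sum to 100 within
#'   each stratum.
#' @export
tally_categories <- function(records, precedence = CATEGORY_PRECEDENCE) {
  one <- assign_categories(records, precedence)
  tally_by <- function(stratum) {
    tab <- table(one[[stratum]], factor(one$category, levels = precedence))
    cnt <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(cnt) <- c(stratum, "category", "count")
    totals <- rowSums(tab)
    cnt$percent <- 100 * cnt$count / as.numeric(totals[cnt[[stratum]]])
    cnt
  }
  out <- list(by_island = tally_by("island"))
  if ("substrate" %in% names(one)) out$by_substrate <- tally_by("substrate")
  out$n_samples <- nrow(one)
  out
}

#' Substrate/island enrichment of a taxon (Fisher's exact test)
#'
#' Builds the 2x2 table (taxon-positive vs not, stratum A vs stratum B)
#' and applies the two-sided exact test (minimum-likelihood method:
#' summing hypergeometric outcome probabilities no larger than the
#' observed table's). No multiplicity adjustment is applied by default;
#' pass the returned p values through [stats::p.adjust()] for a
#' Bonferroni correction across several substrate tests.
#'
#' @param records A collections data.frame.
#' @param taxon Category/species label counted as positive (matched
#'   against `collection_type`).
#' @param stratum_a,stratum_b The two strata compared.
#' @param by `"substrate"` or `"island"`.
#' @return A list: `table` (2x2 counts), `odds_ratio` (conditional MLE),
#'   `p_value` (two-sided exact).
#' @export
enrichment_test <- function(records, taxon, stratum_a, stratum_b,
                            by = c("substrate", "island")) {
  by <- match.arg(by)
  if (!by %in% names(records)) stop("records lack a ", by, " column",
                                    call. = FALSE)
  in_a <- records[[by]] == stratum_a
  in_b <- records[[by]] == stratum_b
  units_a <- unique(records$c_label[in_a])
  units_b <- unique(records$c_label[in_b])
  if (!length(units_a)) stop("empty stratum: ", stratum_a, call. = FALSE)
  if (!length(units_b)) stop("empty stratum: ", stratum_b, call. = FALSE)
  pos <- unique(records$c_label[records$collection_type == taxon])
  k_a <- sum(units_a %in% pos); n_a <- length(units_a)
  k_b <- sum(units_b %in% pos); n_b <- length(units_b)
  enrichment_test_counts(k_a, n_a, k_b, n_b)
}

#' Fisher's exact enrichment test from raw counts
#'
#' @param k_a,n_a Taxon-positive count and total in stratum A.
#' @param k_b,n_b Same for stratum B.
#' @return A list: `table`, `odds_ratio`, `p_value`.
#' @export
enrichment_test_counts <- function(k_a, n_a, k_b, n_b) {
  stopifnot(k_a >= 0, k_b >= 0, k_a <= n_a, k_b <= n_b)
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2, byrow = TRUE,
                dimnames = list(c("stratum_a", "stratum_b"),
                                c("positive", "negative")))
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Cluster collections geographically and average environmental values
#'
#' Single-linkage clustering of collection coordinates under great-circle
#' (haversine) distance with a 20 m linkage radius by default: two
#' collections are in one cluster whenever they are joined by a chain of
#' collections each within the radius of the next. Environmental
#' parameters are then averaged per cluster over non-missing values, so
#' locally oversampled spots contribute one value each.
#'
#' @param records A collections data.frame with `Longitude`/`Latitude`
#'   (records with missing coordinates are excluded, logged).
#' @param env Optional long-format environmental table (`c_label`,
#'   `env_par`, `value`).
#' @param radius_m Linkage radius in meters (default 20).
#' @return A list: `clusters` (data.frame `c_label`, `geo_cluster`) and,
#'   when `env` is given, `cluster_means` (`geo_cluster`, `env_par`,
#'   `mean_value`, `n`).
#' @export
geo_cluster_collections <- function(records, env = NULL, radius_m = 20) {
  ok <- !is.na(records$Longitude) & !is.na(records$Latitude)
  if (any(!ok)) {
    message("geo_cluster_collections: excluded ", sum(!ok),
            " record(s) with missing coordinates")
  }
  d <- records[ok, , drop = FALSE]
  d <- d[!duplicated(d$c_label), , drop = FALSE]
  n <- nrow(d)
  if (n == 0) stop("no records with coordinates", call. = FALSE)
  cl <- if (n == 1) 1L else {
    dist_m <- geosphere::distm(cbind(d$Longitude, d$Latitude),
                               fun = geosphere::distHaversine)
    hc <- stats::hclust(stats::as.dist(dist_m), method = "single")
    stats::cutree(hc, h = radius_m)
  }
  clusters <- data.frame(c_label = d$c_label, geo_cluster = as.integer(cl),
                         stringsAsFactors = FALSE)
  out <- list(clusters = clusters)
  if (!is.null(env)) {
    e <- merge(env, clusters, by = "c_label")
    e <- e[!is.na(e$value), , drop = FALSE]
    agg <- stats::aggregate(value ~ geo_cluster + env_par, data = e,
                            FUN = mean)
    names(agg)[names(agg) == "value"] <- "mean_value"
    cnt <- stats::aggregate(value ~ geo_cluster + env_par, data = e,
                            FUN = length)
    agg$n <- cnt$value[match(paste(agg$geo_cluster, agg$env_par),
                             paste(cnt$geo_cluster, cnt$env_par))]
    out$cluster_means <- agg
  }
  out
}

#' Compare an environmental parameter among groups
#'
#' Kruskal-Wallis omnibus rank test followed by pairwise Dunn z tests
#' with Bonferroni-adjusted p values. The Dunn statistic for groups i, j
#' is `(Ri - Rj) / sqrt((N(N+1)/12 - T)(1/ni + 1/nj))` with `Ri` the
#' mean rank, `N` the pooled size and `T = sum(t^3 - t)/(12(N-1))` the
#' tie correction.
#'
#' @param values Numeric vector of parameter values.
#' @param groups Group labels, same length; >= 2 groups with >= 2 values
#'   each.
#' @return A list: `kruskal` (the `htest`), `pairwise` (data.frame
#'   `group_a`, `group_b`, `z`, `p`, `p_adj`), and `degenerate` (TRUE
#'   when all values are tied across all groups, in which case the
#'   omnibus is reported as degenerate with p = NA).
#' @export
compare_env_by_group <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  tabn <- table(groups)
  if (length(tabn) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tabn < 2)) stop("every group needs at least 2 values",
                          call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(kruskal = NULL, pairwise = NULL, degenerate = TRUE))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  Tcorr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gs <- names(rbar)
  pairs <- utils::combn(gs, 2)
  z <- apply(pairs, 2, function(p2) {
    se <- sqrt((N * (N + 1) / 12 - Tcorr) *
                 (1 / ns[[p2[1]]] + 1 / ns[[p2[2]]]))
    (rbar[[p2[1]]] - rbar[[p2[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  list(kruskal = kw,
       pairwise = data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                             z = z, p = p,
                             p_adj = stats::p.adjust(p, "bonferroni"),
                             stringsAsFactors = FALSE),
       degenerate = FALSE)
}

#' Species co-occurrence counts at substrate or gridsect scale
#'
#' For every unordered pair of species, counts the number of units
#' (collection samples, or gridsects) from which both species were
#' isolated, and the number from which either was.
#'
#' @param records A collections data.frame (needs `gridsect` for the
#'   gridsect scale).
#' @param isolations An isolations data.frame with `species_or_genus`.
#' @param scale `"substrate"` (unit = `c_label`) or `"gridsect"`.
#' @param species Species labels considered; default: all distinct
#'   `species_or_genus` values.
#' @return A data.frame per unordered pair: `species_a`, `species_b`,
#'   `n_both`, `n_either`.
#' @export
colocalization_counts <- function(records, isolations,
                                  scale = c("substrate", "gridsect"),
                                  species = NULL) {
  scale <- match.arg(scale)
  iso <- isolations[!is.na(isolations$species_or_genus) &
                      isolations$species_or_genus != "", , drop = FALSE]
  if (scale == "substrate") {
    iso$unit <- iso$c_label
  } else {
    if (!"gridsect" %in% names(records)) {
      stop("records lack a gridsect column", call. = FALSE)
    }
    map <- records$gridsect[match(iso$c_label, records$c_label)]
    iso$unit <- as.character(map)
    iso <- iso[!is.na(iso$unit) & iso$unit != "", , drop = FALSE]
  }
  if (is.null(species)) species <- sort(unique(iso$species_or_genus))
  units_by_sp <- lapply(species, function(s) {
    unique(iso$unit[iso$species_or_genus == s])
  })
  names(units_by_sp) <- species
  if (length(species) < 2) {
    return(data.frame(species_a = character(0), species_b = character(0),
                      n_both = integer(0), n_either = integer(0)))
  }
  pairs <- utils::combn(species, 2)
  data.frame(
    species_a = pairs[1, ], species_b = pairs[2, ],
    n_both = apply(pairs, 2, function(p2) {
      length(intersect(units_by_sp[[p2[1]]], units_by_sp[[p2[2]]]))
    }),
    n_either = apply(pairs, 2, function(p2) {
      length(union(units_by_sp[[p2[1]]], units_by_sp[[p2[2]]]))
    }),
    stringsAsFactors = FALSE
  )
}
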