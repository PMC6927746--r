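# All randomness flows through one seeded generator; the caller's global
# random state is saved and restored, never consumed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Describe one simulated population
#'
#' @param name Population label.
#' @param n_isotypes Number of isotypes.
#' @param diversity Per-site nucleotide diversity target (expected
#'   realized genome-wide pi; must be in (0, 0.5)).
#' @param swept Does the population share a long swept haplotype?
#' @param sweep_chroms Chromosomes carrying the sweep (default
#'   I, IV, V, X).
#' @param sweep_tract_fraction Fraction of each sweep chromosome covered
#'   by the shared tract (centered), in `[0, 1]`.
#' @param sweep_carrier_fraction Fraction of the population's isotypes
#'   carrying the swept haplotype.
#' @return A list of class `sim_population`.
#' @export
sim_population <- function(name, n_isotypes, diversity, swept = FALSE,
                           sweep_chroms = c("I", "IV", "V", "X"),
                           sweep_tract_fraction = 0.7,
                           sweep_carrier_fraction = 0.85) {
  stopifnot(n_isotypes >= 2, diversity > 0,
            sweep_tract_fraction >= 0, sweep_tract_fraction <= 1,
            sweep_carrier_fraction >= 0, sweep_carrier_fraction <= 1)
  if (diversity > 0.5) stop("infeasible diversity target > 0.5",
                            call. = FALSE)
  structure(list(name = name, n_isotypes = n_isotypes,
                 diversity = diversity, swept = swept,
                 sweep_chroms = sweep_chroms,
                 sweep_tract_fraction = if (swept) sweep_tract_fraction else 0,
                 sweep_carrier_fraction = sweep_carrier_fraction),
            class = "sim_population")
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions this package targets: a
#' high-diversity "divergent" island population of 43 isotypes at
#' pi = 0.00109 and a low-diversity "global" population of 233 isotypes
#' at pi = 0.000368 sharing one long swept haplotype on chromosomes I,
#' IV, V and X, on a six-chromosome genome (lengths scaled down; the
#' generator is linear in length, so contig lengths are free
#' parameters).
#'
#' @param seed Mandatory integer seed; no unseeded runs.
#' @param contig_lengths Named chromosome lengths in bp.
#' @param populations List of [sim_population()] specs.
#' @param fixed_diff_rate Per-bp rate of sites fixed for the ALT allele
#'   privately in each population (between-population divergence; each
#'   pair of populations then differs at about twice this rate).
#' @param n_sites_per_chrom Optional integer: overrides the
#'   SFS-derived segregating-site count per population and chromosome
#'   (used for sparse-marker fixtures where site density, not diversity
#'   magnitude, matters).
#' @param clone_groups List of `list(isotype=, n_copies=, error_rate=)`:
#'   near-identical copies of a parent isotype with per-call flip errors
#'   (same-isotype groups for deduplication tests).
#' @param admixed List of `list(name=, source_a=, source_b=,
#'   mean_tract_bp=)`: recombination mosaics of two source isotypes with
#'   exponential tract lengths.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       contig_lengths = c(I = 1e6, II = 1e6, III = 1e6,
                                          IV = 1e6, V = 1e6, X = 1e6),
                       populations = list(
                         sim_population("Hawaiian", 43, 0.00109),
                         sim_population("non-Hawaiian", 233, 0.000368,
                                        swept = TRUE)
                       ),
                       fixed_diff_rate = 5e-4,
                       n_sites_per_chrom = NULL,
                       clone_groups = list(),
                       admixed = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(contig_lengths > 0), fixed_diff_rate >= 0)
  structure(list(seed = as.integer(seed), contig_lengths = contig_lengths,
                 populations = populations,
                 fixed_diff_rate = fixed_diff_rate,
                 n_sites_per_chrom = n_sites_per_chrom,
                 clone_groups = clone_groups, admixed = admixed),
            class = "sim_config")
}

# Expected deflation of the n/(n-1)-corrected heterozygosity at sweep
# tract sites when c of n isotypes are forced to the founder (REF)
# allele, under the neutral 1/k site-frequency spectrum. Derived-count k
# is placed on a uniform random k-subset; after forcing, the derived
# count among the m = n - c non-carriers is hypergeometric, so
# E[k'(n - k')] has the closed form used below.
sweep_het_deflation <- function(n, c) {
  if (c <= 0) return(1)
  m <- n - c
  k <- seq_len(n - 1)
  ek <- k * m / n
  vk <- k * (m / n) * (c / n) * (n - k) / (n - 1)
  e_prod <- n * ek - (vk + ek^2)       # E[k'(n-k')]
  num <- sum((1 / k) * e_prod)
  den <- sum((1 / k) * k * (n - k))
  num / den
}

#' Simulate genotype matrices with planted population structure
#'
#' A site-frequency founder model: each population receives segregating
#' sites at density `diversity * a1(n)` per bp with derived-allele
#' counts drawn from the neutral `1/k` spectrum, so the expected
#' realized per-site diversity equals the configured target. Swept
#' populations share a designated founder haplotype over centered
#' tracts on the sweep chromosomes: carrier isotypes are forced to the
#' founder allele there, and the site density is pre-compensated by the
#' exact expected heterozygosity deflation so the configured diversity
#' remains the realized genome-wide expectation. Populations are
#' separated by privately fixed ALT sites at `fixed_diff_rate` per bp.
#' Clone groups copy a parent column with independent per-call flip
#' errors; admixed isotypes are recombination mosaics of two sources
#' with exponential tract lengths. Output is reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genotypes` (a [genotype_matrix()]) and `truth`
#'   (`populations`: isotype/population/sweep-carrier table;
#'   `sweep_tracts`: planted tract intervals per carrier;
#'   `clone_partition`: isolate -> planted clone group).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    chroms <- names(cfg$contig_lengths)
    pops <- cfg$populations
    iso_names <- list()
    for (p in pops) {
      iso_names[[p$name]] <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "",
                                                     p$name),
                                     seq_len(p$n_isotypes))
    }
    all_iso <- unlist(iso_names, use.names = FALSE)
    n_tot <- length(all_iso)
    col_of <- stats::setNames(seq_len(n_tot), all_iso)

    carriers <- list()
    tract <- list()
    for (p in pops) {
      if (p$swept && p$sweep_tract_fraction > 0) {
        n_car <- round(p$sweep_carrier_fraction * p$n_isotypes)
        carriers[[p$name]] <- sort(sample(iso_names[[p$name]], n_car))
        tract[[p$name]] <- lapply(
          stats::setNames(nm = intersect(p$sweep_chroms, chroms)),
          function(chr) {
            L <- cfg$contig_lengths[[chr]]
            len <- round(p$sweep_tract_fraction * L)
            s <- max(1, round((L - len) / 2) + 1)
            c(start = s, end = min(L, s + len - 1))
          })
      }
    }

    site_chrom <- site_pos <- character(0)
    calls_chunks <- list()
    for (chr in chroms) {
      L <- cfg$contig_lengths[[chr]]
      # per-population site counts
      plans <- list()
      for (p in pops) {
        n <- p$n_isotypes
        a1 <- sum(1 / seq_len(n - 1))
        defl <- 1
        if (p$swept && chr %in% p$sweep_chroms &&
            p$sweep_tract_fraction > 0) {
          r <- sweep_het_deflation(n, length(carriers[[p$name]]))
          defl <- (1 - p$sweep_tract_fraction) +
            p$sweep_tract_fraction * r
        }
        S <- if (!is.null(cfg$n_sites_per_chrom)) cfg$n_sites_per_chrom
             else stats::rpois(1, p$diversity / defl * a1 * L)
        Fx <- stats::rpois(1, cfg$fixed_diff_rate * L)
        plans[[p$name]] <- list(S = S, Fx = Fx)
      }
      tot <- sum(vapply(plans, function(x) x$S + x$Fx, numeric(1)))
      if (tot == 0) next
      pos <- sort(sample.int(L, min(tot, L)))
      tot <- length(pos)
      owner <- sample(rep(seq_along(pops),
                          times = vapply(plans, function(x) x$S + x$Fx,
                                         numeric(1)))[seq_len(tot)])
      calls <- matrix(GT_REF, nrow = tot, ncol = n_tot)
      for (pi_ in seq_along(pops)) {
        p <- pops[[pi_]]
        n <- p$n_isotypes
        mine <- which(owner == pi_)
        if (!length(mine)) next
        n_fx <- min(plans[[p$name]]$Fx, length(mine))
        fx_sites <- if (n_fx > 0) sample(mine, n_fx) else integer(0)
        poly_sites <- setdiff(mine, fx_sites)
        pop_cols <- col_of[iso_names[[p$name]]]
        if (length(fx_sites)) calls[fx_sites, pop_cols] <- GT_ALT
        if (length(poly_sites)) {
          kprob <- 1 / seq_len(n - 1)
          kk <- sample(n - 1, length(poly_sites), replace = TRUE,
                       prob = kprob)
          in_tract <- rep(FALSE, length(poly_sites))
          if (!is.null(tract[[p$name]]) && chr %in% names(tract[[p$name]])) {
            tr <- tract[[p$name]][[chr]]
            in_tract <- pos[poly_sites] >= tr["start"] &
              pos[poly_sites] <= tr["end"]
          }
          car_cols <- if (!is.null(carriers[[p$name]])) {
            col_of[carriers[[p$name]]]
          } else integer(0)
          for (s in seq_along(poly_sites)) {
            chosen <- sample(pop_cols, kk[s])
            if (in_tract[s]) chosen <- setdiff(chosen, car_cols)
            if (length(chosen)) calls[poly_sites[s], chosen] <- GT_ALT
          }
        }
      }
      site_chrom <- c(site_chrom, rep(chr, tot))
      site_pos <- c(site_pos, pos)
      calls_chunks[[chr]] <- calls
    }
    calls <- do.call(rbind, calls_chunks)
    pos <- as.integer(site_pos)

    samples <- all_iso
    # admixture mosaics
    admix_rows <- list()
    for (a in cfg$admixed) {
      src_a <- col_of[[a$source_a]]; src_b <- col_of[[a$source_b]]
      newcol <- integer(nrow(calls))
      for (chr in chroms) {
        idx <- which(site_chrom == chr)
        L <- cfg$contig_lengths[[chr]]
        bp <- cumsum(stats::rexp(ceiling(L / a$mean_tract_bp) + 10,
                                 rate = 1 / a$mean_tract_bp))
        bp <- bp[bp < L]
        seg_of_site <- findInterval(pos[idx], c(0, bp))
        use_a <- (seg_of_site + stats::rbinom(1, 1, 0.5)) %% 2 == 0
        newcol[idx] <- ifelse(use_a, calls[idx, src_a], calls[idx, src_b])
      }
      calls <- cbind(calls, newcol)
      samples <- c(samples, a$name)
      col_of[a$name] <- ncol(calls)
      admix_rows[[length(admix_rows) + 1]] <-
        data.frame(isotype = a$name, population = "admixed",
                   sweep_carrier = FALSE, stringsAsFactors = FALSE)
    }

    # clone copies with per-call flip errors
    clone_rows <- list(data.frame(isolate = samples,
                                  clone_group = samples,
                                  stringsAsFactors = FALSE))
    for (cg in cfg$clone_groups) {
      parent <- cg$isotype
      for (k in seq_len(cg$n_copies)) {
        child <- sprintf("%s_clone%d", parent, k)
        colv <- calls[, col_of[[parent]]]
        flip <- stats::runif(length(colv)) < cg$error_rate
        colv[flip] <- ifelse(colv[flip] == GT_ALT, GT_REF, GT_ALT)
        calls <- cbind(calls, colv)
        samples <- c(samples, child)
        col_of[child] <- ncol(calls)
        clone_rows[[length(clone_rows) + 1]] <-
          data.frame(isolate = child, clone_group = parent,
                     stringsAsFactors = FALSE)
      }
    }

    n_cells <- length(calls)
    dp <- matrix(stats::rpois(n_cells, 45) + 5L, nrow = nrow(calls))
    ad_ratio <- matrix(stats::runif(n_cells, 0.92, 1), nrow = nrow(calls))
    ref <- sample(c("A", "C", "G", "T"), nrow(calls), replace = TRUE)
    alt <- ifelse(ref == "T", "G", "T")
    g <- genotype_matrix(
      chrom = site_chrom, pos = pos,
      ref = ref, alt = alt, calls = calls, samples = samples,
      dp = dp, ad_ratio = ad_ratio,
      mq = stats::runif(nrow(calls), 50, 60),
      qual = stats::runif(nrow(calls), 200, 1000),
      contig_lengths = cfg$contig_lengths
    )

    pop_tab <- do.call(rbind, c(lapply(pops, function(p) {
      data.frame(isotype = iso_names[[p$name]], population = p$name,
                 sweep_carrier = iso_names[[p$name]] %in%
                   (carriers[[p$name]] %||% character(0)),
                 stringsAsFactors = FALSE)
    }), admix_rows))
    tract_tab <- do.call(rbind, lapply(names(tract), function(pn) {
      do.call(rbind, lapply(names(tract[[pn]]), function(chr) {
        tr <- tract[[pn]][[chr]]
        data.frame(isotype = carriers[[pn]], chrom = chr,
                   start = tr[["start"]], end = tr[["end"]],
                   stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(tract_tab)) {
      tract_tab <- data.frame(isotype = character(0), chrom = character(0),
                              start = numeric(0), end = numeric(0))
    }
    list(genotypes = g,
         truth = list(populations = pop_tab,
                      sweep_tracts = tract_tab,
                      clone_partition = do.call(rbind, clone_rows)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated bundle to disk
#'
#' Produces a plain-text VCF v4.2 (contig headers carry chromosome
#' lengths), truth TSVs sufficient to score isotype and sweep recovery,
#' and a BED of planted sweep tracts. Reading the VCF back with
#' [read_vcf_genotypes()] reproduces the call matrix exactly.
#'
#' @param sim A [simulate_genotypes()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_fixture_bundle <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    populations = file.path(out_dir, "populations.tsv"),
    clones = file.path(out_dir, "clone_partition.tsv"),
    sweep_bed = file.path(out_dir, "sweep_tracts.bed")
  )
  write_genotypes_vcf(sim$genotypes, paths[["vcf"]])
  utils::write.table(sim$truth$populations, paths[["populations"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$clone_partition, paths[["clones"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(sim$truth$sweep_tracts, paths[["sweep_bed"]],
            name_col = "isotype")
  paths
}
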