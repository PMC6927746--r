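#' Field-collection simulation configuration
#'
#' Defaults emulate the study's field campaign: 2263 collection samples
#' across five Hawaiian islands with the published substrate composition
#' (1493 leaf litter, 327 fruit, 202 flower collections), 2531 isolated
#' nematodes of which 427 are PCR-positive, the five Caenorhabditis
#' species at their observed sample frequencies (C. briggsae on 95
#' samples = 4.2%, C. elegans 38, C. tropicalis 13, C. oiwi 12,
#' C. kamaaina 2, including the published flower/leaf-litter enrichment
#' counts and the observed cohabitation events), 431 tracks-only
#' samples, and per-species environmental distributions (C. elegans
#' sites above 500 m with mean elevation 867 m and mean substrate
#' temperature 19.4 C; C. tropicalis 26.0 C; C. briggsae 23.7 C;
#' C. oiwi on drier substrates).
#'
#' @param seed Mandatory integer seed.
#' @param n_samples Total collection samples.
#' @param island_counts,substrate_counts Named sample counts per island
#'   and substrate class (must each sum to `n_samples`).
#' @param species_substrate Matrix-like list: for each species, named
#'   counts of positive samples per substrate class.
#' @param cohabitations List of species pairs placed on one shared
#'   sample each.
#' @param n_isolates,n_pcr_positive Total isolation records and total
#'   PCR-positive isolates among them.
#' @param n_tracks Samples with tracks only.
#' @param n_worm_positive Samples from which nematodes were isolated.
#' @param env_model Per-species environmental means/SDs; see default.
#' @param n_gridsects Number of gridsect sampling designs.
#' @return A list of class `sim_collections_config`.
#' @export
sim_collections_config <- function(
    seed,
    n_samples = 2263,
    island_counts = c("Kauai" = 440, "Oahu" = 500, "Molokai" = 160,
                      "Maui" = 463, "Big Island" = 700),
    substrate_counts = c("leaf litter" = 1493, "fruit" = 327,
                         "flower" = 202, "fungus" = 110,
                         "invertebrate" = 60, "vegetation" = 71),
    species_substrate = list(
      "C. briggsae" = c("flower" = 21, "leaf litter" = 51, "fruit" = 15,
                        "fungus" = 4, "vegetation" = 4),
      "C. elegans" = c("leaf litter" = 25, "fruit" = 5, "flower" = 3,
                       "fungus" = 2, "vegetation" = 3),
      "C. tropicalis" = c("flower" = 4, "leaf litter" = 3, "fruit" = 4),
      "C. oiwi" = c("flower" = 8, "fruit" = 3),
      "C. kamaaina" = c("leaf litter" = 2)
    ),
    cohabitations = list(
      list(species = "C. tropicalis", host = "C. briggsae",
           substrate = "flower"),
      list(species = "C. tropicalis", host = "C. briggsae",
           substrate = "fruit"),
      list(species = "C. oiwi", host = "C. briggsae",
           substrate = "flower")
    ),
    n_isolates = 2531,
    n_pcr_positive = 427,
    n_tracks = 431,
    n_worm_positive = 1120,
    env_model = list(
      elevation = list(
        "C. elegans" = c(mean = 867, sd = 100, min = 500),
        "C. briggsae" = c(mean = 250, sd = 150, min = 0),
        "C. tropicalis" = c(mean = 200, sd = 100, min = 0),
        "C. oiwi" = c(mean = 320, sd = 150, min = 0),
        background = c(mean = 400, sd = 250, min = 0)
      ),
      substrate_temperature = list(
        "C. elegans" = c(mean = 19.4, sd = 1.5),
        "C. briggsae" = c(mean = 23.7, sd = 1.5),
        "C. tropicalis" = c(mean = 26.0, sd = 1.5),
        "C. oiwi" = c(mean = 23.0, sd = 1.5),
        background = c(mean = 23.0, sd = 3.0)
      ),
      ambient_temperature = list(
        "C. elegans" = c(mean = 20.0, sd = 1.5),
        background = c(mean = 24.0, sd = 2.0)
      ),
      ambient_humidity = list(background = c(mean = 85, sd = 8)),
      substrate_moisture = list(
        "C. oiwi" = c(mean = 30, sd = 12),
        "C. elegans" = c(mean = 55, sd = 12),
        background = c(mean = 50, sd = 15)
      )
    ),
    n_gridsects = 20) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(sum(island_counts) == n_samples,
            sum(substrate_counts) == n_samples,
            n_pcr_positive <= n_isolates,
            n_worm_positive + n_tracks <= n_samples)
  structure(as.list(environment()), class = "sim_collections_config")
}

ISLAND_CENTERS <- list(
  "Kauai" = c(lon = -159.50, lat = 22.06),
  "Oahu" = c(lon = -157.98, lat = 21.47),
  "Molokai" = c(lon = -157.02, lat = 21.13),
  "Maui" = c(lon = -156.30, lat = 20.80),
  "Big Island" = c(lon = -155.50, lat = 19.60)
)

# jitter a lon/lat center by normally distributed meters
jitter_m <- function(center, n, sd_m) {
  lat <- center[["lat"]] + stats::rnorm(n, 0, sd_m) / 111320
  lon <- center[["lon"]] + stats::rnorm(n, 0, sd_m) /
    (111320 * cos(center[["lat"]] * pi / 180))
  cbind(lon = lon, lat = lat)
}

#' Simulate field-collection, isolation and environmental tables
#'
#' Generates tables in the source-data dialect (`c_label`,
#' `collection_type`, `island`, `PCR_positive`, `worms_on_sample`,
#' `Longitude`, `Latitude`, `multiple_type`, plus `substrate` and
#' `gridsect`; a long environmental table with `env_par`/`value`; an
#' isolation table keyed by `s_label`). Species-positive samples receive
#' environmental values from their species' distribution; C. elegans
#' sites are placed at a handful of tight geographic knots (one of 18
#' collections within a 20 m chain, four smaller ones) plus scattered
#' singletons, mirroring local oversampling.
#'
#' @param cfg A [sim_collections_config()].
#' @return A list: `collections`, `isolations`, `environment` (the
#'   three tables) and `truth` (per-sample planted species and category,
#'   expected headline tallies).
#' @export
simulate_collections <- function(cfg) {
  stopifnot(inherits(cfg, "sim_collections_config"))
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_samples
    c_label <- sprintf("C-%04d", seq_len(n))
    island <- sample(rep(names(cfg$island_counts), cfg$island_counts))
    substrate <- rep(names(cfg$substrate_counts), cfg$substrate_counts)
    # substrates assigned independently of island
    substrate <- sample(substrate)

    # plant species-positive samples on their substrate counts
    species_of <- vector("list", n)
    used <- logical(n)
    # C. elegans only on the Big Island (high-elevation island interior)
    for (sp in names(cfg$species_substrate)) {
      for (sub in names(cfg$species_substrate[[sp]])) {
        k <- cfg$species_substrate[[sp]][[sub]]
        pool <- which(!used & substrate == sub &
                        (sp != "C. elegans" | island == "Big Island"))
        pick <- pool[seq_len(k)]
        for (i in pick) species_of[[i]] <- c(species_of[[i]], sp)
        used[pick] <- TRUE
      }
    }
    # cohabitation events: second species added onto a host-species
    # sample of the stated substrate (sample counted for both species)
    for (co in cfg$cohabitations) {
      host <- which(vapply(species_of, function(s) {
        identical(s, co$host)
      }, logical(1)) & substrate == co$substrate)[1]
      species_of[[host]] <- c(species_of[[host]], co$species)
    }
    n_species_samples <- sum(!vapply(species_of, is.null, logical(1)))

    # remaining worm-positive and tracks-only samples
    free <- which(vapply(species_of, is.null, logical(1)))
    free <- sample(free)
    n_plain_positive <- cfg$n_worm_positive - n_species_samples
    plain_positive <- free[seq_len(n_plain_positive)]
    tracks <- free[n_plain_positive + seq_len(cfg$n_tracks)]
    worms <- rep("No", n)
    worms[tracks] <- "Tracks"
    worms[plain_positive] <- "Yes"
    worms[!vapply(species_of, is.null, logical(1))] <- "Yes"

    # gridsects: ~16% of samples in n_gridsects local designs
    gridsect <- rep("", n)
    n_grid_samples <- round(0.16 * n / cfg$n_gridsects)
    grid_pool <- sample(seq_len(n))
    gi <- 0
    for (gnum in seq_len(cfg$n_gridsects)) {
      members <- grid_pool[gi + seq_len(n_grid_samples)]
      gridsect[members] <- sprintf("gridsect-%d", gnum)
      gi <- gi + n_grid_samples
    }

    # coordinates: broad island scatter; C. elegans samples at knots
    lon <- lat <- numeric(n)
    for (isl in names(ISLAND_CENTERS)) {
      idx <- which(island == isl)
      xy <- jitter_m(ISLAND_CENTERS[[isl]], length(idx), 8000)
      lon[idx] <- xy[, "lon"]; lat[idx] <- xy[, "lat"]
    }
    ce <- which(vapply(species_of, function(s) "C. elegans" %in% s,
                       logical(1)))
    knot_sizes <- c(18, 4, 3, 2, 2)
    ki <- 0
    for (ks in knot_sizes) {
      ks <- min(ks, length(ce) - ki)
      if (ks <= 0) break
      members <- ce[ki + seq_len(ks)]
      center <- c(lon = ISLAND_CENTERS[["Big Island"]][["lon"]] +
                    stats::runif(1, -0.2, 0.2),
                  lat = ISLAND_CENTERS[["Big Island"]][["lat"]] +
                    stats::runif(1, -0.2, 0.2))
      xy <- jitter_m(center, ks, 5)   # within a 20 m chain
      lon[members] <- xy[, "lon"]; lat[members] <- xy[, "lat"]
      ki <- ki + ks
    }
    # remaining C. elegans samples: isolated, km apart
    if (ki < length(ce)) {
      rest <- ce[(ki + 1):length(ce)]
      xy <- jitter_m(ISLAND_CENTERS[["Big Island"]], length(rest), 15000)
      lon[rest] <- xy[, "lon"]; lat[rest] <- xy[, "lat"]
    }

    # isolation records
    s_rows <- list()
    s_id <- 0
    pcr_left <- cfg$n_pcr_positive
    iso_left <- cfg$n_isolates
    positive_samples <- which(worms == "Yes")
    # species isolates first (all PCR-positive, identified to species)
    for (i in seq_len(n)) {
      for (sp in species_of[[i]]) {
        n_iso <- sample(1:2, 1)
        for (k in seq_len(n_iso)) {
          s_id <- s_id + 1
          s_rows[[s_id]] <- data.frame(
            s_label = sprintf("S-%04d", s_id), c_label = c_label[i],
            genotype_outcome = "PCR-positive", species_or_genus = sp,
            stringsAsFactors = FALSE)
          pcr_left <- pcr_left - 1
          iso_left <- iso_left - 1
        }
      }
    }
    # other PCR-positive taxa spread over positive samples
    other_taxa <- c("Oscheius sp.", "Rhabditis sp.", "Panagrolaimus sp.",
                    "Mesorhabditis sp.", "Pristionchus sp.",
                    "Teratorhabditis sp.", "Choriorhabditis sp.",
                    "Cruznema sp.")
    hosts <- sample(positive_samples, pcr_left, replace = TRUE)
    for (i in hosts) {
      s_id <- s_id + 1
      s_rows[[s_id]] <- data.frame(
        s_label = sprintf("S-%04d", s_id), c_label = c_label[i],
        genotype_outcome = "PCR-positive",
        species_or_genus = sample(other_taxa, 1),
        stringsAsFactors = FALSE)
      iso_left <- iso_left - 1
    }
    # remaining isolates PCR-negative or not genotyped; every
    # worm-positive sample receives at least one isolation record
    no_iso_yet <- setdiff(c_label[positive_samples],
                          unique(vapply(s_rows, function(r) r$c_label, "")))
    hosts <- c(match(no_iso_yet, c_label),
               sample(positive_samples, iso_left - length(no_iso_yet),
                      replace = TRUE))
    outcome <- sample(c("PCR-negative", "Not genotyped"), iso_left,
                      replace = TRUE, prob = c(0.8, 0.2))
    for (k in seq_along(hosts)) {
      s_id <- s_id + 1
      s_rows[[s_id]] <- data.frame(
        s_label = sprintf("S-%04d", s_id), c_label = c_label[hosts[k]],
        genotype_outcome = outcome[k], species_or_genus = "",
        stringsAsFactors = FALSE)
    }
    isolations <- do.call(rbind, s_rows)

    # per-sample categories (long: one row per observed category)
    pcr_by_sample <- tapply(isolations$genotype_outcome == "PCR-positive",
                            isolations$c_label, sum)
    iso_by_c <- split(isolations, isolations$c_label)
    cat_rows <- list()
    for (i in seq_len(n)) {
      cats <- species_of[[i]]
      iso_here <- iso_by_c[[c_label[i]]]
      if (is.null(iso_here)) iso_here <- isolations[0, , drop = FALSE]
      if (is.null(cats)) {
        cats <- if (worms[i] == "Tracks") "Tracks"
        else if (worms[i] == "No") "No nematode"
        else if (any(iso_here$genotype_outcome == "PCR-positive")) {
          "Other PCR-positive"
        } else if (any(iso_here$genotype_outcome == "PCR-negative")) {
          "PCR-negative"
        } else "Not genotyped"
      } else if (any(iso_here$genotype_outcome == "PCR-positive" &
                       !iso_here$species_or_genus %in% cats)) {
        cats <- c(cats, "Other PCR-positive")
      }
      cat_rows[[i]] <- data.frame(
        c_label = c_label[i], collection_type = cats, island = island[i],
        PCR_positive = as.integer(pcr_by_sample[c_label[i]] %||% 0),
        worms_on_sample = worms[i], Longitude = lon[i], Latitude = lat[i],
        multiple_type = if (length(cats) > 1) "yes" else "no",
        substrate = substrate[i], gridsect = gridsect[i],
        stringsAsFactors = FALSE)
    }
    collections <- do.call(rbind, cat_rows)
    collections$PCR_positive[is.na(collections$PCR_positive)] <- 0L

    # environmental values per sample, drawn from the distribution of
    # the highest-precedence species present (background otherwise)
    env_rows <- list()
    sp_for_env <- vapply(seq_len(n), function(i) {
      s <- species_of[[i]]
      if (is.null(s)) "background" else {
        s[order(match(s, CATEGORY_PRECEDENCE))][1]
      }
    }, "")
    for (par in names(cfg$env_model)) {
      mod <- cfg$env_model[[par]]
      pick <- function(sp) if (sp %in% names(mod)) mod[[sp]] else
        mod[["background"]]
      pars <- lapply(sp_for_env, pick)
      mu <- vapply(pars, `[[`, 0, "mean")
      sd <- vapply(pars, `[[`, 0, "sd")
      lo <- vapply(pars, function(x) {
        if ("min" %in% names(x)) x[["min"]] else -Inf
      }, 0)
      val <- stats::rnorm(n, mu, sd)
      redo <- which(val < lo)
      while (length(redo)) {
        val[redo] <- stats::rnorm(length(redo), mu[redo], sd[redo])
        redo <- redo[val[redo] < lo[redo]]
      }
      env_rows[[par]] <- data.frame(
        c_label = c_label, s_label = "", species_family = sp_for_env,
        env_par = par, value = val, stringsAsFactors = FALSE)
    }
    environment_tab <- do.call(rbind, env_rows)
    rownames(environment_tab) <- NULL

    truth <- list(
      species_of = stats::setNames(species_of, c_label),
      n_samples = n,
      n_isolates = nrow(isolations),
      n_pcr_positive = sum(isolations$genotype_outcome == "PCR-positive"),
      species_sample_counts = vapply(
        names(cfg$species_substrate),
        function(sp) sum(vapply(species_of, function(s) sp %in% s,
                                logical(1))),
        integer(1))
    )
    list(collections = collections, isolations = isolations,
         environment = environment_tab, truth = truth)
  })
}

#' Write simulated field tables as CSV
#'
#' @param sim A [simulate_collections()] result.
#' @param out_dir Output directory.
#' @return Named vector of written paths.
#' @export
write_collection_bundle <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(collections = file.path(out_dir, "collections.csv"),
             isolations = file.path(out_dir, "isolations.csv"),
             environment = file.path(out_dir, "environment.csv"))
  utils::write.csv(sim$collections, paths[["collections"]],
                   row.names = FALSE)
  utils::write.csv(sim$isolations, paths[["isolations"]],
                   row.names = FALSE)
  utils::write.csv(sim$environment, paths[["environment"]],
                   row.names = FALSE)
  paths
}
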