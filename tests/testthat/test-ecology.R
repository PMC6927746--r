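toy_records <- function() {
  data.frame(
    c_label = c("C-1", "C-2", "C-2", "C-3", "C-4", "C-5"),
    collection_type = c("C. briggsae", "C. elegans", "Tracks",
                        "No nematode", "Tracks", "PCR-negative"),
    island = c("Kauai", "Big Island", "Big Island", "Kauai", "Oahu",
               "Kauai"),
    PCR_positive = c(1L, 2L, 2L, 0L, 0L, 0L),
    worms_on_sample = c("Yes", "Yes", "Yes", "No", "Tracks", "Yes"),
    Longitude = c(-159.5, -155.5, -155.5, -159.4, -158, -159.3),
    Latitude = c(22, 19.6, 19.6, 22.1, 21.5, 22.05),
    multiple_type = c("no", "yes", "yes", "no", "no", "no"),
    substrate = c("flower", "leaf litter", "leaf litter", "fruit",
                  "fungus", "flower"),
    stringsAsFactors = FALSE
  )
}

test_that("collection records validate identifiers and vocabularies", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy_records(), path, row.names = FALSE)
  d <- read_collections(path)
  expect_equal(nrow(d), 6)

  bad <- toy_records()
  bad$island[1] <- "Atlantis"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_collections(path), "Atlantis")

  bad2 <- toy_records()
  bad2$Latitude[1] <- 95
  utils::write.csv(bad2, path, row.names = FALSE)
  expect_error(read_collections(path), "out of range")
})

test_that("multi-category samples collapse by legend precedence", {
  one <- assign_categories(toy_records())
  expect_equal(nrow(one), 5)
  # C-2 observed as C. elegans and Tracks -> counted as C. elegans
  expect_equal(one$category[one$c_label == "C-2"], "C. elegans")
})

test_that("tallies count once per sample and percentages sum to 100", {
  tal <- tally_categories(toy_records())
  expect_equal(tal$n_samples, 5)
  by_isl <- tal$by_island
  for (isl in unique(by_isl$island)) {
    expect_equal(sum(by_isl$percent[by_isl$island == isl]), 100)
  }
  # 3 Kauai samples: 1 C. briggsae, 1 No nematode, 1 PCR-negative
  kb <- by_isl[by_isl$island == "Kauai" & by_isl$category == "C. briggsae", ]
  expect_equal(kb$count, 1)
  expect_equal(kb$percent, 100 / 3)
  for (sub in unique(tal$by_substrate$substrate)) {
    expect_equal(sum(tal$by_substrate$percent[
      tal$by_substrate$substrate == sub]), 100)
  }
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  r <- enrichment_test_counts(3, 10, 1, 10)
  expect_equal(r$p_value, 0.582, tolerance = 1e-3)
  expect_equal(r$p_value, oracle_fisher(3, 10, 1, 10), tolerance = 1e-9)
  expect_equal(enrichment_test_counts(5, 10, 5, 10)$p_value, 1)
  expect_equal(enrichment_test_counts(10, 10, 0, 10)$p_value,
               2 / choose(20, 10), tolerance = 1e-9)
  # oracle equivalence on all tables with N <= 40
  set.seed(17)
  for (rep in 1:60) {
    n_a <- sample(2:20, 1); n_b <- sample(2:20, 1)
    k_a <- sample(0:n_a, 1); k_b <- sample(0:n_b, 1)
    expect_equal(enrichment_test_counts(k_a, n_a, k_b, n_b)$p_value,
                 oracle_fisher(k_a, n_a, k_b, n_b), tolerance = 1e-7)
  }
})

test_that("record-level enrichment builds the right 2x2 table", {
  rec <- toy_records()
  r <- enrichment_test(rec, "C. briggsae", "flower", "leaf litter")
  expect_equal(unname(r$table["stratum_a", ]), c(1, 1))   # 1 of 2 flowers
  expect_equal(unname(r$table["stratum_b", ]), c(0, 1))
  expect_error(enrichment_test(rec, "C. briggsae", "flower", "vegetation"),
               "empty stratum")
})

test_that("geographic clustering respects the 20 m linkage radius", {
  base <- c(lon = -155.5, lat = 19.6)
  m_lon <- 1 / (111320 * cos(base["lat"] * pi / 180))
  mk <- function(offsets_m) {
    data.frame(c_label = paste0("C-", seq_along(offsets_m)),
               Longitude = base[["lon"]] + offsets_m * m_lon,
               Latitude = base[["lat"]],
               stringsAsFactors = FALSE)
  }
  # 10 m apart -> one cluster; 25 m apart -> two
  expect_equal(length(unique(
    geo_cluster_collections(mk(c(0, 10)))$clusters$geo_cluster)), 1)
  expect_equal(length(unique(
    geo_cluster_collections(mk(c(0, 25)))$clusters$geo_cluster)), 2)
  # chaining: 0-15-30 m single-links into one cluster
  expect_equal(length(unique(
    geo_cluster_collections(mk(c(0, 15, 30)))$clusters$geo_cluster)), 1)
  # radius monotonicity: clusters only merge as the radius grows
  pts <- mk(c(0, 12, 40, 90))
  n10 <- length(unique(geo_cluster_collections(pts,
                                               radius_m = 10)$clusters$geo_cluster))
  n20 <- length(unique(geo_cluster_collections(pts,
                                               radius_m = 20)$clusters$geo_cluster))
  n60 <- length(unique(geo_cluster_collections(pts,
                                               radius_m = 60)$clusters$geo_cluster))
  expect_true(n10 >= n20 && n20 >= n60)
  # order invariance
  shuf <- pts[c(3, 1, 4, 2), ]
  cl1 <- geo_cluster_collections(pts)$clusters
  cl2 <- geo_cluster_collections(shuf)$clusters
  grp <- function(cl) {
    split(cl$c_label, cl$geo_cluster)
  }
  expect_setequal(unname(vapply(grp(cl1), paste, "", collapse = ",")),
                  unname(vapply(grp(cl2), function(x) {
                    paste(sort(x), collapse = ",")
                  }, "")))
})

test_that("cluster environmental means average non-missing values", {
  rec <- data.frame(c_label = c("C-1", "C-2"),
                    Longitude = c(-155.5, -155.5),
                    Latitude = c(19.6, 19.6 + 10 / 111320))
  env <- data.frame(c_label = c("C-1", "C-2", "C-1"),
                    env_par = c("substrate_temperature",
                                "substrate_temperature", "elevation"),
                    value = c(18, 20, 850))
  out <- geo_cluster_collections(rec, env)
  expect_equal(length(unique(out$clusters$geo_cluster)), 1)
  st <- out$cluster_means[out$cluster_means$env_par ==
                            "substrate_temperature", ]
  expect_equal(st$mean_value, 19)
  expect_equal(st$n, 2)
})

test_that("Kruskal-Wallis/Dunn comparisons separate and adjust correctly", {
  vals <- c(1, 2, 3, 101, 102, 103, 201, 202, 203)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- compare_env_by_group(vals, grp)
  expect_lt(res$kruskal$p.value, 0.05)
  # ordered groups: z for (a,b), (a,c), (b,c) all negative and |a,c| largest
  pw <- res$pairwise
  expect_true(all(pw$z < 0))
  expect_equal(pw$group_b[which.max(abs(pw$z))], "c")
  expect_equal(pw$group_a[which.max(abs(pw$z))], "a")
  # rank-arithmetic oracle for the (a,c) z statistic: no ties, T = 0
  N <- 9
  se <- sqrt((N * (N + 1) / 12) * (1 / 3 + 1 / 3))
  z_ac <- (mean(rank(vals)[1:3]) - mean(rank(vals)[7:9])) / se
  expect_equal(pw$z[pw$group_a == "a" & pw$group_b == "c"], z_ac,
               tolerance = 1e-12)
  expect_equal(pw$p_adj, pmin(1, pw$p * 3))

  # identical groups -> adjusted pairwise p = 1
  same <- compare_env_by_group(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$pairwise$p_adj, 1)
  # all values tied -> degenerate
  expect_true(compare_env_by_group(rep(5, 6),
                                   rep(c("a", "b"), each = 3))$degenerate)
  expect_error(compare_env_by_group(1:3, c("a", "a", "b")), "at least 2")
})

test_that("null-distributed groups rarely reject", {
  set.seed(41)
  rejections <- 0
  for (rep in 1:50) {
    vals <- stats::rnorm(30)
    grp <- rep(c("a", "b"), each = 15)
    if (compare_env_by_group(vals, grp)$kruskal$p.value < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_lte(rejections, 5)   # > 90% of replicates above 0.05
})

test_that("co-occurrence counts are symmetric and match planted truth", {
  rec <- data.frame(c_label = paste0("C-", 1:4),
                    gridsect = c("g1", "g1", "", ""),
                    stringsAsFactors = FALSE)
  iso <- data.frame(
    s_label = paste0("S-", 1:6),
    c_label = c("C-1", "C-1", "C-2", "C-3", "C-4", "C-4"),
    species_or_genus = c("A", "B", "A", "B", "A", "B"),
    stringsAsFactors = FALSE
  )
  sub <- colocalization_counts(rec, iso, scale = "substrate")
  expect_equal(sub$n_both, 2)     # C-1 and C-4
  expect_equal(sub$n_either, 4)
  grid <- colocalization_counts(rec, iso, scale = "gridsect")
  expect_equal(grid$n_both, 1)    # g1 via C-1 + C-2
  expect_equal(grid$n_either, 1)
  # symmetry under species relabeling
  iso2 <- iso
  iso2$species_or_genus <- c("B", "A", "B", "A", "B", "A")
  sub2 <- colocalization_counts(rec, iso2, scale = "substrate")
  expect_equal(sub2$n_both, sub$n_both)
  # disjoint species -> zero
  iso3 <- iso[c(1, 3, 4), ]
  iso3$species_or_genus <- c("A", "A", "B")
  expect_equal(colocalization_counts(rec, iso3, "substrate")$n_both, 0)
})
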