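# helper: a sweep-study simulation (20 isotypes, 12 carriers of a
# centered 10 Mb tract on four 15 Mb chromosomes)
sweep_sim <- function(seed, n_iso = 20, carrier_frac = 0.6) {
  cfg <- sim_config(
    seed = seed,
    contig_lengths = c(I = 15e6, IV = 15e6, V = 15e6, X = 15e6),
    populations = list(
      sim_population("P", n_iso, 0.001, swept = TRUE,
                     sweep_chroms = c("I", "IV", "V", "X"),
                     sweep_tract_fraction = 10 / 15,
                     sweep_carrier_fraction = carrier_frac)
    ),
    fixed_diff_rate = 0,
    n_sites_per_chrom = 1500
  )
  simulate_genotypes(cfg)
}

test_that("clones produce one IBD segment spanning the chromosome", {
  calls <- matrix(sample(c(0L, 1L), 200, TRUE), 100, 2)
  calls[, 2] <- calls[, 1]
  pos <- sort(sample.int(2e6, 100))
  g <- make_gm(calls, pos = pos, contig_lengths = c(I = 2e6))
  segs <- detect_ibd_segments(g, min_length = 1e6, max_mismatch = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, pos[1])
  expect_equal(segs$end, pos[100])
})

test_that("a planted 1.5 Mb shared tract is recovered at >= 90% overlap", {
  set.seed(21)
  n_sites <- 600
  pos <- sort(sample.int(3e6, n_sites))
  a <- sample(c(0L, 1L), n_sites, TRUE)
  b <- sample(c(0L, 1L), n_sites, TRUE)
  tract <- pos >= 1e6 & pos <= 2.5e6
  b[tract] <- a[tract]
  g <- make_gm(cbind(A = a, B = b), pos = pos, contig_lengths = c(I = 3e6))
  segs <- detect_ibd_segments(g, min_length = 1e6, max_mismatch = 1)
  expect_gte(nrow(segs), 1)
  ov <- pmin(segs$end, 2.5e6) - pmax(segs$start, 1e6) + 1
  expect_gte(max(ov) / 1.5e6, 0.9)

  # unrelated random haplotypes -> no megabase-scale segments
  set.seed(22)
  g2 <- make_gm(matrix(sample(c(0L, 1L), 1200, TRUE), 600, 2),
                pos = pos, contig_lengths = c(I = 3e6))
  expect_equal(nrow(detect_ibd_segments(g2, min_length = 1e6,
                                        max_mismatch = 1)), 0)
})

test_that("haplotype blocks follow the interval-component rules", {
  segs <- data.frame(isotype_a = c("A", "A", "B"),
                     isotype_b = c("B", "C", "C"),
                     chrom = "I",
                     start = c(1, 1, 1), end = c(1e6, 1e6, 1e6))
  b <- infer_haplotype_blocks(segs, c("A", "B", "C"))
  expect_equal(nrow(b), 3)            # one group covering all three
  expect_equal(unique(b$group_id), "I_g1")
  expect_equal(unique(b$start), 1)
  expect_equal(unique(b$end), 1e6)

  segs2 <- data.frame(isotype_a = c("A", "B"), isotype_b = c("B", "C"),
                      chrom = "I", start = c(1, 4e5), end = c(5e5, 9e5))
  b2 <- infer_haplotype_blocks(segs2, c("A", "B", "C"))
  in_iv <- function(s, e) b2[b2$start == s & b2$end == e, ]
  expect_setequal(in_iv(1, 4e5 - 1)$isotype, c("A", "B"))
  expect_setequal(in_iv(4e5, 5e5)$isotype, c("A", "B", "C"))
  expect_setequal(in_iv(5e5 + 1, 9e5)$isotype, c("B", "C"))

  expect_error(infer_haplotype_blocks(segs2, c("A", "B")), "unknown")
})

test_that("block sets tile without overlap within isotype-chromosome", {
  sim <- sweep_sim(seed = 41)
  segs <- detect_ibd_segments(sim$genotypes, min_length = 1e6)
  blocks <- infer_haplotype_blocks(segs, sim$genotypes$samples)
  for (iso in unique(blocks$isotype)) {
    for (chr in unique(blocks$chrom)) {
      b <- blocks[blocks$isotype == iso & blocks$chrom == chr, ]
      if (nrow(b) < 2) next
      b <- b[order(b$start), ]
      expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    }
  }
})

test_that("group labels are deterministic under segment row shuffling", {
  sim <- sweep_sim(seed = 42)
  segs <- detect_ibd_segments(sim$genotypes, min_length = 1e6)
  b1 <- infer_haplotype_blocks(segs, sim$genotypes$samples)
  set.seed(1)
  segs_shuffled <- segs[sample(nrow(segs)), ]
  b2 <- infer_haplotype_blocks(segs_shuffled, sim$genotypes$samples)
  rownames(b2) <- NULL
  expect_equal(b1, b2)
})

test_that("the most common haplotype wins by total bp, then members", {
  blocks <- rbind(
    data.frame(isotype = paste0("i", 1:10), chrom = "I", start = 1,
               end = 5e6, group_id = "I_g1", n_members = 10),
    data.frame(isotype = paste0("j", 1:3), chrom = "I", start = 1,
               end = 6e6, group_id = "I_g2", n_members = 3)
  )
  class(blocks) <- c("haplotype_blocks", "data.frame")
  swept <- identify_swept_haplotype(blocks, sweep_chroms = "I")
  expect_equal(unname(swept["I"]), "I_g1")  # 50 Mb > 18 Mb
  only <- identify_swept_haplotype(blocks[blocks$group_id == "I_g2", ],
                                   sweep_chroms = "I")
  expect_equal(unname(only["I"]), "I_g2")
  expect_message(
    none <- identify_swept_haplotype(blocks, sweep_chroms = "X"),
    "no groups")
  expect_true(is.na(none["X"]))
})

test_that("swept-chromosome calls apply the printed strict thresholds", {
  mk_blocks <- function(bp_by_iso) {
    b <- do.call(rbind, lapply(names(bp_by_iso), function(iso) {
      data.frame(isotype = iso, chrom = "I", start = 1,
                 end = bp_by_iso[[iso]], group_id = "I_g1",
                 n_members = length(bp_by_iso))
    }))
    class(b) <- c("haplotype_blocks", "data.frame")
    b
  }
  # retained 0.9 Mb -> not swept (needs > 1 Mb)
  calls <- classify_swept_chromosomes(
    mk_blocks(list(a = 0.9e6, b = 18e6)), c(I = "I_g1"),
    contig_lengths = c(I = 20e6))
  expect_false(calls$is_swept[calls$isotype == "a"])
  # retained 2 Mb with population max 18 Mb -> ratio 0.111 -> swept
  calls2 <- classify_swept_chromosomes(
    mk_blocks(list(a = 2e6, b = 18e6)), c(I = "I_g1"),
    contig_lengths = c(I = 20e6))
  expect_true(calls2$is_swept[calls2$isotype == "a"])
  expect_equal(calls2$ratio[calls2$isotype == "a"], 2 / 18)
  # exactly 0.03 * max is NOT retained (strict inequality)
  calls3 <- classify_swept_chromosomes(
    mk_blocks(list(a = 0.03 * 100e6, b = 100e6)), c(I = "I_g1"),
    contig_lengths = c(I = 120e6))
  expect_false(calls3$is_swept[calls3$isotype == "a"])
  # no swept bp anywhere -> genome fraction 0
  calls4 <- classify_swept_chromosomes(
    mk_blocks(list(b = 18e6)), c(I = "I_g1"),
    contig_lengths = c(I = 20e6), isotypes = c("a", "b"))
  expect_equal(calls4$genome_swept_fraction[calls4$isotype == "a"], 0)
})

test_that("planted sweeps are recovered carrier-for-carrier", {
  for (seed in 1:2) {
    sim <- sweep_sim(seed = seed + 60)
    g <- sim$genotypes
    truth <- sim$truth$populations
    segs <- detect_ibd_segments(g, min_length = 1e6)
    blocks <- infer_haplotype_blocks(segs, g$samples)
    swept <- identify_swept_haplotype(blocks,
                                      sweep_chroms = c("I", "IV", "V", "X"))
    # the largest group's member set matches the planted carriers on
    # >= 95% of the tract length
    tract <- sim$truth$sweep_tracts
    tr_i <- tract[tract$chrom == "I", ][1, ]
    sel <- blocks[blocks$chrom == "I" & blocks$group_id == swept["I"], ]
    carriers <- truth$isotype[truth$sweep_carrier]
    expect_setequal(unique(sel$isotype), carriers)
    cov_bp <- sum(pmin(sel$end[sel$isotype == carriers[1]], tr_i$end) -
                    pmax(sel$start[sel$isotype == carriers[1]],
                         tr_i$start) + 1)
    expect_gte(cov_bp / (tr_i$end - tr_i$start + 1), 0.95)

    calls <- classify_swept_chromosomes(blocks, swept, g$contig_lengths,
                                        isotypes = g$samples)
    called <- tapply(calls$is_swept, calls$isotype, any)
    expect_setequal(names(called)[called], carriers)
    frac <- calls$genome_swept_fraction[match(carriers[1], calls$isotype)]
    expect_gt(frac, 0.5)   # ~40 of 60 Mb planted swept
  }
})

test_that("IBD tables round-trip through the TSV reader", {
  segs <- data.frame(isotype_a = "A", isotype_b = "B", chrom = "I",
                     start = 100, end = 2e6)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(segs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_ibd_segments(path), segs)
  # IBDSeq-style headers are accepted
  segs2 <- data.frame(sample1 = "A", sample2 = "B", chr = "I",
                      start = 100, end = 2e6, lod = 5)
  utils::write.table(segs2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_ibd_segments(path)$isotype_a, "A")
  segs$start <- 3e6
  utils::write.table(segs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_ibd_segments(path), "start < end")
})
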