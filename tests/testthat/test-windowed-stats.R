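test_that("window grids follow the full-window rule", {
  w <- make_windows(c(I = 20000), window_size = 10000, step = 1000)
  expect_equal(nrow(w), 11)
  expect_equal(w$start, seq(1, 10001, by = 1000))
  expect_equal(w$end[1], 10000)
  expect_message(w0 <- make_windows(c(I = 9999), 10000, 1000),
                 "shorter than window_size")
  expect_null(w0)
  expect_equal(nrow(make_windows(c(I = 10000), 10000, 1000)), 1)
})

test_that("interior positions are covered by window_size/step windows", {
  w <- make_windows(c(I = 50000), window_size = 10000, step = 1000)
  for (pos in c(15000, 20000, 30001, 39999)) {
    expect_equal(sum(w$start <= pos & w$end >= pos), 10)
  }
})

test_that("window pi matches hand-computed and oracle values", {
  # 2 haplotypes, 1 difference, 10 kb window -> pi = 1e-4
  g <- make_gm(cbind(c(0L), c(1L)), pos = 500,
               contig_lengths = c(I = 10000))
  ws <- window_stats(g, window_size = 10000, step = 10000)
  expect_equal(ws$pi, 1e-4)
  expect_equal(ws$S, 1)

  # 4 haplotypes, 1 kb window, sites (A,A,T,T) and (A,T,T,T)
  g2 <- make_gm(rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L)),
                pos = c(100, 200), contig_lengths = c(I = 1000))
  ws2 <- window_stats(g2, window_size = 1000, step = 1000)
  expect_equal(ws2$pi, (2 * 0.5 * 0.5 * 4 / 3 + 2 * 0.75 * 0.25 * 4 / 3) /
                 1000, tolerance = 1e-10)
  expect_equal(ws2$pi, oracle_pi(g2$calls, 1000), tolerance = 1e-10)

  # identical haplotypes -> 0
  g3 <- make_gm(matrix(1L, 5, 4), contig_lengths = c(I = 1000))
  expect_equal(window_stats(g3, window_size = 1000, step = 1000)$pi, 0)

  expect_error(window_stats(make_gm(matrix(0L, 2, 1),
                                    contig_lengths = c(I = 1000)),
                            window_size = 1000, step = 1000),
               "at least 2")
})

test_that("window pi equals the pairwise-Hamming oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    S <- sample(5:40, 1)
    calls <- matrix(stats::rbinom(S * n, 1, stats::runif(1, 0.1, 0.9)),
                    S, n)
    storage.mode(calls) <- "integer"
    L <- 5000
    g <- make_gm(calls, pos = sort(sample.int(L, S)),
                 contig_lengths = c(I = L))
    ws <- window_stats(g, window_size = L, step = L)
    expect_equal(ws$pi, oracle_pi(calls, L), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches independent evaluation over the n,S grid", {
  expect_equal(tajima_d(2, 1.1667, 4), 0.5918, tolerance = 1e-3)
  a1 <- tajima_constants(6)$a1
  expect_equal(tajima_d(5, 5 / a1, 6), 0)          # numerator forced to 0
  expect_true(is.na(tajima_d(0, 0, 6)))            # S = 0 undefined
  expect_true(is.na(tajima_d(3, 1.2, 2)))          # n < 3 undefined
  set.seed(7)
  for (n in 3:10) {
    for (S in 1:20) {
      pi_sum <- stats::runif(1, 0, 2 * S)
      expect_equal(tajima_d(S, pi_sum, n), oracle_tajima_d(S, pi_sum, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("Tajima's D sign tracks the frequency spectrum", {
  # star-like: every variant a singleton -> D < 0
  n <- 10
  calls_star <- matrix(0L, 20, n)
  for (s in 1:20) calls_star[s, (s %% n) + 1] <- 1L
  g <- make_gm(calls_star, contig_lengths = c(I = 1000))
  ws <- window_stats(g, window_size = 1000, step = 1000)
  expect_lt(ws$tajima_d, 0)
  # intermediate-frequency variants -> D > 0
  calls_mid <- matrix(rep(c(rep(1L, 5), rep(0L, 5)), each = 1), 20, n,
                      byrow = TRUE)
  g2 <- make_gm(calls_mid, contig_lengths = c(I = 1000))
  expect_gt(window_stats(g2, window_size = 1000, step = 1000)$tajima_d, 0)
})

test_that("Hudson F_ST behaves at fixed differences and known frequencies", {
  # fixed difference -> per-site F = 1
  g <- make_gm(matrix(c(rep(1L, 4), rep(0L, 4)), 1), samples = paste0("s", 1:8),
               contig_lengths = c(I = 1000))
  fst <- window_hudson_fst(g, paste0("s", 1:4), paste0("s", 5:8),
                           window_size = 1000, step = 1000)
  expect_equal(fst$fst, 1)
  # p1 = 0.2 (n=10), p2 = 0.8 (n=10) -> F ~ 0.4771
  calls <- matrix(c(rep(1L, 2), rep(0L, 8), rep(1L, 8), rep(0L, 2)), 1)
  g2 <- make_gm(calls, samples = paste0("s", 1:20),
                contig_lengths = c(I = 1000))
  fst2 <- window_hudson_fst(g2, paste0("s", 1:10), paste0("s", 11:20),
                            window_size = 1000, step = 1000)
  expect_equal(fst2$fst, 0.47712, tolerance = 1e-4)
  # identical monomorphic samples -> undefined
  g3 <- make_gm(matrix(0L, 1, 8), samples = paste0("s", 1:8),
                contig_lengths = c(I = 1000))
  expect_true(is.na(window_hudson_fst(g3, paste0("s", 1:4),
                                      paste0("s", 5:8),
                                      window_size = 1000,
                                      step = 1000)$fst))
})

test_that("F_ST of a population against its own random halves centers at 0", {
  fsts <- numeric(5)
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, contig_lengths = c(I = 2e5),
                      populations = list(sim_population("P", 40, 0.002)),
                      fixed_diff_rate = 0)
    g <- simulate_genotypes(cfg)$genotypes
    set.seed(seed + 100)
    half <- sample(g$samples, 20)
    fst <- window_hudson_fst(g, half, setdiff(g$samples, half))
    fsts[seed] <- sum(fst$numerator) / sum(fst$denominator)
  }
  expect_lt(abs(mean(fsts)), 0.02)
})

test_that("LD pruning removes duplicated columns and passes brute force", {
  set.seed(3)
  base <- matrix(stats::rbinom(30 * 20, 1, 0.4), 30, 20)
  dup <- base
  dup[11, ] <- dup[10, ]     # identical pair within one window
  storage.mode(dup) <- "integer"
  g <- make_gm(dup, contig_lengths = c(I = 3000))
  kept <- ld_prune(g, window_sites = 15, step_sites = 5, r2_max = 0.8)
  expect_true(xor(10 %in% kept, 11 %in% kept))

  # brute-force: no retained pair within any scan window exceeds r2_max
  dose <- g$calls
  for (w_start in seq(1, length(kept), by = 5)) {
    win <- kept[w_start:min(w_start + 14, length(kept))]
    if (length(win) < 2) next
    r2 <- suppressWarnings(stats::cor(t(dose[win, , drop = FALSE]))^2)
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    expect_lte(max(r2), 0.8)
  }
})

test_that("independent sites survive pruning; singletons drop on request", {
  set.seed(11)
  calls <- matrix(stats::rbinom(100 * 60, 1, 0.5), 100, 60)
  storage.mode(calls) <- "integer"
  g <- make_gm(calls, contig_lengths = c(I = 10000))
  kept <- ld_prune(g, window_sites = 50, step_sites = 10, r2_max = 0.8)
  expect_gte(length(kept), 95)

  single <- matrix(0L, 3, 10)
  single[1, 1] <- 1L                 # singleton
  single[2, 1:5] <- 1L
  single[3, c(1, 2, 6, 7)] <- 1L     # uncorrelated with site 2
  g2 <- make_gm(single, contig_lengths = c(I = 300))
  kept2 <- ld_prune(g2, window_sites = 3, step_sites = 1, r2_max = 0.99,
                    drop_singletons = TRUE)
  expect_false(1 %in% kept2)
  expect_true(all(c(2, 3) %in% kept2))
})

test_that("genome summaries average windows and ratios track targets", {
  expect_equal(genome_summary(data.frame(pi = c(0.001, 0.001))), 0.001)
  expect_equal(genome_summary(data.frame(pi = c(0, 0.002))), 0.001)
  expect_error(genome_summary(data.frame(pi = numeric(0))), "no windows")

  # populations parameterized 3:1 in diversity estimate near ratio 3
  ratios <- numeric(3)
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed,
                      contig_lengths = c(I = 3e5, II = 3e5),
                      populations = list(sim_population("A", 20, 0.003),
                                         sim_population("B", 20, 0.001)))
    sim <- simulate_genotypes(cfg)
    pops <- sim$truth$populations
    pa <- genome_pi(sim$genotypes, pops$isotype[pops$population == "A"])
    pb <- genome_pi(sim$genotypes, pops$isotype[pops$population == "B"])
    ratios[seed] <- pa / pb
  }
  expect_true(all(abs(ratios - 3) / 3 < 0.15))
})

test_that("missing calls reduce per-site sample size, not the window", {
  calls <- rbind(c(1L, 0L, 3L, 3L),     # p = 1/2 among 2 haplotypes
                 c(1L, 3L, 3L, 3L))     # < 2 non-missing -> contributes 0
  g <- make_gm(calls, contig_lengths = c(I = 1000))
  ws <- window_stats(g, window_size = 1000, step = 1000,
                     min_completeness = 0)
  expect_equal(ws$pi, 2 * 0.5 * 0.5 * 2 / 1 / 1000)
  expect_equal(ws$S, 1)
})
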