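# Singleton-site selection, controlled mixtures, and the per-site
# evaluation statistics.

test_that("singleton CpG detection matches hand scans", {
  # 10 A + CG + 10 A: one site at 0-based position 10
  s1 <- paste0(strrep("A", 10), "CG", strrep("A", 10))
  sites <- find_singleton_cpg_sites(s1, flank = 10)
  expect_equal(sites$pos, 10L)
  expect_equal(sites$context, s1)

  # tandem CGs: every CG has a neighbour inside the flank
  s2 <- paste0(strrep("A", 15), strrep("CG", 8), strrep("A", 15))
  expect_equal(nrow(find_singleton_cpg_sites(s2, flank = 10)), 0)

  # a CG too close to the contig edge is excluded
  s3 <- paste0("AAACG", strrep("T", 40))
  expect_equal(nrow(find_singleton_cpg_sites(s3, flank = 10)), 0)
  expect_equal(find_singleton_cpg_sites(s3, flank = 3)$pos, 3L)

  expect_equal(nrow(find_singleton_cpg_sites(Biostrings::DNAStringSet())), 0)
})

test_that("coverage filtering drops sites below the minimum", {
  s <- paste0(strrep("A", 12), "CG", strrep("T", 30), "CG", strrep("A", 12))
  cov <- data.table(chrom = "contig1", pos = c(12L, 44L), coverage = c(60L, 10L))
  sites <- find_singleton_cpg_sites(s, flank = 10, min_coverage = 50,
                                    coverage = cov)
  expect_equal(sites$pos, 12L)
})

test_that("forward CG counting matches an independent string scan", {
  for (seed in 1:5) {
    g <- simulate_genome(n_contigs = 2, length = 2000, cpg_spacing = 40,
                         seed = seed)
    scan <- sum(vapply(as.character(g$genome), function(s)
      length(gregexpr("CG", s, fixed = TRUE)[[1]]), numeric(1)))
    expect_equal(count_forward_cg(g$genome), scan)
  }
})

make_pools <- function(sites, n_per_pool = 60) {
  rbindlist(lapply(seq_len(nrow(sites)), function(i)
    data.table(chrom = sites$chrom[i], pos = sites$pos[i],
               read_id = sprintf("s%d_read%03d", i, seq_len(n_per_pool)))))
}

test_that("mixtures use round-half-up methylated counts", {
  sites <- data.table(chrom = "chr1", pos = c(10L, 50L))
  pools_p <- make_pools(sites); pools_n <- make_pools(sites)
  pools_n[, read_id := paste0("u", read_id)]

  mix <- build_mixture(pools_p, pools_n, sites, levels = 0.3,
                       reads_per_site = 20, seed = 1)
  expect_equal(mix[pos == 10 & label == 1, .N], 6L)
  expect_equal(mix[pos == 10 & label == 0, .N], 14L)

  # 25 * 0.3 = 7.5 rounds half-up to 8
  mix25 <- build_mixture(pools_p, pools_n, sites, levels = 0.3,
                         reads_per_site = 25, seed = 1)
  expect_equal(mix25[pos == 10 & label == 1, .N], 8L)

  # m = 0: all reads from the unmethylated pool
  mix0 <- build_mixture(pools_p, pools_n, sites, levels = 0,
                        reads_per_site = 20, seed = 1)
  expect_true(all(mix0$label == 0))
  expect_true(all(startsWith(mix0$read_id, "u")))
})

test_that("mixture sampling is deterministic per seed and seed-sensitive", {
  sites <- data.table(chrom = "chr1", pos = c(10L, 50L, 90L))
  pools_p <- make_pools(sites); pools_n <- make_pools(sites)
  pools_n[, read_id := paste0("u", read_id)]
  args <- list(pools_p, pools_n, sites, levels = seq(0, 1, 0.25),
               reads_per_site = 24)
  m1 <- do.call(build_mixture, c(args, seed = 7))
  m2 <- do.call(build_mixture, c(args, seed = 7))
  m3 <- do.call(build_mixture, c(args, seed = 8))
  expect_identical(m1, m2)
  expect_false(identical(m1$read_id, m3$read_id))
  # no read reused within a level at a site
  expect_equal(anyDuplicated(m1, by = c("level", "chrom", "pos", "read_id")), 0)
})

test_that("insufficient pools raise an error naming the shortfall", {
  sites <- data.table(chrom = "chr1", pos = 10L)
  small <- data.table(chrom = "chr1", pos = 10L, read_id = c("a", "b"))
  big <- make_pools(sites)
  expect_error(build_mixture(small, big, sites, levels = 1,
                             reads_per_site = 24, seed = 1),
               "insufficient")
})

test_that("frequency evaluation reproduces closed-form statistics", {
  perfect <- data.table(level = rep(seq(0, 1, 0.1), each = 5),
                        frequency = rep(seq(0, 1, 0.1), each = 5))
  ev <- evaluate_frequencies(perfect)
  expect_equal(ev$pooled$pearson_r, 1)
  expect_equal(ev$pooled$rmse, 0)

  # RMSE = sqrt(mean((0.2-0)^2, (0.4-0.5)^2)) = sqrt(0.025)
  two <- data.table(level = c(0, 0.5), frequency = c(0.2, 0.4))
  expect_equal(evaluate_frequencies(two)$pooled$rmse, sqrt(0.025))

  # constant predictions: correlation undefined, warned
  const <- data.table(level = c(0, 0.5, 1), frequency = rep(0.4, 3))
  expect_warning(ev3 <- evaluate_frequencies(const), "undefined")
  expect_true(is.nan(ev3$pooled$pearson_r))

  expect_error(evaluate_frequencies(data.table(level = numeric(),
                                               frequency = numeric())))
  expect_error(evaluate_frequencies(data.table(level = 0.5,
                                               frequency = 0.4)), "levels")
})

test_that("the outside-window rule clips at the frequency boundaries", {
  expect_equal(outside_window_proportion(0.56, 0.5), 1)   # [0.45, 0.55]
  expect_equal(outside_window_proportion(0.55, 0.5), 0)   # boundary inside
  expect_equal(outside_window_proportion(0.05, 0), 0)     # [0, 0.05]
  expect_equal(outside_window_proportion(0.95, 1), 0)     # [0.95, 1]
  expect_equal(outside_window_proportion(c(0.4, 0.5, 0.61), 0.5), 2 / 3)
})

test_that("outside-window proportion equals brute-force enumeration", {
  for (seed in 1:10) {
    f <- withr::with_seed(seed, runif(50))
    m <- withr::with_seed(seed + 100, sample(seq(0, 1, 0.1), 1))
    brute <- sum(f < max(0, m - 0.05) | f > min(1, m + 0.05)) / 50
    expect_equal(outside_window_proportion(f, m), brute)
  }
})

test_that("TN/TP ECDF counts are exact and monotone", {
  tn <- tn_tp_ecdf(rep(0, 100), "tn")
  expect_equal(tn[threshold == 0.1]$count, 100L)
  expect_equal(tn[threshold == 0]$count, 0L)
  tp <- tn_tp_ecdf(c(0.85, 0.75), "tp")
  expect_equal(tp[threshold == 0.8]$count, 1L)
  f <- withr::with_seed(1, runif(40))
  expect_true(all(diff(tn_tp_ecdf(f, "tn")$count) >= 0))
  expect_true(all(diff(tn_tp_ecdf(f, "tp")$count) <= 0))
})

test_that("a near-noiseless tool recovers mixture levels end to end", {
  # separable scores, divisible n: per-site frequencies equal the target m
  g <- simulate_genome(length = 1500, cpg_spacing = 30, seed = 3)
  sites <- g$sites
  levels <- seq(0, 1, 0.1)
  profile <- tool_profile("sharp", mu_meth = 1, sd_meth = 0,
                          mu_unmeth = -1, sd_unmeth = 0)
  preds <- rbindlist(lapply(levels, function(m) {
    sim <- simulate_read_scores(sites, coverage = 20, m = m,
                                profiles = list(profile),
                                seed = 50 + round(100 * m))
    # force exact composition: relabel reads to the designed mixture
    calls <- sim$calls$sharp
    calls[, idx := seq_len(.N), by = .(chrom, pos)]
    n_meth <- floor(m * 20 + 0.5)
    calls[, score := fifelse(idx <= n_meth, 1, -1)]
    agg <- aggregate_per_site(call_read_states(calls, single_cutoff(0)))
    agg[, level := m]
    agg
  }))
  expect_true(all(abs(preds$frequency - preds$level) < 1e-12))
  ev <- evaluate_frequencies(preds)
  expect_equal(ev$pooled$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ev$pooled$rmse, 0, tolerance = 1e-12)
})
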