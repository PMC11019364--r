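test_that("scan statistic is log2 of het+missing plus pseudocount", {
  p <- scan_params()
  expect_equal(scan_statistic(0, 0, p), 1)             # log2(2)
  expect_equal(scan_statistic(12, 0, p), log2(14))     # all 12 samples het
  expect_equal(scan_statistic(2, 1, p), log2(5))
  expect_equal(scan_statistic(c(0, 12), c(0, 0), p), c(1, log2(14)))
  expect_error(scan_statistic(-1, 0, p), "non-negative")
  expect_error(scan_statistic(c(1, 2), 0, p), "aligned")
})

test_that("a constant series yields a single segment", {
  y <- rep(1, 100)
  seg <- cbs_segment(y, seq_len(100) * 50, scan_params(seed = 1), "chr1")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_sites, 100)
  expect_equal(seg$mean, 1)
  expect_equal(seg$state, "LOW")
})

test_that("a clean two-level series splits at the true boundary", {
  y <- c(rep(1.0, 50), rep(3.5, 50))
  seg <- cbs_segment(y, seq_len(100) * 100, scan_params(seed = 2), "chr1")
  expect_equal(nrow(seg), 2)
  expect_equal(seg$last[1], 50)
  expect_equal(seg$mean, c(1.0, 3.5))
  expect_equal(seg$state, c("LOW", "HIGH"))
})

test_that("a planted 4-sigma shift is localized within one site", {
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    y <- c(rnorm(15, 0, 1), rnorm(15, 4, 1))
    seg <- cbs_segment(y, seq_len(30) * 10, scan_params(seed = NULL), "chr1")
    b <- seg$last[seg$last < 30]
    if (length(b) && any(abs(b - 15) <= 1)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("accepted changepoints equal the exhaustive-search oracle", {
  prm <- scan_params(n_perm = 200)
  for (s in 1:25) {
    n <- sample(10:25, 1)
    shift <- s %% 2 == 0
    set.seed(3000 + s)
    y <- rnorm(n)
    if (shift) {
      cp <- sample(5:(n - 5), 1)
      y[(cp + 1):n] <- y[(cp + 1):n] + 3
    }
    set.seed(5000 + s)
    got <- segment_bounds_of(y, prm)
    set.seed(5000 + s)
    want <- sort(unique(oracle_cbs_bounds(y, 0L, prm)))
    expect_identical(got, want)
  }
})

test_that("hand-executed merge examples match", {
  prm <- scan_params()
  # two segments on opposite sides of the threshold: no merge, one flag
  seg2 <- data.frame(chrom = "chr1", first = c(1L, 11L), last = c(10L, 20L),
                     start = c(0, 10000), end = c(10000, 18000),
                     mean = c(1.0, 2.0), n_sites = c(10L, 10L),
                     state = c("LOW", "HIGH"))
  r2 <- merge_and_flag(seg2, prm)
  expect_equal(nrow(r2$segments), 2)
  expect_equal(nrow(r2$regions), 1)
  expect_equal(r2$regions$start, 10000)
  expect_equal(r2$regions$mean_het_na, 2^2 - 2)

  # positive flicker: high-low-high with a 3-kb middle collapses to one
  # segment whose mean is the site-weighted average
  seg3 <- data.frame(chrom = "chr1",
                     first = c(1L, 21L, 27L), last = c(20L, 26L, 42L),
                     start = c(0, 10000, 13000), end = c(10000, 13000, 21000),
                     mean = c(2.0, 1.0, 2.2), n_sites = c(20L, 6L, 16L),
                     state = c("HIGH", "LOW", "HIGH"))
  r3 <- merge_and_flag(seg3, prm)
  expect_equal(nrow(r3$segments), 1)
  expect_equal(r3$segments$mean, (20 * 2.0 + 6 * 1.0 + 16 * 2.2) / 42)
  expect_equal(r3$segments$state, "HIGH")
  expect_equal(nrow(r3$regions), 1)
  expect_equal(r3$regions$n_sites, 42)

  # all below threshold: everything merges, nothing flagged
  seg_low <- data.frame(chrom = "chr1",
                        first = c(1L, 11L, 21L), last = c(10L, 20L, 30L),
                        start = c(0, 5000, 9000), end = c(5000, 9000, 15000),
                        mean = c(1.1, 1.2, 1.3), n_sites = rep(10L, 3),
                        state = "LOW")
  rl <- merge_and_flag(seg_low, prm)
  expect_equal(nrow(rl$segments), 1)
  expect_equal(nrow(rl$regions), 0)

  # negative flicker: low-high-low with a short middle is absorbed
  seg_nf <- data.frame(chrom = "chr1",
                       first = c(1L, 21L, 25L), last = c(20L, 24L, 44L),
                       start = c(0, 9000, 12000), end = c(9000, 12000, 20000),
                       mean = c(1.0, 2.5, 1.1), n_sites = c(20L, 4L, 20L),
                       state = c("LOW", "HIGH", "LOW"))
  rn <- merge_and_flag(seg_nf, prm)
  expect_equal(nrow(rn$segments), 1)
  expect_equal(rn$segments$state, "LOW")
  expect_equal(nrow(rn$regions), 0)
})

test_that("a mean exactly at the threshold is LOW", {
  seg <- data.frame(chrom = "chr1", first = 1L, last = 10L,
                    start = 0, end = 1000, mean = 1.5, n_sites = 10L,
                    state = "LOW")
  r <- merge_and_flag(seg, scan_params())
  expect_equal(nrow(r$regions), 0)
})

test_that("merging is idempotent and conserves the partition", {
  prm <- scan_params()
  set.seed(31)
  for (trial in 1:200) {
    k <- sample(2:12, 1)
    n_sites <- sample(5:40, k, replace = TRUE)
    last <- cumsum(n_sites)
    first <- c(1L, last[-k] + 1L)
    pos_end <- cumsum(sample(500:8000, k, replace = TRUE))
    pos_start <- c(0, pos_end[-k])
    seg <- data.frame(chrom = "chr1", first = first, last = last,
                      start = pos_start, end = pos_end,
                      mean = runif(k, 0.8, 3), n_sites = n_sites,
                      state = "LOW")
    m1 <- merge_and_flag(seg, prm)
    expect_equal(sum(m1$segments$n_sites), sum(n_sites))
    expect_identical(m1$segments$first,
                     c(1L, m1$segments$last[-nrow(m1$segments)] + 1L))
    m2 <- merge_and_flag(m1$segments, prm)
    expect_equal(m2$segments, m1$segments)
  }
})

test_that("raising the flagging threshold on merged segments never adds regions", {
  set.seed(77)
  for (trial in 1:20) {
    k <- sample(4:12, 1)
    n_sites <- sample(5:40, k, replace = TRUE)
    last <- cumsum(n_sites)
    pos_end <- cumsum(sample(4000:9000, k, replace = TRUE))
    seg <- data.frame(chrom = "chr1", first = c(1L, last[-k] + 1L),
                      last = last, start = c(0, pos_end[-k]), end = pos_end,
                      mean = runif(k, 0.8, 3), n_sites = n_sites,
                      state = "LOW")
    merged <- merge_and_flag(seg, scan_params())$segments
    counts <- vapply(c(1.0, 1.5, 2.0, 2.5), function(T) {
      sum(merged$mean > T)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("non-partition segment input is rejected", {
  seg <- data.frame(chrom = "chr1", first = c(1L, 12L), last = c(10L, 20L),
                    start = c(0, 1100), end = c(1000, 2000),
                    mean = c(1, 2), n_sites = c(10L, 9L), state = "LOW")
  expect_error(merge_and_flag(seg, scan_params()), "partition")
})

test_that("planted collapsed regions are recovered on a clean panel", {
  regions <- data.frame(chrom = "chr1", start = c(2e5, 6e5),
                        end = c(2e5, 6e5) + 10000,
                        het_na_rate = 0.6, depth_multiplier = 2)
  cfg <- sim_config(n_strains = 1, replicates_per_strain = 12,
                    chrom_lengths = c(chr1 = 1e6),
                    background_het_rate = 0, missing_rate = 0,
                    collapsed_regions = regions, seed = 17)
  g <- generate_panel(cfg)
  res <- scan_misassembly(g$panel, scan_params(seed = 4))
  expect_equal(nrow(res$regions), 2)
  for (i in 1:2) {
    ov <- pmin(res$regions$end[i], regions$end[i]) -
      pmax(res$regions$start[i], regions$start[i])
    un <- pmax(res$regions$end[i], regions$end[i]) -
      pmin(res$regions$start[i], regions$start[i])
    expect_gt(ov / un, 0.8)
  }
})

test_that("a panel without reference-strain samples cannot be scanned", {
  p <- tiny_panel(matrix(0L, 20, 3))
  expect_error(scan_misassembly(p), "reference-strain")
})
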