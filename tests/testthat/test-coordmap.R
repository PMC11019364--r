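identity_chain <- function(len = 1000, chrom = "chr1") {
  parse_chain(c(sprintf("chain %d %s %d + 0 %d %s %d + 0 %d 1",
                        len, chrom, len, len, chrom, len, len),
                sprintf("%d", len), ""))
}

test_that("chain parsing validates block arithmetic", {
  cs <- identity_chain()
  expect_s3_class(cs, "chain_set")
  expect_equal(length(cs), 1)
  expect_equal(cs[[1]]$blocks$size, 1000)

  two <- parse_chain(c("chain 90 chr1 200 + 0 100 chr1 150 + 0 90 7",
                       "40 10 0", "50", ""))
  expect_equal(two[[1]]$blocks$dt, c(10, 0))
  expect_equal(two[[1]]$blocks$size, c(40, 50))

  expect_error(parse_chain(c("chain 90 chr1 200 + 0 100 chr1 150 + 0 95 7",
                             "40 10 0", "50", "")), "arithmetic")
  expect_error(parse_chain(c("chain 90 chr1 200 + 0 100 chr1 150 + 0 90 7",
                             "40 10 0")), "truncated")
})

test_that("positions lift by offset, with gaps and absent chroms reported", {
  cs <- identity_chain()
  r <- lift_position(cs, "chr1", c(1L, 50L, 1000L))
  expect_true(all(r$mapped))
  expect_equal(r$tgt_pos, c(1L, 50L, 1000L))

  # block source 1-100 mapping to target 1001-1100: pos 50 -> 1050
  off <- parse_chain(c("chain 100 chrS 200 + 0 100 chrT 2000 + 1000 1100 1",
                       "100", ""))
  r2 <- lift_position(off, "chrS", 50L)
  expect_equal(r2$tgt_pos, 1050L)
  expect_equal(r2$tgt_chrom, "chrT")

  gap <- parse_chain(c("chain 80 chrS 200 + 0 90 chrT 100 + 0 80 1",
                       "40 10 0", "40", ""))
  rg <- lift_position(gap, "chrS", c(45L, 10L, 60L))
  expect_equal(rg$mapped, c(FALSE, TRUE, TRUE))
  expect_equal(rg$reason[1], "gap")
  expect_equal(rg$tgt_pos[2:3], c(10L, 50L))

  ra <- lift_position(cs, "chrZ", 5L)
  expect_equal(ra$reason, "chrom_absent")
})

test_that("generated chains lift exactly as the truth map dictates", {
  lens <- c(chrA = 20000, chrB = 15000)
  ch <- generate_chain(lens, deleted_fraction = 0.2,
                       inverted_blocks = data.frame(chrom = "chrA",
                                                    start = 5001, end = 7000),
                       seed = 6)
  cs <- parse_chain(ch$chain_text)
  for (chrom in names(lens)) {
    pos <- seq(1L, lens[[chrom]], by = 37L)
    got <- lift_position(cs, chrom, pos)
    want <- truth_lift(ch$truth, chrom, pos)
    expect_identical(got$tgt_pos, want)
    expect_identical(got$mapped, !is.na(want))
  }
})

test_that("lifting agrees with rtracklayer liftOver on a generated chain", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("GenomicRanges")
  ch <- generate_chain(c(chrA = 10000), deleted_fraction = 0.1, seed = 9)
  f <- tempfile(fileext = ".chain")
  writeLines(ch$chain_text, f)
  cs <- parse_chain(ch$chain_text)
  pos <- seq(1L, 10000L, by = 11L)
  mine <- lift_position(cs, "chrA", pos)
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(pos, width = 1))
  lifted <- rtracklayer::liftOver(gr, rtracklayer::import.chain(f))
  ref_pos <- vapply(seq_along(lifted), function(i) {
    if (length(lifted[[i]]) == 1L)
      GenomicRanges::start(lifted[[i]]) else NA_integer_
  }, integer(1))
  expect_identical(mine$tgt_pos, ref_pos)
})

test_that("round trip through a chain and its inverse is the identity", {
  lens <- c(chrA = 12000)
  ch <- generate_chain(lens, deleted_fraction = 0.15,
                       inverted_blocks = data.frame(chrom = "chrA",
                                                    start = 8001, end = 9000),
                       seed = 12)
  fwd <- parse_chain(ch$chain_text)
  inv <- parse_chain(invert_truth_chain(ch$truth, lens, ch$target_lengths))
  pos <- seq(1L, 12000L, by = 7L)
  there <- lift_position(fwd, "chrA", pos)
  ok <- there$mapped
  back <- lift_position(inv, "chrA", there$tgt_pos[ok])
  expect_true(all(back$mapped))
  expect_identical(back$tgt_pos, pos[ok])
})

test_that("simulated-site evaluation reports the mappable fraction exactly", {
  sim <- simulate_and_eval_liftover(c(chrA = 5000), identity_chain(5000, "chrA"))
  expect_equal(sim$n_input, 5)       # sites 1, 1001, 2001, 3001, 4001
  expect_equal(sim$fraction_lifted, 1)

  ch <- generate_chain(c(chrA = 100000), deleted_fraction = 0.2, seed = 3)
  cs <- parse_chain(ch$chain_text)
  got <- simulate_and_eval_liftover(c(chrA = 100000), cs)
  sites <- seq(1L, 100000L, by = 1000L)
  want <- mean(!is.na(truth_lift(ch$truth, "chrA", sites)))
  expect_equal(got$fraction_lifted, want)
  expect_error(simulate_and_eval_liftover(c(), cs), "length")
})

test_that("lifted/direct variant comparison is set algebra", {
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos, ref = "A",
                                 alt = "T")
  same <- compare_lifted_vs_direct(mk(1:5), mk(1:5))
  expect_equal(same$n_matched, 5)
  expect_equal(same$frac_direct_only_of_direct, 0)
  r <- compare_lifted_vs_direct(mk(c(1, 2, 3)), mk(c(2, 3, 4)))
  expect_equal(r$n_matched, 2)
  expect_equal(r$n_lifted_only, 1)
  expect_equal(r$n_direct_only, 1)
  expect_equal(r$frac_matched_of_lifted, 2 / 3)
  # alleles are part of the key
  a <- compare_lifted_vs_direct(mk(1), data.frame(chrom = "chr1", pos = 1,
                                                  ref = "A", alt = "G"))
  expect_equal(a$n_matched, 0)
})

test_that("cis/ambiguous/trans classification respects the distance bounds", {
  d <- c(0, 1e6 - 1, 1e6, 3e6, 5e6, 5e6 + 1)
  got <- pair_class("chr1", 1e7 + d, "chr1", 1e7)
  expect_equal(got, c("CIS", "CIS", "AMBIGUOUS", "AMBIGUOUS", "AMBIGUOUS",
                      "TRANS"))
  expect_equal(pair_class("chr2", 100, "chr1", 100), "TRANS")
  expect_equal(pair_class("chr1", 5e5, "chr1", 14e5), "CIS")  # 900 kb
})

test_that("pair reclassification tabulates conversions between references", {
  pairs <- data.frame(snp_id = c("s1", "s2", "s3"),
                      gene_id = c("g1", "g1", "g2"))
  map_a <- data.frame(id = c("s1", "s2", "s3", "g1", "g2"),
                      chrom = c("chr13", "chr1", "chr1", "chr3", "chr1"),
                      pos = c(5e6, 2e6, 1e6, 1e6, 9e6))
  map_b <- data.frame(id = c("s1", "s2", "s3", "g1", "g2"),
                      chrom = c("chr3", "chr1", "chr1", "chr3", "chr1"),
                      pos = c(1.5e6, 2e6, 1e6, 1e6, 9e6))
  r <- classify_pairs(pairs, map_a, map_b)
  # s1 relocated from chr13 to chr3 near its gene: trans -> cis
  expect_equal(r$pairs$class_a[1], "TRANS")
  expect_equal(r$pairs$class_b[1], "CIS")
  expect_equal(unname(r$n_trans_to_cis), 1)
  expect_equal(unname(r$n_unchanged), 2)
  # classes partition the pairs under each map
  expect_equal(sum(r$conversion), nrow(pairs))
  expect_error(classify_pairs(data.frame(snp_id = "sX", gene_id = "g1"),
                              map_a, map_b), "sX")
})

test_that("marker concordance detects inverted runs", {
  mono <- data.frame(chrom = "chr1", pos = 1:100 * 1000,
                     cm = cumsum(runif(100, 0.1, 1)))
  r <- marker_concordance(mono)
  expect_equal(r$per_chrom$rho, 1)
  expect_equal(nrow(r$runs), 0)

  rev10 <- mono
  rev10$cm[41:50] <- rev(rev10$cm[41:50])
  r2 <- marker_concordance(rev10)
  expect_equal(nrow(r2$runs), 1)
  expect_equal(r2$runs$n_markers, 10)
  expect_equal(r2$runs$start_bp, 41000)
  expect_equal(r2$runs$end_bp, 50000)

  full <- data.frame(chrom = "chr1", pos = 1:50 * 1000, cm = 50:1)
  r3 <- marker_concordance(full)
  expect_equal(r3$per_chrom$rho, -1)
  expect_equal(nrow(r3$runs), 1)
  expect_equal(r3$runs$n_markers, 50)
  expect_error(marker_concordance(data.frame(chrom = "chr1", pos = 1,
                                             cm = 1)), "at least 2")
})
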