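test_that("noise-free panels contain only strain-consistent homozygous calls", {
  cfg <- sim_config(n_strains = 5, replicates_per_strain = 3,
                    chrom_lengths = c(chr1 = 1e5),
                    background_het_rate = 0, missing_rate = 0,
                    error_sites = 0, seed = 3)
  g <- generate_panel(cfg)
  expect_true(all(g$panel$geno %in% c(0L, 2L)))
  # replicates of one strain share every genotype
  for (str in unique(g$panel$samples$strain)) {
    cols <- which(g$panel$samples$strain == str)
    for (k in cols[-1]) {
      expect_identical(g$panel$geno[, k], g$panel$geno[, cols[1]],
                       ignore_attr = TRUE)
    }
  }
  # reference strain carries no alternate alleles
  ref_cols <- which(g$panel$samples$is_reference)
  expect_true(all(g$panel$geno[, ref_cols] == 0L))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_strains = 3, replicates_per_strain = 2,
                    chrom_lengths = c(chr1 = 5e4), error_sites = 5,
                    label_swaps = list(c(3L, 5L)), seed = 42)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a, b)
})

test_that("collapsed regions show the configured het+NA rate and depth boost", {
  cfg <- sim_config(n_strains = 12, replicates_per_strain = 1,
                    chrom_lengths = c(chr1 = 5e5),
                    background_het_rate = 0, missing_rate = 0,
                    collapsed_regions = data.frame(
                      chrom = "chr1", start = 2e5, end = 2.2e5,
                      het_na_rate = 0.6, depth_multiplier = 2),
                    base_depth = 40, seed = 9)
  g <- generate_panel(cfg)
  st <- site_statistics(g$panel)$site_table
  inside <- st$pos >= 2e5 & st$pos <= 2.2e5
  hetna <- st$het_count + st$missing_count
  # binomial expectation 12 * 0.6 = 7.2 per site inside; 0 outside
  expect_gt(sum(inside), 50)
  se <- sqrt(12 * 0.6 * 0.4 / sum(inside))
  expect_lt(abs(mean(hetna[inside]) - 7.2), 3 * se + 0.05)
  expect_equal(mean(hetna[!inside]), 0)
  expect_gt(mean(st$mean_depth[inside]) / mean(st$mean_depth[!inside]), 1.8)
})

test_that("site density and homozygosity converge to the configured rates", {
  cfg <- sim_config(n_strains = 8, replicates_per_strain = 1,
                    chrom_lengths = c(chr1 = 4e6), seed = 21)
  g <- generate_panel(cfg)
  n <- n_sites(g$panel)
  # Poisson site count: 6/kb over 4 Mb = 24,000 expected, 3 sigma band
  expect_lt(abs(n - 24000), 3 * sqrt(24000) + 50)
  hom <- site_statistics(g$panel)$sample_homozygosity$hom_fraction
  # non-reference inbred strains are overwhelmingly homozygous; the
  # reference-strain sample carries only residual heterozygosity
  expect_true(all(hom[!g$panel$samples$is_reference] > 0.95))
})

test_that("planted truth resolves to panel coordinates", {
  cfg <- sim_config(n_strains = 4, replicates_per_strain = 2,
                    chrom_lengths = c(chr1 = 2e5, chr2 = 1e5),
                    error_sites = 25, seed = 5)
  g <- generate_panel(cfg)
  key <- paste(g$panel$sites$chrom, g$panel$sites$pos)
  expect_true(all(paste(g$truth$error_sites$chrom,
                        g$truth$error_sites$pos) %in% key))
  # every planted error site is non-reference in every sample
  idx <- match(paste(g$truth$error_sites$chrom, g$truth$error_sites$pos), key)
  expect_true(all(g$panel$geno[idx, ] >= 1L))
})

test_that("label swaps move metadata but not genotypes", {
  base <- sim_config(n_strains = 4, replicates_per_strain = 2,
                     chrom_lengths = c(chr1 = 1e5), seed = 8)
  swapped <- sim_config(n_strains = 4, replicates_per_strain = 2,
                        chrom_lengths = c(chr1 = 1e5), seed = 8,
                        label_swaps = list(c(3L, 5L)))
  a <- generate_panel(base)
  b <- generate_panel(swapped)
  expect_identical(unname(a$panel$geno), unname(b$panel$geno))
  expect_identical(a$panel$samples$strain[c(3, 5)],
                   b$panel$samples$strain[c(5, 3)])
  expect_identical(b$truth$true_labels$true_strain,
                   a$panel$samples$strain)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(variant_density = 0), "variant_density")
  expect_error(sim_config(background_het_rate = 1.2), "rates")
  expect_error(sim_config(collapsed_regions = data.frame(
    chrom = "chr1", start = 1, end = 2e7, het_na_rate = 0.5,
    depth_multiplier = 2)), "outside")
  expect_error(sim_config(collapsed_regions = data.frame(
    chrom = c("chr1", "chr1"), start = c(100, 200), end = c(300, 400),
    het_na_rate = 0.5, depth_multiplier = 2)), "overlapping")
})

test_that("toy assemblies reproduce specified scaffold and contig structure", {
  a <- generate_assembly(list(s1 = c(4L, -10L, 3L)), seed = 1)
  expect_identical(a$contig_lengths$s1, c(4L, 3L))
  expect_identical(unname(a$scaffold_lengths), 17L)

  b <- generate_assembly(list(s1 = c(2L, -9L, 2L)), seed = 1)
  expect_identical(b$contig_lengths$s1, 13L)

  cc <- generate_assembly(list(s1 = 8L, s2 = 8L, s3 = 4L, s4 = 2L, s5 = 1L),
                          seed = 2)
  expect_identical(unname(cc$scaffold_lengths), c(8L, 8L, 4L, 2L, 1L))

  d <- generate_assembly(list(s1 = c(-12L)), seed = 1)
  expect_identical(d$contig_lengths$s1, integer(0))
  expect_error(generate_assembly(list(s1 = c(4L, 0L))), "zero-length")
})

test_that("identity chains map every base to itself", {
  ch <- generate_chain(c(chrA = 5000), deleted_fraction = 0, seed = 1)
  expect_true(all(ch$truth$mapped))
  p <- c(1L, 137L, 2500L, 5000L)
  expect_identical(truth_lift(ch$truth, "chrA", p), p)
})

test_that("deleted fraction is carved out exactly", {
  ch <- generate_chain(c(chrA = 10000), deleted_fraction = 0.2, seed = 4)
  unmappable <- with(ch$truth, sum((src_end - src_start + 1L)[!mapped]))
  expect_identical(unmappable, 2000L)
  expect_identical(unname(ch$target_lengths["chrA"]), 8000L)
  # truth_lift agrees: exactly 2000 positions return NA
  lifted <- truth_lift(ch$truth, "chrA", 1:10000)
  expect_identical(sum(is.na(lifted)), 2000L)
  expect_identical(sort(lifted[!is.na(lifted)]), 1:8000)
})

test_that("inverted blocks map with decreasing target positions", {
  ch <- generate_chain(c(chrA = 6000), deleted_fraction = 0,
                       inverted_blocks = data.frame(chrom = "chrA",
                                                    start = 2001,
                                                    end = 3000),
                       seed = 2)
  tgt <- truth_lift(ch$truth, "chrA", 2001:3000)
  expect_true(all(diff(tgt) == -1L))
  expect_identical(truth_lift(ch$truth, "chrA", 1L), 1L)
})
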