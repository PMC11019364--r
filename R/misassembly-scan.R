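#' Parameters of the misassembly scan
#'
#' The scan statistic is `log2(het + missing + pseudocount)` per site over a
#' designated inbred-sample subset; with pseudocount 2 it mimics copy number
#' on a log2 scale, running from `log2(2) = 1` in clean regions up to
#' `log2(n_subset + 2)` where every sample is heterozygous or missing. The
#' series is segmented by circular binary segmentation with a permutation
#' test, and segments are merged by four triplet rules before flagging.
#'
#' @param pseudocount added to the per-site het+missing count before the
#'   log2 transform (default 2, the baseline copy number).
#' @param threshold high/low boundary on the log2 scale (default 1.5); a
#'   segment is HIGH when its mean is strictly above the threshold.
#' @param min_width minimum number of sites in any segment (default 5).
#' @param alpha permutation-test significance level for accepting a
#'   changepoint (default 0.001).
#' @param flicker_bp maximum genomic length (bp) of an opposite-state middle
#'   segment that is absorbed during merging (default 5000).
#' @param n_perm number of permutations per changepoint test (default 1000).
#' @param seed integer seed for the permutation draws, or `NULL` to use the
#'   current RNG state.
#' @param exact_max longest series scanned over every arc length; longer
#'   series use a geometric grid of arc lengths (all arc positions are
#'   always scanned).
#' @return an object of class `scan_params`.
#' @export
scan_params <- function(pseudocount = 2, threshold = 1.5, min_width = 5L,
                        alpha = 0.001, flicker_bp = 5000, n_perm = 1000L,
                        seed = NULL, exact_max = 1000L) {
  stopifnot(pseudocount >= 1, alpha > 0, alpha < 1, flicker_bp > 0,
            min_width >= 2, n_perm >= 1)
  p <- list(pseudocount = pseudocount, threshold = threshold,
            min_width = as.integer(min_width), alpha = alpha,
            flicker_bp = flicker_bp, n_perm = as.integer(n_perm),
            seed = seed, exact_max = as.integer(exact_max))
  class(p) <- "scan_params"
  p
}

#' Per-site scanning statistic
#'
#' @param het_counts,missing_counts aligned non-negative per-site counts
#'   over the sample subset.
#' @param params a [scan_params()].
#' @return numeric vector `log2(het + missing + pseudocount)`.
#' @export
scan_statistic <- function(het_counts, missing_counts,
                           params = scan_params()) {
  if (length(het_counts) != length(missing_counts)) {
    stop("het and missing count series must be aligned")
  }
  if (any(het_counts < 0) || any(missing_counts < 0)) {
    stop("counts must be non-negative")
  }
  log2(het_counts + missing_counts + params$pseudocount)
}

# arc lengths to scan: every valid length for short series, a geometric grid
# (plus its mirror) for long ones; all arc start positions are scanned either
# way
arc_lengths <- function(n, min_width, exact_max, ratio = 1.25) {
  hi <- n - min_width
  if (hi < min_width) return(integer(0))
  if (n <= exact_max) return(seq.int(min_width, hi))
  g <- min_width
  k <- min_width
  while (k < hi) {
    k <- min(hi, max(k + 1L, as.integer(round(k * ratio))))
    g <- c(g, k)
  }
  sort(unique(c(g, n - g[g <= hi & (n - g) >= min_width])))
}

# permutation test for the best arc of one interval; returns NULL (no split)
# or the accepted arc bounds. Early termination: a permutation run stops as
# soon as the p-value can no longer fall below alpha, which never changes the
# accept/reject decision (the exceed count only grows).
test_arc <- function(xv, params) {
  n <- length(xv)
  if (n < 2L * params$min_width) return(NULL)
  lens <- arc_lengths(n, params$min_width, params$exact_max)
  obs <- max_arc_stat_cpp(xv, lens, params$min_width)
  if (obs$i < 0 || obs$stat <= 0) return(NULL)
  nperm <- params$n_perm
  # a permuted maximum within 1e-9 relative of the observed one counts as an
  # exceedance: an arc and its complement are mathematically tied but can
  # differ in the last float ulp depending on which orientation is scanned
  thr <- obs$stat * (1 - 1e-9)
  b <- 0L
  for (m in seq_len(nperm)) {
    perm <- sample.int(n)
    ps <- max_arc_stat_cpp(xv[perm], lens, params$min_width,
                           stop_above = thr)
    if (ps$stat >= thr) b <- b + 1L
    if ((b + 1) / (nperm + 1) >= params$alpha) return(NULL)
  }
  if ((b + 1) / (nperm + 1) < params$alpha) obs else NULL
}

#' Segment a transformed series by circular binary segmentation
#'
#' Recursively finds, within each interval, the arc of consecutive values
#' maximizing the two-sample statistic between arc and remainder, accepts
#' the split when its permutation p-value `(b + 1) / (n_perm + 1)` is below
#' `alpha`, and recurses into the resulting pieces. No segment of fewer than
#' `min_width` sites is ever created; a series shorter than `2 * min_width`
#' returns a single segment. Segment means are arithmetic means of member
#' values; a segment is HIGH when its mean is strictly above the threshold.
#'
#' @param series numeric vector of transformed per-site values (one
#'   chromosome).
#' @param positions strictly increasing genomic positions (bp) of the sites.
#' @param params a [scan_params()].
#' @param chrom chromosome name carried into the output.
#' @return data.frame of segments: `chrom`, `first`, `last` (1-based site
#'   indices, inclusive), `start`, `end` (0-based half-open bp), `mean`,
#'   `n_sites`, `state`.
#' @export
cbs_segment <- function(series, positions, params = scan_params(),
                        chrom = "chr") {
  stopifnot(length(series) >= 1, length(series) == length(positions))
  if (length(positions) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- length(series)
  bounds <- sort(unique(c(0L, segment_rec(series, 0L, params), n)))
  first <- bounds[-length(bounds)] + 1L
  last <- bounds[-1]
  means <- vapply(seq_along(first),
                  function(i) mean(series[first[i]:last[i]]), numeric(1))
  data.frame(chrom = chrom, first = first, last = last,
             start = positions[first] - 1L, end = positions[last],
             mean = means, n_sites = last - first + 1L,
             state = ifelse(means > params$threshold, "HIGH", "LOW"),
             stringsAsFactors = FALSE)
}

# returns internal boundary offsets (absolute, 0-based) for interval
# x with absolute start offset `off`; traversal order (test, then left,
# middle, right) is fixed so that permutation draws are reproducible
segment_rec <- function(x, off, params) {
  arc <- test_arc(x, params)
  if (is.null(arc)) return(integer(0))
  i <- arc$i
  j <- arc$j
  n <- length(x)
  out <- integer(0)
  if (i > 0L) out <- c(out, segment_rec(x[seq_len(i)], off, params), off + i)
  out <- c(out, segment_rec(x[(i + 1L):j], off + i, params))
  if (j < n) out <- c(out, off + j, segment_rec(x[(j + 1L):n], off + j, params))
  out
}

#' Merge segments by the four triplet rules and flag high regions
#'
#' Walks the segment list in sliding triplets. The first two segments of the
#' current triplet are merged when (1) both means are above the threshold,
#' (2) both are below, (3) the triplet is high-low-high with the middle
#' segment shorter than `flicker_bp` (a positive flicker), or (4) low-high-low
#' with the middle segment shorter than `flicker_bp` (a negative flicker).
#' After a merge the next triplet is (merged, old third, next); otherwise the
#' window advances one segment. The trailing pair at the chromosome end is
#' merged under rules (1)/(2) only. Merged means are site-count-weighted;
#' a mean exactly at the threshold counts as LOW.
#'
#' Flagged regions are the final segments with mean above the threshold,
#' reported in BED convention with the back-transformed mean het+missing
#' count `2^mean - pseudocount`.
#'
#' @param segments segment data.frame as returned by [cbs_segment()]
#'   (possibly covering several chromosomes); must partition each
#'   chromosome's site-index range.
#' @param params a [scan_params()].
#' @return list with `segments` (merged) and `regions` (data.frame `chrom`,
#'   `start`, `end`, `mean_het_na`, `n_sites`).
#' @export
merge_and_flag <- function(segments, params = scan_params()) {
  out <- lapply(split(segments, segments$chrom)[unique(segments$chrom)],
                merge_one_chrom, params = params)
  merged <- do.call(rbind, out)
  rownames(merged) <- NULL
  high <- merged[merged$mean > params$threshold, , drop = FALSE]
  regions <- data.frame(chrom = high$chrom, start = high$start,
                        end = high$end,
                        mean_het_na = 2^high$mean - params$pseudocount,
                        n_sites = high$n_sites, stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  list(segments = merged, regions = regions)
}

# one forward sliding-triplet pass plus trailing-pair handling; applied
# repeatedly until a fixed point, since a merge can make an already-passed
# pair mergeable (the fixed point makes the output idempotent)
merge_one_chrom <- function(seg, params) {
  seg <- seg[order(seg$first), , drop = FALSE]
  if (any(seg$first[-1] != seg$last[-nrow(seg)] + 1L) || seg$first[1] != 1L) {
    stop("segments do not partition the site-index range on ", seg$chrom[1])
  }
  repeat {
    out <- merge_pass(seg, params)
    if (nrow(out) == nrow(seg)) break
    seg <- out
  }
  out$state <- ifelse(out$mean > params$threshold, "HIGH", "LOW")
  rownames(out) <- NULL
  out
}

merge_pass <- function(seg, params) {
  T <- params$threshold
  s <- seg
  merge12 <- function(s, i) {
    w <- s$n_sites[c(i, i + 1L)]
    s$mean[i] <- sum(s$mean[c(i, i + 1L)] * w) / sum(w)
    s$last[i] <- s$last[i + 1L]
    s$end[i] <- s$end[i + 1L]
    s$n_sites[i] <- sum(w)
    s[-(i + 1L), , drop = FALSE]
  }
  i <- 1L
  while (i + 2L <= nrow(s)) {
    m <- s$mean[i:(i + 2L)]
    mid_bp <- s$end[i + 1L] - s$start[i + 1L]
    hit <- (m[1] > T && m[2] > T) ||
      (m[1] <= T && m[2] <= T) ||
      (m[1] > T && m[2] <= T && m[3] > T && mid_bp < params$flicker_bp) ||
      (m[1] <= T && m[2] > T && m[3] <= T && mid_bp < params$flicker_bp)
    if (hit) s <- merge12(s, i) else i <- i + 1L
  }
  # trailing pair: state rules only
  while (nrow(s) >= 2L) {
    k <- nrow(s)
    m <- s$mean[(k - 1L):k]
    if ((m[1] > T && m[2] > T) || (m[1] <= T && m[2] <= T)) {
      s <- merge12(s, k - 1L)
    } else break
  }
  s
}

#' Scan a genotype panel for candidate misassembly regions
#'
#' Runs the full scan over the reference-strain samples (or an explicit
#' subset): per-site het and missing counts, the log2 transform,
#' segmentation, merging, and flagging, chromosome by chromosome. Sex
#' chromosomes and mitochondria are excluded.
#'
#' @param panel a [genotype_panel()].
#' @param params a [scan_params()].
#' @param subset sample ids to scan; default: the panel's reference-strain
#'   samples.
#' @return list with `segments`, `regions` (see [merge_and_flag()]) and
#'   `subset` (the sample ids used).
#' @export
scan_misassembly <- function(panel, params = scan_params(), subset = NULL) {
  if (is.null(subset)) {
    subset <- panel$samples$sample_id[panel$samples$is_reference]
  }
  if (!length(subset)) {
    stop("no reference-strain samples in panel; supply subset explicitly")
  }
  stats <- site_statistics(panel, subset = subset)$site_table
  stats <- stats[!grepl("^(chr)?(X|Y|M|MT)$", stats$chrom), , drop = FALSE]
  if (!nrow(stats)) stop("no autosomal sites to scan")
  if (!is.null(params$seed)) set.seed(params$seed)
  inner <- params
  inner$seed <- NULL   # one stream across chromosomes
  segs <- lapply(unique(stats$chrom), function(ch) {
    st <- stats[stats$chrom == ch, , drop = FALSE]
    y <- scan_statistic(st$het_count, st$missing_count, params)
    cbs_segment(y, st$pos, inner, chrom = ch)
  })
  mf <- merge_and_flag(do.call(rbind, segs), params)
  c(mf, list(subset = subset))
}

#' Write flagged regions as a BED file
#' @param regions data.frame with `chrom`, `start`, `end` plus extra score
#'   columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
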