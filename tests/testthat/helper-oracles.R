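# Independent oracles used across the suite. These re-derive results by
# direct enumeration (no shared code with the implementation paths they
# check).

# exhaustive search over all (i, j] arcs for the maximal two-sample
# statistic, with the same width constraints as the segmentation scan
oracle_max_arc <- function(x, min_width) {
  n <- length(x)
  S <- c(0, cumsum(x))
  tot <- S[n + 1]
  best <- 0; bi <- -1L; bj <- -1L
  for (i in 0:(n - 1L)) {
    if (i != 0L && i < min_width) next
    js <- (i + 1L):n
    k <- js - i
    ok <- k >= min_width & k <= n - min_width &
      ((n - js) == 0L | (n - js) >= min_width)
    js <- js[ok]
    if (!length(js)) next
    k <- js - i
    s_in <- S[js + 1L] - S[i + 1L]
    stat <- abs(s_in / k - (tot - s_in) / (n - k)) /
      sqrt(1 / k + 1 / (n - k))
    m <- which.max(stat)
    if (stat[m] > best) { best <- stat[m]; bi <- i; bj <- js[m] }
  }
  list(stat = best, i = bi, j = bj)
}

# permutation test with the same draw sequence and the same early-stop rule
# as the implementation (stopping only when rejection is already certain)
oracle_test_arc <- function(xv, params) {
  n <- length(xv)
  if (n < 2L * params$min_width) return(NULL)
  obs <- oracle_max_arc(xv, params$min_width)
  if (obs$i < 0 || obs$stat <= 0) return(NULL)
  nperm <- params$n_perm
  thr <- obs$stat * (1 - 1e-9)   # same tie tolerance as the implementation
  b <- 0L
  for (m in seq_len(nperm)) {
    perm <- sample.int(n)
    ps <- oracle_max_arc(xv[perm], params$min_width)
    if (ps$stat >= thr) b <- b + 1L
    if ((b + 1) / (nperm + 1) >= params$alpha) return(NULL)
  }
  obs
}

# full recursive segmentation oracle; traversal order matches the
# implementation so that both consume identical RNG draws
oracle_cbs_bounds <- function(x, off, params) {
  arc <- oracle_test_arc(x, params)
  if (is.null(arc)) return(integer(0))
  i <- arc$i; j <- arc$j; n <- length(x)
  out <- integer(0)
  if (i > 0L) out <- c(out, oracle_cbs_bounds(x[seq_len(i)], off, params),
                       off + i)
  out <- c(out, oracle_cbs_bounds(x[(i + 1L):j], off + i, params))
  if (j < n) out <- c(out, off + j,
                      oracle_cbs_bounds(x[(j + 1L):n], off + j, params))
  out
}

# brute-force UPGMA: cluster distances recomputed at every step as the plain
# mean over all leaf pairs; returns the cophenetic distance matrix
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  minlab <- labs
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  cdist <- function(a, b) mean(d[clusters[[a]], clusters[[b]]])
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- Inf; pick <- NULL
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (bi <= ai) next
        a <- active[ai]; b <- active[bi]
        dd <- cdist(a, b)
        k1 <- min(minlab[a], minlab[b]); k2 <- max(minlab[a], minlab[b])
        if (dd < best - 1e-12 ||
            (abs(dd - best) <= 1e-12 && !is.null(pick) &&
             (k1 < pick$k1 || (k1 == pick$k1 && k2 < pick$k2)))) {
          best <- dd; pick <- list(a = a, b = b, k1 = k1, k2 = k2)
        }
      }
    }
    coph[clusters[[pick$a]], clusters[[pick$b]]] <- best
    coph[clusters[[pick$b]], clusters[[pick$a]]] <- best
    clusters[[pick$a]] <- c(clusters[[pick$a]], clusters[[pick$b]])
    minlab[pick$a] <- min(minlab[pick$a], minlab[pick$b])
    active <- setdiff(active, pick$b)
  }
  coph
}

# build the inverse of a generate_chain() truth map as chain-format text
invert_truth_chain <- function(truth, src_lengths, tgt_lengths) {
  lines <- character(0)
  id <- 0L
  for (i in seq_len(nrow(truth))) {
    if (!truth$mapped[i]) next
    id <- id + 1L
    ch <- truth$chrom[i]
    w <- truth$src_end[i] - truth$src_start[i] + 1L
    sl <- src_lengths[[ch]]; tl <- tgt_lengths[[ch]]
    if (truth$strand[i] == "+") {
      hdr <- sprintf("chain %d %s %d + %d %d %s %d + %d %d %d",
                     w, ch, tl, truth$tgt_start[i] - 1L, truth$tgt_end[i],
                     ch, sl, truth$src_start[i] - 1L, truth$src_end[i], id)
    } else {
      hdr <- sprintf("chain %d %s %d + %d %d %s %d - %d %d %d",
                     w, ch, tl, truth$tgt_start[i] - 1L, truth$tgt_end[i],
                     ch, sl, sl - truth$src_end[i],
                     sl - (truth$src_start[i] - 1L), id)
    }
    lines <- c(lines, hdr, sprintf("%d", w), "")
  }
  lines
}

# small deterministic panel built by hand (no generator involved)
tiny_panel <- function(geno, depth = NULL, qual = NULL, strains = NULL,
                       is_reference = NULL, chrom = "chr1") {
  n_site <- nrow(geno); n_samp <- ncol(geno)
  if (is.null(depth)) depth <- matrix(30L, n_site, n_samp)
  if (is.null(qual)) qual <- rep(60, n_site)
  if (is.null(strains)) {
    strains <- if (!is.null(colnames(geno))) colnames(geno) else
      paste0("S", seq_len(n_samp))
  }
  if (is.null(is_reference)) is_reference <- rep(FALSE, n_samp)
  genotype_panel(
    samples = data.frame(sample_id = paste0(strains, "_r1"),
                         strain = strains,
                         substrain = paste0(strains, "/1"),
                         is_reference = is_reference),
    sites = data.frame(chrom = chrom, pos = seq_len(n_site) * 100L,
                       ref = "A", alt = "T", qual = qual),
    geno = geno, depth = depth)
}

# implementation-side boundary list in the oracle's coordinate convention
segment_bounds_of <- function(y, prm) {
  seg <- cbs_segment(y, seq_along(y) * 10, prm)
  b <- seg$last[seg$last < length(y)]
  sort(as.integer(b))
}
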