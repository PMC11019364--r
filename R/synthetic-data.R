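#' Simulation configuration for synthetic inbred genotype panels
#'
#' Builds a validated configuration for [generate_panel()]. Defaults emulate
#' the statistical structure of a joint call set over a panel of inbred rat
#' strains: roughly 6 variant sites per kb, ~98% of non-reference calls
#' homozygous at the sample level, a small residual heterozygosity and
#' missingness, and Poisson read depth. Collapsed-repeat regions are planted
#' as intervals where every sample shows an elevated rate of heterozygous or
#' missing calls and doubled read depth, the signature of two tandem copies
#' folded into one reference segment. Shared error sites (wrong reference
#' base) are planted as sites where every sample carries a non-reference
#' genotype.
#'
#' @param n_strains number of strains to simulate; strain 1 is the
#'   reference strain (all genotypes homozygous reference away from planted
#'   artifacts, as for samples of the strain the assembly was built from).
#' @param replicates_per_strain biological replicates per strain.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param variant_density expected sites per kb (Poisson-process spacing).
#' @param background_het_rate per-site, per-sample probability of a spurious
#'   heterozygous call outside planted regions.
#' @param missing_rate per-site, per-sample probability of a no-call.
#' @param collapsed_regions data.frame with columns `chrom`, `start`, `end`
#'   (1-based, inclusive), `het_na_rate`, `depth_multiplier`.
#' @param error_sites number of shared non-reference sites to plant; half are
#'   homozygous-alternate in all samples at baseline depth, half heterozygous
#'   in all samples at doubled depth (the collapsed-repeat depth signature).
#' @param base_depth mean read depth (Poisson).
#' @param alt_freq per-site probability that a given non-reference strain
#'   carries the alternate allele (homozygous).
#' @param label_swaps list of length-2 integer vectors; after generation the
#'   sample metadata (ids and strain labels) of each pair is exchanged,
#'   leaving genotypes in place, to emulate sample mislabeling.
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 20,
                       replicates_per_strain = 2,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                       variant_density = 6.0,
                       background_het_rate = 0.005,
                       missing_rate = 0.005,
                       collapsed_regions = NULL,
                       error_sites = 0,
                       base_depth = 40,
                       alt_freq = 0.3,
                       label_swaps = list(),
                       seed = 1L) {
  stopifnot(n_strains >= 1, replicates_per_strain >= 1,
            length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths >= 1))
  if (variant_density <= 0) stop("variant_density must be > 0")
  for (r in c(background_het_rate, missing_rate, alt_freq)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (is.null(collapsed_regions)) {
    collapsed_regions <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), het_na_rate = numeric(),
                                    depth_multiplier = numeric())
  }
  collapsed_regions <- as.data.frame(collapsed_regions)
  if (nrow(collapsed_regions)) {
    stopifnot(all(c("chrom", "start", "end", "het_na_rate",
                    "depth_multiplier") %in% names(collapsed_regions)))
    if (any(collapsed_regions$het_na_rate < 0 |
            collapsed_regions$het_na_rate > 1)) {
      stop("het_na_rate must lie in [0, 1]")
    }
    if (any(collapsed_regions$depth_multiplier < 1)) {
      stop("depth_multiplier must be >= 1")
    }
    for (i in seq_len(nrow(collapsed_regions))) {
      ch <- collapsed_regions$chrom[i]
      if (!ch %in% names(chrom_lengths)) stop("region on unknown chrom ", ch)
      if (collapsed_regions$start[i] < 1 ||
          collapsed_regions$end[i] > chrom_lengths[[ch]]) {
        stop("collapsed region outside chromosome ", ch)
      }
    }
    # overlap check within chromosome
    for (ch in unique(collapsed_regions$chrom)) {
      r <- collapsed_regions[collapsed_regions$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1L && any(r$start[-1] <= r$end[-nrow(r)])) {
        stop("overlapping collapsed regions on ", ch)
      }
    }
  }
  if (error_sites < 0) stop("error_sites must be >= 0")
  cfg <- list(n_strains = as.integer(n_strains),
              replicates_per_strain = as.integer(replicates_per_strain),
              chrom_lengths = chrom_lengths,
              variant_density = variant_density,
              background_het_rate = background_het_rate,
              missing_rate = missing_rate,
              collapsed_regions = collapsed_regions,
              error_sites = as.integer(error_sites),
              base_depth = base_depth,
              alt_freq = alt_freq,
              label_swaps = label_swaps,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic inbred genotype panel with planted truth
#'
#' Simulates a joint call set under a [sim_config()] and returns the panel
#' together with a truth record of everything planted: collapsed-repeat
#' intervals, shared error sites, swapped sample pairs, and each sample's
#' true strain label.
#'
#' Site positions follow a Poisson process with mean spacing
#' `1000 / variant_density` bp. Each non-reference strain carries the
#' alternate allele at a site with probability `alt_freq`; replicates copy
#' their strain's genotype and then receive independent background noise.
#' Inside collapsed regions every sample's call is replaced, with probability
#' `het_na_rate`, by a heterozygous call or a no-call (equal odds), and read
#' depth is multiplied by the region's `depth_multiplier`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (list: `collapsed_regions`, `error_sites`, `swapped_samples`,
#'   `true_labels`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mean_gap <- 1000 / config$variant_density

  sites_l <- list()
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    n_est <- ceiling(len / mean_gap * 1.3) + 50L
    gaps <- pmax(1L, round(stats::rexp(n_est, rate = 1 / mean_gap)))
    pos <- cumsum(gaps)
    pos <- pos[pos <= len]
    while (length(pos) && pos[length(pos)] < len - 3 * mean_gap) {
      extra <- pos[length(pos)] +
        cumsum(pmax(1L, round(stats::rexp(50, rate = 1 / mean_gap))))
      pos <- c(pos, extra[extra <= len])
    }
    sites_l[[ch]] <- as.integer(unique(pos))
  }
  chrom <- rep(names(sites_l), lengths(sites_l))
  pos <- unlist(sites_l, use.names = FALSE)
  n_site <- length(pos)
  if (n_site == 0L) stop("no sites generated; chromosome too short")

  ns <- config$n_strains
  reps <- config$replicates_per_strain
  n_samp <- ns * reps
  strain_names <- c("REFSTR", sprintf("STR%02d", seq_len(max(ns - 1L, 0L))))
  strain_names <- strain_names[seq_len(ns)]

  # per-strain hom-alt draws; strain 1 (reference strain) is always hom-ref
  base <- matrix(0L, n_site, ns)
  if (ns > 1L) {
    draw <- matrix(stats::runif(n_site * (ns - 1L)) < config$alt_freq,
                   n_site, ns - 1L)
    # joint calling only emits sites where some sample is non-reference:
    # force one non-reference strain to carry the alternate where none does
    none <- !rowSums(draw)
    if (any(none)) {
      forced <- sample.int(ns - 1L, sum(none), replace = TRUE)
      draw[cbind(which(none), forced)] <- TRUE
    }
    base[, -1L][draw] <- 2L
  }

  strain_of <- rep(seq_len(ns), each = reps)
  geno <- base[, strain_of, drop = FALSE]

  # independent background noise per sample
  if (config$background_het_rate > 0) {
    hit <- matrix(stats::runif(n_site * n_samp) < config$background_het_rate,
                  n_site, n_samp)
    geno[hit] <- 1L
  }
  if (config$missing_rate > 0) {
    hit <- matrix(stats::runif(n_site * n_samp) < config$missing_rate,
                  n_site, n_samp)
    geno[hit] <- NA_integer_
  }

  depth_mean <- matrix(config$base_depth, n_site, n_samp)

  # planted collapsed-repeat regions: elevated het+NA in every sample,
  # depth multiplied
  cr <- config$collapsed_regions
  truth_regions <- cr
  for (i in seq_len(nrow(cr))) {
    in_reg <- chrom == cr$chrom[i] & pos >= cr$start[i] & pos <= cr$end[i]
    if (!any(in_reg)) next
    k <- sum(in_reg)
    hit <- matrix(stats::runif(k * n_samp) < cr$het_na_rate[i], k, n_samp)
    as_het <- matrix(stats::runif(k * n_samp) < 0.5, k, n_samp)
    sub <- geno[in_reg, , drop = FALSE]
    sub[hit & as_het] <- 1L
    sub[hit & !as_het] <- NA_integer_
    geno[in_reg, ] <- sub
    depth_mean[in_reg, ] <- depth_mean[in_reg, ] * cr$depth_multiplier[i]
  }

  # planted shared error sites (wrong reference base): all samples
  # non-reference; half hom-alt at baseline depth, half het at doubled depth
  err_truth <- data.frame(chrom = character(), pos = integer(),
                          class = character())
  if (config$error_sites > 0L) {
    in_any_reg <- rep(FALSE, n_site)
    for (i in seq_len(nrow(cr))) {
      in_any_reg <- in_any_reg |
        (chrom == cr$chrom[i] & pos >= cr$start[i] & pos <= cr$end[i])
    }
    free <- which(!in_any_reg)
    if (length(free) < config$error_sites) {
      stop("not enough sites outside collapsed regions to plant error sites")
    }
    idx <- sort(sample(free, config$error_sites))
    n_hom <- ceiling(length(idx) / 2)
    hom_idx <- idx[seq_len(n_hom)]
    het_idx <- setdiff(idx, hom_idx)
    geno[hom_idx, ] <- 2L
    if (length(het_idx)) {
      geno[het_idx, ] <- 1L
      depth_mean[het_idx, ] <- depth_mean[het_idx, ] * 2
    }
    err_truth <- data.frame(
      chrom = chrom[idx], pos = pos[idx],
      class = ifelse(idx %in% hom_idx, "HOM_SHARED", "HET_SHARED"))
  }

  # depth is drawn for every call, including no-calls: joint callers
  # record DP even where GT is missing
  depth <- matrix(stats::rpois(n_site * n_samp, lambda = depth_mean),
                  n_site, n_samp)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_site, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  qual <- round(stats::runif(n_site, 40, 90), 1)

  samples <- data.frame(
    sample_id = paste0(strain_names[strain_of], "_r",
                       rep(seq_len(reps), times = ns)),
    strain = strain_names[strain_of],
    substrain = paste0(strain_names[strain_of], "/1"),
    is_reference = strain_of == 1L,
    stringsAsFactors = FALSE)
  true_labels <- data.frame(sample_index = seq_len(n_samp),
                            true_strain = samples$strain,
                            stringsAsFactors = FALSE)

  # label swaps touch metadata only; genotype columns stay in place
  for (pr in config$label_swaps) {
    stopifnot(length(pr) == 2L)
    i <- pr[1]; j <- pr[2]
    samples[c(i, j), c("sample_id", "strain", "substrain", "is_reference")] <-
      samples[c(j, i), c("sample_id", "strain", "substrain", "is_reference")]
  }

  ord <- order(match(chrom, names(config$chrom_lengths)), pos)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      qual = qual, stringsAsFactors = FALSE)[ord, ]
  rownames(sites) <- NULL
  panel <- genotype_panel(samples, sites,
                          geno[ord, , drop = FALSE],
                          depth[ord, , drop = FALSE])
  truth <- list(collapsed_regions = truth_regions,
                error_sites = err_truth,
                swapped_samples = config$label_swaps,
                true_labels = true_labels)
  list(panel = panel, truth = truth)
}

#' Generate a toy assembly FASTA with known contig structure
#'
#' Each scaffold is specified as an integer vector of run lengths: positive
#' entries are runs of random A/C/G/T sequence, negative entries are runs of
#' N. The truth lists the contig lengths obtained by splitting at N-runs of
#' at least `min_gap` bases (shorter runs stay inside a contig).
#'
#' @param scaffolds named list of integer vectors (names become FASTA
#'   headers).
#' @param seed integer seed for the random sequence content.
#' @param min_gap minimum N-run length that splits a scaffold into contigs.
#' @return list with `sequences` (named character vector),
#'   `scaffold_lengths`, and `contig_lengths` (list per scaffold).
#' @export
generate_assembly <- function(scaffolds, seed = 1L, min_gap = 10L) {
  stopifnot(is.list(scaffolds), length(scaffolds) >= 1,
            !is.null(names(scaffolds)))
  set.seed(seed)
  seqs <- character(length(scaffolds))
  contigs <- vector("list", length(scaffolds))
  for (i in seq_along(scaffolds)) {
    runs <- as.integer(scaffolds[[i]])
    if (any(runs == 0L)) stop("zero-length run in scaffold spec")
    pieces <- character(length(runs))
    for (j in seq_along(runs)) {
      pieces[j] <- if (runs[j] > 0L) {
        paste(sample(c("A", "C", "G", "T"), runs[j], replace = TRUE),
              collapse = "")
      } else strrep("N", -runs[j])
    }
    seqs[i] <- paste(pieces, collapse = "")
    # truth from run arithmetic: merge adjacent N runs, then walk, closing a
    # contig at every N run of at least min_gap; shorter N runs count toward
    # the surrounding contig
    sign_grp <- cumsum(c(TRUE, diff(runs > 0L) != 0L))
    merged <- vapply(split(runs, sign_grp), sum, integer(1))
    cur <- 0L
    cl <- integer(0)
    for (r in merged) {
      if (r > 0L) {
        cur <- cur + r
      } else if (-r >= min_gap) {
        if (cur > 0L) cl <- c(cl, cur)
        cur <- 0L
      } else {
        cur <- cur - r
      }
    }
    if (cur > 0L) cl <- c(cl, cur)
    contigs[[i]] <- cl
  }
  names(seqs) <- names(scaffolds)
  names(contigs) <- names(scaffolds)
  list(sequences = seqs,
       scaffold_lengths = nchar(seqs),
       contig_lengths = contigs)
}

#' Write sequences to a FASTA file
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Generate a synthetic UCSC chain file with an exact truth map
#'
#' Builds a source-to-target alignment over the given chromosomes in which a
#' specified fraction of source bases is deleted (unmappable) and selected
#' source blocks map to the reverse strand of the target. Target chromosomes
#' carry the same names as their sources; target blocks are laid out in
#' source order with no target-side gaps, so the target chromosome length is
#' the source length minus the deleted bases.
#'
#' The truth map is returned as a segment table from which the expected
#' target position of every mappable source base can be computed exactly
#' (see [truth_lift()]): forward segments map by offset, inverted segments
#' map with decreasing target positions.
#'
#' @param chrom_lengths named vector of source chromosome lengths (bp).
#' @param deleted_fraction fraction of source bases, per chromosome, with no
#'   target match; the deleted base count is exactly
#'   `round(deleted_fraction * length)`.
#' @param inverted_blocks data.frame with columns `chrom`, `start`, `end`
#'   (1-based, inclusive source coordinates) of blocks mapped to the minus
#'   strand; blocks must not overlap.
#' @param n_gaps number of deletion gaps per chromosome (when any bases are
#'   deleted).
#' @param seed integer seed.
#' @return list with `chain_text` (character vector of chain-format lines),
#'   `truth` (segment table: `chrom`, `src_start`, `src_end`, `mapped`,
#'   `strand`, `tgt_start`, `tgt_end`), and `target_lengths`.
#' @export
generate_chain <- function(chrom_lengths, deleted_fraction = 0,
                           inverted_blocks = NULL, n_gaps = 3L, seed = 1L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  if (deleted_fraction < 0 || deleted_fraction >= 1) {
    stop("deleted_fraction must lie in [0, 1)")
  }
  if (is.null(inverted_blocks)) {
    inverted_blocks <- data.frame(chrom = character(), start = numeric(),
                                  end = numeric())
  }
  inverted_blocks <- as.data.frame(inverted_blocks)
  for (ch in unique(inverted_blocks$chrom)) {
    b <- inverted_blocks[inverted_blocks$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (any(b$start < 1) || any(b$end > chrom_lengths[[ch]]) ||
        any(b$end < b$start)) {
      stop("inverted block outside chromosome ", ch)
    }
    if (nrow(b) > 1L && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("overlapping inverted blocks on ", ch)
    }
  }
  set.seed(seed)

  truth <- list()
  chains <- character(0)
  target_lengths <- numeric(0)
  chain_id <- 0L

  for (ch in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[ch]])
    inv <- inverted_blocks[inverted_blocks$chrom == ch, , drop = FALSE]
    inv <- inv[order(inv$start), , drop = FALSE]
    n_del <- round(deleted_fraction * L)

    # carve deletion gaps out of the non-inverted source space
    del <- data.frame(start = integer(), end = integer())
    if (n_del > 0) {
      k <- max(1L, min(n_gaps, n_del))
      sizes <- rep(n_del %/% k, k)
      sizes[seq_len(n_del %% k)] <- sizes[seq_len(n_del %% k)] + 1L
      # candidate free intervals: complement of inverted blocks
      free <- data.frame(start = c(1, inv$end + 1),
                         end = c(inv$start - 1, L))
      free <- free[free$end >= free$start, , drop = FALSE]
      placed <- data.frame(start = integer(), end = integer())
      for (s in sizes) {
        ok <- FALSE
        for (try in 1:200) {
          fi <- free[free$end - free$start + 1 >= s, , drop = FALSE]
          if (!nrow(fi)) break
          row <- fi[sample.int(nrow(fi), 1L), ]
          st <- row$start + sample.int(row$end - row$start + 2 - s, 1L) - 1L
          en <- st + s - 1L
          clash <- nrow(placed) &&
            any(placed$start <= en & placed$end >= st)
          if (!clash) {
            placed <- rbind(placed, data.frame(start = st, end = en))
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place deletion gaps on ", ch)
      }
      del <- placed[order(placed$start), , drop = FALSE]
    }

    # assemble ordered source segments: deletions, inversions, forward fill
    brk <- sort(unique(c(1, del$start, del$end + 1,
                         inv$start, inv$end + 1, L + 1)))
    seg <- data.frame(src_start = brk[-length(brk)],
                      src_end = brk[-1] - 1L)
    seg$type <- "fwd"
    for (i in seq_len(nrow(del))) {
      seg$type[seg$src_start >= del$start[i] & seg$src_end <= del$end[i]] <- "del"
    }
    for (i in seq_len(nrow(inv))) {
      seg$type[seg$src_start >= inv$start[i] & seg$src_end <= inv$end[i]] <- "rev"
    }
    # merge adjacent segments of identical type
    grp <- cumsum(c(TRUE, seg$type[-1] != seg$type[-nrow(seg)]))
    seg <- data.frame(src_start = tapply(seg$src_start, grp, min),
                      src_end = tapply(seg$src_end, grp, max),
                      type = tapply(seg$type, grp, `[`, 1L))
    rownames(seg) <- NULL

    tgt_len <- as.integer(L - n_del)
    target_lengths[ch] <- tgt_len

    # lay out target coordinates left to right over mapped segments
    tcur <- 0L  # 0-based target cursor
    seg$tgt_start <- NA_integer_
    seg$tgt_end <- NA_integer_
    for (i in seq_len(nrow(seg))) {
      if (seg$type[i] == "del") next
      w <- seg$src_end[i] - seg$src_start[i] + 1L
      seg$tgt_start[i] <- tcur + 1L          # 1-based
      seg$tgt_end[i] <- tcur + w
      tcur <- tcur + w
    }

    truth[[ch]] <- data.frame(
      chrom = ch,
      src_start = as.integer(seg$src_start),
      src_end = as.integer(seg$src_end),
      mapped = seg$type != "del",
      strand = ifelse(seg$type == "rev", "-", "+"),
      tgt_start = as.integer(seg$tgt_start),
      tgt_end = as.integer(seg$tgt_end),
      stringsAsFactors = FALSE)

    # emit chain records: one per maximal run of forward segments (deletions
    # become dt gaps), one per inverted segment (minus-strand record)
    i <- 1L
    while (i <= nrow(seg)) {
      if (seg$type[i] == "del") { i <- i + 1L; next }
      if (seg$type[i] == "fwd") {
        j <- i
        while (j < nrow(seg) && seg$type[j + 1L] != "rev") j <- j + 1L
        run <- seg[i:j, , drop = FALSE]
        keep <- run[run$type == "fwd", , drop = FALSE]
        chain_id <- chain_id + 1L
        score <- sum(keep$src_end - keep$src_start + 1L)
        hdr <- sprintf("chain %d %s %d + %d %d %s %d + %d %d %d",
                       score, ch, L, keep$src_start[1] - 1L,
                       keep$src_end[nrow(keep)], ch, tgt_len,
                       keep$tgt_start[1] - 1L, keep$tgt_end[nrow(keep)],
                       chain_id)
        sizes <- keep$src_end - keep$src_start + 1L
        nb <- nrow(keep)
        body <- character(nb)
        if (nb > 1L) {
          dt <- keep$src_start[-1] - keep$src_end[-nb] - 1L
          dq <- keep$tgt_start[-1] - keep$tgt_end[-nb] - 1L
          body[seq_len(nb - 1L)] <- sprintf("%d %d %d",
                                            sizes[-nb], dt, dq)
        }
        body[nb] <- sprintf("%d", sizes[nb])
        chains <- c(chains, hdr, body, "")
        i <- j + 1L
      } else {               # single inverted segment on the minus strand
        w <- seg$src_end[i] - seg$src_start[i] + 1L
        chain_id <- chain_id + 1L
        q_start_rev <- tgt_len - seg$tgt_end[i]      # 0-based, reversed coords
        q_end_rev <- tgt_len - (seg$tgt_start[i] - 1L)
        hdr <- sprintf("chain %d %s %d + %d %d %s %d - %d %d %d",
                       w, ch, L, seg$src_start[i] - 1L, seg$src_end[i],
                       ch, tgt_len, q_start_rev, q_end_rev, chain_id)
        chains <- c(chains, hdr, sprintf("%d", w), "")
        i <- i + 1L
      }
    }
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(chain_text = chains, truth = truth,
       target_lengths = as.integer(target_lengths) |> stats::setNames(names(target_lengths)))
}

#' Expected target position of source positions under a chain truth map
#'
#' @param truth the `truth` segment table from [generate_chain()].
#' @param chrom source chromosome name.
#' @param pos vector of 1-based source positions.
#' @return integer vector of 1-based target positions, `NA` where unmappable.
#' @export
truth_lift <- function(truth, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  t <- truth[truth$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(t))) {
    hit <- pos >= t$src_start[i] & pos <= t$src_end[i]
    if (!any(hit)) next
    if (!t$mapped[i]) next
    off <- pos[hit] - t$src_start[i]
    out[hit] <- if (t$strand[i] == "+") t$tgt_start[i] + off
                else t$tgt_end[i] - off
  }
  as.integer(out)
}
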