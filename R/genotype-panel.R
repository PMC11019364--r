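#' Genotype panel objects
#'
#' A `genotype_panel` holds jointly-called genotypes for a panel of (mostly
#' inbred) samples: a sample table, an ordered site table, and site-by-sample
#' genotype and read-depth matrices. It is the substrate of every scan in the
#' package.
#'
#' Genotypes are stored as integer allele dosages: `0` homozygous reference,
#' `1` heterozygous, `2` homozygous alternate, `NA` missing (no-call). A
#' parallel character matrix of raw GT strings is kept so that multi-allelic
#' calls survive a read/write round trip; the dosage class of a multi-allelic
#' genotype is derived from its allele indices (two identical non-zero indices
#' are homozygous alternate, two distinct indices are heterozygous, whichever
#' alternate alleles are involved).
#'
#' @param samples data.frame with columns `sample_id`, `strain`, `substrain`,
#'   `is_reference` (logical flag marking samples of the strain the reference
#'   assembly was built from).
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated for multi-allelic records), `qual`.
#' @param geno integer matrix, sites x samples, dosage coding as above.
#' @param depth integer matrix, sites x samples, per-sample read depth.
#' @param gt optional character matrix of raw GT strings (same shape).
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(samples, sites, geno, depth, gt = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "strain", "substrain", "is_reference")
  if (!all(need_s %in% names(samples))) {
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  }
  need_v <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(need_v %in% names(sites))) {
    stop("sites must have columns: ", paste(need_v, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  storage.mode(geno) <- "integer"
  storage.mode(depth) <- "integer"
  if (nrow(geno) != nrow(sites) || ncol(geno) != nrow(samples) ||
      !all(dim(depth) == dim(geno))) {
    stop("geno/depth dimensions must be n_sites x n_samples")
  }
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  # positions strictly increasing within each chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop("positions not strictly increasing on ", ch)
    }
  }
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    if (!all(dim(gt) == dim(geno))) stop("gt dimensions must match geno")
  }
  rownames(geno) <- rownames(depth) <- NULL
  colnames(geno) <- colnames(depth) <- samples$sample_id
  obj <- list(samples = samples, sites = sites, geno = geno, depth = depth,
              gt = gt)
  class(obj) <- "genotype_panel"
  obj
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d sites on %d chromosome(s)\n",
              n_samples(x), n_sites(x), length(unique(x$sites$chrom))))
  cat(sprintf("  reference-strain samples: %d\n", sum(x$samples$is_reference)))
  invisible(x)
}

#' Number of sites / samples in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' @rdname n_sites
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' Subset a panel by site index or by sample id
#'
#' @param panel a `genotype_panel`.
#' @param keep integer site indices (for `subset_sites`) or sample ids /
#'   indices (for `subset_samples`), kept in panel order.
#' @return a new `genotype_panel`.
#' @export
subset_sites <- function(panel, keep) {
  keep <- sort(unique(as.integer(keep)))
  genotype_panel(panel$samples, panel$sites[keep, , drop = FALSE],
                 panel$geno[keep, , drop = FALSE],
                 panel$depth[keep, , drop = FALSE],
                 if (!is.null(panel$gt)) panel$gt[keep, , drop = FALSE])
}

#' @rdname subset_sites
#' @export
subset_samples <- function(panel, keep) {
  if (is.character(keep)) {
    idx <- match(keep, panel$samples$sample_id)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(keep[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(keep)
  }
  genotype_panel(panel$samples[idx, , drop = FALSE], panel$sites,
                 panel$geno[, idx, drop = FALSE],
                 panel$depth[, idx, drop = FALSE],
                 if (!is.null(panel$gt)) panel$gt[, idx, drop = FALSE])
}

# dosage class from a GT string; NA for no-calls
gt_to_dosage <- function(gt) {
  a <- strsplit(gt, "[/|]")
  vapply(a, function(al) {
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai)) return(NA_integer_)
    if (ai[1] == ai[2]) {
      if (ai[1] == 0L) 0L else 2L
    } else 1L
  }, integer(1))
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}
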