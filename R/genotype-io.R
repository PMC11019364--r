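#' Read a multi-sample VCF into a genotype panel
#'
#' Parses a VCFv4.x file (via \pkg{vcfR}) into a [genotype_panel()]. Every
#' record becomes one site; multi-allelic records are preserved with their
#' raw GT strings and classified by allele indices. Input must be sorted
#' (positions strictly increasing within each chromosome) and sample ids
#' must be unique. DP is optional; absent depths are recorded as 0.
#'
#' Strain metadata is taken from `samples` when given; otherwise the strain
#' is derived from the sample id as the prefix before the first underscore
#' (the usual `STRAIN_institute` convention) and the substrain is the full
#' id.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param samples optional data.frame with columns `sample_id`, `strain`,
#'   `substrain`, `is_reference`, overriding derived metadata.
#' @param reference_strain strain name whose samples are flagged as
#'   reference-strain samples when metadata is derived.
#' @return a [genotype_panel()].
#' @export
parse_vcf <- function(path, samples = NULL, reference_strain = NULL) {
  hdr <- readLines(path, n = 2000L)
  chrom_line <- grep("^#CHROM\t", hdr)
  if (!length(chrom_line)) {
    stop("malformed VCF header: no #CHROM line found in ", path)
  }
  cols <- strsplit(hdr[chrom_line[1]], "\t")[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns: ", path)
  ids <- cols[-(1:9)]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT", return.alleles = FALSE)
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(0, nrow(gt), ncol(gt))
  dp[is.na(dp)] <- 0
  gt[is.na(gt)] <- "./."

  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      ref = fix$REF,
                      alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      stringsAsFactors = FALSE)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop("unsorted VCF: positions not strictly increasing on ", ch)
    }
  }
  geno <- apply(gt, 2, gt_to_dosage)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(gt))

  if (is.null(samples)) {
    strain <- sub("_.*$", "", ids)
    samples <- data.frame(sample_id = ids, strain = strain,
                          substrain = ids,
                          is_reference = if (is.null(reference_strain))
                            FALSE else strain == reference_strain,
                          stringsAsFactors = FALSE)
  } else {
    samples <- as.data.frame(samples)
    if (!setequal(samples$sample_id, ids)) {
      stop("samples table does not match VCF sample columns")
    }
    samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  }
  genotype_panel(samples, sites, geno, dp, gt)
}

#' Write a genotype panel to a VCF file
#'
#' Emits a minimal VCFv4.2 with per-sample GT and DP. Raw GT strings are
#' used when the panel carries them (preserving multi-allelic calls);
#' otherwise GT is reconstructed from the dosage class.
#'
#' @param panel a [genotype_panel()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$sample_id),
                     collapse = "\t")), con)
  gt <- if (!is.null(panel$gt)) panel$gt else
    matrix(dosage_to_gt(panel$geno), nrow = n_sites(panel))
  body <- matrix(paste(gt, panel$depth, sep = ":"), nrow = n_sites(panel))
  lines <- paste(panel$sites$chrom, panel$sites$pos, ".",
                 panel$sites$ref, panel$sites$alt,
                 ifelse(is.na(panel$sites$qual), ".",
                        format(panel$sites$qual, trim = TRUE)),
                 "PASS", ".", "GT:DP",
                 apply(body, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Filter variant sites by quality and exclusion list
#'
#' Keeps exactly the sites with `qual >= min_qual` (sites scored below the
#' threshold are removed) that are not in the exclusion set; site order is
#' preserved. An empty result is allowed.
#'
#' @param panel a [genotype_panel()].
#' @param min_qual phred-scaled quality threshold (default 30).
#' @param exclude optional exclusion set: a data.frame with columns `chrom`,
#'   `start`, `end` (0-based half-open intervals, BED convention) or with
#'   columns `chrom`, `pos` (1-based site list).
#' @return a filtered [genotype_panel()].
#' @export
filter_variants <- function(panel, min_qual = 30, exclude = NULL) {
  stopifnot(min_qual >= 0)
  keep <- !is.na(panel$sites$qual) & panel$sites$qual >= min_qual
  if (!is.null(exclude) && nrow(exclude)) {
    exclude <- as.data.frame(exclude)
    if (all(c("chrom", "start", "end") %in% names(exclude))) {
      for (i in seq_len(nrow(exclude))) {
        hit <- panel$sites$chrom == exclude$chrom[i] &
          panel$sites$pos > exclude$start[i] &      # 0-based half-open
          panel$sites$pos <= exclude$end[i]
        keep <- keep & !hit
      }
    } else if (all(c("chrom", "pos") %in% names(exclude))) {
      key <- paste(panel$sites$chrom, panel$sites$pos)
      keep <- keep & !(key %in% paste(exclude$chrom, exclude$pos))
    } else {
      stop("exclude must have columns chrom/start/end or chrom/pos")
    }
  }
  subset_sites(panel, which(keep))
}

#' Per-sample quality control
#'
#' Computes each sample's missing-call rate and mean read depth and removes
#' samples failing either threshold. Both boundaries are inclusive on the
#' passing side: a sample passes iff missing rate `<= max_missing` and mean
#' depth `>= min_depth`.
#'
#' @param panel a [genotype_panel()].
#' @param max_missing maximum tolerated missing-call proportion (default
#'   0.04).
#' @param min_depth minimum mean read depth (default 10).
#' @return list with `panel` (passing samples only) and `report` (data.frame
#'   per input sample: `sample_id`, `missing_rate`, `mean_depth`, `pass`).
#' @export
sample_qc <- function(panel, max_missing = 0.04, min_depth = 10) {
  stopifnot(max_missing > 0, min_depth > 0)
  miss <- colMeans(is.na(panel$geno))
  dep <- colMeans(panel$depth)
  pass <- miss <= max_missing & dep >= min_depth
  report <- data.frame(sample_id = panel$samples$sample_id,
                       missing_rate = unname(miss),
                       mean_depth = unname(dep),
                       pass = unname(pass),
                       stringsAsFactors = FALSE)
  if (!any(pass)) stop("all samples fail QC; no panel remains")
  list(panel = subset_samples(panel, which(pass)), report = report)
}

#' Per-site and per-sample summary statistics
#'
#' Over a sample subset, tabulates per site the heterozygous-call count,
#' missing-call count, non-reference carrier count (heterozygous plus
#' homozygous-alternate; missing calls are not carriers), and mean read
#' depth. Also reports each subset sample's homozygosity fraction among its
#' non-reference calls, `HOM_ALT / (HOM_ALT + HET)`, and the variant density
#' per kb in fixed genomic windows.
#'
#' @param panel a [genotype_panel()].
#' @param subset character vector of sample ids (default: all samples).
#' @param window_bp window size for the density track (default 1 Mb).
#' @return list with `site_table`, `sample_homozygosity`, and `density`
#'   (data.frame `chrom`, `window_start` 0-based, `n_sites`,
#'   `density_per_kb`).
#' @export
site_statistics <- function(panel, subset = NULL, window_bp = 1e6) {
  if (is.null(subset)) subset <- panel$samples$sample_id
  if (!length(subset)) stop("subset must be non-empty")
  idx <- match(subset, panel$samples$sample_id)
  if (anyNA(idx)) {
    stop("unknown sample(s) in subset: ",
         paste(subset[is.na(idx)], collapse = ", "))
  }
  g <- panel$geno[, idx, drop = FALSE]
  d <- panel$depth[, idx, drop = FALSE]
  site_table <- data.frame(
    chrom = panel$sites$chrom,
    pos = panel$sites$pos,
    het_count = rowSums(g == 1L, na.rm = TRUE),
    missing_count = rowSums(is.na(g)),
    nonref_count = rowSums(g >= 1L, na.rm = TRUE),
    mean_depth = rowMeans(d),
    stringsAsFactors = FALSE)

  hom <- colSums(g == 2L, na.rm = TRUE)
  het <- colSums(g == 1L, na.rm = TRUE)
  sample_homozygosity <- data.frame(
    sample_id = subset,
    hom_fraction = ifelse(hom + het > 0, hom / (hom + het), NA_real_),
    stringsAsFactors = FALSE)

  dens <- lapply(unique(panel$sites$chrom), function(ch) {
    p <- panel$sites$pos[panel$sites$chrom == ch]
    win <- floor((p - 1) / window_bp)
    tab <- table(win)
    data.frame(chrom = ch,
               window_start = as.numeric(names(tab)) * window_bp,
               n_sites = as.integer(tab),
               density_per_kb = as.integer(tab) / (window_bp / 1000))
  })
  list(site_table = site_table,
       sample_homozygosity = sample_homozygosity,
       density = do.call(rbind, dens))
}
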