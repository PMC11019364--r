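#' Scan for shared per-site reference anomalies
#'
#' Finds sites at which (nearly) all samples of an inbred panel carry a
#' non-reference genotype — the signature of a wrong base recorded in the
#' reference, or, when the shared calls are heterozygous with doubled read
#' depth, of a collapsed repeat. A site is recorded when at least
#' `min_share` samples carry a non-reference genotype (heterozygous or
#' homozygous-alternate) and, when `require_reference_strain` is set, every
#' reference-strain sample is among the non-reference carriers. The record
#' class is `HET_SHARED` when heterozygous calls are at least as frequent as
#' homozygous-alternate calls among the carriers, else `HOM_SHARED`.
#'
#' The depth summary reports the mean and SD of the per-site mean depth
#' (averaged over all samples) by class, and their HET/HOM ratio — the
#' depth-doubling diagnostic for collapsed repeats.
#'
#' @param panel a [genotype_panel()].
#' @param min_share minimum non-reference carrier count; default
#'   `ceiling(0.95 * n_samples)` ("most of the panel").
#' @param require_reference_strain if `TRUE` (default) the panel must
#'   contain reference-strain samples and all of them must be non-reference
#'   at a recorded site.
#' @return list with `records` (data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `class`, `n_nonref`, `n_het`, `mean_depth`) and `depth_summary`
#'   (data.frame per class plus `het_hom_depth_ratio` attribute; also
#'   returned as list element `het_hom_depth_ratio`).
#' @export
shared_site_scan <- function(panel,
                             min_share = ceiling(0.95 * n_samples(panel)),
                             require_reference_strain = TRUE) {
  n <- n_samples(panel)
  if (min_share < 1 || min_share > n) {
    stop("min_share must lie in [1, n_samples]")
  }
  ref_idx <- which(panel$samples$is_reference)
  if (require_reference_strain && !length(ref_idx)) {
    stop("panel has no reference-strain samples")
  }
  g <- panel$geno
  nonref <- rowSums(g >= 1L, na.rm = TRUE)
  het <- rowSums(g == 1L, na.rm = TRUE)
  hom <- rowSums(g == 2L, na.rm = TRUE)
  hit <- nonref >= min_share
  if (require_reference_strain && length(ref_idx)) {
    rf <- g[, ref_idx, drop = FALSE]
    all_ref_nonref <- rowSums(rf >= 1L, na.rm = TRUE) == length(ref_idx)
    hit <- hit & all_ref_nonref
  }
  idx <- which(hit)
  md <- rowMeans(panel$depth)
  records <- data.frame(
    chrom = panel$sites$chrom[idx],
    pos = panel$sites$pos[idx],
    ref = panel$sites$ref[idx],
    alt = panel$sites$alt[idx],
    class = ifelse(het[idx] >= hom[idx], "HET_SHARED", "HOM_SHARED"),
    n_nonref = nonref[idx],
    n_het = het[idx],
    mean_depth = md[idx],
    stringsAsFactors = FALSE)
  rownames(records) <- NULL

  summ <- do.call(rbind, lapply(c("HOM_SHARED", "HET_SHARED"), function(cl) {
    d <- records$mean_depth[records$class == cl]
    data.frame(class = cl, n = length(d),
               mean_depth = if (length(d)) mean(d) else NA_real_,
               sd_depth = if (length(d) > 1) stats::sd(d) else NA_real_)
  }))
  ratio <- summ$mean_depth[summ$class == "HET_SHARED"] /
    summ$mean_depth[summ$class == "HOM_SHARED"]
  list(records = records, depth_summary = summ,
       het_hom_depth_ratio = ratio)
}

#' Mask recorded anomaly sites out of a panel
#'
#' Removes exactly the recorded sites and reports them as a BED-style
#' exclusion table (0-based half-open). Site counts are conserved:
#' `n_sites(panel) == n_sites(masked) + nrow(records)`.
#'
#' @param panel a [genotype_panel()].
#' @param records data.frame with `chrom` and `pos` columns referring to
#'   panel sites (e.g. from [shared_site_scan()]).
#' @return list with `panel` (masked) and `bed` (data.frame `chrom`,
#'   `start`, `end`).
#' @export
mask_panel <- function(panel, records) {
  if (!nrow(records)) {
    return(list(panel = panel,
                bed = data.frame(chrom = character(), start = integer(),
                                 end = integer())))
  }
  key <- paste(panel$sites$chrom, panel$sites$pos)
  rkey <- paste(records$chrom, records$pos)
  hit <- match(rkey, key)
  if (anyNA(hit)) {
    stop("record not found in panel: ", rkey[which(is.na(hit))[1]])
  }
  bed <- data.frame(chrom = records$chrom, start = records$pos - 1L,
                    end = records$pos, stringsAsFactors = FALSE)
  list(panel = subset_sites(panel, setdiff(seq_len(n_sites(panel)), hit)),
       bed = bed)
}

#' Fold reduction in shared base-level errors between two references
#'
#' Ratio of the shared-variant count under reference `a` to that under
#' reference `b`, rounded to one decimal — the conventional headline for
#' how much an assembly update reduced base-level errors.
#'
#' @param count_ref_a,count_ref_b positive shared-variant counts.
#' @return the fold ratio `a / b`, rounded to one decimal.
#' @export
error_fold_reduction <- function(count_ref_a, count_ref_b) {
  stopifnot(count_ref_a > 0)
  if (count_ref_b <= 0) stop("zero denominator")
  round(count_ref_a / count_ref_b, 1)
}
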