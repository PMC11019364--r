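#' Pipeline configuration
#'
#' Exactly one input source is allowed: a [sim_config()] for a fully
#' synthetic run, or a VCF path for real data. Module parameters default to
#' the package-wide conventions (quality >= 30, missing <= 4%, depth >= 10,
#' scan defaults).
#'
#' @param sim a [sim_config()], or `NULL`.
#' @param vcf path to a multi-sample VCF, or `NULL`.
#' @param reference_strain strain name flagged as reference-strain when
#'   reading a VCF.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in outputs and used for every
#'   stochastic stage.
#' @param min_qual variant quality threshold.
#' @param max_missing,min_depth sample QC thresholds.
#' @param scan a [scan_params()].
#' @param min_share_frac fraction of samples defining "shared" sites.
#' @param proxy_queries strain names to proxy-match (may be empty).
#' @param chain optional path to a chain file (enables the liftover stage).
#' @param chain_chrom_lengths named vector of source chromosome lengths for
#'   the simulated-site liftover evaluation.
#' @param pairs,pos_map_a,pos_map_b optional inputs for the SNP-gene
#'   reclassification stage (see [classify_pairs()]).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, vcf = NULL, reference_strain = NULL,
                            out_dir = tempfile("refpanelqc_run_"),
                            seed = 1L, min_qual = 30, max_missing = 0.04,
                            min_depth = 10, scan = scan_params(),
                            min_share_frac = 0.95,
                            proxy_queries = character(0),
                            chain = NULL, chain_chrom_lengths = NULL,
                            pairs = NULL, pos_map_a = NULL,
                            pos_map_b = NULL) {
  if (is.null(sim) == is.null(vcf)) {
    stop("exactly one of sim / vcf must be given")
  }
  cfg <- list(sim = sim, vcf = vcf, reference_strain = reference_strain,
              out_dir = out_dir, seed = as.integer(seed),
              min_qual = min_qual, max_missing = max_missing,
              min_depth = min_depth, scan = scan,
              min_share_frac = min_share_frac,
              proxy_queries = proxy_queries, chain = chain,
              chain_chrom_lengths = chain_chrom_lengths,
              pairs = pairs, pos_map_a = pos_map_a, pos_map_b = pos_map_b)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full panel-QC pipeline
#'
#' Stages, in order: variant quality filter, per-sample QC, misassembly
#' scan over the reference-strain samples, shared-site scan and masking,
#' identity-by-state matrix / UPGMA tree / proxy and mislabel reports,
#' cross-strain sharing summary, and (when a chain file is configured) the
#' liftover evaluation and SNP-gene reclassification stages. Every stage's
#' input and output counts are recorded in a manifest; with a fixed seed a
#' rerun reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json` alongside the stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed,
                   parameters = list(min_qual = config$min_qual,
                                     max_missing = config$max_missing,
                                     min_depth = config$min_depth,
                                     alpha = config$scan$alpha,
                                     threshold = config$scan$threshold,
                                     min_width = config$scan$min_width,
                                     flicker_bp = config$scan$flicker_bp,
                                     n_perm = config$scan$n_perm,
                                     min_share_frac = config$min_share_frac),
                   stages = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "FAILED",
                                       error = conditionMessage(e))
      flush_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  truth <- NULL
  panel <- stage("input", {
    if (!is.null(config$sim)) {
      g <- generate_panel(config$sim)
      truth <- g$truth
      g$panel
    } else {
      parse_vcf(config$vcf, reference_strain = config$reference_strain)
    }
  })
  manifest$stages$input <- list(status = "OK", n_sites = n_sites(panel),
                                n_samples = n_samples(panel))

  panel <- stage("variant_filter", filter_variants(panel, config$min_qual))
  manifest$stages$variant_filter <-
    list(status = "OK", min_qual = config$min_qual,
         n_sites_kept = n_sites(panel),
         n_sites_removed = manifest$stages$input$n_sites - n_sites(panel))

  qc <- stage("sample_qc",
              sample_qc(panel, config$max_missing, config$min_depth))
  utils::write.table(qc$report, file.path(config$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$sample_qc <-
    list(status = "OK", n_samples_kept = n_samples(qc$panel),
         n_samples_removed = n_samples(panel) - n_samples(qc$panel))
  panel <- qc$panel

  scan <- stage("misassembly_scan", scan_misassembly(panel, config$scan))
  write_bed(scan$regions, file.path(config$out_dir, "flagged_regions.bed"))
  utils::write.table(scan$segments,
                     file.path(config$out_dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$misassembly_scan <-
    list(status = "OK", n_subset = length(scan$subset),
         n_segments = nrow(scan$segments),
         n_flagged_regions = nrow(scan$regions),
         flagged_bp = sum(scan$regions$end - scan$regions$start))

  shared <- stage("shared_site_scan", {
    shared_site_scan(panel,
                     min_share = ceiling(config$min_share_frac *
                                           n_samples(panel)))
  })
  utils::write.table(shared$records,
                     file.path(config$out_dir, "shared_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  masked <- stage("mask", mask_panel(panel, shared$records))
  write_bed(masked$bed, file.path(config$out_dir, "exclusion.bed"))
  manifest$stages$shared_site_scan <-
    list(status = "OK", n_records = nrow(shared$records),
         het_hom_depth_ratio = shared$het_hom_depth_ratio,
         n_sites_masked = nrow(shared$records),
         n_sites_kept = n_sites(masked$panel))
  panel <- masked$panel

  ibs <- stage("strain_genetics", ibs_matrix(panel))
  utils::write.table(round(ibs, 6),
                     file.path(config$out_dir, "ibs_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  tr <- stage("strain_genetics", upgma_tree(ibs))
  writeLines(tr$newick, file.path(config$out_dir, "tree.nwk"))
  rep <- stage("strain_genetics",
               match_and_flag(ibs, panel$samples, config$proxy_queries))
  utils::write.table(rep$mislabels,
                     file.path(config$out_dir, "mislabels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- split(panel$samples$sample_id, panel$samples$strain)
  shr <- stage("sharing_summary", sharing_summary(panel, groups))
  utils::write.table(shr$per_strain,
                     file.path(config$out_dir, "sharing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$strain_genetics <-
    list(status = "OK", n_samples = n_samples(panel),
         mean_offdiag_ibs = mean(ibs[lower.tri(ibs)]),
         n_mislabel_flags = nrow(rep$mislabels),
         n_proxy_queries = nrow(rep$proxies),
         shared_by_all = shr$shared_by_all)

  if (!is.null(config$chain)) {
    lift <- stage("liftover_eval", {
      chains <- parse_chain(config$chain)
      simulate_and_eval_liftover(config$chain_chrom_lengths, chains)
    })
    manifest$stages$liftover_eval <-
      list(status = "OK", n_input = lift$n_input,
           fraction_lifted = lift$fraction_lifted)
  }
  if (!is.null(config$pairs)) {
    cls <- stage("classify_pairs",
                 classify_pairs(config$pairs, config$pos_map_a,
                                config$pos_map_b))
    manifest$stages$classify_pairs <-
      list(status = "OK", n_pairs = nrow(cls$pairs),
           n_trans_to_cis = unname(cls$n_trans_to_cis),
           n_cis_to_trans = unname(cls$n_cis_to_trans),
           n_unchanged = unname(cls$n_unchanged))
  }

  if (!is.null(truth)) {
    manifest$truth_recovery <- list(
      n_planted_regions = nrow(truth$collapsed_regions),
      n_planted_error_sites = nrow(truth$error_sites),
      n_recovered_error_sites =
        sum(paste(shared$records$chrom, shared$records$pos) %in%
              paste(truth$error_sites$chrom, truth$error_sites$pos)))
  }
  manifest$status <- "OK"
  flush_manifest()
  invisible(manifest)
}
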