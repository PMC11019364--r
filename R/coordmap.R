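#' Parse a UCSC chain file
#'
#' Reads chain-format alignment records (header line `chain score tName
#' tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id` followed by
#' block lines `size [dt dq]`). Block arithmetic is validated against the
#' declared source and target spans; reverse-strand records are retained
#' with their strand flag. The source (lift-from) assembly is the chain
#' "target" side `t`, the destination the "query" side `q`, following the
#' convention of liftover chain files.
#'
#' @param x path to a chain file, or a character vector of chain lines.
#' @return an object of class `chain_set`: list of records, each with
#'   `score`, `t_name`, `t_size`, `t_start`, `t_end`, `q_name`, `q_size`,
#'   `q_strand`, `q_start`, `q_end`, `id`, and `blocks` (data.frame `size`,
#'   `dt`, `dq`).
#' @export
parse_chain <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain")) {
      stop("expected chain header at line ", i, ": ", lines[i])
    }
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 12L) stop("malformed chain header at line ", i)
    rec <- list(score = as.numeric(f[2]),
                t_name = f[3], t_size = as.numeric(f[4]),
                t_strand = f[5],
                t_start = as.numeric(f[6]), t_end = as.numeric(f[7]),
                q_name = f[8], q_size = as.numeric(f[9]),
                q_strand = f[10],
                q_start = as.numeric(f[11]), q_end = as.numeric(f[12]),
                id = if (length(f) >= 13L) f[13] else NA_character_)
    if (rec$t_strand != "+") stop("chain ", rec$id, ": tStrand must be +")
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    i <- i + 1L
    repeat {
      if (i > n || !nzchar(lines[i])) {
        stop("truncated chain record (id ", rec$id, ")")
      }
      b <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(b)) stop("malformed block line ", i)
      if (length(b) == 1L) {
        sizes <- c(sizes, b[1]); dts <- c(dts, 0); dqs <- c(dqs, 0)
        i <- i + 1L
        break
      } else if (length(b) == 3L) {
        sizes <- c(sizes, b[1]); dts <- c(dts, b[2]); dqs <- c(dqs, b[3])
        i <- i + 1L
      } else stop("malformed block line ", i)
    }
    if (sum(sizes) + sum(dts) != rec$t_end - rec$t_start ||
        sum(sizes) + sum(dqs) != rec$q_end - rec$q_start) {
      stop("block arithmetic does not match declared span in chain ",
           rec$id)
    }
    rec$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    # absolute block starts (0-based) on both sides, for fast lookup
    rec$tb_start <- rec$t_start + cumsum(c(0, sizes[-length(sizes)] +
                                             dts[-length(dts)]))
    rec$qb_start <- rec$q_start + cumsum(c(0, sizes[-length(sizes)] +
                                             dqs[-length(dqs)]))
    rec$tb_end <- rec$tb_start + sizes
    records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) stop("no chain records found")
  # highest score first: the winning chain for overlapping coverage
  records <- records[order(-vapply(records, `[[`, numeric(1), "score"))]
  class(records) <- "chain_set"
  records
}

#' Lift positions through a chain set
#'
#' A position inside an aligned block maps by offset; on a reverse-strand
#' chain the destination coordinate decreases as the source coordinate
#' increases. Positions falling in an alignment gap of every covering chain
#' are unmapped with reason `"gap"`; positions on chromosomes absent from
#' the chain set are unmapped with reason `"chrom_absent"`. When several
#' chains cover a position the highest-score chain wins.
#'
#' @param chains a `chain_set` from [parse_chain()].
#' @param chrom source chromosome name (scalar).
#' @param pos vector of 1-based source positions.
#' @return data.frame: `chrom`, `pos`, `mapped`, `tgt_chrom`, `tgt_pos`
#'   (1-based), `reason` (`NA`, `"gap"` or `"chrom_absent"`).
#' @export
lift_position <- function(chains, chrom, pos) {
  stopifnot(inherits(chains, "chain_set"))
  out <- data.frame(chrom = chrom, pos = pos, mapped = FALSE,
                    tgt_chrom = NA_character_, tgt_pos = NA_integer_,
                    reason = "chrom_absent", stringsAsFactors = FALSE)
  recs <- Filter(function(r) r$t_name == chrom, chains)
  if (!length(recs)) return(out)
  out$reason <- "gap"
  pos0 <- pos - 1
  todo <- rep(TRUE, length(pos))
  for (r in recs) {           # records come sorted by descending score
    if (!any(todo)) break
    cand <- which(todo & pos0 >= r$t_start & pos0 < r$t_end)
    if (!length(cand)) next
    b <- findInterval(pos0[cand], r$tb_start)
    inblk <- b >= 1 & pos0[cand] < r$tb_end[pmax(b, 1)]
    hit <- cand[inblk]
    if (!length(hit)) next
    bb <- b[inblk]
    off <- pos0[hit] - r$tb_start[bb]
    q0 <- r$qb_start[bb] + off
    if (r$q_strand == "-") q0 <- r$q_size - 1 - q0
    out$mapped[hit] <- TRUE
    out$tgt_chrom[hit] <- r$q_name
    out$tgt_pos[hit] <- as.integer(q0 + 1)
    out$reason[hit] <- NA_character_
    todo[hit] <- FALSE
  }
  out
}

#' Evaluate liftover on evenly spaced simulated sites
#'
#' Plants sites at positions `1, 1 + spacing, ...` on every chromosome and
#' lifts them, reporting the liftable fraction and the unmapped reasons.
#'
#' @param chrom_lengths named vector of source chromosome lengths.
#' @param chains a `chain_set`.
#' @param spacing distance between simulated sites (default 1000 bp).
#' @return list: `n_input`, `n_lifted`, `fraction_lifted`,
#'   `unmapped_reasons` (table), `sites` (the per-site lift table).
#' @export
simulate_and_eval_liftover <- function(chrom_lengths, chains,
                                       spacing = 1000) {
  stopifnot(spacing >= 1, length(chrom_lengths) >= 1)
  res <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    lift_position(chains, ch, seq(1, chrom_lengths[[ch]], by = spacing))
  }))
  list(n_input = nrow(res), n_lifted = sum(res$mapped),
       fraction_lifted = mean(res$mapped),
       unmapped_reasons = table(res$reason[!res$mapped]),
       sites = res)
}

#' Compare lifted and directly called variant sets
#'
#' Variants are keyed by chromosome, position and alleles. Reports the
#' three disjoint sets (matched, lifted-only, direct-only) and the
#' conventional fractions: matched over lifted, and direct-only over
#' direct.
#'
#' @param lifted,direct data.frames with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return list: `n_matched`, `n_lifted_only`, `n_direct_only`,
#'   `frac_matched_of_lifted`, `frac_direct_only_of_direct`.
#' @export
compare_lifted_vs_direct <- function(lifted, direct) {
  kl <- paste(lifted$chrom, lifted$pos, lifted$ref, lifted$alt)
  kd <- paste(direct$chrom, direct$pos, direct$ref, direct$alt)
  matched <- intersect(kl, kd)
  list(n_matched = length(matched),
       n_lifted_only = length(setdiff(kl, kd)),
       n_direct_only = length(setdiff(kd, kl)),
       frac_matched_of_lifted =
         if (length(kl)) length(matched) / length(unique(kl)) else NA_real_,
       frac_direct_only_of_direct =
         if (length(kd)) length(setdiff(kd, kl)) / length(unique(kd))
         else NA_real_)
}

#' Classify SNP-gene pairs as cis, ambiguous, or trans
#'
#' A pair is CIS when SNP and TSS share a chromosome and their distance is
#' strictly below `cis_bp`; TRANS when they are on different chromosomes or
#' the distance is strictly above `ambiguous_bp`; AMBIGUOUS otherwise
#' (distances exactly at either boundary fall here).
#'
#' @param snp_chrom,snp_pos,tss_chrom,tss_pos vectors of loci.
#' @param cis_bp cis distance bound (default 1 Mb).
#' @param ambiguous_bp trans distance bound (default 5 Mb).
#' @return character vector of classes.
#' @export
pair_class <- function(snp_chrom, snp_pos, tss_chrom, tss_pos,
                       cis_bp = 1e6, ambiguous_bp = 5e6) {
  d <- abs(snp_pos - tss_pos)
  same <- snp_chrom == tss_chrom
  ifelse(!same | d > ambiguous_bp, "TRANS",
         ifelse(d < cis_bp, "CIS", "AMBIGUOUS"))
}

#' Reclassification of SNP-gene pairs between two references
#'
#' Classifies every pair independently under two coordinate maps and
#' tabulates the conversions. Coordinate maps give the locus of every SNP
#' and gene TSS id under one reference.
#'
#' @param pairs data.frame with columns `snp_id`, `gene_id`.
#' @param pos_map_a,pos_map_b data.frames with columns `id`, `chrom`,
#'   `pos` covering every SNP and gene id in `pairs`.
#' @param cis_bp,ambiguous_bp classification bounds (see [pair_class()]).
#' @return list: `pairs` (input plus `class_a`, `class_b`), `conversion`
#'   (table of class_a x class_b), `n_trans_to_cis`, `n_cis_to_trans`,
#'   `n_unchanged`, `per_gene` (data.frame of per-gene conversion counts).
#' @export
classify_pairs <- function(pairs, pos_map_a, pos_map_b,
                           cis_bp = 1e6, ambiguous_bp = 5e6) {
  lookup <- function(map, ids, which_map) {
    i <- match(ids, map$id)
    if (anyNA(i)) {
      stop("missing coordinate in map ", which_map, " for id: ",
           ids[which(is.na(i))[1]])
    }
    map[i, , drop = FALSE]
  }
  sa <- lookup(pos_map_a, pairs$snp_id, "a")
  ga <- lookup(pos_map_a, pairs$gene_id, "a")
  sb <- lookup(pos_map_b, pairs$snp_id, "b")
  gb <- lookup(pos_map_b, pairs$gene_id, "b")
  pairs$class_a <- pair_class(sa$chrom, sa$pos, ga$chrom, ga$pos,
                              cis_bp, ambiguous_bp)
  pairs$class_b <- pair_class(sb$chrom, sb$pos, gb$chrom, gb$pos,
                              cis_bp, ambiguous_bp)
  lv <- c("CIS", "AMBIGUOUS", "TRANS")
  conv <- table(factor(pairs$class_a, lv), factor(pairs$class_b, lv))
  changed <- pairs[pairs$class_a != pairs$class_b, , drop = FALSE]
  per_gene <- if (nrow(changed)) {
    ag <- stats::aggregate(list(n = seq_len(nrow(changed))),
                           by = list(gene_id = changed$gene_id,
                                     conversion = paste0(changed$class_a,
                                                         "->",
                                                         changed$class_b)),
                           FUN = length)
    ag[order(ag$gene_id), , drop = FALSE]
  } else {
    data.frame(gene_id = character(), conversion = character(),
               n = integer())
  }
  list(pairs = pairs, conversion = conv,
       n_trans_to_cis = conv["TRANS", "CIS"],
       n_cis_to_trans = conv["CIS", "TRANS"],
       n_unchanged = sum(diag(conv)),
       per_gene = per_gene)
}

#' Genetic-map versus physical-order concordance
#'
#' For each chromosome, computes the Spearman rank correlation between
#' genetic position (cM) and physical position (bp), and flags maximal runs
#' of at least `min_run` consecutive markers whose genetic position is
#' locally decreasing — candidate misoriented (inverted) segments.
#'
#' @param markers data.frame with columns `chrom`, `cm`, `pos`, sorted by
#'   physical position within each chromosome.
#' @param min_run minimum number of markers in a flagged run (default 5).
#' @return list with `per_chrom` (data.frame: `chrom`, `n_markers`, `rho`,
#'   `n_flagged_runs`) and `runs` (data.frame: `chrom`, `start_bp`,
#'   `end_bp`, `n_markers`).
#' @export
marker_concordance <- function(markers, min_run = 5L) {
  per <- list(); runs <- list()
  for (ch in unique(markers$chrom)) {
    mk <- markers[markers$chrom == ch, , drop = FALSE]
    if (nrow(mk) < 2) stop("need at least 2 markers on ", ch)
    if (any(diff(mk$pos) <= 0)) stop("markers not sorted by position on ", ch)
    rho <- stats::cor(mk$cm, mk$pos, method = "spearman")
    dec <- diff(mk$cm) < 0
    r <- rle(dec)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fl <- which(r$values & (r$lengths + 1L) >= min_run)
    for (k in fl) {
      runs[[length(runs) + 1L]] <- data.frame(
        chrom = ch, start_bp = mk$pos[starts[k]],
        end_bp = mk$pos[ends[k] + 1L], n_markers = r$lengths[k] + 1L,
        stringsAsFactors = FALSE)
    }
    per[[length(per) + 1L]] <- data.frame(
      chrom = ch, n_markers = nrow(mk), rho = rho,
      n_flagged_runs = length(fl), stringsAsFactors = FALSE)
  }
  list(per_chrom = do.call(rbind, per),
       runs = if (length(runs)) do.call(rbind, runs) else
         data.frame(chrom = character(), start_bp = numeric(),
                    end_bp = numeric(), n_markers = integer()))
}
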