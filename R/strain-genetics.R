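#' Pairwise identity-by-state matrix
#'
#' For every sample pair, IBS is the shared-allele fraction averaged over
#' the sites at which both samples have a call: identical genotypes score 1,
#' heterozygous versus either homozygote scores 0.5, opposite homozygotes
#' score 0. Sites missing in either sample are excluded pairwise.
#'
#' @param panel a [genotype_panel()].
#' @param biallelic_snps_only if `TRUE` (default), restrict to sites with a
#'   single-base REF and a single-base, single-allele ALT.
#' @return symmetric numeric matrix with unit diagonal, sample ids as
#'   dimnames.
#' @export
ibs_matrix <- function(panel, biallelic_snps_only = TRUE) {
  if (n_samples(panel) < 2) stop("need at least 2 samples")
  g <- panel$geno
  if (biallelic_snps_only) {
    keep <- nchar(panel$sites$ref) == 1L & nchar(panel$sites$alt) == 1L &
      !grepl(",", panel$sites$alt)
    g <- g[keep, , drop = FALSE]
  }
  if (!nrow(g)) stop("no usable sites for IBS")
  n <- ncol(g)
  m <- diag(1, n)
  ids <- panel$samples$sample_id
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(both)) stop("no co-called sites for pair ",
                           ids[i], " / ", ids[j])
      m[i, j] <- m[j, i] <- mean(1 - abs(g[both, i] - g[both, j]) / 2)
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' UPGMA dendrogram from an IBS (or distance) matrix
#'
#' Standard unweighted pair-group clustering: repeatedly join the pair of
#' clusters at minimum distance; the joined node's height is half that
#' distance, and distances to the new cluster are size-weighted averages of
#' its members' distances. Ties are broken deterministically by the
#' lexicographically smallest leaf labels. The result is ultrametric by
#' construction.
#'
#' @param m symmetric matrix with dimnames. Interpreted as similarities
#'   (IBS, unit diagonal) unless `distance = TRUE`; similarities are
#'   converted as `d = 1 - IBS`.
#' @param distance set `TRUE` when `m` already holds distances.
#' @return list with `tree` (an \pkg{ape} `phylo`), `newick` (string with
#'   branch lengths), and `heights` (join heights, one per internal node).
#' @export
upgma_tree <- function(m, distance = FALSE) {
  if (!isSymmetric(unname(m))) stop("matrix must be symmetric")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <-
      paste0("S", seq_len(nrow(m)))
  d <- if (distance) m else 1 - m
  labs <- rownames(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 leaves")
  newick <- labs
  height <- rep(0, n)
  size <- rep(1L, n)
  minlab <- labs
  active <- rep(TRUE, n)
  D <- as.matrix(d)
  diag(D) <- Inf
  heights <- numeric(0)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on the smallest leaf labels involved
    k1 <- pmin(minlab[idx[cand[, 1]]], minlab[idx[cand[, 2]]])
    k2 <- pmax(minlab[idx[cand[, 1]]], minlab[idx[cand[, 2]]])
    pick <- order(k1, k2)[1]
    a <- idx[cand[pick, 1]]
    b <- idx[cand[pick, 2]]
    h <- dmin / 2
    heights <- c(heights, h)
    nk <- sprintf("(%s:%s,%s:%s)", newick[a],
                  format(h - height[a], digits = 12, trim = TRUE),
                  newick[b],
                  format(h - height[b], digits = 12, trim = TRUE))
    # size-weighted average distances to the merged cluster, stored in a
    othr <- setdiff(idx, c(a, b))
    if (length(othr)) {
      D[a, othr] <- D[othr, a] <-
        (size[a] * D[a, othr] + size[b] * D[b, othr]) / (size[a] + size[b])
    }
    newick[a] <- nk
    height[a] <- h
    size[a] <- size[a] + size[b]
    minlab[a] <- min(minlab[a], minlab[b])
    active[b] <- FALSE
  }
  nwk <- paste0(newick[which(active)], ";")
  list(tree = ape::read.tree(text = nwk), newick = nwk, heights = heights)
}

#' Proxy-strain matching and mislabeled-sample flagging
#'
#' Proxy matching: for each query strain, find the best-IBS sample outside
#' the query's own substrain(s) — the closest living relative — and report
#' whether it clears the proxy threshold (a near-identical substitute).
#'
#' Mislabel flagging: pairs of samples labeled with the same substrain are
#' expected to be nearly identical; a pair below `same_low` fires
#' `SAME_STRAIN_LOW`. Pairs labeled as different strains are expected to be
#' well separated; a pair at or above `cross_high` fires
#' `CROSS_STRAIN_HIGH`. Reports are sorted by severity (distance from the
#' threshold).
#'
#' @param m IBS matrix with sample-id dimnames.
#' @param labels data.frame with `sample_id`, `strain`, `substrain` covering
#'   every sample in `m`.
#' @param proxy_queries character vector of strain names to find proxies
#'   for (may be empty).
#' @param proxy_threshold minimum IBS for a passing proxy (default 0.995).
#' @param same_low same-substrain pairs below this IBS are flagged
#'   (default 0.97).
#' @param cross_high different-strain pairs at or above this IBS are
#'   flagged (default 0.98).
#' @return list with `proxies` (data.frame: `query`, `query_sample`,
#'   `best_sample`, `ibs`, `pass`) and `mislabels` (data.frame: `sample_a`,
#'   `sample_b`, `ibs`, `rule`, `severity`).
#' @export
match_and_flag <- function(m, labels, proxy_queries = character(0),
                           proxy_threshold = 0.995, same_low = 0.97,
                           cross_high = 0.98) {
  ids <- rownames(m)
  labels <- as.data.frame(labels)
  if (!all(ids %in% labels$sample_id)) {
    stop("labels must cover all samples in the matrix")
  }
  labels <- labels[match(ids, labels$sample_id), , drop = FALSE]

  proxies <- do.call(rbind, lapply(proxy_queries, function(q) {
    qi <- which(labels$strain == q)
    if (!length(qi)) stop("query strain absent from labels: ", q)
    own_sub <- unique(labels$substrain[qi])
    ci <- which(!(labels$substrain %in% own_sub))
    if (!length(ci)) stop("no candidate samples outside substrain of ", q)
    sub <- m[qi, ci, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    data.frame(query = q,
               query_sample = ids[qi[best[1]]],
               best_sample = ids[ci[best[2]]],
               ibs = max(sub),
               pass = max(sub) >= proxy_threshold,
               stringsAsFactors = FALSE)
  }))
  if (is.null(proxies)) {
    proxies <- data.frame(query = character(), query_sample = character(),
                          best_sample = character(), ibs = numeric(),
                          pass = logical())
  }

  flags <- list()
  n <- length(ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- m[i, j]
      if (labels$substrain[i] == labels$substrain[j] && v < same_low) {
        flags[[length(flags) + 1L]] <- data.frame(
          sample_a = ids[i], sample_b = ids[j], ibs = v,
          rule = "SAME_STRAIN_LOW", severity = same_low - v,
          stringsAsFactors = FALSE)
      } else if (labels$strain[i] != labels$strain[j] && v >= cross_high) {
        flags[[length(flags) + 1L]] <- data.frame(
          sample_a = ids[i], sample_b = ids[j], ibs = v,
          rule = "CROSS_STRAIN_HIGH", severity = v - cross_high,
          stringsAsFactors = FALSE)
      }
    }
  }
  mislabels <- if (length(flags)) do.call(rbind, flags) else
    data.frame(sample_a = character(), sample_b = character(),
               ibs = numeric(), rule = character(), severity = numeric())
  mislabels <- mislabels[order(-mislabels$severity), , drop = FALSE]
  rownames(mislabels) <- NULL
  list(proxies = proxies, mislabels = mislabels)
}

#' Cross-strain variant sharing summary
#'
#' A strain carries a site when any of its samples has a non-reference call
#' there. Reports, per strain, the total carried sites and the count unique
#' to that strain; the count carried by every strain; and a per-chromosome
#' sharing table.
#'
#' @param panel a [genotype_panel()].
#' @param groups named list mapping strain name to a character vector of
#'   sample ids (a partition of a subset of samples).
#' @return list with `per_strain` (data.frame: `strain`, `total`,
#'   `unique`), `shared_by_all` (count), and `per_chromosome` (data.frame:
#'   `chrom`, `shared_by_all`, per-strain unique counts in columns).
#' @export
sharing_summary <- function(panel, groups) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  if (any(!lengths(groups))) stop("empty group")
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("groups must not overlap")
  idx <- match(all_ids, panel$samples$sample_id)
  if (anyNA(idx)) stop("unknown sample in groups")

  carrier <- vapply(groups, function(sid) {
    gi <- match(sid, panel$samples$sample_id)
    rowSums(panel$geno[, gi, drop = FALSE] >= 1L, na.rm = TRUE) > 0L
  }, logical(n_sites(panel)))
  if (is.null(dim(carrier))) carrier <- matrix(carrier, ncol = length(groups))
  colnames(carrier) <- names(groups)

  n_carriers <- rowSums(carrier)
  uniq <- carrier & n_carriers == 1L
  per_strain <- data.frame(strain = names(groups),
                           total = colSums(carrier),
                           unique = colSums(uniq),
                           stringsAsFactors = FALSE)
  rownames(per_strain) <- NULL
  shared_all <- sum(n_carriers == length(groups))

  per_chrom <- do.call(rbind, lapply(unique(panel$sites$chrom), function(ch) {
    r <- panel$sites$chrom == ch
    cbind(data.frame(chrom = ch,
                     shared_by_all = sum(n_carriers[r] == length(groups))),
          as.data.frame(t(colSums(uniq[r, , drop = FALSE]))))
  }))
  list(per_strain = per_strain, shared_by_all = shared_all,
       per_chromosome = per_chrom)
}

#' Write a square distance or IBS matrix in PHYLIP-style layout
#' @param m square matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  writeLines(paste(formatC(rownames(m), width = 12, flag = "-"),
                   apply(m, 1, function(r)
                     paste(formatC(r, digits = 6, format = "f"),
                           collapse = " "))), con)
  invisible(path)
}
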