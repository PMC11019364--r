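#' Contig lengths of a scaffold sequence
#'
#' Splits a scaffold at maximal runs of N of length at least `min_gap`;
#' shorter N-runs remain inside a contig and count toward its length.
#' Lowercase is accepted and ambiguity codes other than N count as non-gap.
#' An all-gap scaffold has no contigs.
#'
#' @param sequence nucleotide string.
#' @param min_gap minimum N-run length defining a gap (default 10).
#' @return integer vector of contig lengths (possibly empty).
#' @export
contig_lengths_from_sequence <- function(sequence, min_gap = 10L) {
  if (!nzchar(sequence)) return(integer(0))
  pieces <- strsplit(toupper(sequence),
                     sprintf("N{%d,}", as.integer(min_gap)))[[1]]
  out <- nchar(pieces)
  as.integer(out[out > 0L])
}

#' Nx / Lx contiguity statistics
#'
#' Sorts lengths in decreasing order; `Nx` is the length at which the
#' cumulative sum first reaches `x`% of the total, and `Lx` is the number of
#' sequences in that prefix. `Nx` is always a member of the input multiset.
#'
#' @param lengths numeric vector of sequence lengths (non-empty).
#' @param x percentage in (0, 100); default 50.
#' @return list with elements `nx` and `lx`.
#' @export
nx_stats <- function(lengths, x = 50) {
  if (!length(lengths)) stop("empty length set")
  stopifnot(x > 0, x < 100)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  i <- which(cs >= x / 100 * cs[length(cs)])[1]
  list(nx = s[i], lx = as.integer(i))
}

#' Summarize an assembly's contiguity
#'
#' Every FASTA record is a scaffold; contigs are obtained by splitting
#' scaffolds at N-runs of at least `min_gap` bases. No minimum-length
#' filtering is applied at any point.
#'
#' @param x path to a (multi-record) FASTA file, or a named character vector
#'   of sequences.
#' @param min_gap minimum N-run length defining a gap.
#' @return An object of class `assembly_summary`: list with
#'   `scaffold_lengths`, `contig_lengths`, `total_length`,
#'   `ungapped_length`, `scaffold_n50`, `scaffold_l50`, `contig_n50`,
#'   `contig_l50`, `n_scaffolds`, `n_contigs`.
#' @export
assembly_summary <- function(x, min_gap = 10L) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    seqs <- as.character(ss)
  } else {
    seqs <- as.character(x)
  }
  if (!length(seqs)) stop("no sequences")
  scaf <- nchar(seqs)
  contigs <- unlist(lapply(seqs, contig_lengths_from_sequence,
                           min_gap = min_gap), use.names = FALSE)
  sn <- nx_stats(scaf)
  cn <- if (length(contigs)) nx_stats(contigs) else list(nx = NA, lx = NA)
  out <- list(scaffold_lengths = unname(scaf),
              contig_lengths = as.integer(contigs),
              total_length = sum(scaf),
              ungapped_length = sum(contigs),
              scaffold_n50 = sn$nx, scaffold_l50 = sn$lx,
              contig_n50 = cn$nx, contig_l50 = cn$lx,
              n_scaffolds = length(scaf), n_contigs = length(contigs))
  class(out) <- "assembly_summary"
  out
}

#' Construct an assembly summary from known length multisets
#'
#' Useful when published scaffold/contig statistics are available without
#' the underlying FASTA.
#'
#' @param scaffold_lengths,contig_lengths numeric length multisets.
#' @return an `assembly_summary`.
#' @export
assembly_summary_from_lengths <- function(scaffold_lengths, contig_lengths) {
  sn <- nx_stats(scaffold_lengths)
  cn <- nx_stats(contig_lengths)
  out <- list(scaffold_lengths = scaffold_lengths,
              contig_lengths = contig_lengths,
              total_length = sum(scaffold_lengths),
              ungapped_length = sum(contig_lengths),
              scaffold_n50 = sn$nx, scaffold_l50 = sn$lx,
              contig_n50 = cn$nx, contig_l50 = cn$lx,
              n_scaffolds = length(scaffold_lengths),
              n_contigs = length(contig_lengths))
  class(out) <- "assembly_summary"
  out
}

#' @exportS3Method base::print
print.assembly_summary <- function(x, ...) {
  cat(sprintf(paste0("assembly_summary: %d scaffolds (N50 %s, L50 %d), ",
                     "%d contigs (N50 %s, L50 %s)\n"),
              x$n_scaffolds, format(x$scaffold_n50, big.mark = ","),
              x$scaffold_l50, x$n_contigs,
              format(x$contig_n50, big.mark = ","),
              format(x$contig_l50)))
  cat(sprintf("  total %s bp, ungapped %s bp\n",
              format(x$total_length, big.mark = ","),
              format(x$ungapped_length, big.mark = ",")))
  invisible(x)
}

#' Fold-ratio comparison of two assemblies
#'
#' Reports the conventional improvement ratios of assembly `b` over
#' assembly `a`: the contig N50 gain (`b` over `a`) and the contig and
#' scaffold count reductions (`a` over `b`). Ratios of at least 100 are also
#' reported rounded to the nearest 10 (N50 gain) or nearest integer (count
#' folds), the precision at which such folds are conventionally quoted.
#'
#' @param a,b `assembly_summary` objects (`a` the older assembly).
#' @return list with `contig_n50_fold`, `contig_count_fold`,
#'   `scaffold_count_fold`, their rounded forms (`*_rounded`), and the two
#'   total lengths.
#' @export
compare_assemblies <- function(a, b) {
  stopifnot(inherits(a, "assembly_summary"), inherits(b, "assembly_summary"))
  if (a$contig_n50 == 0 || b$n_contigs == 0 || b$n_scaffolds == 0) {
    stop("zero denominator in assembly comparison")
  }
  n50_fold <- b$contig_n50 / a$contig_n50
  cc_fold <- a$n_contigs / b$n_contigs
  sc_fold <- a$n_scaffolds / b$n_scaffolds
  # conventional quoting: N50 gains of 100x or more to the nearest 10,
  # count folds to the nearest integer
  list(contig_n50_fold = n50_fold,
       contig_n50_fold_rounded =
         if (n50_fold >= 100) round(n50_fold / 10) * 10 else n50_fold,
       contig_count_fold = cc_fold,
       contig_count_fold_rounded = round(cc_fold),
       scaffold_count_fold = sc_fold,
       total_length_a = a$total_length,
       total_length_b = b$total_length)
}

#' Write an assembly summary as a tab-separated table
#' @param x an `assembly_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly_summary <- function(x, path) {
  df <- data.frame(
    metric = c("Total sequence length", "Total ungapped length",
               "No. of scaffolds", "Scaffold N50", "Scaffold L50",
               "No. of contigs", "Contig N50", "Contig L50"),
    value = c(x$total_length, x$ungapped_length, x$n_scaffolds,
              x$scaffold_n50, x$scaffold_l50, x$n_contigs, x$contig_n50,
              x$contig_l50))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
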