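# Reading repeat catalogs and sequences; preprocessing filters for
# genome-scale repeat analysis.

#' Read and write FASTA sequences
#'
#' Thin wrappers around Biostrings. `read_fasta()` returns the records in
#' file order as a named character vector (full header line as name,
#' multi-line sequences joined).
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Tandem Repeats Finder table
#'
#' Parses the `.dat` output dialect of Tandem Repeats Finder: per-chromosome
#' `Sequence:` headers followed by whitespace-separated data rows with
#' fields start, end, period size, copy number, consensus size, percent
#' matches, percent indels, score, A, C, G, T, entropy, consensus pattern,
#' repeat sequence. Unparseable rows are skipped with a warning carrying the
#' line number.
#'
#' @param path file path.
#' @return A `repeat_catalog` data frame with columns `id`, `chrom`,
#'   `start`, `end` (1-based inclusive), `period` (pattern length d),
#'   `copy_number`, `consensus_size`, `pct_match`, `indel_pct`, `score`,
#'   `entropy`, `consensus`, `sequence`.
#' @export
read_trf_table <- function(path) {
  lines <- readLines(path)
  chrom <- NA_character_
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (grepl("^Sequence:", line)) {
      chrom <- trimws(sub("^Sequence:\\s*", "", line))
      chrom <- strsplit(chrom, "\\s+")[[1L]][1L]
      next
    }
    if (grepl("^(Tandem|Gary|Program|Version|Parameters:)", line)) next
    f <- strsplit(line, "\\s+")[[1L]]
    if (length(f) < 15L || is.na(suppressWarnings(as.numeric(f[1L])))) {
      if (grepl("^[0-9]", line))
        warning("skipping unparseable row at line ", ln, call. = FALSE)
      next
    }
    num <- suppressWarnings(as.numeric(f[1:13]))
    if (anyNA(num)) {
      warning("skipping unparseable row at line ", ln, call. = FALSE)
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = chrom, start = as.integer(num[1L]), end = as.integer(num[2L]),
      period = as.integer(num[3L]), copy_number = num[4L],
      consensus_size = as.integer(num[5L]), pct_match = num[6L],
      indel_pct = num[7L], score = num[8L], entropy = num[13L],
      consensus = f[14L], sequence = f[15L])
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               period = integer(), copy_number = numeric(),
               consensus_size = integer(), pct_match = numeric(),
               indel_pct = numeric(), score = numeric(), entropy = numeric(),
               consensus = character(), sequence = character())
  out <- cbind(id = if (nrow(out)) paste0(out$chrom, ":", out$start, "-",
                                          out$end) else character(), out)
  class(out) <- c("repeat_catalog", "data.frame")
  out
}

#' Write/read a repeat catalog as TSV
#'
#' Plain-text round-trippable representation of a `repeat_catalog`
#' (coordinates are 1-based inclusive).
#'
#' @param records a `repeat_catalog` data frame.
#' @param path file path.
#' @export
write_repeat_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_repeat_table
#' @export
read_repeat_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("repeat_catalog", "data.frame")
  out
}

#' Preprocess a repeat catalog
#'
#' Applies the filters used before genome-scale estimation:
#' \itemize{
#'   \item remove repeats containing unknown (N) bases;
#'   \item remove repeats with copy number below 2 (reported catalog value,
#'     which may be fractional);
#'   \item remove repeats with nonzero indel percentage (the model has no
#'     insertions or deletions);
#'   \item among overlapping repeats (any intersection, per chromosome),
#'     keep exactly one: the highest score, ties broken by length, then by
#'     earliest start.
#' }
#'
#' @param records a `repeat_catalog` data frame.
#' @param verbose print counts removed by each rule.
#' @return The filtered catalog, with attribute `filter_counts` recording
#'   removals per rule. Output intervals are pairwise disjoint.
#' @export
preprocess_repeats <- function(records, verbose = FALSE) {
  records <- as.data.frame(records)
  n0 <- nrow(records)
  has_n <- grepl("[^ACGTacgt]", records$sequence)
  records <- records[!has_n, , drop = FALSE]
  n1 <- nrow(records)
  records <- records[records$copy_number >= 2, , drop = FALSE]
  n2 <- nrow(records)
  records <- records[records$indel_pct == 0, , drop = FALSE]
  n3 <- nrow(records)
  if (nrow(records)) {
    keep <- unlist(lapply(split(seq_len(nrow(records)), records$chrom),
                          function(idx) {
      r <- records[idx, , drop = FALSE]
      ir <- IRanges::IRanges(start = r$start, end = r$end)
      cl <- S4Vectors::subjectHits(
        IRanges::findOverlaps(ir, IRanges::reduce(ir)))
      unlist(lapply(split(seq_along(idx), cl), function(ii) {
        rr <- r[ii, , drop = FALSE]
        o <- order(-rr$score, -(rr$end - rr$start), rr$start)
        idx[ii][o[1L]]
      }))
    }), use.names = FALSE)
    records <- records[sort(keep), , drop = FALSE]
  }
  counts <- c(input = n0, N_bases = n0 - n1, low_copy = n1 - n2,
              indels = n2 - n3, overlap = n3 - nrow(records),
              kept = nrow(records))
  if (verbose)
    message(paste(names(counts), counts, sep = ": ", collapse = "  "))
  rownames(records) <- NULL
  class(records) <- c("repeat_catalog", "data.frame")
  attr(records, "filter_counts") <- counts
  records
}
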