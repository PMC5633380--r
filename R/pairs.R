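# Aligned read pairs are plain data.frames (one row per pair) with 0-based
# half-open coordinates: id, chrom, start1, end1, strand1, start2, end2,
# strand2, proper. SAM/BAM 1-based coordinates are converted at the boundary.

.PAIR_COLS <- c("id", "chrom", "start1", "end1", "strand1",
                "start2", "end2", "strand2", "proper")

#' Construct an aligned-pair table
#'
#' @param id Read-pair identifiers.
#' @param chrom Chromosome (both mates; properly paired reads share one).
#' @param start1,end1,start2,end2 0-based half-open mate coordinates.
#' @param strand1,strand2 `"+"` or `"-"`.
#' @param proper Logical properly-paired flag.
#' @return `data.frame` with one row per pair.
#' @export
aligned_pairs <- function(id, chrom, start1, end1, strand1,
                          start2, end2, strand2, proper = TRUE) {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start1 = as.integer(start1), end1 = as.integer(end1),
                   strand1 = as.character(strand1),
                   start2 = as.integer(start2), end2 = as.integer(end2),
                   strand2 = as.character(strand2),
                   proper = as.logical(proper))
  bad <- df$start1 < 0 | df$end1 <= df$start1 | df$start2 < 0 |
    df$end2 <= df$start2
  if (any(bad)) stop("invalid pair coordinates (0-based half-open required)")
  if (!all(c(df$strand1, df$strand2) %in% c("+", "-"))) {
    stop("strands must be '+' or '-'")
  }
  df
}

#' Read aligned read pairs from SAM/BAM
#'
#' Loads properly-paired primary alignments via
#' [GenomicAlignments::readGAlignmentPairs()] and converts them to the
#' package's 0-based half-open pair table.
#'
#' @param path SAM or BAM file. SAM files are converted in a temporary
#'   directory with [Rsamtools::asBam()].
#' @return An aligned-pair `data.frame` (see [aligned_pairs()]).
#' @export
read_aligned_pairs <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = TRUE)
  }
  gap <- GenomicAlignments::readGAlignmentPairs(
    path, use.names = TRUE,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                    isSecondaryAlignment = FALSE)))
  f <- GenomicAlignments::first(gap)
  s <- GenomicAlignments::second(gap)
  if (length(gap) == 0L) {
    return(aligned_pairs(character(0), character(0), integer(0), integer(0),
                         character(0), integer(0), integer(0), character(0),
                         logical(0)))
  }
  aligned_pairs(
    id = names(gap),
    chrom = as.character(GenomicAlignments::seqnames(f)),
    start1 = GenomicAlignments::start(f) - 1L,
    end1 = GenomicAlignments::end(f),
    strand1 = as.character(GenomicAlignments::strand(f)),
    start2 = GenomicAlignments::start(s) - 1L,
    end2 = GenomicAlignments::end(s),
    strand2 = as.character(GenomicAlignments::strand(s)),
    proper = TRUE)
}

#' Positional deduplication of read pairs
#'
#' Library amplification produces multiple read pairs from one original
#' fragment; distinct original fragments are counted as distinct read-pair
#' start/stop positional combinations. One representative (the first
#' occurrence, preserving input order) is retained per distinct coordinate
#' tuple `(chrom, start1, end1, start2, end2)` plus, when `strand_aware`,
#' both mate strands.
#'
#' @param pairs Aligned-pair `data.frame` (see [aligned_pairs()]).
#' @param strand_aware Include both strands in the deduplication key
#'   (default `TRUE`).
#' @return The deduplicated subset of `pairs`, original order preserved.
#' @export
dedupe_pairs <- function(pairs, strand_aware = TRUE) {
  stopifnot(all(.PAIR_COLS %in% names(pairs)))
  keycols <- c("chrom", "start1", "end1", "start2", "end2",
               if (strand_aware) c("strand1", "strand2"))
  key <- do.call(paste, c(unname(pairs[keycols]), sep = "\r"))
  pairs[!duplicated(key), , drop = FALSE]
}

#' Write intervals as BED
#'
#' Plain BED output, 0-based half-open, no header. Extra columns beyond
#' chrom/start/end are written in the order given.
#'
#' @param df `data.frame` whose first three columns are chrom, start, end.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Exact read mapper (test-scale)
#'
#' Finds every position where `read` or its reverse complement occurs exactly
#' in the genome, including overlapping occurrences. This is a self-contained
#' stand-in for an external aligner on small test genomes; it performs no
#' mismatch or gap handling.
#'
#' @param read DNA string, length >= 1.
#' @param genome A [ref_genome()].
#' @return `data.frame(chrom, pos, strand)` with 0-based start positions,
#'   sorted by `(chrom, pos)`; zero rows when the read is absent.
#' @export
map_exact <- function(read, genome) {
  .check_dna(read, "read")
  stopifnot(length(read) == 1L, nchar(read) >= 1L)
  seqs <- unclass(genome)
  hits <- list()
  queries <- c("+" = read)
  rc <- reverse_complement(read)
  if (!identical(rc, read)) queries <- c(queries, "-" = rc)
  else queries <- c(queries)  # palindromic read: one strand entry suffices
  for (chrom in names(seqs)) {
    subject <- Biostrings::DNAString(seqs[[chrom]])
    for (strand in names(queries)) {
      m <- Biostrings::matchPattern(queries[[strand]], subject)
      if (length(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, pos = Biostrings::start(m) - 1L, strand = strand)
      }
    }
  }
  if (identical(rc, read)) {
    # a reverse-complement palindrome matches both strands wherever it occurs
    fwd <- do.call(rbind, hits)
    if (!is.null(fwd) && nrow(fwd)) {
      hits <- list(fwd, transform(fwd, strand = "-"))
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0)))
  }
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
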