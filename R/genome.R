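# Reference genomes are named character vectors of uppercase DNA; all
# coordinates in the package are 0-based, half-open. Conversion to 1-based
# happens only at SAM boundaries; BED output stays 0-based half-open.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq)) stop(what, " must be a character vector")
  if (any(grepl("[^ACGTN]", seq))) {
    stop("non-DNA character in ", what, " (allowed: A, C, G, T, N)")
  }
  invisible(seq)
}

#' Construct a reference genome
#'
#' A reference genome is a named character vector of uppercase DNA sequences,
#' one element per chromosome, with class `"ref_genome"`.
#'
#' @param seqs Named character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return A `ref_genome` object.
#' @examples
#' g <- ref_genome(c(chrI = "ACGTACGTAC", chrM = "TTTTGGGG"))
#' chrom_lengths(g)
#' @export
ref_genome <- function(seqs) {
  if (length(seqs) > 0 && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    stop("every chromosome must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names")
  nm <- names(seqs)
  seqs <- setNames(toupper(as.character(seqs)), nm)  # toupper drops names
  .check_dna(seqs, "reference")
  structure(seqs, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome with", length(x), "chromosome(s)\n")
  if (length(x)) {
    print(data.frame(chrom = names(x), length = nchar(unclass(x)),
                     row.names = NULL))
  }
  invisible(x)
}

#' Chromosome lengths of a reference genome
#' @param genome A [ref_genome()].
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Read and write reference FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]. Record names are truncated at the first
#' whitespace; duplicate names are an error. Reading back a written genome
#' reproduces it exactly (up to line wrapping).
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a [ref_genome()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate chromosome names in FASTA: ", path)
  ref_genome(setNames(as.character(ss), nm))
}

#' @rdname read_fasta
#' @param genome A [ref_genome()].
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Genomic interval (0-based, half-open)
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @return An `interval` object (a small list).
#' @export
interval <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    stop("invalid interval: require 0 <= start < end")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d\n", x$chrom, x$start, x$end)); invisible(x)
}

.check_interval_bounds <- function(iv, genome) {
  len <- chrom_lengths(genome)
  if (!iv$chrom %in% names(len)) stop("chromosome not in genome: ", iv$chrom)
  if (iv$end > len[[iv$chrom]]) {
    stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                 iv$chrom, iv$start, iv$end, len[[iv$chrom]]))
  }
  invisible(iv)
}

#' Extract a genomic interval as a circular molecule
#'
#' Models eccDNA formation from a specific region of the linear genome: the
#' interval's sequence becomes a covalently closed circle whose stored rotation
#' starts at the interval start, recorded as the molecule's origin.
#'
#' @param genome A [ref_genome()].
#' @param iv An [interval()] within chromosome bounds.
#' @return A circular [molecule()] with `origin = iv`.
#' @export
extract_circle_from_genome <- function(genome, iv) {
  stopifnot(inherits(iv, "interval"))
  .check_interval_bounds(iv, genome)
  bases <- substr(unclass(genome)[[iv$chrom]], iv$start + 1L, iv$end)
  molecule(bases, topology = "circular", origin = iv)
}
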