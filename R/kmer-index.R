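# Canonical k-mer index over a reference genome, the machinery behind
# placement of reads in unique and repetitive genome space. Stored as a keyed
# data.table for binary-search lookup.

#' Build a canonical k-mer index
#'
#' Every position of every chromosome contributes one entry under the
#' canonical form of its k-mer (the lexicographic minimum of the k-mer and
#' its reverse complement); k-mers containing `N` are skipped. Chromosomes
#' shorter than `k` contribute nothing.
#'
#' @param genome A [ref_genome()].
#' @param k K-mer length; the default 31 is a standard odd choice that rules
#'   out reverse-complement palindromes.
#' @return A `kmer_index`: `list(k, table, genome, n_skipped)` where `table`
#'   is a `data.table(kmer, chrom, pos, strand)` keyed on `kmer`, `pos` is
#'   0-based, and `strand` is `"+"` when the genome's forward k-mer equals
#'   the canonical form.
#' @export
build_kmer_index <- function(genome, k = 31L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  lens <- chrom_lengths(genome)
  if (length(lens) == 0L || all(lens < k)) {
    stop("k = ", k, " exceeds the length of every chromosome")
  }
  chunks <- list()
  n_skipped <- 0L
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(unclass(genome)[[chrom]], starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    kmers <- kmers[ok]
    starts <- starts[ok]
    rc <- reverse_complement(kmers)
    fwd_is_canon <- kmers <= rc
    chunks[[length(chunks) + 1L]] <- data.table::data.table(
      kmer = ifelse(fwd_is_canon, kmers, rc),
      chrom = chrom,
      pos = starts - 1L,
      strand = ifelse(fwd_is_canon, "+", "-"))
  }
  table <- data.table::rbindlist(chunks)
  data.table::setkeyv(table, c("kmer", "chrom", "pos"))
  structure(list(k = k, table = table, genome = genome,
                 n_skipped = n_skipped),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k = %d, %d positions over %d chromosome(s)\n",
              x$k, nrow(x$table), length(x$genome)))
  invisible(x)
}

# Genomic start positions where the forward genome sequence equals `q`,
# found through the index by looking up q's first k-mer and verifying the
# full match against the genome (equivalent to requiring every k-mer of q at
# its offset-consistent position).
.index_starts <- function(q, index) {
  k <- index$k
  fk <- substr(q, 1L, k)
  if (grepl("N", fk, fixed = TRUE)) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  rcfk <- reverse_complement(fk)
  canon <- if (fk <= rcfk) fk else rcfk
  rows <- index$table[list(canon), nomatch = NULL]
  if (nrow(rows) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  want <- if (identical(fk, rcfk)) c("+", "-")
          else if (fk <= rcfk) "+" else "-"
  rows <- rows[rows$strand %in% want]
  if (nrow(rows) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  lens <- chrom_lengths(index$genome)
  n <- nchar(q)
  keep <- rows$pos + n <= lens[rows$chrom] &
    substring(unclass(index$genome)[rows$chrom], rows$pos + 1L,
              rows$pos + n) == q
  unique(data.frame(chrom = rows$chrom[keep], pos = rows$pos[keep]))
}

#' Locate a read in the genome through the k-mer index
#'
#' Reports a placement at position p (strand s) iff every k-mer of the read
#' occurs at the offset-consistent position implied by (p, s) -- equivalent
#' to exact full-read matching, computed through the index: candidate
#' positions come from the read's first k-mer, then the full read is verified
#' against the genome. Agrees with [map_exact()] on every genome.
#'
#' @param read DNA string with `nchar(read) >= k`.
#' @param index A [build_kmer_index()] result.
#' @return Placement set: `data.frame(chrom, pos, strand)`, 0-based starts,
#'   sorted, duplicates removed; zero rows for unplaceable reads.
#' @export
locate_read <- function(read, index) {
  stopifnot(inherits(index, "kmer_index"))
  .check_dna(read, "read")
  if (nchar(read) < index$k) {
    stop("read shorter than k = ", index$k)
  }
  rc <- reverse_complement(read)
  fwd <- .index_starts(read, index)
  placements <- list()
  if (nrow(fwd)) placements[[1L]] <- transform(fwd, strand = "+")
  if (identical(rc, read)) {
    # reverse-complement palindrome: every occurrence matches both strands
    if (nrow(fwd)) placements[[2L]] <- transform(fwd, strand = "-")
  } else {
    rev <- .index_starts(rc, index)
    if (nrow(rev)) {
      placements[[length(placements) + 1L]] <- transform(rev, strand = "-")
    }
  }
  out <- do.call(rbind, placements)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0)))
  }
  out <- unique(out)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
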