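# DNA molecules with explicit topology. Circular molecules store an explicit
# rotation (deterministic serialization); rotation-invariant comparison lives
# in the test helpers, not here.

#' DNA molecule with topology
#'
#' @param bases DNA string over `{A,C,G,T,N}`, length >= 1.
#' @param topology `"linear"` or `"circular"`.
#' @param origin Optional [interval()] recording the genomic origin.
#' @return A `molecule` object.
#' @examples
#' m <- molecule("ACGTACGT", "circular")
#' mol_length(m)
#' @export
molecule <- function(bases, topology = c("linear", "circular"), origin = NULL) {
  topology <- match.arg(topology)
  bases <- toupper(as.character(bases))
  if (length(bases) != 1L || nchar(bases) < 1L) {
    stop("molecule requires a single non-empty DNA string")
  }
  .check_dna(bases, "molecule")
  if (!is.null(origin)) stopifnot(inherits(origin, "interval"))
  structure(list(bases = bases, topology = topology, origin = origin),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("%s molecule, %d bp%s\n", x$topology, nchar(x$bases),
              if (is.null(x$origin)) "" else
                sprintf(" (origin %s:%d-%d)", x$origin$chrom, x$origin$start,
                        x$origin$end)))
  invisible(x)
}

#' Length of a molecule in bp
#' @param mol A [molecule()].
#' @export
mol_length <- function(mol) nchar(mol$bases)

#' Reverse complement of DNA sequences
#'
#' Vectorized Watson-Crick reverse complement; `N` maps to `N`. Input is
#' validated against the `{A,C,G,T,N}` alphabet.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAACCC")  # "GGGTTT"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  if (length(seq) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Excise the segment between two direct repeats from a circular molecule
#'
#' Models site-specific recombination between directly repeated sites (the
#' Cre/loxP mechanism used to manufacture reference DNA circles): the spacer
#' between the two repeats leaves as a circle carrying exactly one repeat
#' copy, and the rest of the parent re-closes with the other copy. Lengths are
#' conserved: `len(circle) + len(remainder) = len(parent)`.
#'
#' @param parent Circular [molecule()].
#' @param repeat_len Length in bp of the direct repeat.
#' @param pos_a,pos_b 0-based start offsets of the two repeat copies on the
#'   stored rotation, `pos_a < pos_b`; the copies must be identical and
#'   non-overlapping. The spacer is the segment between the end of copy A and
#'   the start of copy B.
#' @return List with circular molecules `circle` (spacer + one repeat) and
#'   `remainder` (everything else + one repeat).
#' @examples
#' # 10-bp repeats flanking a 5-bp spacer on a 100-bp backbone
#' rep <- "ACGTACGTAC"
#' parent <- molecule(paste0(rep, "TTTTT", rep, strrep("G", 100)), "circular")
#' ex <- excise_between_direct_repeats(parent, 10, 0, 15)
#' mol_length(ex$circle)     # 15
#' mol_length(ex$remainder)  # 110
#' @export
excise_between_direct_repeats <- function(parent, repeat_len, pos_a, pos_b) {
  stopifnot(inherits(parent, "molecule"))
  if (parent$topology != "circular") stop("parent must be circular")
  L <- mol_length(parent)
  repeat_len <- as.integer(repeat_len)
  pos_a <- as.integer(pos_a); pos_b <- as.integer(pos_b)
  if (repeat_len < 1L) stop("repeat_len must be >= 1")
  if (pos_a < 0L || pos_b <= pos_a || pos_b + repeat_len > L) {
    stop("repeat positions out of range (require 0 <= pos_a < pos_b, both copies within the stored rotation)")
  }
  if (pos_b < pos_a + repeat_len) stop("repeat copies overlap")
  rep_a <- substr(parent$bases, pos_a + 1L, pos_a + repeat_len)
  rep_b <- substr(parent$bases, pos_b + 1L, pos_b + repeat_len)
  if (rep_a != rep_b) stop("repeat copies are not identical")
  # recombination resolves between the aligned repeats: the excised circle is
  # [pos_a, pos_b) = one repeat copy + spacer; the remainder keeps the other.
  circle_bases <- substr(parent$bases, pos_a + 1L, pos_b)
  remainder_bases <- paste0(substr(parent$bases, pos_b + 1L, L),
                            if (pos_a > 0L) substr(parent$bases, 1L, pos_a) else "")
  list(circle = molecule(circle_bases, "circular"),
       remainder = molecule(remainder_bases, "circular"))
}
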