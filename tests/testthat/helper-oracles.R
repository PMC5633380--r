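# Independent oracles: deliberately naive re-implementations used only to
# verify package results. None of them call the code paths they check.

# Reverse complement by explicit character surgery.
oracle_revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Brute-force sliding-window exact search over both strands; genome is a
# named character vector.
oracle_scan <- function(read, seqs) {
  n <- nchar(read)
  rc <- oracle_revcomp(read)
  hits <- list()
  for (chrom in names(seqs)) {
    L <- nchar(seqs[[chrom]])
    if (L < n) next
    starts <- seq_len(L - n + 1L)
    windows <- substring(seqs[[chrom]], starts, starts + n - 1L)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else rc
      at <- starts[windows == q]
      if (length(at)) {
        hits[[length(hits) + 1L]] <-
          data.frame(chrom = chrom, pos = at - 1L, strand = strand)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0)))
  }
  out <- unique(out[order(out$chrom, out$pos, out$strand), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# Direct transcription of the category rules, applied to a placement set.
oracle_classify <- function(placements, focal_range) {
  if (nrow(placements) == 0L) return("UNPLACEABLE")
  if (nrow(placements) == 1L) return("UNIQUE")
  if (length(unique(placements$chrom)) > 1L) return("DISPERSED_REPEAT")
  if (max(placements$pos) - min(placements$pos) <= focal_range) {
    "FOCAL_REPEAT"
  } else {
    "INTRACHROMOSOMAL_REPEAT"
  }
}

# Rotation-invariant equality of circular sequences.
rotations_equal <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

# Fast batch of random fixed-length reads (uniform base composition).
random_reads <- function(n, len) {
  cols <- replicate(len, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    simplify = FALSE)
  do.call(paste0, cols)
}

# Exhaustive minimum-likelihood two-tailed binomial p-value.
oracle_binom_p <- function(s, S, p0) {
  probs <- dbinom(0:S, S, p0)
  sum(probs[probs <= probs[s + 1] * (1 + 1e-07)])
}

# Reassemble a fragment list by collapsing one duplication copy per junction.
oracle_reassemble <- function(frag_bases, d) {
  n <- length(frag_bases)
  if (n == 1L) return(frag_bases)
  head_parts <- substr(frag_bases[-n], 1L,
                       nchar(frag_bases[-n]) - d)
  paste0(paste(head_parts, collapse = ""), frag_bases[n])
}
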