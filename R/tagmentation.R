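# Tn5 tagmentation model. Every insertion duplicates `dup_len` bases of
# target sequence (9 bp for Tn5): a cut at position p hands bases [p, p+d) to
# BOTH flanking fragments, so consecutive fragments overlap in exactly d bases
# and a circle cut once linearizes with identical d-base termini.

#' Tagmentation model parameters
#'
#' @param cut_rate Expected Tn5 insertions per bp (Poisson rate). The default
#'   0.004 gives a mean fragment length of ~250 bp, typical of standard
#'   Nextera libraries.
#' @param dup_len Target-site duplication length in bp (9 for Tn5).
#' @param attenuated Logical; model an attenuated (time-limited) reaction by
#'   forcing exactly one cut on circular molecules. Linear molecules are
#'   unaffected.
#' @param read_len Sequenced read length in bp; must exceed `dup_len`.
#' @param error_rate Per-base substitution probability applied to reads
#'   (default 0: error-free, the regime in which signature detection with
#'   exact 9-mers is analytic).
#' @return A `tagmentation_params` list.
#' @export
tagmentation_params <- function(cut_rate = 0.004, dup_len = 9L,
                                attenuated = FALSE, read_len = 50L,
                                error_rate = 0) {
  stopifnot(cut_rate > 0, dup_len >= 0, read_len > dup_len,
            error_rate >= 0, error_rate < 1)
  structure(list(cut_rate = cut_rate, dup_len = as.integer(dup_len),
                 attenuated = isTRUE(attenuated),
                 read_len = as.integer(read_len), error_rate = error_rate),
            class = "tagmentation_params")
}

#' Tagment a linear molecule
#'
#' Cut positions follow a homogeneous Poisson process at `cut_rate` per bp.
#' A cut at position p yields a left fragment ending at `p + dup_len` and a
#' right fragment starting at `p`, so total fragment length equals molecule
#' length plus `dup_len` times the number of cuts.
#'
#' @param mol Linear [molecule()].
#' @param params A [tagmentation_params()].
#' @return List of linear fragment [molecule()]s, left to right; each carries
#'   its 0-based start offset in the parent as attribute `"offset"`.
#' @export
tagment_linear <- function(mol, params) {
  stopifnot(inherits(mol, "molecule"), inherits(params, "tagmentation_params"))
  if (mol$topology != "linear") stop("tagment_linear requires a linear molecule")
  L <- mol_length(mol)
  d <- params$dup_len
  n_sites <- max(0L, L - d)  # a cut at p duplicates [p, p+d): need p + d <= L
  ncuts <- if (n_sites == 0L) 0L else min(rpois(1L, params$cut_rate * L), n_sites)
  cuts <- if (ncuts > 0L) sort(sample(seq_len(n_sites), ncuts)) else integer(0)
  starts <- c(0L, cuts)
  ends <- c(cuts + d, L)
  frags <- substring(mol$bases, starts + 1L, ends)
  out <- vector("list", length(frags))
  for (i in seq_along(frags)) {
    m <- molecule(frags[[i]], "linear", origin = mol$origin)
    attr(m, "offset") <- starts[[i]]
    out[[i]] <- m
  }
  out
}

#' Tagment a circular molecule
#'
#' The number of cuts is Poisson(`cut_rate * length`) conditioned on at least
#' one (a circle with no insertion yields no library molecule); attenuated
#' mode forces exactly one cut. A single cut at p linearizes the circle into
#' one fragment of length `L + dup_len` whose first and last `dup_len` bases
#' are identical copies of the target-site duplication -- the signature that
#' [detect_duplication_signature()] reads out. With c cuts, the c fragments
#' partition the circle with a `dup_len` overlap at every junction.
#'
#' @param mol Circular [molecule()].
#' @param params A [tagmentation_params()].
#' @return List of linear fragment [molecule()]s in circular order starting
#'   from the first cut; attribute `"offset"` records each fragment's 0-based
#'   start on the stored rotation.
#' @export
tagment_circle <- function(mol, params) {
  stopifnot(inherits(mol, "molecule"), inherits(params, "tagmentation_params"))
  if (mol$topology != "circular") {
    stop("tagment_circle requires a circular molecule")
  }
  L <- mol_length(mol)
  d <- params$dup_len
  if (L < d) stop("circle shorter than the duplication length")
  if (params$attenuated) {
    ncuts <- 1L
  } else {
    ncuts <- 0L
    while (ncuts < 1L) ncuts <- rpois(1L, params$cut_rate * L)
    ncuts <- min(ncuts, L)
  }
  cuts <- sort(sample(seq_len(L), ncuts) - 1L)  # 0-based positions on rotation
  # a fragment can span up to L + d bases past its cut, so unroll the circle
  # far enough that no substring is truncated
  doubled <- paste0(mol$bases, mol$bases, substr(mol$bases, 1L, d))
  gaps <- diff(c(cuts, cuts[1L] + L))  # circular gaps; sum = L
  lens <- gaps + d
  frags <- substring(doubled, cuts + 1L, cuts + lens)
  out <- vector("list", length(frags))
  for (i in seq_along(frags)) {
    m <- molecule(frags[[i]], "linear", origin = mol$origin)
    attr(m, "offset") <- cuts[[i]]
    out[[i]] <- m
  }
  out
}

#' Convert fragments to paired-end reads
#'
#' R1 is the first `read_len` bases of the fragment's top strand; R2 is the
#' first `read_len` bases of the bottom strand read inward from the right end
#' (the reverse complement of the fragment's last `read_len` bases). Reads are
#' error-free unless `error_rate > 0`. Fragments shorter than `read_len` are
#' skipped and counted.
#'
#' @param frags List of linear fragment [molecule()]s (or a character vector
#'   of fragment sequences).
#' @param params A [tagmentation_params()].
#' @param label Prefix for read identifiers (provenance label).
#' @return `data.frame(id, r1, r2)` with attribute `"n_skipped"`, the number
#'   of fragments shorter than the read length.
#' @export
fragments_to_read_pairs <- function(frags, params, label = "frag") {
  stopifnot(inherits(params, "tagmentation_params"))
  bases <- if (is.character(frags)) frags
           else vapply(frags, function(m) m$bases, "")
  rl <- params$read_len
  keep <- nchar(bases) >= rl
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(n_skipped, " fragment(s) shorter than the read length skipped")
  }
  bases <- bases[keep]
  idx <- which(keep)
  if (length(bases) == 0L) {
    out <- data.frame(id = character(0), r1 = character(0), r2 = character(0))
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  r1 <- substr(bases, 1L, rl)
  r2 <- substr(reverse_complement(bases), 1L, rl)
  if (params$error_rate > 0) {
    r1 <- .add_substitutions(r1, params$error_rate)
    r2 <- .add_substitutions(r2, params$error_rate)
  }
  out <- data.frame(id = sprintf("%s/%d", label, idx), r1 = r1, r2 = r2)
  attr(out, "n_skipped") <- n_skipped
  out
}

# Uniform substitution noise; each base mutates to one of the three others.
.add_substitutions <- function(reads, rate) {
  vapply(reads, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}
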