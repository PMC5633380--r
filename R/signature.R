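# The 9-bp duplication signature. A circle cut once by Tn5 linearizes with
# the same 9-mer at both termini; with inward-facing paired-end chemistry the
# first 9 bases of R1 equal the reverse complement of the first 9 bases of
# R2. Detection is sequence-only: no alignment is required.

#' Detect the target-site duplication signature in a read pair
#'
#' Positive iff the first `d` bases of R1 match the reverse complement of the
#' first `d` bases of R2 (the two ends of a singly cut circle, sequenced from
#' opposite strands). Exact matching is the default; `max_mismatch` admits
#' error-bearing data at the cost of the analytic chance-level bound
#' (`4^-d` per pair for exact matching).
#'
#' @param r1,r2 Mate sequences, each of length >= `d`.
#' @param d Duplication length in bp (9 for Tn5).
#' @param orientation `"opposite"` (standard inward-facing paired-end
#'   chemistry; R1 start vs reverse complement of R2 start) or `"same"`
#'   (direct comparison, for nonstandard preps).
#' @param max_mismatch Maximum tolerated mismatches (default 0).
#' @return `list(is_evidence, duplicated_kmer)`; the k-mer (R1's first `d`
#'   bases) is present only on a positive call.
#' @examples
#' detect_duplication_signature(
#'   paste0("ACGTACGTA", strrep("G", 40)),
#'   paste0(reverse_complement("ACGTACGTA"), strrep("C", 40)))
#' @export
detect_duplication_signature <- function(r1, r2, d = 9L,
                                         orientation = c("opposite", "same"),
                                         max_mismatch = 0L) {
  orientation <- match.arg(orientation)
  stopifnot(length(r1) == 1L, length(r2) == 1L)
  hit <- signature_calls(r1, r2, d = d, orientation = orientation,
                         max_mismatch = max_mismatch)
  list(is_evidence = hit,
       duplicated_kmer = if (hit) substr(r1, 1L, d) else NULL)
}

#' Vectorized signature calls over many read pairs
#'
#' @inheritParams detect_duplication_signature
#' @return Logical vector, one call per pair.
#' @export
signature_calls <- function(r1, r2, d = 9L,
                            orientation = c("opposite", "same"),
                            max_mismatch = 0L) {
  orientation <- match.arg(orientation)
  d <- as.integer(d)
  stopifnot(length(r1) == length(r2), d >= 1L)
  if (length(r1) == 0L) return(logical(0))
  if (any(nchar(r1) < d) || any(nchar(r2) < d)) {
    stop("read shorter than the duplication length d = ", d)
  }
  a <- substr(r1, 1L, d)
  b <- substr(r2, 1L, d)
  if (orientation == "opposite") b <- reverse_complement(b)
  if (max_mismatch == 0L) return(a == b)
  mm <- mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
  mm <= max_mismatch
}

#' Signature fraction of a sample
#'
#' The fraction (in percent) of read pairs carrying the duplication
#' signature, i.e. the fraction of captured incidents that are singly
#' tagmented circles.
#'
#' @param r1,r2 Mate sequence vectors, or a `data.frame` with `r1`/`r2`
#'   columns passed as `r1` (then `r2` is ignored).
#' @inheritParams detect_duplication_signature
#' @return `list(n_pairs, n_evidence, fraction)` with `fraction` in percent.
#' @export
signature_fraction <- function(r1, r2 = NULL, d = 9L,
                               orientation = c("opposite", "same"),
                               max_mismatch = 0L) {
  if (is.data.frame(r1)) {
    r2 <- r1$r2
    r1 <- r1$r1
  }
  if (length(r1) == 0L) stop("signature fraction is undefined for zero pairs")
  hits <- signature_calls(r1, r2, d = d, orientation = orientation,
                          max_mismatch = max_mismatch)
  n <- length(hits)
  k <- sum(hits)
  list(n_pairs = n, n_evidence = k, fraction = 100 * k / n)
}

#' Fold enrichment of singly tagmented circles over a control
#'
#' Ratio of the signature fractions of an eccDNA fraction and its matched
#' total-genomic control.
#'
#' @param sample,control Statistics from [signature_fraction()].
#' @param allow_infinite Return `Inf` instead of erroring when the control
#'   fraction is zero.
#' @return Dimensionless fold.
#' @examples
#' # printed sperm fractions: 0.22% over 0.008% gives 27.5
#' s <- list(n_pairs = 10000, n_evidence = 22, fraction = 0.22)
#' g <- list(n_pairs = 100000, n_evidence = 8, fraction = 0.008)
#' signature_fold_enrichment(s, g)
#' @export
signature_fold_enrichment <- function(sample, control, allow_infinite = FALSE) {
  if (control$fraction == 0) {
    if (allow_infinite) return(Inf)
    stop("fold enrichment undefined: control signature fraction is zero")
  }
  sample$fraction / control$fraction
}

#' Tabulated signature report for several samples
#'
#' One row per sample with pair counts, signature positives, fraction in
#' percent, and fold enrichment against a named control sample (controls
#' report no fold).
#'
#' @param samples Named list; each element a `data.frame` with `r1`/`r2`
#'   columns (e.g. from [read_fastq_pair()]).
#' @param control Name of the control sample in `samples`, or `NULL`.
#' @param d Duplication length in bp.
#' @return `data.frame(sample, n_pairs, n_evidence, fraction_pct, fold_vs_control)`.
#' @export
signature_report <- function(samples, control = NULL, d = 9L) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  stats <- lapply(samples, signature_fraction, d = d)
  ctrl <- if (!is.null(control)) {
    if (!control %in% names(samples)) stop("unknown control sample: ", control)
    stats[[control]]
  }
  fold <- vapply(names(stats), function(nm) {
    if (is.null(ctrl) || nm == control) NA_real_
    else signature_fold_enrichment(stats[[nm]], ctrl)
  }, numeric(1))
  data.frame(sample = names(stats),
             n_pairs = vapply(stats, `[[`, numeric(1), "n_pairs"),
             n_evidence = vapply(stats, `[[`, numeric(1), "n_evidence"),
             fraction_pct = vapply(stats, `[[`, numeric(1), "fraction"),
             fold_vs_control = fold, row.names = NULL)
}
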