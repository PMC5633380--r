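# Binned enrichment of an eccDNA fraction over its matched total-genomic
# control. A bin is called enriched when its sampling-robust fold lower
# bound clears the fold threshold AND its exact two-tailed binomial p-value
# survives the correction policy.

#' Partition a genome into fixed-width bins
#'
#' Half-open bins of `bin_size` bp per chromosome; the last bin of each
#' chromosome may be short.
#'
#' @param genome A [ref_genome()].
#' @param bin_size Bin width in bp (1 kb suits worm-scale genomes, 25 kb
#'   human-scale ones).
#' @return `data.table(chrom, start, end)`.
#' @export
bin_genome <- function(genome, bin_size) {
  stopifnot(bin_size >= 1)
  bin_size <- as.integer(bin_size)
  lens <- chrom_lengths(genome)
  data.table::rbindlist(lapply(names(lens), function(chrom) {
    starts <- seq.int(0L, lens[[chrom]] - 1L, by = bin_size)
    data.table::data.table(chrom = chrom, start = starts,
                           end = pmin(starts + bin_size, lens[[chrom]]))
  }))
}

#' Count read placements per genomic bin
#'
#' Each read is assigned to the bin containing its representative placement
#' position (single placement for unique reads, span midpoint for focal
#' repeats); rows with missing positions are dropped. Totals are conserved:
#' the bin counts sum to the number of placed reads.
#'
#' @param positions `data.frame(chrom, pos)` of 0-based placement positions.
#' @param genome A [ref_genome()].
#' @param bin_size Bin width in bp.
#' @return A `binned_counts` object: `data.table(chrom, start, end, count)`
#'   over the full genome partition, with attributes `bin_size` and `total`.
#' @export
bin_reads <- function(positions, genome, bin_size) {
  positions <- positions[!is.na(positions$pos) & !is.na(positions$chrom), ,
                         drop = FALSE]
  lens <- chrom_lengths(genome)
  if (nrow(positions)) {
    if (!all(positions$chrom %in% names(lens))) {
      stop("placement on a chromosome absent from the genome")
    }
    if (any(positions$pos < 0 | positions$pos >= lens[positions$chrom])) {
      stop("placement position beyond chromosome end")
    }
  }
  part <- bin_genome(genome, bin_size)
  bin_size <- as.integer(bin_size)
  if (nrow(positions)) {
    hits <- data.table::data.table(
      chrom = positions$chrom,
      start = (as.integer(positions$pos) %/% bin_size) * bin_size)
    tallied <- hits[, list(count = .N), by = c("chrom", "start")]
    part <- tallied[part, on = c("chrom", "start")]
    data.table::setnafill(part, fill = 0L, cols = "count")
  } else {
    part[, count := 0L]
  }
  data.table::setcolorder(part, c("chrom", "start", "end", "count"))
  data.table::setattr(part, "bin_size", bin_size)
  data.table::setattr(part, "total", sum(part$count))
  data.table::setattr(part, "class",
                      c("binned_counts", class(part)))
  part[]
}

#' Construct binned counts from a count vector
#'
#' For workflows that produce per-bin counts directly (e.g. multinomial
#' simulation): attaches counts to a genome partition.
#'
#' @param partition `data.table(chrom, start, end)` from [bin_genome()].
#' @param counts Integer vector, one count per bin.
#' @param bin_size Bin width used to build the partition.
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(partition, counts, bin_size) {
  stopifnot(nrow(partition) == length(counts))
  out <- data.table::data.table(partition[, c("chrom", "start", "end")],
                                count = as.integer(counts))
  data.table::setattr(out, "bin_size", as.integer(bin_size))
  data.table::setattr(out, "total", sum(out$count))
  data.table::setattr(out, "class", c("binned_counts", class(out)))
  out[]
}

.check_same_partition <- function(a, b) {
  if (!identical(list(a$chrom, a$start, a$end),
                 list(b$chrom, b$start, b$end))) {
    stop("sample and control were binned over different partitions")
  }
}

#' Multiple-testing correction policy for enrichment calls
#'
#' `"bonferroni_bins"` divides `alpha` by the number of tested bins
#' (family-wise control over the genome scan). `"per_gene"` uses the fixed
#' per-test threshold `0.05 / (2 * n_genes)`, the gene-count-based default
#' used for per-gene scans.
#'
#' @param mode Correction mode.
#' @param alpha Significance level (ignored under `"per_gene"`).
#' @param n_genes Number of genes (required under `"per_gene"`).
#' @return A `correction_policy` list.
#' @export
correction_policy <- function(mode = c("bonferroni_bins", "per_gene"),
                              alpha = 0.05, n_genes = NULL) {
  mode <- match.arg(mode)
  if (mode == "per_gene") {
    if (is.null(n_genes) || n_genes < 1) {
      stop("per_gene correction requires n_genes >= 1")
    }
    alpha <- 0.05 / (2 * n_genes)
  }
  structure(list(mode = mode, alpha = alpha,
                 n_genes = if (is.null(n_genes)) NA_integer_
                           else as.integer(n_genes)),
            class = "correction_policy")
}

# Per-test p-value threshold implied by a policy for n tested bins.
.per_test_threshold <- function(policy, n_tested) {
  switch(policy$mode,
         bonferroni_bins = policy$alpha / max(1L, n_tested),
         per_gene = policy$alpha)
}

#' Call eccDNA-enriched bins against a matched control
#'
#' For every bin computes the point fold, the sampling-robust fold lower
#' bound ([robust_fold_lower()]) and the exact two-tailed binomial p-value of
#' the sample count under the control proportion
#' ([binomial_pvalue_two_tailed()]). A bin is significant iff its robust fold
#' lower bound reaches `min_fold` (the stricter reading of "a greater than
#' fourfold enrichment robust to binomial variation") and its p-value clears
#' the policy's per-test threshold. Bins empty in both libraries are
#' untestable and never significant, but every bin is retained in the
#' report.
#'
#' @param sample,control `binned_counts` over identical partitions.
#' @param min_fold Fold threshold applied to the robust lower bound
#'   (default 4; the per-gene variant conventionally uses 2).
#' @param policy A [correction_policy()].
#' @param pseudocount Passed to [fold_enrichment()] for control-empty bins.
#' @param confidence Confidence level of the robust fold bound.
#' @return `data.table(chrom, start, end, s, c, fold, robust_fold_lower, p,
#'   tested, significant)` sorted by `(chrom, start)`.
#' @export
call_enriched <- function(sample, control, min_fold = 4,
                          policy = correction_policy(), pseudocount = 0.5,
                          confidence = 0.95) {
  .check_same_partition(sample, control)
  stopifnot(inherits(policy, "correction_policy"))
  s <- sample$count
  c <- control$count
  S <- sum(s)
  C <- sum(c)
  if (S == 0 || C == 0) stop("sample and control must each contain reads")
  tested <- !(s == 0L & c == 0L)
  fold <- fold_enrichment(s, S, c, C, pseudocount)
  robust <- robust_fold_lower(s, S, c, C, confidence)
  p <- rep(NA_real_, length(s))
  p[tested] <- binomial_pvalue_two_tailed(s[tested], S, c[tested] / C)
  thr <- .per_test_threshold(policy, sum(tested))
  significant <- tested & robust >= min_fold & !is.na(p) & p <= thr
  out <- data.table::data.table(
    chrom = sample$chrom, start = sample$start, end = sample$end,
    s = s, c = c, fold = fold, robust_fold_lower = robust, p = p,
    tested = tested, significant = significant)
  data.table::setorderv(out, c("chrom", "start"))
  data.table::setattr(out, "threshold", thr)
  data.table::setattr(out, "policy", policy)
  data.table::setattr(out, "min_fold", min_fold)
  out[]
}

#' Whole-chromosome mitochondrial internal-control fold
#'
#' The mitochondrial genome is circular in vivo, so a genuine circular
#' enrichment must enrich it; its whole-chromosome fold is the assay's
#' internal control.
#'
#' @param sample,control `binned_counts` over identical partitions.
#' @param mito_chrom Mitochondrial chromosome name.
#' @return Point fold enrichment of the whole mitochondrial chromosome.
#' @export
mito_control_enrichment <- function(sample, control, mito_chrom) {
  .check_same_partition(sample, control)
  if (!mito_chrom %in% sample$chrom) {
    stop("chromosome not in the partition: ", mito_chrom)
  }
  s_m <- sum(sample$count[sample$chrom == mito_chrom])
  c_m <- sum(control$count[control$chrom == mito_chrom])
  fold_enrichment(s_m, sum(sample$count), c_m, sum(control$count))
}

#' Replicate reproducibility: correlation of log10 binned coverage
#'
#' Pearson correlation of `log10(count + 1)` across all bins of two
#' replicate tracks on the same partition.
#'
#' @param a,b `binned_counts` over identical partitions (>= 3 bins).
#' @return Correlation coefficient.
#' @export
replicate_log_coverage_correlation <- function(a, b) {
  .check_same_partition(a, b)
  if (nrow(a) < 3L) stop("correlation undefined for fewer than 3 bins")
  cor(log10(a$count + 1), log10(b$count + 1))
}

#' Write enrichment calls as BED
#'
#' BED6+2: chrom, start, end, name, fold (score field), strand (`.`),
#' p-value, significance flag; 0-based half-open. Unsorted input is sorted
#' before writing (with a message). By default only significant bins are
#' written.
#'
#' @param results Output of [call_enriched()].
#' @param path Output path.
#' @param significant_only Write only significant bins (default `TRUE`).
#' @export
write_enrichment_bed <- function(results, path, significant_only = TRUE) {
  df <- as.data.frame(results)
  if (is.unsorted(order(df$chrom, df$start))) {
    message("sorting enrichment results before writing BED")
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = sprintf("%s_%d", df$chrom, df$start),
                    score = df$fold,
                    strand = rep(".", nrow(df)),
                    p = ifelse(is.na(df$p), ".", format(df$p, digits = 6)),
                    significant = as.integer(df$significant))
  write_bed(bed, path)
}
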