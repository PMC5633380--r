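# Sample pools model the biochemical enrichment step: a mixture of linear
# genomic molecules and covalently closed circles, from which linear copies
# are removed with probability epsilon (exonuclease V treatment spares closed
# circles), then tagmented and sequenced. epsilon = 0 reproduces a
# total-genomic control; epsilon near 1 approximates the exoV-treated
# eccDNA fraction.

#' Describe a sequencing sample pool
#'
#' @param circles `data.frame(chrom, start, end)` of planted eccDNA circle
#'   intervals (0-based half-open), or `NULL` for none.
#' @param circle_copies Copy number of each planted circle.
#' @param genome_copies Copy number of each genomic chromosome (the
#'   mitochondrial chromosome, when the truth names one, is carried as a
#'   circle at this copy number).
#' @param epsilon Linear-removal efficiency in `[0, 1]`: each linear molecule
#'   copy survives with probability `1 - epsilon`; circles always survive.
#' @param n_pairs Subsample the pooled read pairs down to this many (keep all
#'   when `NULL`).
#' @param seed Integer seed; FASTQ output is byte-identical given it.
#' @return A `sample_pool` list.
#' @export
sample_pool <- function(circles = NULL, circle_copies = 200L,
                        genome_copies = 20L, epsilon = 0, n_pairs = NULL,
                        seed = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1, circle_copies >= 0, genome_copies >= 1)
  structure(list(circles = circles, circle_copies = as.integer(circle_copies),
                 genome_copies = as.integer(genome_copies), epsilon = epsilon,
                 n_pairs = if (is.null(n_pairs)) NULL else as.integer(n_pairs),
                 seed = as.integer(seed)),
            class = "sample_pool")
}

#' Simulate the read pairs of an enrichment pool
#'
#' Builds the molecule inventory (chromosome copies, the circular
#' mitochondrial chromosome, planted circles), removes each linear copy with
#' probability `epsilon`, tagments every surviving molecule (circles under the
#' attenuated single-cut regime when `params$attenuated` is set) and emits
#' error-free paired-end reads with per-read provenance.
#'
#' @param genome A [ref_genome()].
#' @param truth Truth list from [simulate_reference()] (used for
#'   `mito_chrom`); may be `NULL` when the genome has no mitochondrion.
#' @param pool A [sample_pool()].
#' @param params A [tagmentation_params()].
#' @param fastq_prefix When non-`NULL`, write `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (read ids suffixed `/1` and `/2`).
#' @return `data.table` with one row per read pair: `id`, `r1`, `r2`,
#'   `src_type` (`"linear"`, `"mito"` or `"circle"`), `src_chrom`,
#'   `src_start`, `src_end`. Attributes: `n_skipped` (fragments shorter than
#'   the read length) and `files` (the FASTQ paths, when written).
#' @export
simulate_enrichment_pool <- function(genome, truth, pool, params,
                                     fastq_prefix = NULL) {
  stopifnot(inherits(pool, "sample_pool"),
            inherits(params, "tagmentation_params"))
  set.seed(pool$seed)
  lens <- chrom_lengths(genome)
  mito_chrom <- if (!is.null(truth)) truth$mito_chrom else NULL
  chunks <- list()
  n_skipped <- 0L
  emit <- function(frag_bases, label, src_type, chrom, start, end) {
    rp <- suppressMessages(
      fragments_to_read_pairs(frag_bases, params, label = label))
    n_skipped <<- n_skipped + attr(rp, "n_skipped")
    if (nrow(rp) == 0L) return(invisible(NULL))
    dt <- data.table::as.data.table(rp)
    dt[, `:=`(src_type = src_type, src_chrom = chrom,
              src_start = start, src_end = end)]
    chunks[[length(chunks) + 1L]] <<- dt
    invisible(NULL)
  }
  circ_params <- params
  nuclear <- setdiff(names(lens), mito_chrom)
  for (chrom in nuclear) {
    kept <- rbinom(1L, pool$genome_copies, 1 - pool$epsilon)
    mol <- molecule(unclass(genome)[[chrom]], "linear")
    for (copy in seq_len(kept)) {
      frags <- tagment_linear(mol, params)
      emit(vapply(frags, `[[`, "", "bases"),
           sprintf("lin:%s:c%d", chrom, copy), "linear", chrom, 0L,
           lens[[chrom]])
    }
  }
  if (!is.null(mito_chrom)) {
    mol <- molecule(unclass(genome)[[mito_chrom]], "circular",
                    origin = interval(mito_chrom, 0L, lens[[mito_chrom]]))
    for (copy in seq_len(pool$genome_copies)) {
      frags <- tagment_circle(mol, circ_params)
      emit(vapply(frags, `[[`, "", "bases"),
           sprintf("mito:%s:c%d", mito_chrom, copy), "mito", mito_chrom, 0L,
           lens[[mito_chrom]])
    }
  }
  if (!is.null(pool$circles) && nrow(pool$circles) > 0L) {
    for (i in seq_len(nrow(pool$circles))) {
      ci <- pool$circles[i, ]
      mol <- extract_circle_from_genome(
        genome, interval(ci$chrom, ci$start, ci$end))
      for (copy in seq_len(pool$circle_copies)) {
        frags <- tagment_circle(mol, circ_params)
        emit(vapply(frags, `[[`, "", "bases"),
             sprintf("circ:%s:%d-%d:c%d", ci$chrom, ci$start, ci$end, copy),
             "circle", ci$chrom, as.integer(ci$start), as.integer(ci$end))
      }
    }
  }
  pairs <- if (length(chunks)) data.table::rbindlist(chunks)
           else data.table::data.table(id = character(0), r1 = character(0),
                                       r2 = character(0),
                                       src_type = character(0),
                                       src_chrom = character(0),
                                       src_start = integer(0),
                                       src_end = integer(0))
  if (!is.null(pool$n_pairs) && nrow(pairs) > pool$n_pairs) {
    pairs <- pairs[sort(sample(nrow(pairs), pool$n_pairs))]
  }
  data.table::setattr(pairs, "n_skipped", n_skipped)
  if (!is.null(fastq_prefix) && nrow(pairs) > 0L) {
    files <- write_fastq_pair(pairs$id, pairs$r1, pairs$r2, fastq_prefix)
    data.table::setattr(pairs, "files", files)
  }
  pairs[]
}

#' Write and read paired FASTQ
#'
#' `write_fastq_pair()` writes `<prefix>_1.fastq` / `<prefix>_2.fastq` with
#' `/1` and `/2` id suffixes and uniform maximal base qualities (the simulator
#' emits error-free reads). `read_fastq_pair()` reads any paired FASTQ back
#' into an `id`/`r1`/`r2` table, stripping mate suffixes.
#'
#' @param id Read identifiers (without mate suffix).
#' @param r1,r2 Mate sequences.
#' @param prefix Output path prefix.
#' @return `write_fastq_pair()`: the two file paths, invisibly.
#' @export
write_fastq_pair <- function(id, r1, r2, prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  s1 <- Biostrings::DNAStringSet(setNames(r1, paste0(id, "/1")))
  s2 <- Biostrings::DNAStringSet(setNames(r2, paste0(id, "/2")))
  Biostrings::writeXStringSet(
    s1, f1, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(r1))))
  Biostrings::writeXStringSet(
    s2, f2, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(r2))))
  invisible(c(f1, f2))
}

#' @rdname write_fastq_pair
#' @param path1,path2 Paired FASTQ files in matching order.
#' @return `read_fastq_pair()`: `data.frame(id, r1, r2)`.
#' @export
read_fastq_pair <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) stop("unpaired FASTQ files: ", path1)
  strip <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- strip(names(s1)); id2 <- strip(names(s2))
  if (!identical(id1, id2)) stop("FASTQ mate ids do not match")
  data.frame(id = id1, r1 = as.character(s1), r2 = as.character(s2))
}
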