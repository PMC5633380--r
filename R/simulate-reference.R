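# Synthetic reference genomes with planted repeat structure. The generator is
# the fixture factory for the whole package: every planted feature is recorded
# in a truth table so recovery can be scored exactly.

#' Random DNA of given GC content
#'
#' Draws bases i.i.d. with `P(G) = P(C) = gc/2`. Uses the current RNG state;
#' callers seed via [set.seed()].
#'
#' @param n Length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return A single DNA string (never contains `N`).
#' @export
random_dna <- function(n, gc = 0.36) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Describe a synthetic genome architecture
#'
#' The defaults emulate a desk-scale nematode-like genome: two 100-kb nuclear
#' chromosomes at GC 0.36 plus a 14-kb circular mitochondrial chromosome, with
#' one focal repeat family (copies confined to a short span on one chromosome)
#' and one dispersed family (copies on every nuclear chromosome). Repeat
#' spacings are validated against `focal_range`, the span rule (default 300 kb)
#' under which focal and intrachromosomal repeats are distinguished; an
#' intrachromosomal family therefore requires a chromosome longer than
#' `focal_range` (or an explicitly smaller `focal_range`).
#'
#' @param chrom_lengths Named lengths (bp) of the nuclear chromosomes.
#' @param mito `list(name=, length=)` for a circular mitochondrial chromosome,
#'   or `NULL` for none.
#' @param focal List of focal-family specs
#'   `list(unit_len=, copies=, span=, chrom=)` (`chrom = NULL` means the first
#'   nuclear chromosome); all copies land within `span` bp.
#' @param dispersed List of dispersed-family specs
#'   `list(unit_len=, copies_per_chrom=)`; copies are planted on every nuclear
#'   chromosome.
#' @param intra List of intrachromosomal-family specs
#'   `list(unit_len=, separation=, chrom=)`; two copies `separation` bp apart,
#'   which must exceed `focal_range`.
#' @param gc GC fraction of the random background.
#' @param focal_range Span rule in bp used to validate planted spacings.
#' @param seed Integer seed; the whole reference is deterministic given it.
#' @return A `genome_architecture` list.
#' @export
genome_architecture <- function(
    chrom_lengths = c(chrI = 100000L, chrII = 100000L),
    mito = list(name = "chrM", length = 14000L),
    focal = list(list(unit_len = 500L, copies = 5L, span = 10000L,
                      chrom = NULL)),
    dispersed = list(list(unit_len = 400L, copies_per_chrom = 2L)),
    intra = list(),
    gc = 0.36,
    focal_range = 300000L,
    seed = 1L) {
  stopifnot(all(chrom_lengths > 0), gc >= 0, gc <= 1, focal_range >= 1)
  for (f in focal) {
    if (f$span > focal_range) {
      stop("focal family span ", f$span, " exceeds focal_range ", focal_range)
    }
    if (f$copies * f$unit_len * 2 > f$span) {
      stop("focal family does not fit: need span >= 2 * copies * unit_len")
    }
  }
  for (f in intra) {
    if (f$separation <= focal_range) {
      stop("intrachromosomal family separation ", f$separation,
           " must exceed focal_range ", focal_range)
    }
  }
  structure(list(chrom_lengths = chrom_lengths, mito = mito, focal = focal,
                 dispersed = dispersed, intra = intra, gc = gc,
                 focal_range = as.integer(focal_range),
                 seed = as.integer(seed)),
            class = "genome_architecture")
}

# Allocate non-overlapping placement starts on one chromosome, walking a
# cursor left to right with random gaps. Errors when the chromosome is full.
.place_copies <- function(cursor, starts_needed, unit_len, chrom_len,
                          max_gap = 2000L) {
  starts <- integer(starts_needed)
  for (i in seq_len(starts_needed)) {
    cursor <- cursor + sample(500:max_gap, 1L)
    if (cursor + unit_len > chrom_len) {
      stop("planted repeat specs do not fit in the chromosome")
    }
    starts[i] <- cursor
    cursor <- cursor + unit_len
  }
  list(starts = starts, cursor = cursor)
}

#' Generate a synthetic reference with planted repeat families
#'
#' Draws random background sequence per chromosome, then overwrites exact
#' copies of randomly drawn repeat units at non-overlapping positions
#' according to the architecture. Byte-identical output under a fixed seed.
#'
#' @param arch A [genome_architecture()].
#' @return `list(genome, truth)`: the [ref_genome()] (mitochondrion included as
#'   a chromosome) and a truth list with `placements` (a `data.table` of
#'   `family, type, chrom, start, end`), `mito_chrom`, `focal_range` and
#'   `seed`.
#' @export
simulate_reference <- function(arch) {
  stopifnot(inherits(arch, "genome_architecture"))
  set.seed(arch$seed)
  seqs <- vapply(arch$chrom_lengths, random_dna, "", gc = arch$gc)
  nuclear <- names(arch$chrom_lengths)
  cursors <- setNames(rep(1000L, length(nuclear)), nuclear)
  placements <- list()
  note <- function(family, type, chrom, starts, unit_len) {
    data.table::data.table(family = family, type = type, chrom = chrom,
                           start = starts, end = starts + unit_len)
  }
  plant <- function(chrom, starts, unit) {
    for (s in starts) {
      substr(seqs[[chrom]], s + 1L, s + nchar(unit)) <<- unit
    }
  }
  fam_id <- 0L
  for (f in arch$focal) {
    fam_id <- fam_id + 1L
    chrom <- if (is.null(f$chrom)) nuclear[1] else f$chrom
    unit <- random_dna(f$unit_len, arch$gc)
    # confine all copies to a window of length span
    base <- cursors[[chrom]] + sample(500:2000, 1L)
    if (base + f$span > arch$chrom_lengths[[chrom]]) {
      stop("focal family window does not fit in ", chrom)
    }
    slot <- floor(seq(0L, f$span - f$unit_len, length.out = f$copies))
    starts <- as.integer(base + slot)
    plant(chrom, starts, unit)
    cursors[[chrom]] <- base + f$span
    placements[[length(placements) + 1L]] <-
      note(sprintf("focal_%d", fam_id), "focal", chrom, starts, f$unit_len)
  }
  for (f in arch$intra) {
    fam_id <- fam_id + 1L
    chrom <- if (is.null(f$chrom)) nuclear[1] else f$chrom
    unit <- random_dna(f$unit_len, arch$gc)
    res <- .place_copies(cursors[[chrom]], 1L, f$unit_len,
                         arch$chrom_lengths[[chrom]])
    s1 <- res$starts
    s2 <- s1 + f$separation
    if (s2 + f$unit_len > arch$chrom_lengths[[chrom]]) {
      stop("intrachromosomal family does not fit in ", chrom)
    }
    plant(chrom, c(s1, s2), unit)
    cursors[[chrom]] <- res$cursor
    placements[[length(placements) + 1L]] <-
      note(sprintf("intra_%d", fam_id), "intra", chrom, c(s1, s2), f$unit_len)
  }
  for (f in arch$dispersed) {
    fam_id <- fam_id + 1L
    unit <- random_dna(f$unit_len, arch$gc)
    for (chrom in nuclear) {
      res <- .place_copies(cursors[[chrom]], f$copies_per_chrom, f$unit_len,
                           arch$chrom_lengths[[chrom]])
      plant(chrom, res$starts, unit)
      cursors[[chrom]] <- res$cursor
      placements[[length(placements) + 1L]] <-
        note(sprintf("dispersed_%d", fam_id), "dispersed", chrom, res$starts,
             f$unit_len)
    }
  }
  mito_chrom <- NULL
  if (!is.null(arch$mito)) {
    seqs[[arch$mito$name]] <- random_dna(arch$mito$length, arch$gc)
    mito_chrom <- arch$mito$name
  }
  truth <- list(
    placements = if (length(placements)) data.table::rbindlist(placements)
                 else data.table::data.table(family = character(0),
                                             type = character(0),
                                             chrom = character(0),
                                             start = integer(0),
                                             end = integer(0)),
    mito_chrom = mito_chrom,
    focal_range = arch$focal_range,
    seed = arch$seed)
  list(genome = ref_genome(seqs), truth = truth)
}
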