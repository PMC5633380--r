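# Read categories over unique and repetitive genome space. A read with one
# placement is UNIQUE; multi-placement reads on one chromosome are FOCAL
# repeats when all occurrences fall within the focal span rule (300 kb by
# default) and INTRACHROMOSOMAL repeats beyond it; placements on several
# chromosomes make a DISPERSED repeat.

#' Read category levels, least to most repetitive
#' @export
CLASS_LEVELS <- c("UNIQUE", "FOCAL_REPEAT", "INTRACHROMOSOMAL_REPEAT",
                  "DISPERSED_REPEAT", "UNPLACEABLE")

#' Classify a placement set
#'
#' A pure function of the placement set and the focal span rule:
#' * `UNIQUE`: exactly one placement;
#' * `FOCAL_REPEAT`: >= 2 placements, all on one chromosome, outermost start
#'   positions no more than `focal_range` apart;
#' * `INTRACHROMOSOMAL_REPEAT`: >= 2 placements on one chromosome spanning
#'   more than `focal_range`;
#' * `DISPERSED_REPEAT`: placements on >= 2 chromosomes;
#' * `UNPLACEABLE`: empty placement set.
#'
#' Growing `focal_range` can only turn `INTRACHROMOSOMAL_REPEAT` into
#' `FOCAL_REPEAT`, never any other transition.
#'
#' @param placements `data.frame(chrom, pos, strand)` from [locate_read()] or
#'   [map_exact()], duplicates removed.
#' @param focal_range Span rule in bp (default 300 kb).
#' @return `list(category, span, n_placements)`; `span` (bp between outermost
#'   placement starts) is reported for single-chromosome multi-placement
#'   reads and is `NA` otherwise.
#' @export
classify_placements <- function(placements, focal_range = 300000L) {
  n <- nrow(placements)
  if (n == 0L) {
    return(list(category = "UNPLACEABLE", span = NA_integer_,
                n_placements = 0L))
  }
  chroms <- unique(placements$chrom)
  if (n == 1L) {
    return(list(category = "UNIQUE", span = NA_integer_, n_placements = 1L))
  }
  if (length(chroms) > 1L) {
    return(list(category = "DISPERSED_REPEAT", span = NA_integer_,
                n_placements = n))
  }
  span <- max(placements$pos) - min(placements$pos)
  list(category = if (span <= focal_range) "FOCAL_REPEAT"
                  else "INTRACHROMOSOMAL_REPEAT",
       span = as.integer(span), n_placements = n)
}

# Deterministic representative genome position of a classified read: UNIQUE
# reads sit at their single placement, FOCAL reads at the midpoint of their
# placement span (unbiased within the family); other categories have no
# single location.
.representative_position <- function(placements, category) {
  if (category == "UNIQUE") {
    list(chrom = placements$chrom[1L], pos = placements$pos[1L])
  } else if (category == "FOCAL_REPEAT") {
    list(chrom = placements$chrom[1L],
         pos = as.integer(floor((min(placements$pos) +
                                   max(placements$pos)) / 2)))
  } else {
    list(chrom = NA_character_, pos = NA_integer_)
  }
}

# Batched equivalent of locate_read() over a read vector: one keyed join on
# the index instead of one lookup per read. Returns a data.table of
# (read_i, chrom, pos, strand) placements, deduplicated.
.locate_batch <- function(reads, index) {
  k <- index$k
  n <- length(reads)
  if (any(nchar(reads) < k)) stop("read shorter than k = ", k)
  rcs <- reverse_complement(reads)
  queries <- c(reads, rcs)          # rows 1..n map forward, n+1..2n reverse
  qstrand <- rep(c("+", "-"), each = n)
  fk <- substr(queries, 1L, k)
  ok <- !grepl("N", fk, fixed = TRUE)
  rcfk <- fk
  rcfk[ok] <- reverse_complement(fk[ok])
  fwd_ok <- fk <= rcfk
  qdt <- data.table::data.table(
    kmer = ifelse(fwd_ok, fk, rcfk),
    qrow = seq_along(queries), fwd_ok = fwd_ok,
    pal = fk == rcfk)[ok]
  m <- index$table[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(m) == 0L) {
    return(data.table::data.table(read_i = integer(0), chrom = character(0),
                                  pos = integer(0), strand = character(0)))
  }
  # a row is a candidate when the genome's forward k-mer equals the query's
  # first k-mer (palindromic k-mers match either way)
  m <- m[(m$strand == "+" & m$fwd_ok) |
           (m$strand == "-" & (!m$fwd_ok | m$pal))]
  if (nrow(m) == 0L) {
    return(data.table::data.table(read_i = integer(0), chrom = character(0),
                                  pos = integer(0), strand = character(0)))
  }
  qlen <- nchar(queries)[m$qrow]
  lens <- chrom_lengths(index$genome)
  inb <- m$pos + qlen <= lens[m$chrom]
  m <- m[inb]
  qlen <- qlen[inb]
  full <- substring(unclass(index$genome)[m$chrom], m$pos + 1L,
                    m$pos + qlen) == queries[m$qrow]
  m <- m[full]
  out <- data.table::data.table(
    read_i = ((m$qrow - 1L) %% n) + 1L,
    chrom = m$chrom, pos = m$pos, strand = qstrand[m$qrow])
  unique(out)
}

#' Locate and classify a batch of reads
#'
#' The batched equivalent of running [locate_read()] and
#' [classify_placements()] per read (one keyed index join instead of one
#' lookup per read, with identical results); records each read's
#' representative position (single placement for UNIQUE, span midpoint for
#' FOCAL_REPEAT, none otherwise).
#'
#' @param reads Character vector of read sequences.
#' @param index A [build_kmer_index()].
#' @param focal_range Span rule in bp.
#' @param ids Optional read identifiers.
#' @return `data.table(id, category, n_placements, span, chrom, pos)`, one
#'   row per read in input order.
#' @export
classify_reads <- function(reads, index, focal_range = 300000L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  stopifnot(length(ids) == length(reads))
  pl <- .locate_batch(reads, index)
  read_i <- NULL  # data.table NSE
  stats <- pl[, list(
    n_placements = .N,
    n_chrom = data.table::uniqueN(chrom),
    minp = min(pos), maxp = max(pos), chrom1 = chrom[1L], pos1 = pos[1L]),
    by = read_i]
  out <- data.table::data.table(
    id = ids, category = "UNPLACEABLE", n_placements = 0L,
    span = NA_integer_, chrom = NA_character_, pos = NA_integer_)
  if (nrow(stats)) {
    span_all <- stats$maxp - stats$minp
    cat_s <- ifelse(stats$n_placements == 1L, "UNIQUE",
             ifelse(stats$n_chrom > 1L, "DISPERSED_REPEAT",
             ifelse(span_all <= focal_range, "FOCAL_REPEAT",
                    "INTRACHROMOSOMAL_REPEAT")))
    i <- stats$read_i
    out$category[i] <- cat_s
    out$n_placements[i] <- stats$n_placements
    out$span[i] <- ifelse(cat_s %in% c("FOCAL_REPEAT",
                                       "INTRACHROMOSOMAL_REPEAT"),
                          span_all, NA_integer_)
    out$chrom[i] <- ifelse(cat_s %in% c("UNIQUE", "FOCAL_REPEAT"),
                           stats$chrom1, NA_character_)
    out$pos[i] <- ifelse(cat_s == "UNIQUE", stats$pos1,
                  ifelse(cat_s == "FOCAL_REPEAT",
                         as.integer(floor((stats$minp + stats$maxp) / 2)),
                         NA_integer_))
  }
  out
}

#' Combine the two mates' categories into a pair category
#'
#' The pair takes the more-repetitive mate's category
#' (`UNIQUE < FOCAL < INTRACHROMOSOMAL < DISPERSED`); a pair with an
#' unplaceable mate is `UNPLACEABLE`.
#'
#' @param cat1,cat2 Category vectors (values of [CLASS_LEVELS]).
#' @return Character vector of pair categories.
#' @export
pair_category <- function(cat1, cat2) {
  r1 <- match(cat1, CLASS_LEVELS)
  r2 <- match(cat2, CLASS_LEVELS)
  if (anyNA(r1) || anyNA(r2)) stop("unknown read category")
  CLASS_LEVELS[pmax(r1, r2)]
}

#' Class composition of a read set
#'
#' @param categories Character vector of categories ([CLASS_LEVELS]).
#' @return Named numeric vector of fractions over the five categories,
#'   summing to 1.
#' @export
class_composition <- function(categories) {
  if (length(categories) == 0L) {
    stop("class composition is undefined for zero reads")
  }
  if (!all(categories %in% CLASS_LEVELS)) stop("unknown read category")
  tab <- table(factor(categories, levels = CLASS_LEVELS))
  as.vector(tab / length(categories)) |> setNames(CLASS_LEVELS)
}

#' Binned coverage tracks per read category
#'
#' UNIQUE reads are counted at their single placement and FOCAL_REPEAT reads
#' once at their span midpoint; intrachromosomal and dispersed repeats have
#' no single location and are excluded from positional tracks (they are
#' tallied only in the composition).
#'
#' @param classified Output of [classify_reads()].
#' @param genome A [ref_genome()] (defines the bin partition).
#' @param bin_size Bin width in bp.
#' @return `data.table(category, chrom, start, end, count)` restricted to the
#'   positional categories; total count equals the number of UNIQUE plus
#'   FOCAL_REPEAT reads.
#' @export
coverage_by_class <- function(classified, genome, bin_size) {
  stopifnot(bin_size >= 1)
  out <- lapply(c("UNIQUE", "FOCAL_REPEAT"), function(cat) {
    sub <- classified[classified$category == cat, ]
    bc <- bin_reads(sub[, c("chrom", "pos")], genome, bin_size)
    data.table::data.table(category = cat, bc)
  })
  data.table::rbindlist(out)
}

#' Write a coverage track as BEDGRAPH
#'
#' @param track `data.table(chrom, start, end, count)` (one category's rows
#'   of [coverage_by_class()], or any binned counts).
#' @param path Output path.
#' @param drop_zero Omit zero-count bins (default `TRUE`, the BEDGRAPH
#'   convention).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  df <- as.data.frame(track)[, c("chrom", "start", "end", "count")]
  if (drop_zero) df <- df[df$count > 0, , drop = FALSE]
  write_bed(df, path)
}
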