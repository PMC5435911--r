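# Circular genome container, coordinate arithmetic and annotation IO.
#
# All internal coordinates are 0-based half-open on the forward ("heavy")
# strand; user-facing exports are 1-based inclusive. Intervals may extend
# past L to denote origin-spanning features and are normalized mod L on
# demand.

#' Construct a circular genome from a DNA sequence
#'
#' @param sequence single DNA string; lowercase and U are normalized.
#' @param name genome name (used in SAM/BEDGraph/Circos headers).
#' @return A `CircularGenome`: list with `name`, `seq` and `length`.
#' @export
genome_from_sequence <- function(sequence, name = "genome") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- chartr("u", "t", sequence)
  seq <- toupper(chartr("U", "T", seq))
  if (!nzchar(seq)) stop("empty genome sequence")
  if (grepl("[^ACGTN]", seq)) stop("illegal characters in genome sequence")
  structure(list(name = name, seq = seq, length = nchar(seq)),
            class = "CircularGenome")
}

#' Load a circular genome from a single-record FASTA file
#'
#' @param path FASTA file (optionally gzipped) with exactly one record.
#' @return A `CircularGenome`.
#' @export
load_genome <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  if (length(recs) > 1L) stop("multiple records in ", path,
                              "; a single circular genome is required")
  nm <- sub("\\s.*$", "", names(recs)[1L])
  genome_from_sequence(as.character(recs[[1L]]), name = nm)
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("CircularGenome '%s': %d nt (circular)\n", x$name, x$length))
  invisible(x)
}

# position arithmetic on the circle -----------------------------------------

#' Circular coordinate helpers
#'
#' `wrap_pos()` maps a position onto `[0, L)`; `advance_pos()` moves `n`
#' bases downstream in transcript direction on the given strand;
#' `transcript_length()` is the inclusive 5'->3' length of a molecule
#' interval on the circle.
#'
#' @param p,pos 0-based genome position(s).
#' @param n number of bases to move (may be negative).
#' @param five,three 0-based positions of the first / last transcribed nt.
#' @param strand `"+"` or `"-"`.
#' @param L genome length.
#' @name circular-coords
NULL

#' @rdname circular-coords
#' @export
wrap_pos <- function(p, L) ((p %% L) + L) %% L

#' @rdname circular-coords
#' @export
advance_pos <- function(pos, n, strand, L) {
  if (strand == "+") wrap_pos(pos + n, L) else wrap_pos(pos - n, L)
}

#' @rdname circular-coords
#' @export
transcript_length <- function(five, three, strand, L) {
  if (strand == "+") wrap_pos(three - five, L) + 1L
  else wrap_pos(five - three, L) + 1L
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

#' Fetch genome sequence, wrapping through the origin
#'
#' Coordinates are 0-based half-open; `end` may exceed the genome length to
#' denote an origin-spanning interval. `strand = "-"` returns the reverse
#' complement.
#'
#' @param genome a `CircularGenome`.
#' @param start,end 0-based half-open interval with `end - start <= L`.
#' @param strand `"+"` or `"-"`.
#' @return DNA string of length `end - start`.
#' @export
fetch <- function(genome, start, end, strand = "+") {
  L <- genome$length
  if (end <= start) stop("end must be greater than start")
  if (end - start > L) stop("interval longer than genome")
  start <- wrap_pos(start, L)
  end2 <- start + (end - start)
  s <- if (end2 <= L) {
    substr(genome$seq, start + 1L, end2)
  } else {
    paste0(substr(genome$seq, start + 1L, L),
           substr(genome$seq, 1L, end2 - L))
  }
  if (strand == "-") revcomp(s) else s
}

# transcript-direction fetch of n bases starting at pos (inclusive)
fetch_downstream <- function(genome, pos, n, strand) {
  L <- genome$length
  if (n <= 0L) return("")
  n <- min(n, L)
  if (strand == "+") fetch(genome, pos, pos + n, "+")
  else fetch(genome, wrap_pos(pos - n + 1L, L), wrap_pos(pos - n + 1L, L) + n, "-")
}

# molecule sequence along its strand from 5' to 3' terminus (inclusive ends)
transcript_fetch <- function(genome, five, three, strand) {
  L <- genome$length
  len <- transcript_length(five, three, strand, L)
  if (strand == "+") fetch(genome, five, five + len, "+")
  else fetch(genome, three, three + len, "-")
}

#' Fraction of an interval covered by a feature, on the circle
#'
#' Both interval and feature are 0-based half-open; either may wrap the
#' origin (encoded as `end > L` or given modulo L).
#'
#' @param start,end query interval.
#' @param f_start,f_end feature interval (vectorized).
#' @param L genome length.
#' @return numeric vector: |interval intersect feature| / |interval|.
#' @export
overlap_fraction <- function(start, end, f_start, f_end, L) {
  ilen <- end - start
  flen <- f_end - f_start
  stopifnot(all(ilen > 0L), all(ilen <= L), all(flen > 0L), all(flen <= L))
  # shift so the query starts at 0; the feature and its wrap copy may both
  # intersect when ilen + flen > L
  fs <- wrap_pos(f_start - wrap_pos(start, L), L)
  seg <- function(a, b) pmax(0, pmin(b, ilen) - pmax(a, 0))
  (seg(fs, fs + flen) + seg(fs - L, fs - L + flen)) / ilen
}

# annotation -----------------------------------------------------------------

BIOTYPES <- c("tRNA", "rRNA", "mRNA", "ncRNA", "dloop")

#' Build an annotation set from a data frame of gene features
#'
#' @param df data frame with columns `gene_id`, `biotype`, `start`, `end`
#'   (0-based half-open; `end` may exceed L for origin-spanning features)
#'   and `strand`.
#' @param genome_name name of the genome the coordinates refer to.
#' @param L optional genome length for validation.
#' @return An `AnnotationSet` (a data frame).
#' @export
annotation_from_data_frame <- function(df, genome_name = "genome", L = NULL) {
  need <- c("gene_id", "biotype", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_ids in annotation")
  if (!all(df$biotype %in% BIOTYPES)) {
    stop("unknown biotype(s): ",
         paste(setdiff(df$biotype, BIOTYPES), collapse = ", "))
  }
  if (any(df$end <= df$start)) stop("feature end must exceed start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(L)) {
    if (any(df$start < 0L | df$start >= L)) stop("feature start out of range")
    if (any(df$end - df$start > L)) stop("feature longer than genome")
  }
  attr(df, "genome_name") <- genome_name
  class(df) <- c("AnnotationSet", "data.frame")
  df
}

#' Load gene annotation from BED6 or GFF3
#'
#' BED input is 0-based half-open with the biotype taken from the prefix of
#' the name column (`tRNA-`, `rRNA-`, `mRNA-`, `ncRNA-`, `dloop`); GFF3 is
#' 1-based inclusive (converted internally) with the biotype taken from the
#' `type` column or a `biotype` attribute.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param genome optional `CircularGenome` for coordinate validation.
#' @return An `AnnotationSet` in unified 0-based half-open coordinates.
#' @export
load_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  md <- S4Vectors::mcols(gr)
  if (format == "bed") {
    nm <- as.character(md$name)
    biotype <- ifelse(grepl("^dloop", nm, ignore.case = TRUE), "dloop",
                      sub("-.*$", "", nm))
  } else {
    biotype <- if ("biotype" %in% names(md)) as.character(md$biotype)
               else as.character(md$type)
    nm <- if ("ID" %in% names(md) && !all(is.na(md$ID))) as.character(md$ID)
          else if ("Name" %in% names(md)) as.character(md$Name)
          else paste0("feature", seq_along(gr))
  }
  df <- data.frame(gene_id = nm,
                   biotype = biotype,
                   start = BiocGenerics::start(gr) - 1L,  # to 0-based
                   end = BiocGenerics::end(gr),           # half-open
                   strand = as.character(BiocGenerics::strand(gr)),
                   stringsAsFactors = FALSE)
  gname <- if (!is.null(genome)) genome$name
           else as.character(GenomeInfoDb::seqnames(gr)[1L])
  annotation_from_data_frame(df, genome_name = gname,
                             L = if (!is.null(genome)) genome$length else NULL)
}

#' Write an annotation set to BED6
#'
#' @param annotation an `AnnotationSet`.
#' @param path output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   attr(annotation, "genome_name"),
                   annotation$start, annotation$end,
                   ifelse(annotation$biotype == "dloop", "dloop",
                          ifelse(startsWith(annotation$gene_id,
                                            paste0(annotation$biotype, "-")),
                                 annotation$gene_id,
                                 paste0(annotation$biotype, "-",
                                        annotation$gene_id))),
                   annotation$strand)
  writeLines(lines, path)
  invisible(path)
}

# run-length of leading A's
a_run_len <- function(s) {
  m <- regmatches(s, regexpr("^A*", s))
  nchar(m)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# common prefix tolerating up to `budget` isolated mismatches (sequencing
# errors), each accepted only when the following `look` bases all match --
# so a genuine junction (sustained divergence) still terminates the prefix
tolerant_prefix_len <- function(a, b, budget = 2L, look = 6L) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  i <- 0L; used <- 0L
  while (i < n) {
    if (av[i + 1L] == bv[i + 1L]) {
      i <- i + 1L
    } else if (used < budget && i + 1L + look <= n &&
               all(av[(i + 2L):(i + 1L + look)] ==
                   bv[(i + 2L):(i + 1L + look)])) {
      used <- used + 1L
      i <- i + 1L
    } else break
  }
  i
}
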