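# Junction ("link") calling: convert placed read segments into the inferred
# 5' and 3' termini of the original linear molecule.
#
# Two adjacent segments of one read whose genome placements are not
# contiguous (transcript-direction gap outside +/- contiguity_tol) witness
# the circularization junction: the earlier segment ends at the molecule's
# 3' terminus and the later one starts at its 5' terminus. Unaligned read
# bases between the segments are the junction sequence (non-templated tail
# or noise). For collapsed monomers the junction comes from the cyclic
# placement instead. Every call is normalized with canonicalize_call() so
# that genomically ambiguous junction representations are comparable. Reads
# with several junctions (rolling-circle copies) must agree within the
# rotation tolerance or are discarded as chimeras.

empty_calls <- function() {
  data.frame(read_id = character(), five_prime = integer(),
             three_prime = integer(), strand = character(),
             tail_kind = character(), tail_len = integer(),
             junction_in_read = integer(), support_class = character(),
             wraps_origin = logical(), stringsAsFactors = FALSE)
}

call_row <- function(read_id, cc, strand, jpos, support, L) {
  wraps <- if (strand == "+") cc$five > cc$three else cc$five < cc$three
  structure(list(read_id = read_id, five_prime = as.integer(cc$five),
                 three_prime = as.integer(cc$three), strand = strand,
                 tail_kind = cc$tail_kind, tail_len = as.integer(cc$tail_len),
                 junction_in_read = as.integer(jpos), support_class = support,
                 wraps_origin = wraps),
            class = "data.frame", row.names = c(NA, -1L))
}

circ_dist <- function(a, b, L) {
  d <- wrap_pos(a - b, L)
  pmin(d, L - d)
}

#' Call molecule termini from one read's split segments
#'
#' @param segments segment data frame of one read (from [align_read()]),
#'   ordered by read coordinate; must all be on one strand.
#' @param read_seq the read sequence (for the junction gap bases).
#' @param genome the `CircularGenome`.
#' @param contiguity_tol genome gap (nt) up to which adjacent segments are
#'   one locus rather than a junction.
#' @param max_junction_gap maximum unexplained (non-tail) junction sequence
#'   tolerated.
#' @param rotation_tol maximum disagreement (nt) between the junctions of a
#'   multi-junction (rolling-circle) read.
#' @param min_len minimum molecule length accepted.
#' @return one-row call data frame, or `NULL` (no junction, mixed strands,
#'   inconsistent rotation, or oversized junction gap).
#' @export
call_precursor <- function(segments, read_seq, genome, contiguity_tol = 2L,
                           max_junction_gap = 4L, rotation_tol = 2L,
                           min_len = 20L) {
  if (is.null(segments) || nrow(segments) < 2L) return(NULL)
  if (length(unique(segments$strand)) != 1L) return(NULL)
  strand <- segments$strand[1L]
  L <- genome$length
  segments <- segments[order(segments$qstart), , drop = FALSE]
  calls <- list()
  for (i in seq_len(nrow(segments) - 1L)) {
    a <- segments[i, ]; b <- segments[i + 1L, ]
    g <- if (strand == "+") {
      wrap_signed(b$gstart - (a$gstart + a$glen), L)
    } else {
      wrap_signed(a$gstart - (b$gstart + b$glen), L)
    }
    if (abs(g) <= contiguity_tol) next  # same locus, not a junction
    three0 <- if (strand == "+") wrap_pos(a$gstart + a$glen - 1L, L)
              else a$gstart
    five0 <- if (strand == "+") b$gstart
             else wrap_pos(b$gstart + b$glen - 1L, L)
    gapseq <- if (b$qstart > a$qend)
      substr(read_seq, a$qend + 1L, b$qstart) else ""
    cc <- canonicalize_call(genome, five0, three0, strand, gapseq)
    if (cc$gap_len > max_junction_gap) next
    calls[[length(calls) + 1L]] <- list(cc = cc, jpos = a$qend)
  }
  if (length(calls) == 0L) return(NULL)
  cc <- calls[[1L]]$cc
  if (length(calls) > 1L) {
    for (other in calls[-1L]) {
      if (circ_dist(other$cc$five, cc$five, L) > rotation_tol ||
          circ_dist(other$cc$three, cc$three, L) > rotation_tol) {
        return(NULL)  # rotation-inconsistent: chimera
      }
    }
  }
  mlen <- transcript_length(cc$five, cc$three, strand, L)
  if (mlen < min_len) return(NULL)
  support <- if (length(calls) > 1L || nrow(segments) > 2L)
    "rotation_consistent" else "junction_spanning"
  call_row(segments$read_id[1L], cc, strand, calls[[1L]]$jpos, support, L)
}

#' Call molecule termini for a collapsed monomer's cyclic placement
#'
#' @param placement result of [place_monomer()].
#' @param genome the `CircularGenome`.
#' @inheritParams call_precursor
#' @return one-row call data frame or `NULL`.
#' @export
call_from_monomer <- function(placement, genome, max_junction_gap = 4L,
                              min_len = 15L) {
  j <- placement$junction
  cc <- canonicalize_call(genome, j$five0, j$three0, j$strand, j$resid)
  if (cc$gap_len > max_junction_gap) return(NULL)
  L <- genome$length
  if (transcript_length(cc$five, cc$three, j$strand, L) < min_len) return(NULL)
  call_row(placement$segment$read_id[1L], cc, j$strand,
           placement$segment$qend[1L], "rotation_consistent", L)
}

#' Annotate calls with the genes their molecule interval spans
#'
#' @param calls call data frame.
#' @param annotation an `AnnotationSet`.
#' @param genome the `CircularGenome`.
#' @param min_gene_overlap minimum overlap (nt) for a feature to count as
#'   spanned; keeps few-nt junction-representation shifts across abutting
#'   gene boundaries from inflating multi-gene calls.
#' @return `calls` with `n_genes_spanned` and `classes` (comma-separated
#'   biotypes of overlapped same-strand features) columns added.
#' @export
annotate_calls <- function(calls, annotation, genome, min_gene_overlap = 15L) {
  L <- genome$length
  n <- nrow(calls)
  ng <- integer(n); cls <- character(n)
  for (i in seq_len(n)) {
    s <- calls$strand[i]
    five <- calls$five_prime[i]; three <- calls$three_prime[i]
    len <- transcript_length(five, three, s, L)
    start <- if (s == "+") five else three
    same <- annotation[annotation$strand == s, , drop = FALSE]
    if (nrow(same) == 0L) { ng[i] <- 0L; cls[i] <- ""; next }
    ovl <- overlap_fraction(start, start + len, same$start, same$end, L) * len
    hit <- ovl >= pmin(min_gene_overlap, same$end - same$start)
    ng[i] <- sum(hit)
    cls[i] <- paste(sort(unique(same$biotype[hit])), collapse = ",")
  }
  calls$n_genes_spanned <- ng
  calls$classes <- cls
  calls
}

#' Aggregate calls into a link table and per-position end profiles
#'
#' @param calls annotated call data frame (one condition / replicate pool).
#' @param annotation an `AnnotationSet`.
#' @param genome the `CircularGenome`.
#' @param condition label stored on the result.
#' @return list with `links` (rows of five_prime, three_prime, strand,
#'   read_count, n_genes_spanned, classes) and `ends` (an `EndProfile`:
#'   per-strand 5'/3' end count vectors of length L, raw normalization).
#' @export
aggregate_links <- function(calls, annotation, genome, condition = "sample") {
  L <- genome$length
  if (!"n_genes_spanned" %in% names(calls)) {
    calls <- annotate_calls(calls, annotation, genome)
  }
  if (nrow(calls) == 0L) {
    links <- data.frame(five_prime = integer(), three_prime = integer(),
                        strand = character(), read_count = integer(),
                        n_genes_spanned = integer(), classes = character(),
                        stringsAsFactors = FALSE)
  } else {
    key <- paste(calls$five_prime, calls$three_prime, calls$strand)
    agg <- aggregate(list(read_count = key), by = list(key = key), FUN = length)
    first <- calls[!duplicated(key), ]
    first_key <- key[!duplicated(key)]
    m <- match(agg$key, first_key)
    links <- data.frame(five_prime = first$five_prime[m],
                        three_prime = first$three_prime[m],
                        strand = first$strand[m],
                        read_count = agg$read_count,
                        n_genes_spanned = first$n_genes_spanned[m],
                        classes = first$classes[m],
                        stringsAsFactors = FALSE)
    links <- links[order(-links$read_count), ]
    rownames(links) <- NULL
  }
  ends <- list(five = list("+" = integer(L), "-" = integer(L)),
               three = list("+" = integer(L), "-" = integer(L)),
               normalization = "raw", L = L, condition = condition)
  for (s in c("+", "-")) {
    cs <- calls[calls$strand == s, , drop = FALSE]
    if (nrow(cs)) {
      ends$five[[s]] <- tabulate(cs$five_prime + 1L, nbins = L)
      ends$three[[s]] <- tabulate(cs$three_prime + 1L, nbins = L)
    }
  }
  class(ends) <- "EndProfile"
  list(links = links, ends = ends, condition = condition)
}

#' Fraction of aligned reads that witness a multi-gene junction
#'
#' @param n_aligned number of genome-aligned reads (the denominator).
#' @param calls annotated call data frame.
#' @return fraction of aligned reads yielding a call spanning two or more
#'   genes (the split-read precursor fraction).
#' @export
split_fraction <- function(n_aligned, calls) {
  if (n_aligned <= 0L) stop("zero aligned reads")
  if (nrow(calls) == 0L) return(0)
  sum(calls$n_genes_spanned >= 2L) / n_aligned
}

#' Per-link log2 fold change between two conditions
#'
#' Link read counts are CPM-normalized to each library's aligned total, then
#' compared as log2((A + pseudo) / (B + pseudo)) per (five, three, strand)
#' link over the union of both tables.
#'
#' @param links_a,links_b link tables from [aggregate_links()].
#' @param total_a,total_b aligned read totals for CPM normalization.
#' @param pseudocount pseudocount on the CPM scale.
#' @return data frame with the link keys, `cpm_a`, `cpm_b` and `log2fc`.
#' @export
compare_links <- function(links_a, links_b, total_a, total_b,
                          pseudocount = 1) {
  stopifnot(total_a > 0, total_b > 0, pseudocount > 0)
  ka <- paste(links_a$five_prime, links_a$three_prime, links_a$strand)
  kb <- paste(links_b$five_prime, links_b$three_prime, links_b$strand)
  keys <- union(ka, kb)
  ca <- links_a$read_count[match(keys, ka)]; ca[is.na(ca)] <- 0
  cb <- links_b$read_count[match(keys, kb)]; cb[is.na(cb)] <- 0
  parts <- do.call(rbind, strsplit(keys, " "))
  cpm_a <- ca * 1e6 / total_a
  cpm_b <- cb * 1e6 / total_b
  data.frame(five_prime = as.integer(parts[, 1L]),
             three_prime = as.integer(parts[, 2L]),
             strand = parts[, 3L],
             cpm_a = cpm_a, cpm_b = cpm_b,
             log2fc = log2((cpm_a + pseudocount) / (cpm_b + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Export a link table and gene karyotype in Circos text format
#'
#' Coordinates are 1-based inclusive. Link thickness encodes read count;
#' karyotype bands are colored by biotype.
#'
#' @param links link table.
#' @param annotation an `AnnotationSet`.
#' @param genome the `CircularGenome`.
#' @param link_path,karyotype_path output paths.
#' @export
export_circos <- function(links, annotation, genome, link_path,
                          karyotype_path) {
  nm <- genome$name
  lines <- sprintf("%s %d %d %s %d %d thickness=%dp,strand=%s",
                   nm, links$five_prime + 1L, links$five_prime + 1L,
                   nm, links$three_prime + 1L, links$three_prime + 1L,
                   links$read_count, links$strand)
  writeLines(lines, link_path)
  colmap <- c(tRNA = "grey", rRNA = "green", mRNA = "lblue",
              ncRNA = "purple", dloop = "white")
  kar <- c(sprintf("chr - %s %s 0 %d grey", nm, nm, genome$length),
           sprintf("band %s %s %s %d %d %s",
                   nm, annotation$gene_id, annotation$gene_id,
                   annotation$start + 1L, annotation$end,
                   colmap[annotation$biotype]))
  writeLines(kar, karyotype_path)
  invisible(link_path)
}

#' Parse a Circos link file written by [export_circos()]
#'
#' @param link_path path of the link file.
#' @return link table with `five_prime`, `three_prime` (0-based), `strand`
#'   and `read_count`.
#' @export
read_circos_links <- function(link_path) {
  ln <- readLines(link_path)
  if (length(ln) == 0L) {
    return(data.frame(five_prime = integer(), three_prime = integer(),
                      strand = character(), read_count = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(ln, " "))
  opts <- strsplit(f[, 7L], ",")
  data.frame(five_prime = as.integer(f[, 2L]) - 1L,
             three_prime = as.integer(f[, 5L]) - 1L,
             strand = vapply(opts, function(x)
               sub("strand=", "", x[2L]), ""),
             read_count = as.integer(sub("thickness=(\\d+)p", "\\1",
                                         vapply(opts, `[[`, "", 1L))),
             stringsAsFactors = FALSE)
}
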