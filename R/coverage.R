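# Strand-aware depth of coverage, CPM normalization and log2 fold-change
# tracks. Every reference-consuming aligned base increments its position's
# depth on its strand; circular wraparound is respected. CPM = raw depth *
# 1e6 / (aligned reads in the library), following the convention of
# normalizing to total reads mapped to the genome.

#' Strand-aware depth of coverage from segment alignments
#'
#' @param segments segment data frame (needs `gstart`, `glen`, `strand`).
#' @param L genome length.
#' @param library_total number of aligned reads (CPM denominator); defaults
#'   to the number of distinct read_ids in `segments`.
#' @return a `CoverageTrack`: list with per-strand depth vectors (`plus`,
#'   `minus`), `library_total` and `normalization = "raw"`.
#' @export
coverage_track <- function(segments, L, library_total = NULL) {
  depth <- list("+" = numeric(L), "-" = numeric(L))
  if (!is.null(segments) && nrow(segments) > 0L) {
    for (s in c("+", "-")) {
      idx <- segments$strand == s
      if (!any(idx)) next
      d <- numeric(L + 1L)
      gs <- wrap_pos(segments$gstart[idx], L)
      ge <- gs + segments$glen[idx]
      for (i in seq_along(gs)) {
        if (ge[i] <= L) {
          d[gs[i] + 1L] <- d[gs[i] + 1L] + 1
          d[ge[i] + 1L] <- d[ge[i] + 1L] - 1
        } else {  # wraps the origin
          d[gs[i] + 1L] <- d[gs[i] + 1L] + 1
          d[L + 1L] <- d[L + 1L] - 1
          d[1L] <- d[1L] + 1
          d[ge[i] - L + 1L] <- d[ge[i] - L + 1L] - 1
        }
      }
      depth[[s]] <- cumsum(d[seq_len(L)])
    }
  }
  if (is.null(library_total)) {
    library_total <- if (is.null(segments)) 0L
                     else length(unique(segments$read_id))
  }
  structure(list(plus = depth[["+"]], minus = depth[["-"]],
                 library_total = library_total, normalization = "raw",
                 L = L),
            class = "CoverageTrack")
}

#' Counts-per-million normalization of a coverage track
#'
#' @param track a raw `CoverageTrack`.
#' @return the track scaled by `1e6 / library_total`,
#'   `normalization = "CPM"`.
#' @export
cpm <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (track$normalization != "raw") stop("track is already CPM-normalized")
  if (track$library_total <= 0L) stop("zero library total")
  track$plus <- track$plus * 1e6 / track$library_total
  track$minus <- track$minus * 1e6 / track$library_total
  track$normalization <- "CPM"
  track
}

#' Per-position log2 fold change between two CPM coverage tracks
#'
#' @param track_a,track_b CPM-normalized `CoverageTrack`s of equal length.
#' @param pseudocount positive pseudocount keeping the ratio finite.
#' @return a `DiffTrack`: per-strand log2((A + psi) / (B + psi)) vectors.
#' @export
log2fc_track <- function(track_a, track_b, pseudocount = 1) {
  stopifnot(inherits(track_a, "CoverageTrack"),
            inherits(track_b, "CoverageTrack"),
            pseudocount > 0)
  if (track_a$normalization != "CPM" || track_b$normalization != "CPM") {
    stop("both tracks must be CPM-normalized")
  }
  if (track_a$L != track_b$L) stop("track length mismatch")
  structure(list(plus = log2((track_a$plus + pseudocount) /
                             (track_b$plus + pseudocount)),
                 minus = log2((track_a$minus + pseudocount) /
                              (track_b$minus + pseudocount)),
                 pseudocount = pseudocount, L = track_a$L),
            class = "DiffTrack")
}

#' Write a per-position vector as BEDGraph
#'
#' @param values numeric vector of length L (0-based positions 0..L-1).
#' @param genome_name sequence name.
#' @param path output path.
#' @param track_name BEDGraph track name line.
#' @export
write_bedgraph <- function(values, genome_name, path, track_name = "track") {
  L <- length(values)
  # run-length compress consecutive equal values
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  if (any(keep)) {
    writeLines(sprintf("%s\t%d\t%d\t%g", genome_name, starts[keep],
                       ends[keep], r$values[keep]), con)
  }
  invisible(path)
}
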