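# Adapter trimming and paired-end overlap merging, computed internally.
#
# Trimming removes 3' adapter occurrences (up to a 10% mismatch rate, with a
# minimum terminal overlap of 3 nt) and drops pairs with a mate shorter than
# `min_len`. Merging reverse-complements mate 2, evaluates every candidate
# overlap length and keeps the one with the lowest mismatch density
# (longest overlap on ties), requiring the density to stay below a threshold;
# disagreeing bases take the mate with the higher quality (mate 1 on ties).
# Unmerged pairs contribute only read 1 downstream; mate 2 is discarded.

# position (1-based, leftmost) where the adapter starts, or 0 for no match
adapter_cut_pos <- function(seq, adapter, max_error_rate = 0.1,
                            min_overlap = 3L) {
  cpp_adapter_pos(seq, adapter, max_error_rate, as.integer(min_overlap))
}

#' Trim 3' adapters from read pairs and apply a length filter
#'
#' @param reads data frame with `read_id`, `seq1`, `seq2`, `qual1`, `qual2`
#'   (as produced by [simulate_library()] or assembled from FASTQ input).
#' @param adapter1,adapter2 3' adapter of mate 1 / mate 2.
#' @param min_len pairs with either trimmed mate shorter than this are
#'   dropped.
#' @param max_error_rate,min_overlap adapter matching parameters.
#' @return list with `reads` (trimmed, surviving pairs) and `dropped`
#'   (number of pairs removed by the length filter).
#' @export
trim_adapters <- function(reads, adapter1, adapter2, min_len = 20L,
                          max_error_rate = 0.1, min_overlap = 3L) {
  n <- nrow(reads)
  if (n == 0L) return(list(reads = reads, dropped = 0L))
  cut1 <- vapply(reads$seq1, adapter_cut_pos, 0L, adapter = adapter1,
                 max_error_rate = max_error_rate, min_overlap = min_overlap,
                 USE.NAMES = FALSE)
  cut2 <- vapply(reads$seq2, adapter_cut_pos, 0L, adapter = adapter2,
                 max_error_rate = max_error_rate, min_overlap = min_overlap,
                 USE.NAMES = FALSE)
  len1 <- ifelse(cut1 > 0L, cut1 - 1L, nchar(reads$seq1))
  len2 <- ifelse(cut2 > 0L, cut2 - 1L, nchar(reads$seq2))
  out <- data.frame(read_id = reads$read_id,
                    seq1 = substr(reads$seq1, 1L, len1),
                    seq2 = substr(reads$seq2, 1L, len2),
                    qual1 = substr(reads$qual1, 1L, len1),
                    qual2 = substr(reads$qual2, 1L, len2),
                    stringsAsFactors = FALSE)
  keep <- len1 >= min_len & len2 >= min_len
  list(reads = out[keep, , drop = FALSE], dropped = sum(!keep))
}

#' Merge one trimmed read pair by overlap
#'
#' @param seq1,seq2 trimmed mate sequences (mate 2 in sequencing
#'   orientation; it is reverse-complemented internally).
#' @param qual1,qual2 quality strings (optional; mate 1 wins ties).
#' @param min_overlap,max_overlap candidate overlap length range.
#' @param max_mismatch_density maximum fraction of mismatching bases in the
#'   accepted overlap.
#' @return list with `seq`, `merged` (flag) and `overlap_len` (0 if
#'   unmerged; unmerged output is mate 1).
#' @export
merge_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                       min_overlap = 10L, max_overlap = 245L,
                       max_mismatch_density = 0.25) {
  s2 <- revcomp(seq2)
  n1 <- nchar(seq1); n2 <- nchar(s2)
  omax <- min(n1, n2, max_overlap)
  if (omax >= min_overlap) {
    mm <- cpp_overlap_mismatches(seq1, s2)
    o <- seq_len(omax)
    dens <- mm[o] / o
    ok <- o >= min_overlap & dens <= max_mismatch_density
    if (any(ok)) {
      cand <- o[ok]
      # lowest mismatch density, longest overlap on ties
      best <- cand[order(dens[cand], -cand)][1L]
      q2r <- if (!is.null(qual2)) paste(rev(strsplit(qual2, "")[[1L]]),
                                        collapse = "") else NULL
      head1 <- substr(seq1, 1L, n1 - best)
      ov1 <- substr(seq1, n1 - best + 1L, n1)
      ov2 <- substr(s2, 1L, best)
      ov <- ov1
      if (ov1 != ov2) {
        c1 <- strsplit(ov1, "")[[1L]]; c2 <- strsplit(ov2, "")[[1L]]
        diff <- which(c1 != c2)
        if (!is.null(qual1) && !is.null(q2r)) {
          p1 <- utf8ToInt(substr(qual1, n1 - best + 1L, n1))
          p2 <- utf8ToInt(substr(q2r, 1L, best))
          take2 <- diff[p2[diff] > p1[diff]]
          c1[take2] <- c2[take2]
        }
        ov <- paste(c1, collapse = "")
      }
      tail2 <- substr(s2, best + 1L, n2)
      return(list(seq = paste0(head1, ov, tail2), merged = TRUE,
                  overlap_len = best))
    }
  }
  list(seq = seq1, merged = FALSE, overlap_len = 0L)
}

#' Merge all trimmed pairs; unmerged pairs pass through as read 1
#'
#' @param reads trimmed pair data frame (see [trim_adapters()]).
#' @inheritParams merge_pair
#' @return data frame with `read_id`, `seq`, `merged`, `overlap_len`.
#' @export
merge_pairs <- function(reads, min_overlap = 10L, max_overlap = 245L,
                        max_mismatch_density = 0.25) {
  n <- nrow(reads)
  seqs <- character(n); merged <- logical(n); ol <- integer(n)
  for (i in seq_len(n)) {
    r <- merge_pair(reads$seq1[i], reads$seq2[i], reads$qual1[i],
                    reads$qual2[i], min_overlap, max_overlap,
                    max_mismatch_density)
    seqs[i] <- r$seq; merged[i] <- r$merged; ol[i] <- r$overlap_len
  }
  data.frame(read_id = reads$read_id, seq = seqs, merged = merged,
             overlap_len = ol, stringsAsFactors = FALSE)
}
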