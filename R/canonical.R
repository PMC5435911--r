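# Canonical representation of a molecule's termini.
#
# A circularized molecule is observed only through its junction, so its
# linear representation (five_prime, three_prime, tail) is identifiable only
# up to sliding the junction point through genomically templated bases:
# if the genome continues past the 3' terminus with the same bases that the
# tail (or the molecule's own 5' start) provides, the data cannot distinguish
# the representations. All calls and all simulator truth are therefore
# normalized to one canonical form before comparison or aggregation:
#
#   1. the junction is slid 3'-ward as far as the genome flank matches the
#      bases that follow the 3' terminus in the molecule (tail first, then
#      the molecule's own 5' start), and
#   2. for a residual poly(A) tail, genome-encoded A's at the 5' start are
#      counted as tail rather than body (and a residual partial CCA is
#      completed from the body's leading bases).
#
# The same convention is applied to simulated truth and to pipeline calls,
# making exact-recovery comparisons well defined.

#' Canonicalize a molecule representation (termini + non-templated tail)
#'
#' @param genome a `CircularGenome`.
#' @param five 0-based genome position of the first transcribed nt.
#' @param three 0-based genome position of the last transcribed nt.
#' @param strand `"+"` or `"-"` (transcript strand).
#' @param tail_seq non-templated 3' tail sequence (may be `""`).
#' @return list with canonical `five`, `three`, `tail_kind`
#'   (`"none"`, `"CCA"`, `"polyA"`), `tail_len`, `tail_seq` and `gap_len`
#'   (length of junction sequence that is neither templated nor a
#'   recognizable tail).
#' @export
canonicalize_call <- function(genome, five, three, strand, tail_seq = "") {
  L <- genome$length
  k <- nchar(tail_seq)
  body_len <- transcript_length(five, three, strand, L)
  # window of molecule bases that follow the 3' terminus around the junction
  w <- min(body_len - 1L, 60L)
  jseq <- paste0(tail_seq, fetch_downstream(genome, five, w, strand))
  flank <- fetch_downstream(genome, advance_pos(three, 1L, strand, L),
                            nchar(jseq), strand)
  s <- tolerant_prefix_len(jseq, flank)
  three <- advance_pos(three, s, strand, L)
  if (s >= k) {
    five <- advance_pos(five, s - k, strand, L)
    tail <- ""
  } else {
    tail <- substr(tail_seq, s + 1L, k)
  }
  gap_len <- 0L
  kind <- "none"
  if (nzchar(tail)) {
    if (grepl("^A+$", tail)) {
      kind <- "polyA"
    } else if (tail %in% c("CCA", "CA")) {
      # residual of a CCA tail whose leading base(s) were genome-templated
      # and already absorbed into the body 3'-ward
      kind <- "CCA"
    } else if (tail %in% c("C", "CC")) {
      # a CCA remnant whose trailing base(s) were attributed to the body
      # start (they matched the genome there): re-expel the minimal number
      # of leading body bases that reassemble a suffix of CCA
      lead <- fetch_downstream(genome, five, 3L - nchar(tail), strand)
      done <- FALSE
      for (extra in seq_len(nchar(lead))) {
        cand <- paste0(tail, substr(lead, 1L, extra))
        if (cand %in% c("CA", "CCA")) {
          five <- advance_pos(five, extra, strand, L)
          tail <- cand
          kind <- "CCA"
          done <- TRUE
          break
        }
      }
      if (!done) {
        gap_len <- nchar(tail)
        tail <- ""
      }
    } else {
      gap_len <- nchar(tail)
      tail <- ""
    }
  }
  if (nzchar(tail)) {
    # 5'-backward absorption: tail bases that the genome also encodes
    # immediately upstream of the 5' terminus are indistinguishable from
    # body; the canonical form counts them as body (minimal tail). A CCA
    # tail is absorbed only as a whole (partial absorption would conflict
    # with the completion rule above); poly(A) absorbs base by base.
    up <- fetch_downstream(genome, advance_pos(five, -nchar(tail), strand, L),
                           nchar(tail), strand)
    a <- 0L
    while (a < nchar(tail) &&
           substr(up, nchar(up) - a, nchar(up) - a) ==
           substr(tail, nchar(tail) - a, nchar(tail) - a)) {
      a <- a + 1L
    }
    if (kind == "CCA" && a < nchar(tail)) a <- 0L
    if (a > 0L) {
      five <- advance_pos(five, -a, strand, L)
      tail <- substr(tail, 1L, nchar(tail) - a)
    }
    # a poly(A) residual shorter than the 3 nt detection floor is not
    # annotated as a tail (CCA keeps its identity at any residual length);
    # the leftover bases count as unexplained junction sequence
    if (kind == "polyA" && nchar(tail) < 3L) {
      kind <- "none"
      gap_len <- gap_len + nchar(tail)
      tail <- ""
    }
  }
  list(five = five, three = three, tail_kind = kind,
       tail_len = nchar(tail), tail_seq = tail, gap_len = gap_len)
}
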