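# Rolling-circle tandem-repeat detection and consensus collapsing.
#
# Circularized molecules shorter than half the read are sequenced as tandem
# direct repeats. A self-correlation scan finds the smallest period p such
# that comparing every base with the base p positions downstream gives a
# mismatch rate at or below a threshold; qualifying reads are collapsed to a
# per-column majority-vote consensus monomer. Reads without a qualifying
# period pass through unchanged (copies = 1), preserving split-read junction
# evidence for longer molecules.

#' Find the tandem-repeat period of a read
#'
#' Returns the smallest period `p` in `[min_period, len / min_copies]` whose
#' self-correlation mismatch rate (over all `len - p` comparisons, i.e. the
#' full read) is at most `max_mismatch_rate`, or `NA` if none qualifies.
#'
#' @param seq read sequence.
#' @param min_period smallest period considered (the shortest biologically
#'   expected small-RNA fragment).
#' @param min_copies required minimum number of copies (bounds the largest
#'   period at `len / min_copies`).
#' @param max_mismatch_rate maximum self-correlation mismatch rate.
#' @return integer period or `NA_integer_`.
#' @export
find_period <- function(seq, min_period = 15L, min_copies = 2,
                        max_mismatch_rate = 0.1) {
  n <- nchar(seq)
  maxp <- floor(n / min_copies)
  if (n < 2L * min_period || maxp < min_period) return(NA_integer_)
  sc <- cpp_period_scan(seq, as.integer(min_period), as.integer(maxp))
  ok <- sc$mismatches <= max_mismatch_rate * sc$compared
  if (!any(ok)) return(NA_integer_)
  sc$period[which(ok)[1L]]
}

#' Collapse a tandem-repeat read to its consensus monomer
#'
#' Consensus is a per-column majority vote across the full copies (the
#' partial last copy contributes where present); ties take the base of the
#' earliest copy.
#'
#' @param seq read sequence.
#' @param period repeat period from [find_period()]; `NA` passes the read
#'   through uncollapsed.
#' @return list with `monomer_seq`, `period`, `copies`, `consensus_support`
#'   and `was_collapsed`.
#' @export
collapse_repeat <- function(seq, period) {
  n <- nchar(seq)
  if (is.na(period) || period >= n) {
    return(list(monomer_seq = seq, period = n, copies = 1,
                consensus_support = 1, was_collapsed = FALSE))
  }
  cons <- cpp_consensus(seq, as.integer(period))
  list(monomer_seq = cons$consensus, period = as.integer(period),
       copies = n / period, consensus_support = cons$support,
       was_collapsed = TRUE)
}

#' Collapse rolling-circle repeats across a set of reads
#'
#' @param reads data frame with `read_id` and `seq` (merged reads or
#'   unmerged read 1, see [merge_pairs()]).
#' @inheritParams find_period
#' @return data frame with one row per read: `read_id`, `monomer`, `period`,
#'   `copies`, `support`, `was_collapsed`.
#' @export
monomerize <- function(reads, min_period = 15L, min_copies = 2,
                       max_mismatch_rate = 0.1) {
  n <- nrow(reads)
  monomer <- character(n); period <- integer(n); copies <- numeric(n)
  support <- numeric(n); collapsed <- logical(n)
  for (i in seq_len(n)) {
    p <- find_period(reads$seq[i], min_period, min_copies, max_mismatch_rate)
    r <- collapse_repeat(reads$seq[i], p)
    monomer[i] <- r$monomer_seq; period[i] <- r$period
    copies[i] <- r$copies; support[i] <- r$consensus_support
    collapsed[i] <- r$was_collapsed
  }
  data.frame(read_id = reads$read_id, monomer = monomer, period = period,
             copies = copies, support = support, was_collapsed = collapsed,
             stringsAsFactors = FALSE)
}
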