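# Small-RNA extraction and 3' tail classification.
#
# Small RNAs are the monomers recovered from rolling-circle tandem repeats
# (copies >= 2) within the length window. Their genome placement and
# junction tail come from the cyclic monomer placement; features are
# assigned with the strand-aware overlap rules: tRNA when the body overlaps
# a same-strand tRNA by at least 80% (3' extensions allowed), rRNA/mRNA when
# the body is entirely inside a same-strand feature and its 3' terminus is
# not the feature's annotated 3' end with a poly(A) tail (which would be a
# canonical tail, not a decay mark). Per-tRNA CCA ratios and per-gene
# poly(A) proportions with replicate t-tests reproduce the tail statistics.

#' Select small-RNA candidates among collapsed monomers
#'
#' @param monomers monomer table from [monomerize()].
#' @param min_len,max_len monomer length window in nt.
#' @param min_copies required rolling-circle copy number.
#' @return subset of `monomers` that are small-RNA candidates.
#' @export
extract_srnas <- function(monomers, min_len = 15L, max_len = 60L,
                          min_copies = 2) {
  len <- nchar(monomers$monomer)
  keep <- monomers$was_collapsed & monomers$copies >= min_copies &
    len >= min_len & len <= max_len
  monomers[keep, , drop = FALSE]
}

#' Classify the non-templated 3' tail of a transcript-oriented sequence
#'
#' Exact trailing `CCA` takes precedence over a trailing A-run of length
#' 3-20 (poly(A)); a tail is templated when the genome immediately 3' of the
#' placement encodes the identical bases (in which case the bases belong to
#' the body, and a fully templated A-run is never reported as poly(A)).
#'
#' @param seq sequence oriented 5'->3' of the transcript.
#' @param three 0-based genome position of the placement's 3' terminal
#'   (last aligned) nt.
#' @param strand transcript strand.
#' @param genome the `CircularGenome`.
#' @return list with `kind` (`none`/`CCA`/`polyA`), `length` and `templated`.
#' @export
detect_tail <- function(seq, three, strand, genome) {
  n <- nchar(seq)
  none <- list(kind = "none", length = 0L, templated = FALSE)
  tail <- NULL
  if (n >= 3L && endsWith(seq, "CCA")) {
    tail <- list(kind = "CCA", length = 3L)
  } else {
    run <- nchar(seq) - nchar(sub("A*$", "", seq))
    if (run >= 3L) tail <- list(kind = "polyA", length = min(run, 20L))
  }
  if (is.null(tail)) return(none)
  tseq <- substr(seq, n - tail$length + 1L, n)
  flank <- fetch_downstream(genome, advance_pos(three, 1L, strand,
                                                genome$length),
                            tail$length, strand)
  tail$templated <- identical(flank, tseq)
  if (tail$templated && tail$kind == "polyA") return(none)
  tail
}

#' Assemble the small-RNA table from monomer placements and calls
#'
#' @param srnas candidate monomers from [extract_srnas()].
#' @param calls call data frame (canonical termini and junction tails, from
#'   the monomer placement path of [call_precursors()]).
#' @return data frame with one row per placed small RNA: `read_id`,
#'   `length` (monomer), `five_prime`, `three_prime`, `strand`,
#'   `tail_kind`, `tail_len`.
#' @export
srna_table <- function(srnas, calls) {
  m <- match(srnas$read_id, calls$read_id)
  keep <- !is.na(m)
  s <- srnas[keep, , drop = FALSE]
  c <- calls[m[keep], , drop = FALSE]
  data.frame(read_id = s$read_id, length = nchar(s$monomer),
             copies = s$copies,
             five_prime = c$five_prime, three_prime = c$three_prime,
             strand = c$strand, tail_kind = c$tail_kind,
             tail_len = c$tail_len, stringsAsFactors = FALSE)
}

#' Assign each small RNA to a feature class
#'
#' @param srnas small-RNA table from [srna_table()].
#' @param annotation an `AnnotationSet`.
#' @param genome the `CircularGenome`.
#' @param trna_min_overlap minimum fraction of the body inside a tRNA.
#' @return `srnas` with `feature` (gene_id or `NA`) and `feature_class`
#'   (`tRNA`/`rRNA`/`mRNA`/`unassigned`) columns; the cascade is a
#'   partition.
#' @export
assign_features <- function(srnas, annotation, genome,
                            trna_min_overlap = 0.8) {
  L <- genome$length
  n <- nrow(srnas)
  feature <- rep(NA_character_, n)
  fclass <- rep("unassigned", n)
  for (i in seq_len(n)) {
    s <- srnas$strand[i]
    five <- srnas$five_prime[i]; three <- srnas$three_prime[i]
    blen <- transcript_length(five, three, s, L)
    bstart <- if (s == "+") five else three
    same <- annotation[annotation$strand == s, , drop = FALSE]
    if (nrow(same) == 0L) next
    fr <- overlap_fraction(bstart, bstart + blen, same$start, same$end, L)
    tr <- same$biotype == "tRNA" & fr >= trna_min_overlap
    if (any(tr)) {
      j <- which(tr)[which.max(fr[tr])]
      feature[i] <- same$gene_id[j]; fclass[i] <- "tRNA"
      next
    }
    rm_ <- same$biotype %in% c("rRNA", "mRNA") & fr >= 1
    if (any(rm_)) {
      j <- which(rm_)[1L]
      f3 <- if (s == "+") same$end[j] - 1L else same$start[j]
      canonical_tail <- srnas$tail_kind[i] == "polyA" && three == f3
      if (!canonical_tail) {
        feature[i] <- same$gene_id[j]
        fclass[i] <- same$biotype[j]
      }
    }
  }
  srnas$feature <- feature
  srnas$feature_class <- fclass
  srnas
}

#' Per-tRNA ratio of 3'-CCA-bearing to total reads at the 3' terminal nt
#'
#' The denominator is the depth of tRNA-assigned small RNAs covering the
#' tRNA's annotated 3' terminal nucleotide; the numerator restricts to
#' CCA-tailed ones. Undefined ratios (zero depth) are `NA`.
#'
#' @param srnas assigned small-RNA table (see [assign_features()]).
#' @param annotation an `AnnotationSet`.
#' @param genome the `CircularGenome`.
#' @return data frame with `gene_id`, `total`, `cca` and `ratio`.
#' @export
cca_ratio <- function(srnas, annotation, genome) {
  L <- genome$length
  tr <- annotation[annotation$biotype == "tRNA", , drop = FALSE]
  out <- data.frame(gene_id = tr$gene_id, total = 0L, cca = 0L,
                    ratio = NA_real_, stringsAsFactors = FALSE)
  s3 <- srnas[srnas$feature_class == "tRNA", , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    f <- tr[i, ]
    term <- if (f$strand == "+") f$end - 1L else f$start
    rows <- s3$feature == f$gene_id & s3$strand == f$strand
    if (!any(rows)) next
    cov <- vapply(which(rows), function(j) {
      blen <- transcript_length(s3$five_prime[j], s3$three_prime[j],
                                s3$strand[j], L)
      bstart <- if (s3$strand[j] == "+") s3$five_prime[j] else s3$three_prime[j]
      overlap_fraction(bstart, bstart + blen, term, term + 1L, L) > 0
    }, logical(1))
    idx <- which(rows)[cov]
    out$total[i] <- length(idx)
    out$cca[i] <- sum(s3$tail_kind[idx] == "CCA")
    if (out$total[i] > 0L) out$ratio[i] <- out$cca[i] / out$total[i]
  }
  out
}

#' Per-gene poly(A) proportions of small RNAs, with a replicate t-test
#'
#' Proportions are computed per replicate as polyadenylated / total assigned
#' small RNAs per gene; with two or more replicates per condition a
#' two-sided, equal-variance (Student's) two-sample t-test compares the
#' per-replicate proportions between conditions. Degenerate cases are
#' guarded: identical groups give p = 1; zero within-group variance with
#' different means gives p = 0.
#'
#' @param srna_tables list of assigned small-RNA tables, one per replicate.
#' @param conditions character vector of condition labels per replicate
#'   (two conditions for testing).
#' @param genes genes to evaluate; defaults to all mRNA-class features seen.
#' @return data frame with per-gene, per-condition mean proportions, the
#'   per-replicate proportions (as a comma string), `t` and `p` (`NA`
#'   without two replicates per condition).
#' @export
polya_proportion <- function(srna_tables, conditions, genes = NULL) {
  stopifnot(length(srna_tables) == length(conditions))
  conds <- unique(conditions)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(srna_tables, function(x)
      x$feature[x$feature_class == "mRNA"]))))
  }
  prop_of <- function(tab, g) {
    rows <- tab$feature_class == "mRNA" & !is.na(tab$feature) &
      tab$feature == g
    if (!any(rows)) return(NA_real_)
    sum(tab$tail_kind[rows] == "polyA") / sum(rows)
  }
  out <- list()
  for (g in genes) {
    props <- vapply(srna_tables, prop_of, 0, g = g)
    pa <- props[conditions == conds[1L]]
    pb <- if (length(conds) > 1L) props[conditions == conds[2L]] else numeric(0)
    t_stat <- p <- NA_real_
    if (sum(!is.na(pa)) >= 2L && sum(!is.na(pb)) >= 2L) {
      a <- pa[!is.na(pa)]; b <- pb[!is.na(pb)]
      if (isTRUE(all.equal(var(c(a, b)), 0)) ||
          (var(a) == 0 && var(b) == 0 && mean(a) == mean(b))) {
        p <- 1; t_stat <- 0
      } else if (var(a) == 0 && var(b) == 0) {
        p <- 0; t_stat <- if (mean(a) > mean(b)) Inf else -Inf
      } else {
        tt <- t.test(a, b, var.equal = TRUE)
        t_stat <- unname(tt$statistic); p <- tt$p.value
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = g,
      mean_a = mean(pa, na.rm = TRUE), mean_b = mean(pb, na.rm = TRUE),
      props_a = paste(signif(pa, 4), collapse = ","),
      props_b = paste(signif(pb, 4), collapse = ","),
      t = t_stat, p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "conditions") <- conds
  res
}

#' Histogram of small-RNA monomer lengths
#'
#' @param srnas small-RNA table.
#' @param min_len,max_len histogram range.
#' @return data frame with `length` and `count` over the full range.
#' @export
length_histogram <- function(srnas, min_len = 15L, max_len = 60L) {
  lens <- srnas$length
  counts <- vapply(min_len:max_len, function(l) sum(lens == l), 0L)
  data.frame(length = min_len:max_len, count = counts)
}
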