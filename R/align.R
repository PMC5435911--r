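# Seed-and-extend alignment to a small circular genome.
#
# A k-mer index over the forward strand (with origin-spanning k-mers) seeds
# candidate diagonals; the best diagonal clusters are refined by a banded-
# window Smith-Waterman with affine gaps (match +2, mismatch -4, gap open -6,
# gap extend -1, the usual local-mode scoring), reporting the single best
# local alignment with soft-clipped ends. Soft clips of at least `min_clip`
# bases are realigned end-to-end (full length, substitution edits only,
# budget max(2, 10% of length)), after optionally stripping a candidate
# non-templated tail (poly(A) run or CCA remnant) from the junction-facing
# end of the clip; among the strip variants the placement with the fewest
# edits wins, smallest strip on ties, so genome-templated bases stay in the
# body. Light-strand hits are found by aligning the reverse complement of
# the read; read ("transcript") coordinates are reported in original read
# space throughout.

SW_MATCH <- 2L; SW_MISMATCH <- -4L; SW_GAP_OPEN <- 6L; SW_GAP_EXT <- 1L

# Trim unreliable terminal blocks from a local alignment: a terminal match
# run shorter than `anchor_min` that is separated from the alignment body by
# a mismatch or gap is more likely a spurious extension across the
# circularization junction than signal, so it is returned to the soft clip
# (junction refinement then happens at the call stage).
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MXID]", cigar)[[1L]]
  toks <- regmatches(cigar, gregexpr("\\d+[MXID]", cigar))[[1L]]
  data.frame(len = as.integer(sub("[MXID]", "", toks)),
             op = sub("\\d+", "", toks), stringsAsFactors = FALSE)
}

trim_weak_ends <- function(r, anchor_min = 10L) {
  ops <- parse_cigar(r$cigar)
  qstart <- r$qstart; qend <- r$qend
  sstart <- r$sstart; send <- r$send
  qcons <- function(o) o$op %in% c("M", "X", "I")
  scons <- function(o) o$op %in% c("M", "X", "D")
  changed <- TRUE
  while (changed && nrow(ops) > 1L) {
    changed <- FALSE
    # leading
    if (ops$op[1L] != "M" ||
        (ops$len[1L] < anchor_min && ops$op[2L] != "M")) {
      drop <- 1L
      while (drop < nrow(ops) && ops$op[drop + 1L] != "M") drop <- drop + 1L
      cut <- ops[seq_len(drop), , drop = FALSE]
      qstart <- qstart + sum(cut$len[qcons(cut)])
      sstart <- sstart + sum(cut$len[scons(cut)])
      ops <- ops[-seq_len(drop), , drop = FALSE]
      changed <- TRUE
      next
    }
    n <- nrow(ops)
    if (n > 1L && (ops$op[n] != "M" ||
                   (ops$len[n] < anchor_min && ops$op[n - 1L] != "M"))) {
      drop <- n
      while (drop > 1L && ops$op[drop - 1L] != "M") drop <- drop - 1L
      cut <- ops[drop:n, , drop = FALSE]
      qend <- qend - sum(cut$len[qcons(cut)])
      send <- send - sum(cut$len[scons(cut)])
      ops <- ops[seq_len(drop - 1L), , drop = FALSE]
      changed <- TRUE
    }
  }
  nm <- sum(ops$len[ops$op == "M"])
  nx <- sum(ops$len[ops$op == "X"])
  gaps <- ops[ops$op %in% c("I", "D"), , drop = FALSE]
  r$score <- SW_MATCH * nm + SW_MISMATCH * nx -
    (if (nrow(gaps)) sum(SW_GAP_OPEN + SW_GAP_EXT * gaps$len) else 0L)
  r$edits <- nx + sum(gaps$len)
  r$qstart <- qstart; r$qend <- qend; r$sstart <- sstart; r$send <- send
  r$cigar <- paste0(ops$len, ops$op, collapse = "")
  r
}

# signed circular difference mapped to (-L/2, L/2]
wrap_signed <- function(x, L) {
  y <- wrap_pos(x, L)
  ifelse(y > L / 2, y - L, y)
}

#' Build a k-mer index of a circular genome
#'
#' Every genome position contributes one k-mer per strand (queries are
#' searched in both orientations against the forward index); k-mers spanning
#' the origin are included.
#'
#' @param genome a `CircularGenome`.
#' @param k k-mer size.
#' @return a `KmerIndex` list.
#' @export
build_index <- function(genome, k = 12L) {
  L <- genome$length
  if (k > L) stop("k exceeds genome length")
  ext <- paste0(genome$seq, substr(genome$seq, 1L, k - 1L))
  kmers <- substring(ext, seq_len(L), seq_len(L) + k - 1L)
  env <- new.env(hash = TRUE, parent = emptyenv(), size = L)
  sp <- split(0:(L - 1L), kmers)
  for (nm in names(sp)) assign(nm, sp[[nm]], envir = env)
  structure(list(k = as.integer(k), env = env, L = L,
                 genome_name = genome$name,
                 # forward genome with generous pad for ungapped scans
                 ext_scan = paste0(genome$seq,
                                   substr(genome$seq, 1L,
                                          min(L, 600L)))),
            class = "KmerIndex")
}

# seed hits of an oriented query against the forward genome: diagonals
# (genome position of query base 0, mod L) and the 0-based query offsets
seed_hits <- function(q, index, stride) {
  k <- index$k; L <- index$L
  nq <- nchar(q)
  if (nq < k) return(list(diag = integer(0), off = integer(0)))
  offs <- unique(c(seq(1L, nq - k + 1L, by = stride), nq - k + 1L))
  kms <- substring(q, offs, offs + k - 1L)
  dg <- vector("list", length(offs))
  of <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    pos <- get0(kms[i], envir = index$env, ifnotfound = NULL)
    if (!is.null(pos) && length(pos) <= 16L) {
      dg[[i]] <- wrap_pos(pos - (offs[i] - 1L), L)
      of[[i]] <- rep.int(offs[i] - 1L, length(pos))
    }
  }
  list(diag = unlist(dg), off = unlist(of))
}

seed_diags <- function(q, index, stride) seed_hits(q, index, stride)$diag

# cluster seed diagonals (within `gap` of each other) -> list of cluster
# bounds d0, d1 and vote counts, ordered by votes then diagonal
cluster_diags <- function(diags, gap = 16L) {
  if (length(diags) == 0L) return(NULL)
  sd_ <- sort(diags)
  brk <- c(0L, which(diff(sd_) > gap), length(sd_))
  n <- length(brk) - 1L
  d0 <- sd_[brk[-length(brk)] + 1L]
  d1 <- sd_[brk[-1L]]
  votes <- diff(brk)
  o <- order(-votes, d0)
  list(d0 = d0[o], d1 = d1[o], votes = votes[o], n = n)
}

segment_row <- function(read_id, part, qstart, qend, ostart, oend,
                        gstart, glen, strand, cigar, score, edits) {
  structure(list(read_id = read_id, part = part,
                 qstart = as.integer(qstart), qend = as.integer(qend),
                 ostart = as.integer(ostart), oend = as.integer(oend),
                 gstart = as.integer(gstart), glen = as.integer(glen),
                 strand = strand, cigar = cigar,
                 score = as.integer(score), edits = as.integer(edits)),
            class = "data.frame", row.names = c(NA, -1L))
}

# oriented coords -> read-space coords
orient_to_read <- function(os, oe, n, strand) {
  if (strand == "+") c(os, oe) else c(n - oe, n - os)
}

#' Local (soft-clipping) alignment of a read to the circular genome
#'
#' @param seq read or monomer sequence (>= 20 nt for the default scoring).
#' @param index a [build_index()] `KmerIndex`.
#' @param genome the `CircularGenome`.
#' @param min_score minimum local alignment score (default 40, i.e. 20
#'   matching bases).
#' @param read_id read name recorded in the output.
#' @param stride seed sampling stride along the read.
#' @param pad window padding around the seeded diagonal range.
#' @param max_clusters number of diagonal clusters refined per strand.
#' @param trim trim unreliable terminal alignment blocks (see details);
#'   disable to obtain the raw Smith-Waterman optimum.
#' @return one-row segment data frame (read/oriented/genome coordinates,
#'   CIGAR with `M/X/I/D` ops, score, edit distance) or `NULL` when no
#'   alignment reaches `min_score`. Ties prefer the lowest genome
#'   coordinate, then the forward strand.
#' @export
align_local <- function(seq, index, genome, min_score = 40L,
                        read_id = "read", stride = 6L, pad = 40L,
                        max_clusters = 4L, trim = TRUE) {
  L <- index$L
  best <- NULL
  for (strand in c("+", "-")) {
    # a full-length exact forward hit cannot be beaten (ties prefer "+")
    if (strand == "-" && !is.null(best) &&
        best$score >= SW_MATCH * nchar(seq)) break
    q <- if (strand == "+") seq else revcomp(seq)
    nq <- nchar(q)
    hits <- seed_hits(q, index, stride)
    # diagonals within 500 nt share one window, so that any profitable
    # deletion-bridged alignment (gap < 2 * min part - 6, bounded by ~480
    # for <= 490 nt reads) is seen whole; a circularization junction jumps
    # backwards on the genome, which no forward window can bridge, so
    # junction reads still resolve into separate local/clip placements
    cl <- cluster_diags(hits$diag, gap = 500L)
    if (is.null(cl)) next
    # ignore single-seed noise clusters when well-supported ones exist
    if (cl$votes[1L] >= 3L) {
      keep <- cl$votes >= 2L
      cl <- list(d0 = cl$d0[keep], d1 = cl$d1[keep],
                 votes = cl$votes[keep], n = sum(keep))
    }
    for (ci in seq_len(min(cl$n, max_clusters))) {
      d0 <- cl$d0[ci]; d1 <- cl$d1[ci]
      # fast path (single diagonal): a maximal exact seed extension whose
      # flanks diverge hard is exactly what the DP plus weak-end trimming
      # would report, so the DP can be skipped
      if (trim && d0 == d1) {
        off0 <- hits$off[hits$diag == d0][1L]
        ee <- cpp_exact_extend(q, index$ext_scan, off0, d0 + off0)
        run <- ee$qend - ee$qstart
        start_ok <- ee$qstart == 0L || (ee$n_back >= 11L && ee$mm_back >= 2L)
        end_ok <- ee$qend == nq || (ee$n_fwd >= 11L && ee$mm_fwd >= 2L)
        if (run > 0L && start_ok && end_ok) {
          cand <- list(score = SW_MATCH * run,
                       gstart = wrap_pos(ee$sstart, L), glen = run,
                       os = ee$qstart, oe = ee$qend,
                       cigar = sprintf("%dM", run), edits = 0L,
                       strand = strand)
          best <- better_alignment(best, cand)
          next
        }
      }
      wlen <- min(L, (d1 - d0) + nq + 2L * pad)
      ws <- wrap_pos(d0 - pad, L)
      subject <- fetch(genome, ws, ws + wlen, "+")
      r <- cpp_sw(q, subject, SW_MATCH, SW_MISMATCH, SW_GAP_OPEN, SW_GAP_EXT)
      if (r$score <= 0L) next
      if (trim) r <- trim_weak_ends(r)
      cand <- list(score = r$score, gstart = wrap_pos(ws + r$sstart, L),
                   glen = r$send - r$sstart,
                   os = r$qstart, oe = r$qend, cigar = r$cigar,
                   edits = r$edits, strand = strand)
      best <- better_alignment(best, cand)
    }
  }
  if (is.null(best) || best$score < min_score) return(NULL)
  n <- nchar(seq)
  qc <- orient_to_read(best$os, best$oe, n, best$strand)
  segment_row(read_id, "middle", qc[1L], qc[2L], best$os, best$oe,
              best$gstart, best$glen, best$strand, best$cigar,
              best$score, best$edits)
}

better_alignment <- function(best, cand) {
  if (is.null(best)) return(cand)
  if (cand$score > best$score) return(cand)
  if (cand$score == best$score) {
    if (cand$gstart < best$gstart) return(cand)
    if (cand$gstart == best$gstart &&
        cand$strand == "+" && best$strand == "-") return(cand)
  }
  best
}

#' Extract soft-clip intervals from a local alignment
#'
#' @param segment one-row segment data frame from [align_local()].
#' @param read_len total read length.
#' @param min_clip clips shorter than this are ignored.
#' @return data frame with `side` (`left`/`right`, in read space) and the
#'   0-based half-open `cstart`, `cend` clip interval; zero rows when no
#'   clip qualifies.
#' @export
extract_clips <- function(segment, read_len, min_clip = 15L) {
  out <- list()
  if (segment$qstart >= min_clip) {
    out[[1L]] <- data.frame(side = "left", cstart = 0L,
                            cend = segment$qstart, stringsAsFactors = FALSE)
  }
  if (read_len - segment$qend >= min_clip) {
    out[[length(out) + 1L]] <- data.frame(side = "right",
                                          cstart = segment$qend,
                                          cend = read_len,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(side = character(), cstart = integer(),
                      cend = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' End-to-end (full length) placement of a clipped read part
#'
#' Seeds candidate offsets from the k-mer index and counts substitution
#' edits at each; when seeding fails the full genome is scanned. The
#' placement with the fewest edits wins (lowest genome coordinate, then
#' forward strand on ties); `NULL` if the best placement exceeds the edit
#' budget.
#'
#' @param seq clip sequence.
#' @param index,genome index and genome.
#' @param max_edits edit budget; default `max(2, floor(0.1 * nchar(seq)))`.
#' @param strands strands to search (restrict to the middle segment's strand
#'   during split-read realignment).
#' @param read_id read name for the output row.
#' @return one-row segment data frame (part `"e2e"`) or `NULL`.
#' @export
align_end_to_end <- function(seq, index, genome, max_edits = NULL,
                             strands = c("+", "-"), read_id = "read") {
  n <- nchar(seq)
  L <- index$L
  if (n > L) stop("clip longer than genome")
  if (is.null(max_edits)) max_edits <- max(2L, floor(0.1 * n))
  best <- NULL
  take <- function(mm, d, strand) {
    if (is.null(best) || mm < best$edits ||
        (mm == best$edits && d < best$gstart)) {
      best <<- list(edits = mm, gstart = d, strand = strand)
    }
  }
  for (strand in strands) {
    q <- if (strand == "+") seq else revcomp(seq)
    diags <- unique(seed_diags(q, index, stride = 3L))
    strand_best <- Inf
    if (length(diags) > 0L && length(diags) <= 64L) {
      for (d in sort(diags)) {
        mm <- cpp_hamming_scan(q, fetch(genome, d, d + n, "+"))[1L]
        strand_best <- min(strand_best, mm)
        take(mm, d, strand)
      }
    }
    if (strand_best > max_edits) {
      # exhaustive ungapped scan of the whole circle
      mmv <- cpp_hamming_scan(q, index$ext_scan)
      mmv <- mmv[seq_len(min(length(mmv), L))]
      d <- which.min(mmv) - 1L
      take(mmv[d + 1L], d, strand)
    }
  }
  if (is.null(best) || best$edits > max_edits) return(NULL)
  segment_row(read_id, "e2e", 0L, n, 0L, n, best$gstart, n, best$strand,
              sprintf("%dM", n), SW_MATCH * (n - best$edits) +
                SW_MISMATCH * best$edits, best$edits)
}

# strip candidates (number of bases to remove) for a clip's junction-facing
# end; `leading` for right clips, trailing for left clips. Besides the tail
# patterns (A-runs, CCA remnants) a few generic depths are tried, because
# junction-adjacent body bases can end up on the wrong side of the local
# alignment boundary; the minimum-edit / minimum-strip rule plus the
# canonical junction shift make the outcome representation-invariant.
strip_candidates <- function(clip, leading) {
  cand <- 0:min(5L, nchar(clip) - 12L)
  if (leading) {
    run <- a_run_len(clip)
    if (run > 0L) cand <- c(cand, run)
  } else {
    run <- nchar(clip) - nchar(sub("A*$", "", clip))
    if (run > 0L) cand <- c(cand, run)
  }
  sort(unique(cand[cand >= 0L]))
}

# Trim bases that mismatch the genome from the junction-facing end of a
# placed clip (an edit-tolerant end-to-end placement may overshoot the
# junction); the trimmed bases return to the junction gap where the
# canonical shift re-absorbs genuine sequencing errors.
trim_junction_face <- function(seg, sub, genome, leading) {
  if (seg$edits == 0L) return(seg)
  n <- nchar(sub)
  while (n > 0L) {
    if (leading) {
      gp <- if (seg$strand == "+") seg$gstart
            else wrap_pos(seg$gstart + seg$glen - 1L, genome$length)
      rb <- substr(sub, nchar(sub) - n + 1L, nchar(sub) - n + 1L)
      gb <- fetch(genome, gp, gp + 1L, seg$strand)
      if (rb == gb) break
      seg$qstart <- seg$qstart + 1L
      if (seg$strand == "+") seg$gstart <- wrap_pos(seg$gstart + 1L,
                                                    genome$length)
      seg$glen <- seg$glen - 1L
    } else {
      gp <- if (seg$strand == "+") wrap_pos(seg$gstart + seg$glen - 1L,
                                            genome$length)
            else seg$gstart
      rb <- substr(sub, n, n)
      gb <- fetch(genome, gp, gp + 1L, seg$strand)
      if (rb == gb) break
      seg$qend <- seg$qend - 1L
      if (seg$strand == "-") seg$gstart <- wrap_pos(seg$gstart + 1L,
                                                    genome$length)
      seg$glen <- seg$glen - 1L
    }
    seg$edits <- seg$edits - 1L
    n <- n - 1L
  }
  seg$cigar <- sprintf("%dM", seg$glen)
  seg
}

#' Align one (uncollapsed) read: local pass plus end-to-end clip realignment
#'
#' @param read_id read name.
#' @param seq read sequence (transcript orientation, i.e. merged read or
#'   read 1).
#' @param index,genome index and genome.
#' @param min_score local alignment score threshold.
#' @param min_clip minimum clip length realigned (and the granularity of the
#'   `complete` flag).
#' @return list with `segments` (0-3 rows, ordered by read coordinate),
#'   `complete` (no unplaced read stretch of at least `min_clip` remains)
#'   and `status` (`aligned` / `unaligned`).
#' @export
align_read <- function(read_id, seq, index, genome, min_score = 40L,
                       min_clip = 15L) {
  n <- nchar(seq)
  mid <- align_local(seq, index, genome, min_score = min_score,
                     read_id = read_id)
  if (is.null(mid)) {
    return(list(segments = NULL, complete = FALSE, status = "unaligned"))
  }
  segs <- mid
  complete <- TRUE
  clips <- extract_clips(mid, n, min_clip)
  for (i in seq_len(nrow(clips))) {
    side <- clips$side[i]
    cs <- clips$cstart[i]; ce <- clips$cend[i]
    clip <- substr(seq, cs + 1L, ce)
    leading <- side == "right"
    placed <- NULL; placed_strip <- NA_integer_
    for (s in strip_candidates(clip, leading)) {
      sub <- if (leading) substr(clip, s + 1L, nchar(clip))
             else substr(clip, 1L, nchar(clip) - s)
      # stripped variants may be slightly shorter than min_clip: a 12-mer is
      # still effectively unique on a <= 20 kb genome
      if (nchar(sub) < max(12L, min_clip - 3L)) next
      r <- align_end_to_end(sub, index, genome, strands = mid$strand,
                            read_id = read_id)
      if (!is.null(r) && (is.null(placed) || r$edits < placed$edits)) {
        placed <- r; placed_strip <- s
      }
    }
    if (is.null(placed)) { complete <- FALSE; next }
    qs <- if (leading) cs + placed_strip else cs
    qe <- if (leading) ce else ce - placed_strip
    placed$part <- side
    placed$qstart <- qs; placed$qend <- qe
    placed <- trim_junction_face(placed, substr(seq, qs + 1L, qe), genome,
                                 leading)
    qs <- placed$qstart; qe <- placed$qend
    oc <- if (mid$strand == "+") c(qs, qe) else c(n - qe, n - qs)
    placed$ostart <- oc[1L]; placed$oend <- oc[2L]
    segs <- rbind(segs, placed)
  }
  segs <- segs[order(segs$qstart), , drop = FALSE]
  if (nrow(segs) == 1L && nrow(clips) == 0L) segs$part <- "whole"
  rownames(segs) <- NULL
  list(segments = segs, complete = complete, status = "aligned")
}

#' Place a collapsed monomer on the genome by cyclic anchor extension
#'
#' A collapsed monomer is a rotation of the molecule (body plus tail), so
#' instead of split alignment the placement extends an anchor k-mer match
#' cyclically through the monomer in both directions, tolerating isolated
#' substitutions; the maximal genome-contiguous run is the molecule body and
#' the cyclic remainder is the junction sequence (tail). Works down to
#' small-RNA sized monomers where split parts would fall below `min_clip`.
#'
#' @param read_id read name.
#' @param monomer consensus monomer sequence.
#' @param index,genome index and genome.
#' @param min_body minimum genome-contiguous run length accepted.
#' @return list with `segment` (one row) and `junction` (list: `five0`,
#'   `three0`, `strand`, `resid` junction read sequence), or `NULL` when no
#'   placement is found.
#' @export
place_monomer <- function(read_id, monomer, index, genome, min_body = 15L) {
  L <- index$L
  p <- nchar(monomer)
  gseq <- genome$seq
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") monomer else revcomp(monomer)
    diags <- seed_diags(q, index, stride = 2L)
    if (length(diags) == 0L) next
    cl <- cluster_diags(diags, gap = 2L)
    if (is.null(best) || cl$votes[1L] > best$votes) {
      # anchor: first seeded offset on the top diagonal
      d <- cl$d0[1L]
      best <- list(strand = strand, q = q, d = d, votes = cl$votes[1L])
    }
  }
  if (is.null(best)) return(NULL)
  q <- best$q; strand <- best$strand
  # find an anchor position on the diagonal: first exact k-mer
  k <- index$k
  q0 <- NA_integer_
  for (off in seq_len(max(1L, p - k + 1L))) {
    pos <- get0(substring(q, off, off + k - 1L), envir = index$env,
                ifnotfound = NULL)
    if (!is.null(pos) && any(wrap_pos(pos - (off - 1L), L) == best$d)) {
      q0 <- off - 1L
      break
    }
  }
  if (is.na(q0)) return(NULL)
  g0 <- wrap_pos(best$d + q0, L)
  qd <- paste0(q, q)
  ext <- cpp_cyclic_extend(q, gseq, q0, g0,
                           budget = max(2L, as.integer(ceiling(0.05 * p))))
  tf <- ext$tf; tb <- ext$tb; mm_used <- ext$mismatches
  rlen <- tb + tf + 1L
  if (rlen < min(p, min_body)) return(NULL)
  gs <- wrap_pos(g0 - tb, L)
  # cyclic remainder after the forward end (oriented space)
  resid_o <- if (rlen == p) "" else {
    st <- (q0 + tf + 1L) %% p
    substr(qd, st + 1L, st + (p - rlen))
  }
  if (strand == "+") {
    five0 <- gs; three0 <- wrap_pos(g0 + tf, L)
    resid <- resid_o
  } else {
    five0 <- wrap_pos(g0 + tf, L); three0 <- gs
    resid <- if (nzchar(resid_o)) revcomp(resid_o) else ""
  }
  seg <- segment_row(read_id, "whole", 0L, rlen, 0L, rlen, gs, rlen,
                     strand, sprintf("%dM", rlen),
                     SW_MATCH * (rlen - mm_used) + SW_MISMATCH * mm_used,
                     mm_used)
  list(segment = seg,
       junction = list(five0 = five0, three0 = three0, strand = strand,
                       resid = resid))
}

#' Write segment alignments as SAM
#'
#' Soft clips are encoded as `S` operations; the header declares the
#' circular genome length. Alignments crossing the origin are written with
#' their unwrapped start position (noted in a comment line).
#'
#' @param segments segment data frame (rows from [align_read()] /
#'   [place_monomer()]).
#' @param reads data frame with `read_id` and `seq` used to emit sequences.
#' @param genome the `CircularGenome`.
#' @param path output SAM path.
#' @export
write_sam <- function(segments, reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length),
               "@CO\tcircular genome; origin-spanning alignments unwrapped"),
             con)
  if (is.null(segments) || nrow(segments) == 0L) return(invisible(path))
  seqmap <- setNames(reads$seq, reads$read_id)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    rs <- seqmap[[s$read_id]]
    n <- nchar(rs)
    oseq <- if (s$strand == "+") rs else revcomp(rs)
    lead <- s$ostart
    trail <- n - s$oend
    cigar <- paste0(if (lead > 0L) sprintf("%dS", lead) else "",
                    s$cigar,
                    if (trail > 0L) sprintf("%dS", trail) else "")
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                       s$read_id, if (s$strand == "+") 0L else 16L,
                       genome$name, s$gstart + 1L, 60L, cigar, oseq,
                       s$edits), con)
  }
  invisible(path)
}
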