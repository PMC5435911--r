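# Ground-truth simulator for circularized RNA sequencing libraries.
#
# Generative model (mirrors the library chemistry): linear RNAs with defined
# 5'/3' termini and optional non-templated tails (CCA on tRNAs, poly(A) on
# decay fragments) are circularized by intramolecular ligation with some
# probability; non-circularized molecules are destroyed (RNase R step) and
# never yield reads. Each circle is reverse transcribed by rolling-circle,
# randomly primed synthesis into a cDNA of one or more tandem copies of the
# molecule, entered at a uniformly random rotation. The cDNA is fragmented,
# and each fragment is sequenced as a 250 bp paired-end read with
# substitution errors; inserts shorter than the read length show adapter
# read-through. The library is directional: read 1 is in the sense of the
# RNA. Every molecule and every read is recorded in a truth table.

#' Simulation configuration
#'
#' @param n_molecules number of RNA molecules to draw from the templates.
#' @param circularization_prob probability a molecule circularizes (only
#'   circles survive the exonuclease step and yield reads).
#' @param copy_mean mean rolling-circle copy number; copies are
#'   `1 + Geometric` with this mean (>= 1).
#' @param fragment_mean mean cDNA fragment length in nt (uniform breakpoint
#'   model: expected spacing between breaks).
#' @param fragment_sd fragment length sd, used only by the `"normal"`
#'   fragmentation mode.
#' @param fragmentation `"uniform"` (breakpoints uniform on the cDNA) or
#'   `"normal"` (sequential Normal(mean, sd) fragment lengths).
#' @param read_length read length in nt (>= 30).
#' @param error_rate per-base substitution error rate in `[0, 0.05]`.
#' @param adapter1,adapter2 3' adapter sequences seen on read 1 / read 2
#'   (defaults: Illumina TruSeq stems).
#' @param min_insert fragments shorter than this are lost to size selection.
#' @param allocation `"proportional"` draws template counts by deterministic
#'   proportional allocation (expected composition with minimal Monte-Carlo
#'   variance); `"multinomial"` samples each molecule independently.
#' @param seed RNG seed; fixed-seed runs are byte-identical.
#' @return list of validated simulation parameters.
#' @export
sim_config <- function(n_molecules = 2000L,
                       circularization_prob = 0.5,
                       copy_mean = 2.5,
                       fragment_mean = 350,
                       fragment_sd = 80,
                       fragmentation = c("uniform", "normal"),
                       read_length = 250L,
                       error_rate = 0.002,
                       adapter1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       adapter2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA",
                       min_insert = 30L,
                       allocation = c("proportional", "multinomial"),
                       seed = 1L) {
  fragmentation <- match.arg(fragmentation)
  allocation <- match.arg(allocation)
  stopifnot(n_molecules >= 1L,
            circularization_prob >= 0, circularization_prob <= 1,
            copy_mean >= 1,
            fragment_mean >= 50,
            read_length >= 30L,
            error_rate >= 0, error_rate <= 0.05,
            nzchar(adapter1), nzchar(adapter2))
  list(n_molecules = as.integer(n_molecules),
       circularization_prob = circularization_prob,
       copy_mean = copy_mean,
       fragment_mean = fragment_mean,
       fragment_sd = fragment_sd,
       fragmentation = fragmentation,
       read_length = as.integer(read_length),
       error_rate = error_rate,
       adapter1 = adapter1, adapter2 = adapter2,
       min_insert = as.integer(min_insert),
       allocation = allocation,
       seed = as.integer(seed))
}

tail_sequence <- function(kind, len) {
  switch(kind,
         none = "",
         CCA = "CCA",
         polyA = strrep("A", len),
         stop("unknown tail kind: ", kind))
}

new_templates <- function(df, genome) {
  df$weight <- df$weight / sum(df$weight)
  L <- genome$length
  tlen <- mapply(transcript_length, df$five_prime, df$three_prime,
                 df$strand, MoreArgs = list(L = L))
  if (any(tlen < 15L)) stop("template shorter than 15 nt")
  if (any(df$tail_kind == "polyA" & (df$tail_len < 0L | df$tail_len > 60L)))
    stop("polyA tail length out of [0, 60]")
  df$length <- as.integer(tlen)
  class(df) <- c("TranscriptTemplates", "data.frame")
  df
}

#' Default transcript templates for a WT or processing-deficient scenario
#'
#' Builds a template population from the annotation: mature species with
#' exact annotated ends (tRNAs carry 3'-CCA), multi-gene precursors spanning
#' tRNA boundaries, and partially degraded, polyadenylated intermediates with
#' ends internal to ORFs. The `KO` scenario (loss of the tRNA 5' nuclease)
#' doubles the precursor and degradation weight fractions relative to `WT`.
#'
#' @param annotation an `AnnotationSet`.
#' @param genome the `CircularGenome` the annotation refers to.
#' @param scenario `"WT"` or `"KO"`.
#' @param precursor_fraction total weight fraction of precursor templates
#'   (default 0.05 for WT, doubled to 0.10 for KO).
#' @param degradation_fraction weight fraction of degradation intermediates
#'   (defaults to `precursor_fraction`).
#' @param n_precursors,n_degradation number of precursor / degradation
#'   templates to construct.
#' @param polya_len poly(A) tail length on degradation intermediates.
#' @return A `TranscriptTemplates` data frame with normalized weights.
#' @export
make_default_templates <- function(annotation, genome,
                                   scenario = c("WT", "KO"),
                                   precursor_fraction = NULL,
                                   degradation_fraction = NULL,
                                   n_precursors = 4L,
                                   n_degradation = 3L,
                                   polya_len = 8L) {
  scenario <- match.arg(scenario)
  if (is.null(precursor_fraction)) {
    precursor_fraction <- if (scenario == "KO") 0.10 else 0.05
  }
  if (is.null(degradation_fraction)) degradation_fraction <- precursor_fraction
  ann <- annotation[order(annotation$start), ]
  L <- genome$length

  mature_ends <- function(f) {
    if (f$strand == "+") c(f$start, f$end - 1L) else c(f$end - 1L, f$start)
  }
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    f <- ann[i, ]
    if (f$biotype == "dloop") next
    e <- mature_ends(f)
    rows[[length(rows) + 1L]] <- data.frame(
      template_id = paste0("mature_", f$gene_id), class = "mature",
      five_prime = e[1L], three_prime = e[2L], strand = f$strand,
      tail_kind = if (f$biotype == "tRNA") "CCA" else "none",
      tail_len = if (f$biotype == "tRNA") 3L else 0L,
      weight = if (f$biotype == "tRNA") 0.4 else 1.0,
      stringsAsFactors = FALSE)
  }
  mature <- do.call(rbind, rows)

  # adjacent same-strand feature runs containing a tRNA -> precursors
  prec <- list()
  n <- nrow(ann)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    a <- ann[i, ]; b <- ann[j, ]
    if (a$strand != b$strand) next
    if (wrap_pos(b$start - a$end, L) != 0L) next
    if (!("tRNA" %in% c(a$biotype, b$biotype))) next
    if (all(c(a$biotype, b$biotype) == "tRNA") && a$strand == "+") next
    iv <- c(a$start, a$start + (a$end - a$start) + (b$end - b$start))
    ends <- if (a$strand == "+") c(iv[1L], iv[2L] - 1L) else c(iv[2L] - 1L, iv[1L])
    prec[[length(prec) + 1L]] <- data.frame(
      template_id = paste0("precursor_", a$gene_id, "_", b$gene_id),
      class = "precursor",
      five_prime = wrap_pos(ends[1L], L), three_prime = wrap_pos(ends[2L], L),
      strand = a$strand, tail_kind = "none", tail_len = 0L, weight = 1,
      stringsAsFactors = FALSE)
  }
  precursor <- do.call(rbind, prec)
  if (!is.null(precursor) && nrow(precursor) > n_precursors) {
    keep <- round(seq(1L, nrow(precursor), length.out = n_precursors))
    precursor <- precursor[keep, ]
  }

  mr <- ann[ann$biotype == "mRNA", ]
  deg <- list()
  for (i in seq_len(min(n_degradation, nrow(mr)))) {
    f <- mr[i, ]
    len <- f$end - f$start
    e <- mature_ends(f)
    five <- advance_pos(e[1L], as.integer(floor(0.30 * len)), f$strand, L)
    three <- advance_pos(e[1L], as.integer(floor(0.65 * len)) - 1L, f$strand, L)
    deg[[length(deg) + 1L]] <- data.frame(
      template_id = paste0("decay_", f$gene_id),
      class = "degradation_intermediate",
      five_prime = five, three_prime = three, strand = f$strand,
      tail_kind = "polyA", tail_len = as.integer(polya_len), weight = 1,
      stringsAsFactors = FALSE)
  }
  degradation <- do.call(rbind, deg)

  mature$weight <- mature$weight / sum(mature$weight) *
    (1 - precursor_fraction - degradation_fraction)
  out <- mature
  if (precursor_fraction > 0 && !is.null(precursor)) {
    precursor$weight <- precursor_fraction / nrow(precursor)
    out <- rbind(out, precursor)
  }
  if (degradation_fraction > 0 && !is.null(degradation)) {
    degradation$weight <- degradation_fraction / nrow(degradation)
    out <- rbind(out, degradation)
  }
  rownames(out) <- NULL
  new_templates(out, genome)
}

#' Small-RNA template population with defined tail chemistry
#'
#' Builds 3'-anchored tRNA fragments that carry 3'-CCA with probability
#' `cca_fraction`, and short internal mRNA decay fragments that carry a
#' non-templated poly(A) tail with per-gene probability `polya_fraction`.
#'
#' @param annotation an `AnnotationSet`.
#' @param genome the `CircularGenome`.
#' @param cca_fraction fraction of tRNA fragments bearing 3'-CCA.
#' @param polya_fraction per-gene fraction of polyadenylated mRNA fragments
#'   (recycled over the selected mRNAs).
#' @param n_trna,n_mrna number of tRNA / mRNA genes to draw fragments from.
#' @param trna_frag_len length of the 3'-anchored tRNA fragment body.
#' @param mrna_frag_lens fragment body lengths for mRNA decay fragments
#'   (alternated across genes; the 19/22 nt species seen in mitochondrial
#'   small-RNA data).
#' @param polya_len poly(A) tail length on tailed mRNA fragments.
#' @param trna_weight total weight of the tRNA fragment group (the mRNA
#'   group receives the remainder).
#' @return A `TranscriptTemplates` data frame.
#' @export
make_srna_templates <- function(annotation, genome,
                                cca_fraction = 0.6,
                                polya_fraction = 0.1,
                                trna_weight = 0.25,
                                n_trna = 4L, n_mrna = 4L,
                                trna_frag_len = 32L,
                                mrna_frag_lens = c(19L, 22L),
                                polya_len = 6L) {
  L <- genome$length
  tr <- annotation[annotation$biotype == "tRNA" & annotation$strand == "+", ]
  tr <- tr[seq_len(min(n_trna, nrow(tr))), ]
  mr <- annotation[annotation$biotype == "mRNA" & annotation$strand == "+", ]
  mr <- mr[seq_len(min(n_mrna, nrow(mr))), ]
  polya_fraction <- rep_len(polya_fraction, nrow(mr))
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    f <- tr[i, ]
    three <- f$end - 1L
    five <- wrap_pos(f$end - trna_frag_len, L)
    for (tailed in c(TRUE, FALSE)) {
      w <- trna_weight / nrow(tr) * if (tailed) cca_fraction else 1 - cca_fraction
      if (w <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = paste0("srna_", f$gene_id, if (tailed) "_CCA" else "_noCCA"),
        class = "sRNA", five_prime = five, three_prime = three,
        strand = f$strand, tail_kind = if (tailed) "CCA" else "none",
        tail_len = if (tailed) 3L else 0L, weight = w,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(mr))) {
    f <- mr[i, ]
    len <- mrna_frag_lens[(i - 1L) %% length(mrna_frag_lens) + 1L]
    five <- f$start + 40L
    three <- five + len - 1L
    for (tailed in c(TRUE, FALSE)) {
      w <- (1 - trna_weight) / nrow(mr) *
        if (tailed) polya_fraction[i] else 1 - polya_fraction[i]
      if (w <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = paste0("srna_", f$gene_id, if (tailed) "_pA" else "_nopA"),
        class = "sRNA", five_prime = five, three_prime = three,
        strand = f$strand, tail_kind = if (tailed) "polyA" else "none",
        tail_len = if (tailed) as.integer(polya_len) else 0L, weight = w,
        stringsAsFactors = FALSE)
    }
  }
  new_templates(do.call(rbind, rows), genome)
}

# substitution errors at a fixed per-base rate
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "")[[1L]]
    pos <- sample.int(length(s), nerr[i])
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a circularized RNA sequencing library with full ground truth
#'
#' @param templates a `TranscriptTemplates` data frame.
#' @param genome a `CircularGenome`.
#' @param config a [sim_config()] list.
#' @return list with `reads` (data frame: `read_id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`), `molecules` (per-molecule truth incl. canonical termini
#'   `five_c`/`three_c`, see [canonicalize_call()]) and `read_truth`
#'   (per-read source coordinates and junction-recoverability flags).
#' @export
simulate_library <- function(templates, genome, config = sim_config()) {
  set.seed(config$seed)
  L <- genome$length
  rl <- config$read_length
  nt <- nrow(templates)

  tpl_seq <- character(nt)
  tpl_canon <- vector("list", nt)
  for (i in seq_len(nt)) {
    t <- templates[i, ]
    tail <- tail_sequence(t$tail_kind, t$tail_len)
    tpl_seq[i] <- paste0(
      transcript_fetch(genome, t$five_prime, t$three_prime, t$strand), tail)
    tpl_canon[[i]] <- canonicalize_call(genome, t$five_prime, t$three_prime,
                                        t$strand, tail)
  }
  if (any(nchar(tpl_seq) > L)) stop("template longer than genome")

  n <- config$n_molecules
  ti <- if (identical(config$allocation, "multinomial")) {
    sample.int(nt, n, replace = TRUE, prob = templates$weight)
  } else {
    # deterministic proportional allocation; remainder goes to the largest
    # fractional parts
    exp_n <- n * templates$weight / sum(templates$weight)
    cnt <- floor(exp_n)
    short <- n - sum(cnt)
    if (short > 0L) {
      add <- order(exp_n - cnt, decreasing = TRUE)[seq_len(short)]
      cnt[add] <- cnt[add] + 1L
    }
    sample(rep.int(seq_len(nt), cnt))
  }
  circ <- runif(n) < config$circularization_prob
  copies <- 1L + rgeom(n, 1 / config$copy_mean)

  mol <- data.frame(
    molecule_id = sprintf("m%06d", seq_len(n)),
    template_id = templates$template_id[ti],
    class = templates$class[ti],
    five_prime = templates$five_prime[ti],
    three_prime = templates$three_prime[ti],
    strand = templates$strand[ti],
    tail_kind = templates$tail_kind[ti],
    tail_len = templates$tail_len[ti],
    circularized = circ,
    copies = copies,
    five_c = vapply(tpl_canon, `[[`, 0, "five")[ti],
    three_c = vapply(tpl_canon, `[[`, 0, "three")[ti],
    tail_kind_c = vapply(tpl_canon, `[[`, "", "tail_kind")[ti],
    stringsAsFactors = FALSE)

  ids <- list(); s1 <- list(); s2 <- list(); rt <- list()
  pad_bases <- c("A", "C", "G", "T")
  for (m in which(circ)) {
    tseq <- tpl_seq[ti[m]]
    mt <- nchar(tseq)
    tl <- templates$tail_len[ti[m]]
    ci <- copies[m]
    cdna_len <- ci * mt
    r <- sample.int(mt, 1L) - 1L
    cdna <- substr(strrep(tseq, ci + 1L), r + 1L, r + cdna_len)
    bounds <- seq.int(mt - r, by = mt, length.out = ci)
    bounds <- bounds[bounds > 0L & bounds < cdna_len]

    if (config$fragmentation == "uniform") {
      nb <- rpois(1L, cdna_len / config$fragment_mean)
      cuts <- if (nb > 0L) sort(sample.int(cdna_len - 1L, min(nb, cdna_len - 1L)))
              else integer(0)
    } else {
      cuts <- integer(0); at <- 0
      repeat {
        step <- max(config$min_insert,
                    round(rnorm(1L, config$fragment_mean, config$fragment_sd)))
        at <- at + step
        if (at >= cdna_len) break
        cuts <- c(cuts, at)
      }
    }
    fs <- c(0L, cuts); fe <- c(cuts, cdna_len)
    keep <- (fe - fs) >= config$min_insert
    fs <- fs[keep]; fe <- fe[keep]
    if (length(fs) == 0L) next

    for (fgi in seq_along(fs)) {
      a <- fs[fgi]; b <- fe[fgi]
      insert <- substr(cdna, a + 1L, b)
      il <- b - a
      rid <- sprintf("%s:f%02d", mol$molecule_id[m], fgi)
      r1 <- if (il >= rl) substr(insert, 1L, rl) else {
        full <- paste0(insert, config$adapter1)
        if (nchar(full) < rl) {
          full <- paste0(full, paste(sample(pad_bases, rl - nchar(full),
                                            replace = TRUE), collapse = ""))
        }
        substr(full, 1L, rl)
      }
      ins_rc <- revcomp(insert)
      r2 <- if (il >= rl) substr(ins_rc, 1L, rl) else {
        full <- paste0(ins_rc, config$adapter2)
        if (nchar(full) < rl) {
          full <- paste0(full, paste(sample(pad_bases, rl - nchar(full),
                                            replace = TRUE), collapse = ""))
        }
        substr(full, 1L, rl)
      }
      merged_expected <- il <= 2L * rl - 10L
      ds_s <- a; ds_e <- if (merged_expected) b else min(b, a + rl)
      bb <- bounds[bounds > ds_s & bounds < ds_e]
      jrec <- any((bb - tl - ds_s) >= 15L & (ds_e - bb) >= 15L)
      collapsible <- (ds_e - ds_s) >= 2L * mt
      k <- length(ids) + 1L
      ids[[k]] <- rid; s1[[k]] <- r1; s2[[k]] <- r2
      rt[[k]] <- data.frame(
        read_id = rid, molecule_id = mol$molecule_id[m],
        template_id = mol$template_id[m],
        frag_start = a, insert_len = il,
        merged_expected = merged_expected,
        n_boundaries = length(bb),
        collapsible = collapsible,
        junction_recoverable = jrec | collapsible,
        stringsAsFactors = FALSE)
    }
  }

  seq1 <- mutate_seqs(unlist(s1), config$error_rate)
  seq2 <- mutate_seqs(unlist(s2), config$error_rate)
  reads <- data.frame(read_id = unlist(ids),
                      seq1 = seq1, seq2 = seq2,
                      qual1 = strrep("I", nchar(seq1)),
                      qual2 = strrep("I", nchar(seq2)),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) {
    reads <- data.frame(read_id = character(), seq1 = character(),
                        seq2 = character(), qual1 = character(),
                        qual2 = character(), stringsAsFactors = FALSE)
  }
  read_truth <- if (length(rt)) do.call(rbind, rt) else NULL
  list(reads = reads, molecules = mol, read_truth = read_truth,
       config = config)
}

#' Expected per-terminus molecule counts from simulator truth
#'
#' Counts circularized molecules (the population surviving the exonuclease
#' step) by canonical (five_prime, three_prime, strand).
#'
#' @param molecules the `molecules` truth table from [simulate_library()].
#' @return data frame with `five_prime`, `three_prime`, `strand`, `count`.
#' @export
truth_end_table <- function(molecules) {
  m <- molecules[molecules$circularized, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(five_prime = integer(), three_prime = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(list(count = m$molecule_id),
                   by = list(five_prime = m$five_c, three_prime = m$three_c,
                             strand = m$strand),
                   FUN = length)
  agg[order(-agg$count), ]
}

#' Write sequences to FASTQ
#'
#' @param ids,seqs,quals read names, sequences and quality strings.
#' @param path output path (`.gz` for gzip).
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped).
#' @return list with `ids`, `seqs`, `quals` character vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(ids = names(x), seqs = unname(as.character(x)),
       quals = unname(as.character(S4Vectors::mcols(x)$qualities)))
}
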