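# Pipeline orchestration: trim -> merge -> monomerize -> align -> call ->
# aggregate/quantify/sRNA, for single samples and two-condition comparisons.
# Replicates are pooled for link and coverage analysis but kept separate for
# the per-gene small-RNA statistics.

#' Default pipeline parameters
#'
#' @param ... overrides for individual parameters.
#' @return named list of stage parameters (adapter sequences, trim/merge
#'   thresholds, monomerize period scan settings, aligner seeds and scores,
#'   junction tolerances, small-RNA window, CPM pseudocount).
#' @export
pipeline_params <- function(...) {
  p <- list(
    adapter1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
    adapter2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA",
    trim_min_len = 20L,
    merge_min_overlap = 10L,
    merge_max_overlap = 245L,
    merge_max_mismatch_density = 0.25,
    min_period = 15L,
    min_copies = 2,
    period_max_mismatch_rate = 0.1,
    k = 12L,
    min_score = 40L,
    min_clip = 15L,
    min_body = 15L,
    contiguity_tol = 2L,
    max_junction_gap = 4L,
    rotation_tol = 2L,
    min_molecule_len = 15L,
    srna_min_len = 15L,
    srna_max_len = 60L,
    pseudocount = 1
  )
  o <- list(...)
  p[names(o)] <- o
  p
}

#' Align processed reads and call molecule termini
#'
#' Routes collapsed monomers through the cyclic placement
#' ([place_monomer()]) and uncollapsed reads through split alignment
#' ([align_read()]), then calls junctions ([call_precursor()],
#' [call_from_monomer()]).
#'
#' @param monomers monomer table from [monomerize()].
#' @param index,genome k-mer index and genome.
#' @param params [pipeline_params()] list.
#' @return list with `segments`, `calls`, `n_aligned`, and per-read `status`
#'   (`unaligned`, `aligned_single`, `aligned_split`, `aligned_collapsed`).
#' @export
call_precursors <- function(monomers, index, genome,
                            params = pipeline_params()) {
  seg_list <- list(); call_list <- list()
  status <- character(nrow(monomers))
  for (i in seq_len(nrow(monomers))) {
    id <- monomers$read_id[i]
    mono <- monomers$monomer[i]
    if (monomers$was_collapsed[i]) {
      pm <- place_monomer(id, mono, index, genome,
                          min_body = params$min_body)
      if (is.null(pm)) { status[i] <- "unaligned"; next }
      seg_list[[length(seg_list) + 1L]] <- pm$segment
      cl <- call_from_monomer(pm, genome,
                              max_junction_gap = params$max_junction_gap,
                              min_len = params$min_molecule_len)
      if (!is.null(cl)) call_list[[length(call_list) + 1L]] <- cl
      status[i] <- "aligned_collapsed"
    } else {
      ar <- align_read(id, mono, index, genome,
                       min_score = params$min_score,
                       min_clip = params$min_clip)
      if (is.null(ar$segments)) { status[i] <- "unaligned"; next }
      seg_list[[length(seg_list) + 1L]] <- ar$segments
      status[i] <- if (nrow(ar$segments) > 1L) "aligned_split"
                   else "aligned_single"
      if (ar$complete && nrow(ar$segments) >= 2L) {
        cl <- call_precursor(ar$segments, mono, genome,
                             contiguity_tol = params$contiguity_tol,
                             max_junction_gap = params$max_junction_gap,
                             rotation_tol = params$rotation_tol,
                             min_len = params$min_molecule_len)
        if (!is.null(cl)) call_list[[length(call_list) + 1L]] <- cl
      }
    }
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else NULL
  calls <- if (length(call_list)) do.call(rbind, call_list) else empty_calls()
  list(segments = segments, calls = calls,
       n_aligned = sum(status != "unaligned"),
       status = data.frame(read_id = monomers$read_id, status = status,
                           stringsAsFactors = FALSE))
}

#' Run the full pipeline on one sample
#'
#' @param reads read-pair data frame (`read_id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`), e.g. from [simulate_library()] or two FASTQ files via
#'   [read_fastq()].
#' @param genome,annotation genome and annotation.
#' @param params [pipeline_params()] list.
#' @param index optional prebuilt [build_index()] (rebuilt otherwise).
#' @param sample_id label for the outputs.
#' @return list with per-stage outputs: `trimmed` counts, `merged`,
#'   `monomers`, `segments`, `calls` (annotated), `links` + `ends`,
#'   `coverage` (raw `CoverageTrack`), `srnas` (assigned small-RNA table),
#'   `n_aligned` and a `counts` stage log.
#' @export
run_sample <- function(reads, genome, annotation,
                       params = pipeline_params(), index = NULL,
                       sample_id = "sample") {
  if (is.null(index)) index <- build_index(genome, params$k)
  tr <- trim_adapters(reads, params$adapter1, params$adapter2,
                      min_len = params$trim_min_len)
  merged <- merge_pairs(tr$reads,
                        min_overlap = params$merge_min_overlap,
                        max_overlap = params$merge_max_overlap,
                        max_mismatch_density = params$merge_max_mismatch_density)
  monomers <- monomerize(merged,
                         min_period = params$min_period,
                         min_copies = params$min_copies,
                         max_mismatch_rate = params$period_max_mismatch_rate)
  ac <- call_precursors(monomers, index, genome, params)
  calls <- annotate_calls(ac$calls, annotation, genome)
  agg <- aggregate_links(calls, annotation, genome, condition = sample_id)
  cov <- coverage_track(ac$segments, genome$length,
                        library_total = ac$n_aligned)
  srna_cand <- extract_srnas(monomers, params$srna_min_len,
                             params$srna_max_len, params$min_copies)
  srnas <- assign_features(srna_table(srna_cand, calls), annotation, genome)
  counts <- data.frame(
    stage = c("input_pairs", "dropped_trim", "merged", "unmerged_r1",
              "collapsed", "aligned", "calls"),
    n = c(nrow(reads), tr$dropped, sum(merged$merged), sum(!merged$merged),
          sum(monomers$was_collapsed), ac$n_aligned, nrow(calls)),
    stringsAsFactors = FALSE)
  list(sample_id = sample_id, merged = merged, monomers = monomers,
       segments = ac$segments, status = ac$status, calls = calls,
       links = agg$links, ends = agg$ends, coverage = cov,
       srnas = srnas, n_aligned = ac$n_aligned, counts = counts)
}

#' Run a two-condition comparison
#'
#' Replicates are pooled per condition for links and coverage; per-replicate
#' small-RNA tables feed the poly(A) proportion t-tests.
#'
#' @param samples list of samples; each a list with `reads`, `condition`,
#'   `replicate`.
#' @param genome,annotation genome and annotation.
#' @param params [pipeline_params()] list.
#' @return list with per-sample results, pooled per-condition `links`,
#'   `link_fc` ([compare_links()], condition A vs B), `coverage_fc`
#'   ([log2fc_track()]), `polya` ([polya_proportion()]; `NULL` with fewer
#'   than 2 replicates in a condition, with a warning) and pooled per-tRNA
#'   `cca` ratios per condition.
#' @export
run_comparison <- function(samples, genome, annotation,
                           params = pipeline_params()) {
  index <- build_index(genome, params$k)
  conds <- vapply(samples, `[[`, "", "condition")
  uc <- unique(conds)
  if (length(uc) < 2L) stop("two conditions are required")
  res <- lapply(seq_along(samples), function(i) {
    run_sample(samples[[i]]$reads, genome, annotation, params, index,
               sample_id = sprintf("%s_rep%s", samples[[i]]$condition,
                                   samples[[i]]$replicate))
  })
  pool <- function(cond) {
    idx <- which(conds == cond)
    calls <- do.call(rbind, lapply(res[idx], `[[`, "calls"))
    segs <- do.call(rbind, lapply(res[idx], `[[`, "segments"))
    n_aligned <- sum(vapply(res[idx], `[[`, 0L, "n_aligned"))
    agg <- aggregate_links(calls, annotation, genome, condition = cond)
    cov <- coverage_track(segs, genome$length, library_total = n_aligned)
    srnas <- do.call(rbind, lapply(res[idx], `[[`, "srnas"))
    list(calls = calls, links = agg$links, ends = agg$ends, coverage = cov,
         n_aligned = n_aligned, srnas = srnas)
  }
  pa <- pool(uc[1L]); pb <- pool(uc[2L])
  link_fc <- compare_links(pa$links, pb$links, pa$n_aligned, pb$n_aligned,
                           pseudocount = params$pseudocount)
  coverage_fc <- log2fc_track(cpm(pa$coverage), cpm(pb$coverage),
                              pseudocount = params$pseudocount)
  polya <- NULL
  if (all(table(conds)[uc] >= 2L)) {
    polya <- polya_proportion(lapply(res, `[[`, "srnas"), conds)
  } else {
    warning("fewer than 2 replicates in a condition; t-tests skipped")
  }
  cca <- lapply(setNames(list(pa, pb), uc[1:2]), function(p)
    cca_ratio(p$srnas, annotation, genome))
  list(samples = res, conditions = uc,
       pooled = setNames(list(pa, pb), uc[1:2]),
       link_fc = link_fc, coverage_fc = coverage_fc,
       polya = polya, cca = cca)
}

#' Write the standard output files for a processed sample
#'
#' Emits the monomer sidecar TSV, SAM alignments, link table TSV (1-based
#' coordinates), per-strand 5'/3' end BEDGraph tracks, coverage BEDGraph,
#' Circos link/karyotype files and the small-RNA TSV.
#'
#' @param result a [run_sample()] result.
#' @param genome,annotation genome and annotation.
#' @param dir output directory (created if needed).
#' @export
write_sample_outputs <- function(result, genome, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write.table(result$monomers[, c("read_id", "period", "copies", "support",
                                  "was_collapsed")],
              fp("monomers.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write_sam(result$segments, setNames(result$monomers[, c("read_id",
                                                          "monomer")],
                                      c("read_id", "seq")),
            genome, fp("alignments.sam"))
  links1 <- result$links
  links1$five_prime <- links1$five_prime + 1L
  links1$three_prime <- links1$three_prime + 1L
  write.table(links1, fp("links.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  for (s in c("+", "-")) {
    tag <- if (s == "+") "plus" else "minus"
    write_bedgraph(result$ends$five[[s]], genome$name,
                   fp(sprintf("ends5_%s.bedgraph", tag)),
                   sprintf("five_prime_ends_%s", tag))
    write_bedgraph(result$ends$three[[s]], genome$name,
                   fp(sprintf("ends3_%s.bedgraph", tag)),
                   sprintf("three_prime_ends_%s", tag))
  }
  write_bedgraph(result$coverage$plus, genome$name,
                 fp("coverage_plus.bedgraph"), "coverage_plus")
  write_bedgraph(result$coverage$minus, genome$name,
                 fp("coverage_minus.bedgraph"), "coverage_minus")
  export_circos(result$links, annotation, genome, fp("links.circos.txt"),
                fp("karyotype.circos.txt"))
  write.table(result$srnas, fp("srnas.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(result$counts, fp("stage_counts.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with `genome`, `annotation`, `samples` (list of
#'   `condition`, `replicate`, `r1`, `r2`) and optional `params` overrides.
#' @return list with loaded `genome`, `annotation`, `samples` (reads read
#'   from FASTQ) and `params`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  genome <- load_genome(cfg$genome)
  annotation <- load_annotation(cfg$annotation, genome = genome)
  params <- do.call(pipeline_params, as.list(cfg$params %||% list()))
  samples <- lapply(cfg$samples, function(s) {
    r1 <- read_fastq(s$r1); r2 <- read_fastq(s$r2)
    list(reads = data.frame(read_id = sub("\\s.*", "", r1$ids),
                            seq1 = r1$seqs, seq2 = r2$seqs,
                            qual1 = r1$quals, qual2 = r2$quals,
                            stringsAsFactors = FALSE),
         condition = s$condition, replicate = s$replicate)
  })
  list(genome = genome, annotation = annotation, samples = samples,
       params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
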