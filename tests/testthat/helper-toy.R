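# Shared fixtures: the synthetic mitochondrial-like toy genome and its
# k-mer index, built once per test run.

toy <- toy_mito()
toy_genome <- toy$genome
toy_ann <- toy$annotation
toy_index <- build_index(toy_genome)

# random DNA of length n using the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force minimal-period scan: smallest p with self-correlation mismatch
# rate <= rate over the whole read (independent oracle for find_period)
oracle_period <- function(seq, min_period = 15L, min_copies = 2,
                          rate = 0.1) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  maxp <- floor(n / min_copies)
  if (n < 2L * min_period || maxp < min_period) return(NA_integer_)
  for (p in min_period:maxp) {
    mm <- sum(ch[seq_len(n - p)] != ch[(p + 1L):n])
    if (mm <= rate * (n - p)) return(p)
  }
  NA_integer_
}

# brute-force leftmost 3' adapter occurrence (oracle for trim_adapters)
oracle_adapter_pos <- function(seq, adapter, max_error_rate = 0.1,
                               min_overlap = 3L) {
  n <- nchar(seq); na <- nchar(adapter)
  for (st in seq_len(max(0L, n - min_overlap + 1L))) {
    o <- min(na, n - st + 1L)
    mm <- sum(strsplit(substr(seq, st, st + o - 1L), "")[[1L]] !=
              strsplit(substr(adapter, 1L, o), "")[[1L]])
    if (mm <= floor(max_error_rate * o)) return(st)
  }
  0L
}

# exhaustive Smith-Waterman score on the doubled circular genome (both
# strands) via Biostrings -- the independent alignment oracle
oracle_sw_score <- function(seq, genome) {
  dg <- Biostrings::DNAString(paste0(genome$seq, genome$seq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(2, -4)
  s1 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq), dg, type = "local",
    substitutionMatrix = mat, gapOpening = 6, gapExtension = 1,
    scoreOnly = TRUE)
  s2 <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)), dg,
    type = "local", substitutionMatrix = mat, gapOpening = 6,
    gapExtension = 1, scoreOnly = TRUE)
  max(s1, s2)
}

empty_calls_test <- function() circmito:::empty_calls()

# simulate + run one sample, returning recovery stats against truth
recovery_stats <- function(templates, genome, annotation, config,
                           tol = 0L) {
  sim <- simulate_library(templates, genome, config)
  res <- run_sample(sim$reads, genome, annotation)
  rt <- sim$read_truth
  mol <- sim$molecules
  jr <- rt$read_id[rt$junction_recoverable]
  calls <- res$calls
  m <- match(calls$read_id, rt$read_id)
  mm <- match(rt$molecule_id[m], mol$molecule_id)
  L <- genome$length
  d5 <- abs(calls$five_prime - mol$five_c[mm])
  d3 <- abs(calls$three_prime - mol$three_c[mm])
  d5 <- pmin(d5, L - d5); d3 <- pmin(d3, L - d3)
  ok <- d5 <= tol & d3 <= tol & calls$strand == mol$strand[mm]
  list(sim = sim, res = res, n_jr = length(jr),
       recovery = mean(jr %in% calls$read_id[ok]),
       calls = calls)
}
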