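test_that("build_index covers every position including origin spanners", {
  g <- genome_from_sequence("ACGTACGTTG")
  idx <- build_index(g, k = 4)
  # every position contributes one k-mer
  n_pos <- sum(vapply(ls(idx$env), function(k)
    length(get(k, idx$env)), 0L))
  expect_equal(n_pos, 10L)
  # origin-spanning k-mer: positions L-2 wraps to cover 8,9,0,1
  km <- paste0(substr(g$seq, 9, 10), substr(g$seq, 1, 2))
  expect_true(8L %in% get(km, idx$env))
  expect_error(build_index(g, k = 20), "exceeds genome length")
})

test_that("align_local places exact substrings and rejects noise", {
  s <- fetch(toy_genome, 5000, 5100)
  a <- align_local(s, toy_index, toy_genome)
  expect_equal(a$gstart, 5000L)
  expect_equal(a$glen, 100L)
  expect_equal(a$cigar, "100M")
  expect_equal(a$edits, 0L)
  expect_equal(a$strand, "+")

  # minus strand: the reverse complement maps to the same locus
  am <- align_local(revcomp(s), toy_index, toy_genome)
  expect_equal(am$gstart, 5000L)
  expect_equal(am$strand, "-")

  # a chimeric read splits: the local pass takes one 60 nt side
  chim <- paste0(fetch(toy_genome, 5000, 5060), fetch(toy_genome, 9000, 9060))
  ac <- align_local(chim, toy_index, toy_genome)
  expect_equal(ac$glen, 60L)
  expect_true(ac$gstart %in% c(5000L, 9000L))

  # random 30-mers with no genomic source fail the score threshold
  set.seed(51)
  hits <- 0L
  for (i in 1:10) {
    r <- align_local(random_dna(30), toy_index, toy_genome)
    if (!is.null(r)) hits <- hits + 1L
  }
  expect_equal(hits, 0L)
})

test_that("seeded local alignment attains the exhaustive SW optimum", {
  # dual route: package = seeded window DP; oracle = Biostrings full DP on
  # the doubled circular genome (trim disabled to compare raw optima)
  set.seed(52)
  for (i in 1:12) {
    n <- sample(c(40, 80, 150, 250), 1)
    s0 <- sample(0:(toy_genome$length - 1L), 1)
    q <- fetch(toy_genome, s0, s0 + n,
               sample(c("+", "-"), 1))
    nerr <- rbinom(1, n, 0.01)
    if (nerr > 0) {
      ch <- strsplit(q, "")[[1]]
      pos <- sample(n, nerr)
      ch[pos] <- sample(c("A", "C", "G", "T"), nerr, replace = TRUE)
      q <- paste(ch, collapse = "")
    }
    a <- align_local(q, toy_index, toy_genome, trim = FALSE)
    expect_equal(a$score, oracle_sw_score(q, toy_genome), info = i)
  }
})

test_that("extract_clips applies CIGAR arithmetic and the length gate", {
  seg <- data.frame(qstart = 45L, qend = 145L)
  cl <- extract_clips(seg, read_len = 145L, min_clip = 15L)
  expect_equal(cl$side, "left")
  expect_equal(cl$cend - cl$cstart, 45L)

  seg2 <- data.frame(qstart = 0L, qend = 100L)
  expect_equal(nrow(extract_clips(seg2, read_len = 108L)), 0L)  # 8 < 15

  seg3 <- data.frame(qstart = 30L, qend = 120L)
  cl3 <- extract_clips(seg3, read_len = 150L)
  expect_equal(cl3$side, c("left", "right"))
})

test_that("end-to-end realignment respects the edit budget", {
  s <- fetch(toy_genome, 7000, 7045)
  r <- align_end_to_end(s, toy_index, toy_genome)
  expect_equal(r$gstart, 7000L)
  expect_equal(r$edits, 0L)

  # 6 substitutions in 45 nt exceed max(2, 4.5)
  ch <- strsplit(s, "")[[1]]
  ch[c(5, 12, 19, 26, 33, 40)] <- vapply(ch[c(5, 12, 19, 26, 33, 40)],
    function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  expect_null(align_end_to_end(paste(ch, collapse = ""), toy_index,
                               toy_genome))

  # a non-templated 8xA tail plus 20 genome nt fails end-to-end placement
  tailseq <- paste0(strrep("A", 8), fetch(toy_genome, 7000, 7020))
  expect_null(align_end_to_end(tailseq, toy_index, toy_genome))
})

test_that("placed segments reproduce genome sequence within reported edits", {
  set.seed(53)
  tpl <- make_default_templates(toy_ann, toy_genome, "WT")
  cfg <- sim_config(n_molecules = 40, error_rate = 0.005, seed = 53)
  sim <- simulate_library(tpl, toy_genome, cfg)
  tr <- trim_adapters(sim$reads, cfg$adapter1, cfg$adapter2)
  mg <- merge_pairs(tr$reads)
  checked <- 0L
  for (i in seq_len(min(nrow(mg), 60))) {
    ar <- align_read(mg$read_id[i], mg$seq[i], toy_index, toy_genome)
    if (is.null(ar$segments)) next
    for (j in seq_len(nrow(ar$segments))) {
      seg <- ar$segments[j, ]
      if (grepl("[ID]", seg$cigar)) next
      gs <- fetch(toy_genome, seg$gstart, seg$gstart + seg$glen, seg$strand)
      rs <- substr(mg$seq[i], seg$qstart + 1, seg$qend)
      if (seg$strand == "-") rs <- rs  # read space equals transcript space
      mm <- sum(utf8ToInt(gs) != utf8ToInt(rs))
      expect_lte(mm, seg$edits)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("alignment is consistent under genome rotation", {
  r <- 1000L
  L <- toy_genome$length
  rot <- genome_from_sequence(paste0(substr(toy_genome$seq, r + 1, L),
                                     substr(toy_genome$seq, 1, r)),
                              name = "rot")
  idx_rot <- build_index(rot)
  set.seed(54)
  for (i in 1:8) {
    s0 <- sample(0:(L - 1L), 1)
    q <- fetch(toy_genome, s0, s0 + 120)
    a <- align_local(q, toy_index, toy_genome)
    b <- align_local(q, idx_rot, rot)
    expect_equal(wrap_pos(b$gstart + r, L), a$gstart)
    expect_equal(b$glen, a$glen)
  }
})

test_that("place_monomer recovers rotated small molecules and their tails", {
  f <- toy_ann[toy_ann$gene_id == "tRNA-D", ]
  body <- fetch(toy_genome, f$start, f$end)
  mol <- paste0(body, "CCA")
  set.seed(55)
  for (i in 1:10) {
    rotoff <- sample(nchar(mol), 1)
    mono <- paste0(substr(mol, rotoff, nchar(mol)),
                   substr(mol, 1, rotoff - 1))
    pm <- place_monomer("m", mono, toy_index, toy_genome)
    expect_false(is.null(pm))
    cl <- call_from_monomer(pm, toy_genome)
    cc <- canonicalize_call(toy_genome, f$start, f$end - 1L, "+", "CCA")
    expect_equal(cl$five_prime, as.integer(cc$five))
    expect_equal(cl$three_prime, as.integer(cc$three))
  }
})

test_that("SAM export writes parseable records with soft clips", {
  s <- paste0(random_dna(20), fetch(toy_genome, 3000, 3100))
  ar <- align_read("r1", s, toy_index, toy_genome)
  fp <- tempfile(fileext = ".sam")
  write_sam(ar$segments, data.frame(read_id = "r1", seq = s,
                                    stringsAsFactors = FALSE),
            toy_genome, fp)
  ln <- readLines(fp)
  expect_true(any(grepl("^@SQ\tSN:chrM", ln)))
  rec <- strsplit(ln[!grepl("^@", ln)][1], "\t")[[1]]
  expect_equal(rec[3], "chrM")
  expect_true(grepl("S", rec[6]) || ar$segments$qstart[1] == 0L)
})
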