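make_junction_read <- function(five, three, strand, tail = "",
                               flank5 = 60L, flank3 = 60L) {
  # read bridging the circularization junction: [3' end of body][tail][5'
  # start of body], in transcript orientation
  L <- toy_genome$length
  mol <- paste0(transcript_fetch_test(five, three, strand), tail)
  m <- nchar(mol)
  paste0(substr(mol, m - nchar(tail) - flank3 + 1L, m),
         substr(mol, 1L, flank5))
}

transcript_fetch_test <- function(five, three, strand) {
  L <- toy_genome$length
  len <- transcript_length(five, three, strand, L)
  if (strand == "+") fetch(toy_genome, five, five + len, "+")
  else fetch(toy_genome, three, three + len, "-")
}

call_read <- function(seq) {
  ar <- align_read("r", seq, toy_index, toy_genome)
  if (is.null(ar$segments) || nrow(ar$segments) < 2) return(NULL)
  call_precursor(ar$segments, seq, toy_genome)
}

test_that("junction reads recover molecule termini on both strands", {
  set.seed(61)
  for (i in 1:12) {
    strand <- sample(c("+", "-"), 1)
    five <- sample(200:(toy_genome$length - 2000), 1)
    mlen <- sample(300:900, 1)
    three <- advance_pos(five, mlen - 1L, strand, toy_genome$length)
    cl <- call_read(make_junction_read(five, three, strand))
    cc <- canonicalize_call(toy_genome, five, three, strand, "")
    expect_false(is.null(cl), info = i)
    expect_equal(cl$five_prime, as.integer(cc$five), info = i)
    expect_equal(cl$three_prime, as.integer(cc$three), info = i)
    expect_equal(cl$strand, strand, info = i)
  }
})

test_that("strand mirroring mirrors the call exactly", {
  five <- 5100L; mlen <- 500L
  three_p <- advance_pos(five, mlen - 1L, "+", toy_genome$length)
  cl_p <- call_read(make_junction_read(five, three_p, "+"))
  # mirrored molecule: same genomic interval read off the light strand
  cl_m <- call_read(make_junction_read(three_p, five, "-"))
  expect_equal(cl_m$five_prime, cl_p$three_prime)
  expect_equal(cl_m$three_prime, cl_p$five_prime)
  expect_equal(cl_m$strand, "-")
})

test_that("non-junction and chimeric reads yield no call", {
  # read fully inside one locus: no junction
  s <- fetch(toy_genome, 4100, 4400)
  ar <- align_read("r", s, toy_index, toy_genome)
  expect_equal(nrow(ar$segments), 1L)
  expect_null(call_precursor(ar$segments, s, toy_genome))

  # mixed-strand segment groups are rejected
  segs <- rbind(
    data.frame(read_id = "r", part = "middle", qstart = 0L, qend = 50L,
               ostart = 0L, oend = 50L, gstart = 100L, glen = 50L,
               strand = "+", cigar = "50M", score = 100L, edits = 0L,
               stringsAsFactors = FALSE),
    data.frame(read_id = "r", part = "right", qstart = 50L, qend = 100L,
               ostart = 50L, oend = 100L, gstart = 900L, glen = 50L,
               strand = "-", cigar = "50M", score = 100L, edits = 0L,
               stringsAsFactors = FALSE))
  expect_null(call_precursor(segs, strrep("A", 100), toy_genome))
})

test_that("genome-contiguous split segments are one locus, not a link", {
  segs <- rbind(
    data.frame(read_id = "r", part = "middle", qstart = 0L, qend = 50L,
               ostart = 0L, oend = 50L, gstart = 100L, glen = 50L,
               strand = "+", cigar = "50M", score = 100L, edits = 0L,
               stringsAsFactors = FALSE),
    data.frame(read_id = "r", part = "right", qstart = 50L, qend = 100L,
               ostart = 50L, oend = 100L, gstart = 151L, glen = 50L,
               strand = "+", cigar = "50M", score = 100L, edits = 0L,
               stringsAsFactors = FALSE))
  # gap of 1 nt <= contiguity_tol
  expect_null(call_precursor(segs, strrep("A", 100), toy_genome))
})

test_that("aggregation pools identical calls and conserves counts", {
  five <- 2000L; three <- 2500L
  cl <- call_read(make_junction_read(five, three, "+"))
  calls <- rbind(cl, cl, cl)
  calls$read_id <- c("a", "b", "c")
  agg <- aggregate_links(calls, toy_ann, toy_genome)
  expect_equal(nrow(agg$links), 1L)
  expect_equal(agg$links$read_count, 3L)
  expect_equal(sum(agg$links$read_count), nrow(calls))
  expect_equal(sum(agg$ends$five[["+"]]), 3L)
  expect_equal(sum(agg$ends$three[["+"]]), 3L)
  expect_equal(which(agg$ends$five[["+"]] > 0) - 1L, cl$five_prime)
})

test_that("split_fraction handles edge cases", {
  calls0 <- annotate_calls(empty_calls_test(), toy_ann, toy_genome)
  expect_equal(split_fraction(100, calls0), 0)
  expect_error(split_fraction(0, calls0), "zero aligned")
})

test_that("compare_links follows pseudocount arithmetic and antisymmetry", {
  la <- data.frame(five_prime = c(10L, 50L), three_prime = c(400L, 700L),
                   strand = "+", read_count = c(1L, 4L),
                   stringsAsFactors = FALSE)
  lb <- data.frame(five_prime = 10L, three_prime = 400L, strand = "+",
                   read_count = 1L, stringsAsFactors = FALSE)
  fc <- compare_links(la, lb, 1e6, 1e6, pseudocount = 1)
  # identical link: log2 1 = 0
  expect_equal(fc$log2fc[fc$five_prime == 10], 0)
  # present at CPM 4 vs absent: log2((4+1)/(0+1))
  expect_equal(fc$log2fc[fc$five_prime == 50], log2(5))
  # antisymmetry
  fc_ba <- compare_links(lb, la, 1e6, 1e6, pseudocount = 1)
  m <- match(paste(fc$five_prime, fc$three_prime),
             paste(fc_ba$five_prime, fc_ba$three_prime))
  expect_equal(fc$log2fc, -fc_ba$log2fc[m])
})

test_that("Circos link export round-trips", {
  links <- data.frame(five_prime = c(100L, 5000L), three_prime = c(500L, 90L),
                      strand = c("+", "-"), read_count = c(7L, 2L),
                      stringsAsFactors = FALSE)
  lp <- tempfile(); kp <- tempfile()
  export_circos(links, toy_ann, toy_genome, lp, kp)
  back <- read_circos_links(lp)
  expect_equal(back$five_prime, links$five_prime)
  expect_equal(back$three_prime, links$three_prime)
  expect_equal(back$strand, links$strand)
  expect_equal(back$read_count, links$read_count)
  # karyotype: one chromosome line + one band per feature
  expect_equal(length(readLines(kp)), 1L + nrow(toy_ann))
  # empty table -> empty link file, valid karyotype
  export_circos(links[0, ], toy_ann, toy_genome, lp, kp)
  expect_equal(length(readLines(lp)), 0L)
  expect_gt(length(readLines(kp)), 0L)
})
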