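# The canonical junction representation must be invariant to how the
# circularization junction is cut: representations that differ by sliding
# the junction through genome-templated bases describe the same circle and
# must canonicalize identically.

test_that("canonicalize_call is idempotent on clean representations", {
  # representations with unexplained junction bases (gap_len > 0) describe
  # noisy junctions and carry no unique canonical form; clean ones must be
  # fixed points
  set.seed(11)
  L <- toy_genome$length
  checked <- 0L
  for (i in 1:40) {
    five <- sample(0:(L - 1L), 1)
    three <- wrap_pos(five + sample(50:400, 1), L)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") { tmp <- five; five <- three; three <- tmp }
    tail <- sample(c("", "CCA", strrep("A", 8)), 1)
    c1 <- canonicalize_call(toy_genome, five, three, strand, tail)
    if (c1$gap_len > 0L) next
    c2 <- canonicalize_call(toy_genome, c1$five, c1$three, strand,
                            c1$tail_seq)
    expect_equal(c2$five, c1$five)
    expect_equal(c2$three, c1$three)
    expect_equal(c2$tail_len, c1$tail_len)
    checked <- checked + 1L
  }
  expect_gt(checked, 25L)
})

test_that("junction slides through templated bases canonicalize equally", {
  L <- toy_genome$length
  gseq <- toy_genome$seq

  # poly(A): genomic A's immediately upstream of the 5' end are
  # indistinguishable from tail; representations assigning them either way
  # must agree
  aa <- gregexpr("AA", gseq)[[1L]]
  five <- aa[aa > 100 & aa < L - 600][1L] + 2L - 1L  # 0-based pos after "AA"
  three <- five + 300L
  c_tail <- canonicalize_call(toy_genome, five, three, "+", strrep("A", 8))
  c_slid <- canonicalize_call(toy_genome, five - 2L, three, "+",
                              strrep("A", 6))
  expect_equal(c_slid$five, c_tail$five)
  expect_equal(c_slid$three, c_tail$three)
  expect_equal(c_slid$tail_len, c_tail$tail_len)

  # CCA: a trailing tail base attributed to the body start (genome happens
  # to encode it) is restored by completion
  an <- gregexpr("A", gseq)[[1L]]
  five2 <- an[an > 100 & an < L - 600][1L]  # 0-based position after an A
  three2 <- five2 + 250L
  c_cca <- canonicalize_call(toy_genome, five2, three2, "+", "CCA")
  c_cc <- canonicalize_call(toy_genome, five2 - 1L, three2, "+", "CC")
  expect_equal(c_cc$five, c_cca$five)
  expect_equal(c_cc$three, c_cca$three)
})

test_that("forward junction shift absorbs templated flank matches", {
  # construct a case where the genome after `three` repeats the molecule
  # start: the canonical 3' end must advance over the shared bases for any
  # starting representation
  L <- toy_genome$length
  set.seed(4)
  for (i in 1:20) {
    five <- sample(0:(L - 1L), 1)
    three <- wrap_pos(five + 200L, L)
    cc <- canonicalize_call(toy_genome, five, three, "+", "")
    # canonical: no further forward shift possible
    nxt <- fetch(toy_genome, wrap_pos(cc$three + 1L, L),
                 wrap_pos(cc$three + 1L, L) + 1L)
    lead <- fetch(toy_genome, cc$five, cc$five + 1L)
    expect_false(nxt == lead)
  }
})

test_that("tail residuals classify by content with CCA precedence", {
  # find a 3' flank that does not begin with C or A so nothing is absorbed
  L <- toy_genome$length
  gpos <- gregexpr("TT", toy_genome$seq)[[1L]]
  three <- gpos[gpos > 1000][1L] - 1L - 1L  # 0-based, flank starts T
  five <- wrap_pos(three - 150L, L)
  expect_equal(canonicalize_call(toy_genome, five, three, "+",
                                 "CCA")$tail_kind, "CCA")
  pa <- canonicalize_call(toy_genome, five, three, "+", "AAAA")
  expect_equal(pa$tail_kind, "polyA")
  # junk that shares no prefix with the flank (which starts with T here)
  ju <- canonicalize_call(toy_genome, five, three, "+", "GCGC")
  expect_equal(ju$tail_kind, "none")
  expect_equal(ju$gap_len, 4L)
})
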