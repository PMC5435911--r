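test_that("extract_srnas applies the length window and copy gate", {
  mono <- data.frame(read_id = c("a", "b", "c", "d"),
                     monomer = c(strrep("A", 22), strrep("C", 300),
                                 strrep("G", 30), strrep("T", 40)),
                     period = c(22L, 300L, 30L, 40L),
                     copies = c(5, 2, 1.2, 2.4),
                     support = 1, was_collapsed = c(TRUE, TRUE, TRUE, TRUE),
                     stringsAsFactors = FALSE)
  out <- extract_srnas(mono)
  expect_equal(out$read_id, c("a", "d"))
})

test_that("detect_tail classifies CCA and poly(A) with templating checks", {
  # place against a flank that is neither CCA nor A-run, with a non-A body
  # terminus so the constructed tail lengths are exact
  gpos <- gregexpr("GT", toy_genome$seq)[[1L]]
  prev <- substring(toy_genome$seq, gpos - 1L, gpos - 1L)
  gpos <- gpos[gpos > 2000 & prev != "A"][1L]
  three <- gpos - 2L  # 0-based last body nt
  body <- fetch(toy_genome, three - 19L, three + 1L)

  t1 <- detect_tail(paste0(body, "CCA"), three, "+", toy_genome)
  expect_equal(t1$kind, "CCA")
  expect_false(t1$templated)

  t2 <- detect_tail(paste0(body, "AAAAA"), three, "+", toy_genome)
  expect_equal(t2$kind, "polyA")
  expect_equal(t2$length, 5L)
  expect_false(t2$templated)

  # a 2 nt A-run is below the detection floor
  t3 <- detect_tail(paste0(body, "AA"), three, "+", toy_genome)
  expect_equal(t3$kind, "none")

  # a fully genome-encoded A-run is body, not tail
  apos <- gregexpr("AAAA", toy_genome$seq)[[1L]]
  th <- apos[apos > 2000][1L] - 1L - 1L
  body2 <- fetch(toy_genome, th - 19L, th + 1L)
  t4 <- detect_tail(paste0(body2, "AAAA"), th, "+", toy_genome)
  expect_equal(t4$kind, "none")
})

srna_row <- function(five, three, strand = "+", tail_kind = "none",
                     tail_len = 0L, id = "r") {
  data.frame(read_id = id, length = transcript_length(five, three, strand,
                                                      toy_genome$length),
             copies = 3, five_prime = five, three_prime = three,
             strand = strand, tail_kind = tail_kind, tail_len = tail_len,
             stringsAsFactors = FALSE)
}

test_that("assign_features implements the strand-aware overlap cascade", {
  tr <- toy_ann[toy_ann$gene_id == "tRNA-D", ]
  mr <- toy_ann[toy_ann$gene_id == "mRNA-CO2", ]

  # 20 nt body inside the tRNA with a CCA extension -> tRNA
  s1 <- srna_row(tr$end - 20L, tr$end - 1L, tail_kind = "CCA", tail_len = 3L)
  a1 <- assign_features(s1, toy_ann, toy_genome)
  expect_equal(a1$feature_class, "tRNA")
  expect_equal(a1$feature, "tRNA-D")

  # body crossing beyond 20% of its length out of the tRNA -> not tRNA
  s2 <- srna_row(tr$end - 10L, tr$end + 29L)
  a2 <- assign_features(s2, toy_ann, toy_genome)
  expect_false(identical(a2$feature_class, "tRNA"))

  # 25 nt body inside an mRNA with a poly(A) tail away from the gene end:
  # a polyadenylated decay fragment
  s3 <- srna_row(mr$start + 100L, mr$start + 124L, tail_kind = "polyA",
                 tail_len = 6L)
  a3 <- assign_features(s3, toy_ann, toy_genome)
  expect_equal(a3$feature_class, "mRNA")

  # poly(A) at the annotated mRNA 3' end is a canonical tail: excluded
  s4 <- srna_row(mr$end - 25L, mr$end - 1L, tail_kind = "polyA",
                 tail_len = 6L)
  a4 <- assign_features(s4, toy_ann, toy_genome)
  expect_equal(a4$feature_class, "unassigned")

  # wrong strand is never assigned (the -s flag)
  s5 <- srna_row(mr$start + 124L, mr$start + 100L, strand = "-")
  a5 <- assign_features(s5, toy_ann, toy_genome)
  expect_equal(a5$feature_class, "unassigned")

  # the cascade is a partition
  all5 <- assign_features(rbind(s1, s2, s3, s4, s5), toy_ann, toy_genome)
  expect_true(all(all5$feature_class %in%
                  c("tRNA", "rRNA", "mRNA", "unassigned")))
})

test_that("cca_ratio is the CCA share of reads covering the 3' terminal nt", {
  tr <- toy_ann[toy_ann$gene_id == "tRNA-D", ]
  rows <- do.call(rbind, lapply(1:10, function(i)
    srna_row(tr$end - 30L, tr$end - 1L,
             tail_kind = if (i <= 8) "CCA" else "none",
             tail_len = if (i <= 8) 3L else 0L, id = paste0("r", i))))
  rows <- assign_features(rows, toy_ann, toy_genome)
  cc <- cca_ratio(rows, toy_ann, toy_genome)
  expect_equal(cc$ratio[cc$gene_id == "tRNA-D"], 0.8)
  # tRNAs without reads at the terminal nt are missing, not zero
  expect_true(is.na(cc$ratio[cc$gene_id == "tRNA-K"]))
})

test_that("polya_proportion computes Student's t with degenerate guards", {
  mk <- function(gene, n_pa, n_tot) {
    do.call(rbind, lapply(seq_len(n_tot), function(i)
      srna_row(100L, 121L, tail_kind = if (i <= n_pa) "polyA" else "none",
               id = paste0(gene, i))))
  }
  tab_with <- function(p, n = 10L) {
    x <- mk("g", round(p * n), n)
    x$feature <- "mRNA-X"; x$feature_class <- "mRNA"
    x
  }
  # separation with zero within-group variance -> p ~ 0
  tabs <- c(lapply(c(.1, .1, .1), tab_with), lapply(c(.3, .3, .3), tab_with))
  res <- polya_proportion(tabs, rep(c("WT", "KO"), each = 3),
                          genes = "mRNA-X")
  expect_lt(res$p, 0.05)
  # identical groups -> p = 1
  tabs2 <- c(lapply(c(.2, .2, .2), tab_with), lapply(c(.2, .2, .2), tab_with))
  res2 <- polya_proportion(tabs2, rep(c("WT", "KO"), each = 3),
                           genes = "mRNA-X")
  expect_equal(res2$p, 1)
  # hand-computed pooled-variance t for (0.1, 0.2, 0.3) vs (0.2, 0.3, 0.4)
  tabs3 <- c(lapply(c(.1, .2, .3), tab_with), lapply(c(.2, .3, .4), tab_with))
  res3 <- polya_proportion(tabs3, rep(c("WT", "KO"), each = 3),
                           genes = "mRNA-X")
  # pooled sd = 0.1, se = 0.1 * sqrt(2/3), t = -0.1 / se
  expect_equal(res3$t, -0.1 / (0.1 * sqrt(2 / 3)), tolerance = 1e-8)
  expect_equal(res3$p, 2 * pt(res3$t, df = 4), tolerance = 1e-8)
  # fewer than two replicates: proportions only
  res4 <- polya_proportion(tabs3[c(1, 4)], c("WT", "KO"), genes = "mRNA-X")
  expect_true(is.na(res4$p))
})

test_that("length_histogram covers the window and finds bimodal mixtures", {
  rows <- rbind(srna_row(100L, 118L, id = "a"), srna_row(100L, 118L, id = "b"),
                srna_row(200L, 221L, id = "c"))
  h <- length_histogram(rows)
  expect_equal(h$length, 15:60)
  expect_equal(h$count[h$length == 19], 2L)
  expect_equal(h$count[h$length == 22], 1L)
  expect_equal(sum(h$count), 3L)
  h0 <- length_histogram(rows[0, ])
  expect_true(all(h0$count == 0L))
})
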