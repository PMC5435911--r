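test_that("default templates encode the scenario contrast", {
  wt <- make_default_templates(toy_ann, toy_genome, "WT")
  ko <- make_default_templates(toy_ann, toy_genome, "KO")
  pw <- function(t) sum(t$weight[t$class == "precursor"])
  expect_equal(pw(ko) / pw(wt), 2.0)
  expect_equal(sum(wt$weight), 1.0)
  expect_equal(sum(ko$weight), 1.0)
  # degenerate config: no precursors and no degradation -> mature only
  wt0 <- make_default_templates(toy_ann, toy_genome, "WT",
                                precursor_fraction = 0)
  expect_true(all(wt0$class == "mature"))
  # a multi-gene precursor spanning a tRNA boundary exists
  expect_true(any(grepl("tRNA", wt$template_id[wt$class == "precursor"])))
})

test_that("simulation is deterministic and respects the RNase R step", {
  tpl <- make_default_templates(toy_ann, toy_genome, "WT")
  cfg <- sim_config(n_molecules = 60, seed = 9)
  s1 <- simulate_library(tpl, toy_genome, cfg)
  s2 <- simulate_library(tpl, toy_genome, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$molecules, s2$molecules)

  cfg0 <- sim_config(n_molecules = 60, circularization_prob = 0, seed = 9)
  s0 <- simulate_library(tpl, toy_genome, cfg0)
  expect_equal(nrow(s0$reads), 0L)
})

test_that("error-free reads from one short template are tandem rotations", {
  f <- toy_ann[toy_ann$gene_id == "tRNA-F", ]
  t1 <- make_srna_templates(toy_ann, toy_genome, cca_fraction = 0,
                            n_trna = 1, n_mrna = 0, trna_frag_len = 60)
  cfg <- sim_config(n_molecules = 40, circularization_prob = 1,
                    copy_mean = 3, error_rate = 0, seed = 2)
  sim <- simulate_library(t1, toy_genome, cfg)
  mono <- fetch(toy_genome, f$end - 60, f$end)
  doubled <- paste0(mono, mono)
  tr <- trim_adapters(sim$reads, cfg$adapter1, cfg$adapter2)
  mg <- merge_pairs(tr$reads)
  for (s in mg$seq) {
    # every merged read is a substring of tandem copies of the 60-mer
    expect_true(grepl(substr(s, 1, min(nchar(s), 120)),
                      strrep(mono, ceiling(nchar(s) / 60) + 1),
                      fixed = TRUE))
  }
})

test_that("truth_end_table counts circularized molecules by canonical ends", {
  t1 <- make_default_templates(toy_ann, toy_genome, "WT",
                               precursor_fraction = 0)[1:2, ]
  t1$weight <- c(0.25, 0.75)
  cfg <- sim_config(n_molecules = 2000, circularization_prob = 1, seed = 3)
  sim <- simulate_library(t1, toy_genome, cfg)
  tab <- truth_end_table(sim$molecules)
  expect_equal(sum(tab$count), 2000L)
  # weight recovery within binomial tolerance (proportional allocation)
  expect_lt(abs(tab$count[tab$count == max(tab$count)] / 2000 - 0.75), 0.01)

  empty <- truth_end_table(sim$molecules[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("single template with full circularization gives one truth row", {
  t1 <- make_default_templates(toy_ann, toy_genome, "WT",
                               precursor_fraction = 0)[5, ]
  t1$weight <- 1
  cfg <- sim_config(n_molecules = 100, circularization_prob = 1, seed = 4)
  sim <- simulate_library(t1, toy_genome, cfg)
  tab <- truth_end_table(sim$molecules)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$count, 100L)
})

test_that("read count scales with molecules and circularization", {
  tpl <- make_default_templates(toy_ann, toy_genome, "WT",
                                precursor_fraction = 0)
  n1 <- nrow(simulate_library(tpl, toy_genome,
    sim_config(n_molecules = 300, circularization_prob = 0.25,
               seed = 8))$reads)
  n2 <- nrow(simulate_library(tpl, toy_genome,
    sim_config(n_molecules = 1200, circularization_prob = 0.5,
               seed = 8))$reads)
  # 8x more expected reads; allow generous stochastic slack
  expect_gt(n2 / n1, 5)
  expect_lt(n2 / n1, 12)
})

test_that("FASTQ round-trips through write_fastq/read_fastq", {
  ids <- c("r1", "r2")
  seqs <- c("ACGTACGTAA", "TTTTGGGGCC")
  quals <- c(strrep("I", 10), strrep("F", 10))
  fp <- tempfile(fileext = ".fastq")
  write_fastq(ids, seqs, quals, fp)
  back <- read_fastq(fp)
  expect_equal(back$ids, ids)
  expect_equal(back$seqs, seqs)
  expect_equal(back$quals, quals)
})
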