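# Synthetic toy genome: a ~16 kb circular genome laid out like a mammalian
# mitochondrial genome (tRNA-punctuated rRNAs and mRNAs on the heavy strand,
# a handful of light-strand tRNAs, one light-strand mRNA, a non-coding
# D-loop). The sequence is random; only the gene architecture matters for
# testing junction recovery. Used throughout the test suite in place of a
# real organellar genome.

toy_layout <- function() {
  f <- function(id, biotype, len, strand) {
    data.frame(gene_id = id, biotype = biotype, len = len, strand = strand,
               stringsAsFactors = FALSE)
  }
  rbind(
    f("dloop",    "dloop", 880L,  "+"),
    f("tRNA-F",   "tRNA",  70L,   "+"),
    f("rRNA-S",   "rRNA",  950L,  "+"),
    f("tRNA-V",   "tRNA",  70L,   "+"),
    f("rRNA-L",   "rRNA",  1570L, "+"),
    f("tRNA-L1",  "tRNA",  75L,   "+"),
    f("mRNA-ND1", "mRNA",  950L,  "+"),
    f("tRNA-I",   "tRNA",  70L,   "+"),
    f("tRNA-Q",   "tRNA",  70L,   "-"),
    f("tRNA-M",   "tRNA",  70L,   "+"),
    f("mRNA-ND2", "mRNA",  1040L, "+"),
    f("tRNA-W",   "tRNA",  70L,   "+"),
    f("tRNA-A",   "tRNA",  70L,   "-"),
    f("tRNA-N",   "tRNA",  70L,   "-"),
    f("tRNA-C",   "tRNA",  70L,   "-"),
    f("tRNA-Y",   "tRNA",  70L,   "-"),
    f("mRNA-CO1", "mRNA",  1540L, "+"),
    f("tRNA-S1",  "tRNA",  70L,   "-"),
    f("tRNA-D",   "tRNA",  70L,   "+"),
    f("mRNA-CO2", "mRNA",  680L,  "+"),
    f("tRNA-K",   "tRNA",  70L,   "+"),
    f("mRNA-ATP", "mRNA",  840L,  "+"),
    f("mRNA-CO3", "mRNA",  780L,  "+"),
    f("tRNA-G",   "tRNA",  70L,   "+"),
    f("mRNA-ND3", "mRNA",  350L,  "+"),
    f("tRNA-R",   "tRNA",  70L,   "+"),
    f("mRNA-ND4", "mRNA",  1380L, "+"),
    f("tRNA-H",   "tRNA",  70L,   "+"),
    f("tRNA-S2",  "tRNA",  60L,   "+"),
    f("tRNA-L2",  "tRNA",  70L,   "+"),
    f("mRNA-ND5", "mRNA",  1820L, "+"),
    f("mRNA-ND6", "mRNA",  520L,  "-"),
    f("tRNA-E",   "tRNA",  70L,   "-"),
    f("mRNA-CYB", "mRNA",  1140L, "+"),
    f("tRNA-T",   "tRNA",  70L,   "+"),
    f("tRNA-P",   "tRNA",  70L,   "-")
  )
}

# evaluate expr with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic circular toy genome with mitochondrial-like architecture
#'
#' @param seed seed for the random genome sequence (the gene layout is fixed).
#' @return list with `genome` (a `CircularGenome`) and `annotation`
#'   (an `AnnotationSet` of tRNA/rRNA/mRNA/dloop features on both strands,
#'   abutting as in a tRNA-punctuated genome).
#' @export
toy_mito <- function(seed = 7L) {
  lay <- toy_layout()
  L <- sum(lay$len)
  seqchars <- with_seed(seed,
    sample(c("A", "C", "G", "T"), L, replace = TRUE,
           prob = c(0.31, 0.25, 0.13, 0.31)))  # AT-rich like mtDNA
  genome <- genome_from_sequence(paste(seqchars, collapse = ""), name = "chrM")
  ends <- cumsum(lay$len)
  ann <- annotation_from_data_frame(
    data.frame(gene_id = lay$gene_id, biotype = lay$biotype,
               start = ends - lay$len, end = ends, strand = lay$strand,
               stringsAsFactors = FALSE),
    genome_name = genome$name, L = L)
  list(genome = genome, annotation = ann)
}
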