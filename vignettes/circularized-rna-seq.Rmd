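---
title: "Reconstructing RNA termini from circularized RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing RNA termini from circularized RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmito)
```

## The problem and the measurement principle

Mammalian mitochondrial RNAs are excised from two genome-length polycistronic
precursors, mostly by cleavage at the tRNAs that punctuate the genome (RNase
P at tRNA 5' ends, RNase Z/ELAC2 at 3' ends). Processing intermediates are
short-lived, and ordinary short-read RNA-Seq destroys exactly the information
needed to characterize them: the positions of each molecule's 5' and 3'
termini, jointly.

Circularizing each RNA molecule by intramolecular ligation before library
construction preserves that information. The two termini become covalently
joined, so any read that crosses the ligation junction carries both ends of
one molecule. After an exonuclease step that removes remaining linear RNA,
rolling-circle reverse transcription with random primers copies each circle
into a cDNA of one or more tandem repeats of the molecule; fragmentation and
250 bp paired-end sequencing follow. Two signatures appear in the reads:

* **Split reads.** A read crossing the junction aligns to the circular
  genome in two (or three) pieces: the piece before the junction ends at the
  molecule's 3' terminus and the piece after it starts at the 5' terminus.
  Joining them is a "link" — the inferred extent of one original molecule.
* **Tandem repeats.** Molecules shorter than half the read appear as direct
  repeats and are collapsed to a consensus *monomer*, which is a rotation of
  the molecule (plus any non-templated tail).

`circmito` implements the full computation: adapter trimming and read-pair
merging, tandem-repeat collapsing, seeded soft-clipping alignment to the
circular genome with end-to-end realignment of clipped parts, junction
("link") calling, CPM-normalized end/coverage/log2 fold-change tracks,
small-RNA extraction with 3'-CCA and poly(A) tail classification, and a
ground-truth library simulator so that every stage has a parameter-recovery
test.

## The simulator as the package's measurement standard

`simulate_library()` draws molecules from a `TranscriptTemplates` population
(`make_default_templates()` builds mature species with exact annotated ends,
multi-gene precursors spanning tRNA boundaries, and polyadenylated
degradation intermediates internal to ORFs; `make_srna_templates()` builds
tRNA fragments with 3'-CCA and short mRNA decay fragments with poly(A)).
The generative model follows the library chemistry stage by stage:
circularization with probability `circularization_prob` (default 0.5; the
efficiency of the ligase step is not quantified anywhere, so this is a
documented guess), destruction of non-circularized molecules (the
exonuclease step — they never yield reads), rolling-circle copy number
`1 + Geometric` with mean `copy_mean` (default 2.5; rolling-circle yields
of "more than two copies" of small RNAs are reported qualitatively, and the
geometric is the simplest memoryless choice), a uniformly random rotation
(random priming), uniform fragmentation with mean spacing `fragment_mean`
(350 nt; fragments under 30 nt are lost to size selection), directional
250 bp paired-end reads (read 1 in the sense of the RNA, per the two-adapter
chemistry), substitution errors at `error_rate` (default 0.002; indels are
out of the default error model), and adapter read-through for short inserts.

Template counts use deterministic proportional allocation by default
(`allocation = "proportional"`): the generator's role is to realize a
*stated* composition, and removing multinomial noise at the template level is
standard variance reduction; `"multinomial"` is available when sampling
noise itself is under study. Scenario defaults encode the biology of
interest: `WT` has a 5% precursor and 5% degradation weight; `KO` (loss of
the mitochondrial RNase P nuclease subunit) doubles both.

What the simulator does **not** emulate: PCR duplicates, quality-score
variation (constant Q40), ligation sequence bias (none was detected for the
ligase used), indel errors (available via none of the defaults), nuclear
mitochondrial insertions (alignment is to the organellar genome only), and
secondary-structure effects on circularization. Passing recovery tests
therefore demonstrate correctness of the *computation* under the stated
chemistry, not robustness to every artifact of real libraries.

## Canonical junction representations (identifiability)

A circularized molecule is observed only through its junction, which makes
the linear representation `(five_prime, three_prime, tail)` identifiable
only up to sliding the junction through genomically templated bases. Three
concrete ambiguities arise:

1. if the genome continues past the 3' terminus with the same bases that
   begin the molecule (or its tail), the junction can sit anywhere in the
   shared run;
2. a poly(A) tail is indistinguishable from genome-encoded A's at either
   terminus;
3. a CCA tail blends into C/A bases the genome happens to encode at the
   flanks.

`canonicalize_call()` fixes one normal form — maximal 3'-forward shift,
reassembly of partial CCA remnants at the 5' start, then backward absorption
of tail bases the genome encodes immediately upstream of the 5' terminus
(all-or-nothing for CCA, per-base for poly(A)) — and is applied identically
to simulator truth and to every pipeline call. Exact-recovery statements are
made in this normal form; without it they would be ill-posed. A corollary:
`tail_kind == "CCA"` may carry a residual length below 3 when part of the
trinucleotide is genome-templated, and sub-3 nt A residuals are reported as
unexplained junction sequence rather than poly(A).

## Alignment engine and its numerical choices

The target is a single circular genome of ~16 kb, so a full read-mapper is
replaced by an in-package seed-and-extend aligner: a 12-mer index over the
forward strand (origin-spanning k-mers included; the reverse strand is
queried by aligning the reverse complement), diagonal clustering, and a
windowed Smith–Waterman with affine gaps (match +2, mismatch −4, gap open
−6, gap extend −1 — the usual local-mode constants; a gap of length *g*
costs 6 + *g*). The single best local alignment is kept, ties broken toward
the lowest genome coordinate and then the forward strand; reads under
`min_score = 40` (20 matched bases) are unaligned. Diagonal clusters within
500 nt share one DP window so that every *profitable* deletion-bridged
alignment is evaluated whole (a gap `g` beats splitting only when
`6 + g < 2 ×` the shorter part, bounding useful bridges below ~480 nt for
reads up to 490 nt); a circularization junction jumps backwards on the
genome, which no forward window can bridge, so junction reads still resolve
into split placements. On a single diagonal an
exact seed extension whose flanks diverge hard (≥2 mismatches in the next
11 bases on both sides) is provably what the DP-plus-trimming would return
and skips the DP.

Two post-processing steps protect junction calls:

* **Weak-end trimming.** A raw SW optimum happily extends across the
  circularization junction through a chance match of a few bases, optionally
  bridged by a short indel. Terminal match blocks shorter than 10 nt that
  are separated from the alignment body by a mismatch or gap are returned to
  the soft clip (`trim = FALSE` recovers the raw optimum; the test suite
  checks that mode against an exhaustive Smith–Waterman oracle computed with
  Biostrings on the doubled genome).
* **Junction-face trimming and tail-aware stripping of clips.** Soft clips
  of ≥15 nt are realigned end-to-end (substitution edits only, budget
  `max(2, 10%)`), after trying a small set of junction-facing strip variants
  (leading/trailing A-runs, CCA remnants, and generic depths up to 5 nt);
  the placement with the fewest edits wins, the smallest strip on ties, so
  genome-templated bases stay in the body. Stripped variants may be as
  short as 12 nt — still effectively unique on a ≤20 kb genome. Bases at
  the junction-facing end of a placed clip that mismatch the genome are
  trimmed back into the junction gap, where the canonical shift re-absorbs
  genuine sequencing errors (tolerating isolated mismatches followed by six
  clean matches).

Collapsed monomers bypass split alignment entirely: since a monomer is a
rotation of the molecule, `place_monomer()` extends an anchor k-mer match
*cyclically* through the monomer in both directions. The maximal
genome-contiguous run is the body and the cyclic remainder is the junction
sequence. This works down to small RNAs (15–60 nt) whose split parts would
fall below any sensible clip threshold, and it is why the package can call
termini and tails for 19–22 nt decay fragments. These calls carry
`support_class = "rotation_consistent"`; split-read calls are
`"junction_spanning"`, and reads with several junctions (more than one
rolling-circle copy) must agree within 2 nt or are discarded as chimeras.

Adjacent segments whose genome placements differ by at most
`contiguity_tol = 2` nt are one locus, not a junction — without this, every
alignment jitter would become a fake 1-nt "processing site". Calls whose
molecule interval crosses the origin are flagged (`wraps_origin`). Duplicate
reads are *not* collapsed before counting: link tables report read-level
abundance.

## Quantification and statistics

Coverage counts every reference-consuming aligned base per strand, with
circular wraparound; CPM divides by the number of genome-aligned reads
(× 10⁶). Fold changes are `log2((A + ψ)/(B + ψ))` with pseudocount ψ = 1
on the CPM scale (configurable; a masked-zero mode is deliberately not the
default because the pseudocount keeps every position finite). In
`annotate_calls()` a gene counts as spanned when it overlaps the molecule
interval by ≥15 nt — canonical-form shifts of a few bases across abutting
gene boundaries must not inflate multi-gene link counts.

Small RNAs are the collapsed monomers with ≥2 copies and length 15–60 nt.
Feature assignment is strand-aware: tRNA when the body overlaps a
same-strand tRNA by ≥80% (3' extensions allowed), else rRNA/mRNA when the
body lies entirely within a same-strand feature *and* is not a
poly(A)-tailed read ending exactly at the feature's annotated 3' end (that
is a canonical tail, not a decay mark), else unassigned. The per-tRNA CCA
ratio is CCA-tailed / total small-RNA depth at the annotated 3' terminal
nucleotide. Per-gene poly(A) proportions are compared between conditions by
a two-sided, equal-variance Student's t-test on per-replicate proportions
(no multiple-testing correction, by design — the analysis reports per-gene
tests as-is); degenerate inputs are guarded (identical groups give p = 1,
zero within-group variance with different means p = 0, fewer than two
replicates per condition skips the test with a warning).

## Scales used by the test suite and acceptance script

All empirical statements in the package are computed by the tests or by
`scripts/acceptance.R`; none are asserted by hand. The standard desk scale:
a synthetic ~16 kb tRNA-punctuated toy genome (`toy_mito()`); 2,000
molecules from 10 templates for junction recovery (exact at zero error,
±1 nt at 0.5% substitutions); 500 reads against the Biostrings
Smith–Waterman oracle and 1,000 constructed repeats against a brute-force
minimal-period scan; 2,200 molecules per condition for the KO-vs-WT
contrast; and twenty seeded runs of six replicates × 600 molecules for the
small-RNA statistics (per-gene poly(A) proportions 0.1 vs 0.3, CCA fraction
0.6). Because several reads descend from each molecule, contrast ratios
disperse at the molecule level, not the read level; the acceptance checks
therefore compare recovered quantities against the *realized* simulation
truth, and separately verify the generator realizes its nominal 2:1
contrast within molecule-level binomial confidence limits.

## Known limitations

* End-to-end realignment of clips scores substitutions only; the default
  error model has no indels (an indel near a junction costs the call, not
  its correctness).
* Inserts within 5 nt of the read length (246–250 nt) imply overlaps above
  the 245 nt merge cap and pass through unmerged as read 1.
* Junctions whose flanking sequence ends within ~2 nt of a clip falling
  below the minimum clip length can evade calling (counted, bounded by the
  recovery criteria).
* SAM export writes origin-spanning alignments with their unwrapped start
  position; consumers that cannot handle coordinates past the declared
  length should use the BEDGraph exports.
* Cross-strand chimeras are dropped rather than reported.

## A minimal end-to-end run

```{r example, eval = FALSE}
toy <- toy_mito()
tpl <- make_default_templates(toy$annotation, toy$genome, "WT")
sim <- simulate_library(tpl, toy$genome,
                        sim_config(n_molecules = 500, seed = 1))
res <- run_sample(sim$reads, toy$genome, toy$annotation, sample_id = "WT1")
head(res$links)        # inferred molecule termini with read support
res$counts             # per-stage read accounting
write_sample_outputs(res, toy$genome, toy$annotation, "wt1_out")
```
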