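---
title: "Learning, calibrating and aligning with splice-site scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning, calibrating and aligning with splice-site scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescore)
```

## The problem

Spliced alignment — aligning mRNA-like sequences to a eukaryotic genome
through introns — has to decide where each intron starts and ends. Residue
alignment alone is often ambiguous around junctions: several GT..AG
placements can score identically, and with diverged or noisy queries the
aligner routinely has to choose among near-ties. Canonical dinucleotides are
no help on their own: a vertebrate-sized genome carries hundreds of millions
of GT/AG, of which only about 0.1% are real splice sites.

`splicescore` implements the full workflow that addresses this:

1. **Training data** — positive donor/acceptor windows from an annotation,
   negatives from the opposite strand of gene bodies, downsampled to a 1:3
   positive:negative ratio.
2. **Model** — a small two-layer 1D convolutional network over one-hot
   202-bp windows, one *joint* model for donors and acceptors.
3. **Calibration** — raw softmax scores binned and converted to
   `2*log2` empirical log-odds against the null model in which every GT/AG
   is equally likely to be real.
4. **Prediction** — every GT/AG on both strands of a target genome scored
   and written to a 5-column TAB file.
5. **Alignment** — a reference global spliced-alignment dynamic program
   with affine gaps and an intron state that consumes the precomputed
   donor/acceptor scores.
6. **Evaluation** — ROC with restricted AUC (rAUC) for site prediction,
   exact-match junction accuracy and base-level Sn/Sp for alignments.

Everything is exercised end to end on synthetic genomes with a planted
splice grammar, so the package is fully testable offline.

## Training data

Annotated introns yield one donor (5' end, GT on the genome) and one
acceptor (3' end, AG) candidate each; non-GT donors and non-AG acceptors
are dropped and counted, and sites shared between overlapping transcripts
are deduplicated genome-wide by `(chrom, pos, strand, type)`.

Unannotated GT/AG are *not* trusted as negatives everywhere: the annotation
of a non-model organism is usually incomplete, and an unannotated GT in an
intergenic region might be a real, unannotated donor. A GT is taken as a
negative donor only when it lies on the strand *opposite* to an annotated
gene body, where transcription of the annotated gene makes a real donor
implausible; regions covered by genes on both strands are excluded
entirely. Negatives are then downsampled — exactly
`min(available, floor(3 * positives))` under the run seed, so the 1:3
target is testable to equality.

Windows take `flank` bases (default 100) on each side of the invariant
dinucleotide, read on the site's strand; rows are ordered A, C, G, T and N
bases one-hot to all-zero columns. Windows that would run past a contig end
are skipped during training (no padding, avoiding composition artifacts)
but zero-padded during the genome scan, where every candidate must receive
a score. Flank values of 50 and 150 are supported alongside the default.

For splitting, odd-numbered chromosomes (1st, 3rd, ... record in the FASTA)
supply training and validation; genes — not sites — are partitioned 80/20
under the seed so isoforms and all sites of a gene stay on one side; even
chromosomes are held out entirely and used for whole-genome testing and
calibration.

## Model and training

The default network is

```
4 x 202 one-hot
  -> conv(16 features, kernel 5) -> ReLU -> maxpool(2)
  -> conv(16 features, kernel 5) -> ReLU -> maxpool(2)
  -> flatten (16 x 47)
  -> dense(8) -> ReLU -> dense(2) -> softmax
```

with 7,674 trainable parameters (`parameter_count(cnn_config())`). Two
design points deserve comment:

* **Joint donor/acceptor model.** One model is trained on the mixture of
  donor and acceptor examples; the central GT vs AG disambiguates the site
  type. During development a purely linear softmax readout over the pooled
  features could not reconcile the two site types — the same positions must
  be read as donor consensus for GT-centered windows and as
  polypyrimidine-tract/YAG evidence for AG-centered ones — and genome-wide
  ranking plateaued far below the per-type models. The small hidden dense
  layer (8 units) gives the readout the single nonlinearity needed to gate
  the two kinds of evidence; `dense_hidden = 0` restores the linear head.
* **Optimization.** Adam with cross-entropy, batch 64, fully seeded
  (initialization, shuffling, downsampling all derive from one seed).
  `train_cnn()` defaults to lr `1e-3`, patience 3 and a light decoupled
  weight decay (`1e-4`). At the desk scale of the synthetic fixture
  (roughly 1.5–2k training windows for 7.7k parameters) those defaults
  stop at a premature validation plateau, so the pipeline wrapper
  `run_pipeline()` uses lr `2e-3`, weight decay `1e-3`, patience 10 and at
  most 60 epochs; all values are arguments, nothing is hard-wired.
  Early stopping halts at the first epoch `best + patience + 1` and
  restores the best-validation weights. The backward pass is hand-written
  (vectorized im2col matrix algebra) and is guarded by a finite-difference
  gradient check in the test suite; a compiled forward pass, asserted
  numerically identical to the R path, is used for genome-scale scoring.

The untrained model outputs exactly 0.5 for any window because the dense
head is zero-initialized — a convenient calibration-free anchor that the
tests rely on.

`activation_rate_diff()` exposes what the model learned: for each cell of
the last max-pooling layer, the frequency of being positive (non-zero after
ReLU) over a positive window set minus the same rate over a negative set.
Cells adjacent to the splice boundary track the consensus signal; cells far
into the flanks track exon/intron composition.

## Calibration

Raw scores `t` are binned into `b = 50` even bins (`i = floor(t*b)`, t = 1
clipped into the top bin). With `P_i`/`N_i` the annotated/unannotated
counts per bin and `P`, `N` their totals,

```
s(t) = 2 * log2( P_i / (P_i + N_i) * (P + N) / P )
```

is the log odds of the model's empirical probability against the null
model; the `2*log2` scale keeps scores compatible with BLOSUM-style
aligner scoring. A bin whose empirical probability equals the global
positive fraction maps to exactly 0. Numerical choices:

* empty bins (`P_i + N_i = 0`) borrow the counts of the nearest non-empty
  bin, ties to the lower bin;
* `P_i = 0` is genuinely degenerate (log odds of minus infinity) and maps
  to `floor_score` (default −64);
* `N_i = 0` is *not* degenerate — the formula tops out at
  `2*log2((P+N)/P)`, about +13 at a 1:75 positive fraction — and is left
  to the formula. (Clamping such bins to the +64 cap was tried and
  measurably harmed alignment: decoy sites that happened to fall in
  pure-positive bins received outsized bonuses that dragged junctions off
  their true boundaries.)
* quantization rounds half away from zero and clamps to
  `[floor_score, cap_score]` (default ±64).

The calibration population is every GT/AG on the held-out even
chromosomes, labeled by the annotation — the same regime as testing, which
mirrors the intended genome-wide prediction task rather than the
downsampled training mixture.

## Score files and the boundary convention

Score records are written as five TAB-separated columns:
`chrom  offset  strand  D|A  score`. The offset is the 0-based
forward-strand coordinate of the base immediately 3' (rightward) of the
exon|intron boundary: a `+` donor points at the first intronic base (the G
of GT), a `+` acceptor at the first exonic base after AG, and `-` sites
follow the same rightward rule on forward coordinates (so a `-` donor sits
at the right end of its intron's forward interval). Whether the original
tool marks the left or right base is not recoverable from its description;
this package's convention is symmetric, documented, and enforced by tests
end to end (extraction, scanning, alignment and evaluation all share it).

## Spliced alignment

`align_spliced()` is a reference global dynamic program over four states:
`H` (match/mismatch), `E`/`F` (affine deletion/insertion, cost
`q + e*len`), and an intron state opened at reference offset `i` for
`d(i) + q~` and closed at offset `i'` for `a(i')`, advancing the reference
at no per-base cost in between. Because calibrated scores are
higher-is-better log odds while the recurrence subtracts costs, the cost
functions are the negated scores (`d(i) = -s_donor(i)`); unscored
boundaries cost `noncanonical_cost` (default 30) each. Defaults: match +2,
mismatch −4, `q = 4`, `e = 2`, minimum intron length 4 (GT + AG), optional
maximum intron length. The intron-open penalty `q~` defaults to 30 — above
the largest donor+acceptor bonus a calibrated score file can deliver
(about twice `2*log2((P+N)/P)`) — so a pair of well-scored decoy
boundaries inside a real intron can never make splitting that intron into
two profitable; with a smaller `q~` such splits are actively rewarded and
show up as paired junction errors. Ties prefer match over intron over
deletion over insertion, then the leftmost intron start, making the
traceback deterministic.

Correctness is checked three ways: an exhaustive run-enumeration oracle
(every alignment decomposed into diagonal steps, gap runs and intron runs,
memoized; ≥200 random tiny instances per run), the degenerate-limit
equality with plain affine-gap alignment computed by an independent
library, and monotonicity (raising any junction's score never lowers the
optimal alignment score).

The DP is a scoring-model reference, not a read mapper: no seeding,
chaining or banding, and memory is quadratic, so keep references at the
gene-locus scale (a few kb).

## The synthetic fixture

`simulate_genome()` builds multi-chromosome genomes with non-overlapping
multi-exon genes on both strands. Every intron starts GT and ends AG by
construction and carries an extended consensus: a GTRAGTA-like donor run,
and a CTRAY-like branch block, a 20-nt polypyrimidine tract and YAG at the
acceptor, with near-deterministic core positions; exons are GC 0.58,
introns GC 0.32, intergenic background GC 0.45. Defaults: 4 chromosomes of
150 kb, 24 genes each, 6 exons per gene. These defaults were set once, as
the weakest signal at which the default CNN clears rAUC 0.9 on the
held-out chromosomes while background GT/AG decoys still outnumber planted
sites by roughly 150:1 — i.e. the bare GT..AG signal stays thoroughly
ambiguous. `consensus_strength` scales the informative positions toward
uniform for ablation experiments.

What the fixture does **not** emulate: alternative isoforms, non-canonical
(GC..AG, AT..AC) introns, branch-point positional variation beyond the
planted block, sequencing-error profiles beyond i.i.d. substitutions and
1-bp indels, and real genome composition (repeats, CpG islands, GC-rich
introns). Passing the suite therefore demonstrates the machinery is
correct and that the method's ordering holds under a realistic
signal-to-noise regime — not that the specific accuracies transfer to any
real genome.

## Evaluation

`roc_points()`/`rauc()` implement the ROC restricted to sensitivity above
50% and false positive rate below 10%, rescaled to [0, 1] — the operating
region that matters for alignment. `junction_accuracy()` uses exact
boundary-and-strand matching and reports
`%unannotated = 100 * (1 - hits/predicted)` (junctions counted per
alignment, with deduplicated counts reported alongside).
`base_sn_sp()` gives base-level sensitivity/specificity by interval
arithmetic; `identity_binning()` stratifies junction error by alignment
identity (default 2% bins); `expected_false_sites()` is the back-of-envelope
product genome size × dinucleotide frequency × FPR that motivates feeding
scores, not hard calls, to the aligner.

## End-to-end check

`run_pipeline(seed)` runs everything on one fixture: train on odd
chromosomes, calibrate and scan the held-out even chromosomes, then align
mutated transcripts (10% substitutions, 1.5% 1-bp indels, three
independently mutated copies per transcript, giving roughly 85–95%
identity) of the even-chromosome genes back to their loci twice —
once with the calibrated learned scores, once with a uniform GT..AG-only
baseline in which every canonical dinucleotide costs the same — and
reports both junction error rates. The package's acceptance script
reproduces this comparison over several seeds; problem sizes throughout
(fixture dimensions, epochs, candidate counts) are the package defaults
described above.

## Known limitations

* GC..AG and AT..AC introns are ignored throughout, as are branch-point
  annotations; the training extractor drops non-canonical sites by design.
* The model scores the reference genome only; sample-specific variants
  that create or destroy splice sites are invisible to it.
* The DP is global over both sequences; partial/local spliced alignment
  and protein-to-genome alignment are out of scope.
* Calibration quality depends on the held-out chromosomes carrying enough
  annotated sites; tiny genomes give coarse, noisy bins.
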