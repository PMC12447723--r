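# splicescore

Splice-site scoring with a small 1D-CNN, empirical log-odds calibration,
and score-aware spliced alignment — an R toolkit for the full
train → calibrate → scan → align workflow, exercised end to end on
synthetic genomes with a planted splice grammar.

## Who this is for

Bioinformaticians working on spliced alignment and gene annotation who
want a self-contained, testable implementation of the idea of feeding
*precomputed, probability-calibrated* splice-site scores into a
dynamic-programming aligner, rather than relying on the bare GT..AG signal
or a fixed consensus.

## The method

**Model.** Candidate donor (GT) and acceptor (AG) sites are scored by a
two-layer 1D convolutional network over one-hot 202-bp windows
(±100 bp around the invariant dinucleotide):

```
4x202 → conv(16, k=5) → ReLU → pool(2) → conv(16, k=5) → ReLU → pool(2)
      → flatten → dense(8) → ReLU → dense(2) → softmax
```

One *joint* model covers donors and acceptors (the central dinucleotide
disambiguates). The default network has 7,674 trainable parameters
(`parameter_count(cnn_config())`). Positives come from annotated introns;
negatives are unannotated GT/AG on the strand *opposite* to annotated gene
bodies (robust to incomplete annotation), downsampled to a 1:3
positive:negative ratio. Odd-numbered chromosomes train (genes split 80/20
into train/validation); even chromosomes are held out.

**Calibration.** Raw scores `t ∈ [0,1]` are divided into `b = 50` bins,
`i = ⌊tb⌋`. With `P_i`/`N_i` the annotated/unannotated counts in bin `i`
on the held-out chromosomes and `P`, `N` their totals, the calibrated
score is the log odds against the null model in which every GT/AG is
equally likely to be real:

```
s(t) = 2·log2( P_i/(P_i+N_i) · (P+N)/P )
```

quantized to integers in [−64, 64]. The `2·log2` scale matches
BLOSUM-style aligner scoring.

**Prediction.** `scan_genome()` scores every GT/AG on both strands and
writes 5-column TAB records (`chrom offset strand D|A score`), where
`offset` is the 0-based forward-strand coordinate of the base immediately
3′ of the exon|intron boundary.

**Alignment.** `align_spliced()` is a global affine-gap DP
(`H`, gap states `E`/`F`, intron state `Ẽ`):

```
H[i,j] = max( H[i-1,j-1] + s(i,j), E[i,j], F[i,j], Ẽ[i,j] − a(i) )
Ẽ[i+1,j] = max( H[i,j] − d(i) − q̃, Ẽ[i,j] )
```

with `d(i) = −s_donor(i)`, `a(i) = −s_acceptor(i)` (calibrated scores act
as junction bonuses), verified against an exhaustive enumeration oracle.

## Worked example

```r
library(splicescore)

pp <- run_pipeline(seed = 1)   # simulate → train → calibrate → scan → align
pp
#> Splice pipeline (seed 1)
#>   held-out rAUC: 0.907 (480 positives / 71742 candidates)
#> # A tibble: 2 × 6
#>   method    n_predicted n_annotated_hits pct_unannotated n_predicted_distinct
#>   <chr>           <int>            <int>           <dbl>                <int>
#> 1 learned           720              719            0.14                  241
#> 2 gtag_only         720              715            0.69                  245
#> # ℹ 1 more variable: pct_unannotated_distinct <dbl>
```

Reading this output: on a fresh 4×150-kb synthetic genome, the CNN trained
on the odd chromosomes ranks every GT/AG of the held-out even chromosomes
with rAUC 0.907 (area under the ROC restricted to sensitivity > 50% and
FPR < 10%, rescaled to [0,1]). Aligning three independently mutated copies
(10% substitutions, 1.5% indels ⇒ ~89% identity) of each held-out
transcript back to its locus, the calibrated learned scores leave 0.14% of
720 predicted junctions unannotated versus 0.69% for uniform GT..AG-only
scoring — the learned splice model resolves junction ambiguities that the
bare dinucleotide signal cannot.

Individual stages are available as plain functions returning tibbles
(`read_fasta()`, `read_bed12()`, `prepare_training_data()`,
`fit_splice_cnn()`, `build_calibration()`, `scan_genome()`,
`align_spliced()`, `roc_points()`, `junction_accuracy()`, ...), with
broom-style `tidy()`/`glance()` and `ggplot2::autoplot()` methods for the
fitted model, calibration table, ROC curve and activation-difference maps.
See the vignette `vignettes/splice-scoring.Rmd` for the model, its
assumptions, and every numerical choice.

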