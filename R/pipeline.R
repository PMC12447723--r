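#' Whole-genome site-prediction evaluation on held-out chromosomes
#'
#' Applies a trained model to every GT/AG on the even-index chromosomes,
#' labels candidates by the annotation, and summarizes with ROC/rAUC --
#' the testing regime that matches the intended genome-wide prediction task
#' rather than the downsampled training mixture.
#'
#' @param fit A `cnn_fit` or `cnn_model`.
#' @param genome Genome tibble.
#' @param genes Gene-model tibble.
#' @param flank Window flank matching the model.
#' @return List: `roc` (a `splice_roc`), `rauc`, `n_positive`, `n_candidates`.
#' @export
evaluate_sites <- function(fit, genome, genes, flank = 100L) {
  even <- genome[genome$index_in_file %% 2L == 0L, , drop = FALSE]
  if (nrow(even) == 0L) abort("genome has no even-index chromosomes to test on")
  cands <- enumerate_candidates(even)
  t <- score_candidates(fit, even, cands, flank = flank)
  ann <- extract_annotated_sites(genes[genes$chrom %in% even$name, , drop = FALSE],
                                 even)
  lab <- paste(cands$chrom, cands$offset, cands$strand, cands$site_type) %in%
    paste(ann$chrom, ann$pos, ann$strand, ann$site_type)
  roc <- roc_points(t, lab)
  list(roc = roc, rauc = rauc(roc), n_positive = sum(lab),
       n_candidates = nrow(cands))
}

#' Align mutated transcripts back to their loci
#'
#' For each gene on the selected chromosomes, builds the spliced transcript,
#' applies seeded point mutations, and globally aligns it to the gene's
#' genomic span (reverse-complemented for minus-strand genes) with the
#' spliced DP, using either learned splice scores or the uniform GT..AG-only
#' baseline. Reported junctions are mapped back to forward genomic
#' coordinates and checked against the annotated introns by exact match.
#'
#' @param genome Genome tibble.
#' @param genes Gene-model tibble.
#' @param scores A `splice_scores` tibble for the learned model, or `NULL`
#'   for the uniform GT..AG baseline.
#' @param chroms Chromosomes whose genes are aligned (default: even-index).
#' @param substitution_rate,indel_rate Query mutation rates.
#' @param replicates Independently mutated copies aligned per transcript.
#' @param params An [align_params()].
#' @param seed Integer seed for the mutations.
#' @return List: `alignments` (per-gene tibble with `gene_id`, `identity`,
#'   `n_junctions`, `n_annotated_hits`), `junctions` (all predicted
#'   junctions in genomic coordinates), `accuracy` (from
#'   [junction_accuracy()]).
#' @export
align_transcripts <- function(genome, genes, scores = NULL, chroms = NULL,
                              substitution_rate = 0.1, indel_rate = 0.015,
                              replicates = 1L, params = align_params(),
                              seed = 1L) {
  if (is.null(chroms)) {
    chroms <- genome$name[genome$index_in_file %% 2L == 0L]
  }
  gset <- genes[genes$chrom %in% chroms, , drop = FALSE]
  truth <- gene_introns(genes)
  truth_key <- paste(truth$chrom, truth$start, truth$end, truth$strand)
  arows <- list(); jrows <- list()
  for (k in seq_len(nrow(gset))) {
    gene <- gset[k, , drop = FALSE]
    seq <- genome$seq[match(gene$chrom, genome$name)]
    span_fwd <- substring(seq, gene$tx_start + 1L, gene$tx_end)
    span <- if (gene$strand == "-") revcomp(span_fwd) else span_fwd
    tx <- spliced_transcript(genome, gene)
    costs <- if (is.null(scores)) {
      gtag_costs(span, params)
    } else {
      locus_costs(scores, gene$chrom, gene$tx_start, nchar(span_fwd),
                  strand = gene$strand, params = params)
    }
    for (rep_i in seq_len(replicates)) {
      qry <- mutate_query(tx, substitution_rate, indel_rate,
                          seed = (seed * 331L + rep_i) * 1000L + k)
      aln <- align_spliced(span, qry, params = params, costs = costs)
      jt <- aln$junctions
      if (nrow(jt) > 0L) {
        if (gene$strand == "+") {
          gs <- gene$tx_start + jt$start; ge <- gene$tx_start + jt$end
        } else {
          gs <- gene$tx_end - jt$end; ge <- gene$tx_end - jt$start
        }
        jg <- tibble(chrom = gene$chrom, start = as.integer(gs),
                     end = as.integer(ge), strand = gene$strand,
                     gene_id = gene$gene_id)
      } else {
        jg <- tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), gene_id = character())
      }
      hit <- paste(jg$chrom, jg$start, jg$end, jg$strand) %in% truth_key
      arows[[length(arows) + 1L]] <- tibble(
        gene_id = gene$gene_id, replicate = rep_i, identity = aln$identity,
        score = aln$score, n_junctions = nrow(jg),
        n_annotated_hits = sum(hit))
      jrows[[length(jrows) + 1L]] <- jg
    }
  }
  alignments <- dplyr::bind_rows(arows)
  junctions <- dplyr::bind_rows(jrows)
  list(
    alignments = alignments,
    junctions = junctions,
    accuracy = junction_accuracy(
      junctions, truth[, c("chrom", "start", "end", "strand")])
  )
}

#' Run the full simulate/train/calibrate/scan/align workflow
#'
#' One call exercising every stage on a synthetic genome: generate the
#' genome, build training data from odd chromosomes, train the CNN,
#' calibrate on held-out even chromosomes, precompute splice scores for the
#' whole genome, and align mutated transcripts of the even-chromosome genes
#' with (a) the calibrated learned scores and (b) the uniform GT..AG-only
#' baseline.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param config A [synthetic_config()]; its own seed is replaced by `seed`.
#' @param flank Window flank.
#' @param substitution_rate,indel_rate Transcript mutation rates (defaults
#'   target roughly 85-95% alignment identity).
#' @param replicates Independently mutated copies aligned per transcript.
#' @param max_epochs,patience,lr,weight_decay Training-loop controls; the
#'   pipeline defaults are tuned for the desk-scale fixture (a couple of
#'   thousand examples), where the generic [train_cnn()] defaults stop too
#'   early.
#' @param verbose Print stage progress.
#' @return List of class `splice_pipeline`: `sim`, `fit`, `calibration`,
#'   `scores`, `site_eval`, and `junction_eval` (tibble with one row per
#'   scoring method).
#' @export
run_pipeline <- function(seed = 1L, config = NULL, flank = 100L,
                         substitution_rate = 0.1, indel_rate = 0.015,
                         replicates = 3L, max_epochs = 60L, patience = 10L,
                         lr = 2e-3, weight_decay = 1e-3, verbose = FALSE) {
  if (is.null(config)) config <- synthetic_config(seed = seed)
  config$seed <- as.integer(seed)
  say <- function(...) if (verbose) inform(paste0(...))
  say("simulating genome")
  sim <- simulate_genome(config)
  say("training CNN")
  fit <- fit_splice_cnn(sim$genome, sim$genes, flank = flank, seed = seed,
                        max_epochs = max_epochs, patience = patience,
                        lr = lr, weight_decay = weight_decay)
  say("evaluating on held-out chromosomes")
  site_eval <- evaluate_sites(fit, sim$genome, sim$genes, flank = flank)
  say("calibrating")
  calib <- calibrate_on_heldout(fit, sim$genome, sim$genes, flank = flank)
  say("scanning genome")
  scores <- scan_genome(sim$genome, fit, calib, flank = flank)
  say("aligning mutated transcripts (learned scores)")
  learned <- align_transcripts(sim$genome, sim$genes, scores = scores,
                               substitution_rate = substitution_rate,
                               indel_rate = indel_rate,
                               replicates = replicates, seed = seed)
  say("aligning mutated transcripts (GT..AG baseline)")
  baseline <- align_transcripts(sim$genome, sim$genes, scores = NULL,
                                substitution_rate = substitution_rate,
                                indel_rate = indel_rate,
                                replicates = replicates, seed = seed)
  junction_eval <- dplyr::bind_rows(
    dplyr::mutate(learned$accuracy, method = "learned", .before = 1L),
    dplyr::mutate(baseline$accuracy, method = "gtag_only", .before = 1L)
  )
  structure(list(
    sim = sim, fit = fit, calibration = calib, scores = scores,
    site_eval = site_eval, junction_eval = junction_eval,
    learned = learned, baseline = baseline, seed = seed
  ), class = "splice_pipeline")
}

#' @export
print.splice_pipeline <- function(x, ...) {
  cat("Splice pipeline (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  held-out rAUC: %.3f (%d positives / %d candidates)\n",
              x$site_eval$rauc, x$site_eval$n_positive,
              x$site_eval$n_candidates))
  print(x$junction_eval)
  invisible(x)
}
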