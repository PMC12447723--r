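#' Configuration for the synthetic genome simulator
#'
#' Describes a toy multi-chromosome genome carrying multi-exon gene models on
#' both strands. Every planted intron begins with GT and ends with AG by
#' construction and carries an extended GTR..YAG-like consensus: a weighted
#' GTRAGT run at the donor, and a polypyrimidine tract followed by YAG at the
#' acceptor. Exons and introns have different GC content (composition bias),
#' and the intergenic background supplies many decoy GT/AG dinucleotides, so
#' the bare GT..AG signal alone is ambiguous.
#'
#' @param n_chromosomes Number of chromosomes (must be >= 2 so odd/even
#'   train/test splitting is possible).
#' @param chrom_length Length of each chromosome in bp.
#' @param genes_per_chrom Genes planted per chromosome.
#' @param exons_per_gene Exons per gene (introns = exons - 1).
#' @param exon_length_range,intron_length_range Integer ranges (min, max) for
#'   exon and intron lengths; introns must be long enough to hold the
#'   acceptor tract (>= 40 bp).
#' @param exon_gc,intron_gc,background_gc GC fractions for exonic, intronic
#'   and intergenic sequence.
#' @param minus_fraction Fraction of genes planted on the minus strand.
#' @param consensus_strength In (0, 1]; scales how strongly the consensus
#'   positions beyond the invariant GT/AG are biased toward the motif.
#' @param seed Integer seed; the whole genome is a deterministic function of
#'   the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 4L,
                             chrom_length = 150000L,
                             genes_per_chrom = 24L,
                             exons_per_gene = 6L,
                             exon_length_range = c(120L, 280L),
                             intron_length_range = c(200L, 700L),
                             exon_gc = 0.58,
                             intron_gc = 0.32,
                             background_gc = 0.45,
                             minus_fraction = 0.5,
                             consensus_strength = 1,
                             seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chrom_length > 0L, genes_per_chrom >= 1L,
            exons_per_gene >= 2L, intron_length_range[1L] >= 40L,
            consensus_strength > 0, consensus_strength <= 1)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    genes_per_chrom = as.integer(genes_per_chrom),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    exon_gc = exon_gc, intron_gc = intron_gc, background_gc = background_gc,
    minus_fraction = minus_fraction,
    consensus_strength = consensus_strength,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Sample iid sequence with a given GC fraction; returns a character scalar.
sample_seq <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Interpolate a motif column toward uniform as strength decreases.
motif_col <- function(p, strength) {
  p <- p / sum(p)
  strength * p + (1 - strength) * rep(0.25, 4)
}

# Donor motif: 3 exonic positions (MAG|-like), then invariant GT, then an
# RAGTATC-like biased run (U1-binding analog). Acceptor motif: a CTRAY-like
# branch-point block, a 20-nt polypyrimidine tract, Y, then invariant AG,
# then one weakly biased exonic G. Rows ordered A, C, G, T.
splice_motifs <- function(strength) {
  don_exon <- cbind(c(.48, .38, .08, .06), c(.78, .04, .12, .06), c(.03, .01, .94, .02))
  don_intron <- cbind(c(.62, .01, .36, .01),  # R
                      c(.96, .02, .01, .01),  # A
                      c(.01, .01, .97, .01),  # G
                      c(.01, .01, .01, .97),  # T
                      c(.85, .05, .06, .04),  # A-ish
                      c(.04, .05, .03, .88),  # T-ish
                      c(.12, .62, .08, .18))  # C-ish
  branch <- cbind(c(.03, .85, .05, .07),     # C
                  c(.03, .05, .04, .88),     # T
                  c(.58, .02, .38, .02),     # R
                  c(.92, .03, .03, .02),     # A
                  c(.06, .48, .03, .43))     # Y
  ppt <- matrix(rep(c(.02, .44, .02, .52), 20L), nrow = 4L)
  acc_y <- c(.01, .60, .01, .38)
  acc_exon <- c(.25, .15, .45, .15)
  list(
    donor_exon = apply(don_exon, 2L, motif_col, strength = strength),
    donor_intron = apply(don_intron, 2L, motif_col, strength = strength),
    acceptor_tract = cbind(apply(branch, 2L, motif_col, strength = strength),
                           apply(ppt, 2L, motif_col, strength = strength)),
    acceptor_y = motif_col(acc_y, strength),
    acceptor_exon = motif_col(acc_exon, strength)
  )
}

sample_motif <- function(cols) {
  bases <- c("A", "C", "G", "T")
  paste0(vapply(seq_len(ncol(cols)), function(j) {
    sample(bases, 1L, prob = cols[, j])
  }, character(1)), collapse = "")
}

#' Simulate a genome with planted splice grammar
#'
#' Builds each gene in its own (transcribed) orientation -- exons with exonic
#' GC, introns starting `GT` + consensus and ending polypyrimidine tract +
#' `YAG` -- then inserts it on the forward strand directly or as its reverse
#' complement for minus-strand genes. Gene placement is sequential with random
#' intergenic gaps; genes never overlap (on either strand).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_genome` with elements `genome` (tibble
#'   as from [read_fasta()]), `genes` (gene-model tibble as from
#'   [read_bed12()]), `sites` (truth tibble of every planted donor/acceptor:
#'   `chrom`, `pos`, `strand`, `site_type`, `gene_id`), and `config`.
#' @export
simulate_genome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "simulate"))
  motifs <- splice_motifs(config$consensus_strength)
  chroms <- vector("list", config$n_chromosomes)
  gene_rows <- list()
  site_rows <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    cname <- paste0("chr", ci)
    pieces <- character(0)
    cursor <- 0L
    genes_here <- 0L
    while (genes_here < config$genes_per_chrom) {
      gap <- sample(400:1200, 1L)
      g <- build_gene(config, motifs)
      if (cursor + gap + nchar(g$seq) + 200L > config$chrom_length) {
        abort(paste0("infeasible packing: ", config$genes_per_chrom,
                     " genes do not fit in ", config$chrom_length,
                     " bp on ", cname))
      }
      strand <- if (runif(1) < config$minus_fraction) "-" else "+"
      gstart <- cursor + gap
      pieces <- c(pieces, sample_seq(gap, config$background_gc),
                  if (strand == "+") g$seq else revcomp(g$seq))
      cursor <- gstart + nchar(g$seq)
      gi <- gi + 1L
      genes_here <- genes_here + 1L
      gname <- sprintf("gene%03d", gi)
      glen <- nchar(g$seq)
      if (strand == "+") {
        ex_s <- gstart + g$exon_starts
        ex_e <- gstart + g$exon_ends
      } else {
        # mirror gene-local half-open intervals through the gene length
        ex_s <- gstart + glen - rev(g$exon_ends)
        ex_e <- gstart + glen - rev(g$exon_starts)
      }
      gene_rows[[gi]] <- tibble(
        chrom = cname, tx_start = gstart, tx_end = gstart + glen,
        name = gname, strand = strand, gene_id = gname,
        exon_starts = list(as.integer(ex_s)), exon_ends = list(as.integer(ex_e))
      )
      if (length(ex_s) > 1L) {
        int_s <- ex_e[-length(ex_e)]
        int_e <- ex_s[-1L]
        if (strand == "+") {
          site_rows[[gi]] <- tibble(
            chrom = cname,
            pos = as.integer(c(int_s, int_e)),
            strand = strand,
            site_type = rep(c("D", "A"), each = length(int_s)),
            gene_id = gname
          )
        } else {
          site_rows[[gi]] <- tibble(
            chrom = cname,
            pos = as.integer(c(int_e, int_s)),
            strand = strand,
            site_type = rep(c("D", "A"), each = length(int_s)),
            gene_id = gname
          )
        }
      }
    }
    pieces <- c(pieces, sample_seq(config$chrom_length - cursor, config$background_gc))
    chroms[[ci]] <- tibble(name = cname, seq = paste0(pieces, collapse = ""),
                           index_in_file = ci)
  }
  structure(list(
    genome = dplyr::bind_rows(chroms),
    genes = dplyr::bind_rows(gene_rows),
    sites = dplyr::bind_rows(site_rows) %>%
      dplyr::arrange(.data$chrom, .data$pos, .data$strand, .data$site_type),
    config = config
  ), class = "synthetic_genome")
}

# One gene in transcribed orientation: returns seq + gene-local half-open
# exon intervals (0-based, relative to gene start).
build_gene <- function(config, motifs) {
  n_ex <- config$exons_per_gene
  ex_len <- sample(config$exon_length_range[1L]:config$exon_length_range[2L],
                   n_ex, replace = TRUE)
  in_len <- sample(config$intron_length_range[1L]:config$intron_length_range[2L],
                   n_ex - 1L, replace = TRUE)
  parts <- character(0)
  exon_starts <- integer(n_ex)
  exon_ends <- integer(n_ex)
  cursor <- 0L
  for (k in seq_len(n_ex)) {
    exon <- sample_seq(ex_len[k], config$exon_gc)
    if (k > 1L) {
      # overwrite first exonic base after the acceptor with its weak consensus
      exon <- paste0(sample_motif(matrix(motifs$acceptor_exon, ncol = 1L)),
                     substring(exon, 2L))
    }
    if (k < n_ex) {
      # last 3 exonic bases carry the donor's exonic consensus
      exon <- paste0(substring(exon, 1L, ex_len[k] - 3L),
                     sample_motif(motifs$donor_exon))
    }
    parts <- c(parts, exon)
    exon_starts[k] <- cursor
    cursor <- cursor + ex_len[k]
    exon_ends[k] <- cursor
    if (k < n_ex) {
      L <- in_len[k]
      head_len <- 2L + ncol(motifs$donor_intron)
      tail_len <- ncol(motifs$acceptor_tract) + 1L + 2L
      mid <- sample_seq(L - head_len - tail_len, config$intron_gc)
      intron <- paste0("GT", sample_motif(motifs$donor_intron), mid,
                       sample_motif(motifs$acceptor_tract),
                       sample_motif(matrix(motifs$acceptor_y, ncol = 1L)), "AG")
      stopifnot(nchar(intron) == L)
      parts <- c(parts, intron)
      cursor <- cursor + L
    }
  }
  list(seq = paste0(parts, collapse = ""), exon_starts = exon_starts,
       exon_ends = exon_ends)
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates the exons and reverse-complements for minus-strand genes, so
#' the result reads in the mRNA sense.
#'
#' @param genome Genome tibble.
#' @param gene One row of a gene-model tibble.
#' @return Character scalar.
#' @export
spliced_transcript <- function(genome, gene) {
  seq <- genome$seq[match(gene$chrom, genome$name)]
  xs <- gene$exon_starts[[1L]]
  xe <- gene$exon_ends[[1L]]
  tx <- paste0(substring(seq, xs + 1L, xe), collapse = "")
  if (gene$strand == "-") revcomp(tx) else tx
}

#' Mutate a query sequence at controlled error rates
#'
#' Applies seeded point substitutions and single-base indels to a transcript
#' so spliced alignment can be exercised at a chosen identity level.
#'
#' @param seq Character scalar (ACGT).
#' @param substitution_rate,indel_rate Per-base rates in \[0, 0.3\].
#' @param seed Integer seed.
#' @return Mutated character scalar.
#' @export
mutate_query <- function(seq, substitution_rate = 0.05, indel_rate = 0, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.3,
            indel_rate >= 0, indel_rate <= 0.3)
  set.seed(derive_seed(seed, "mutate"))
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(x)
  sub_at <- which(runif(n) < substitution_rate)
  for (i in sub_at) {
    x[i] <- sample(setdiff(bases, x[i]), 1L)
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_len(n)) {
      r <- runif(1)
      if (r < indel_rate / 2) {
        next  # deletion
      } else if (r < indel_rate) {
        out <- c(out, x[i], sample(bases, 1L))  # insertion after base
      } else {
        out <- c(out, x[i])
      }
    }
    x <- out
  }
  paste0(x, collapse = "")
}

#' Write a synthetic genome to disk
#'
#' @param sim A `synthetic_genome`.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths (`fasta`, `bed`, `sites`), invisibly.
#' @export
write_synthetic_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    bed = file.path(dir, "annotation.bed"),
    sites = file.path(dir, "true_sites.tsv")
  )
  write_fasta(sim$genome, paths$fasta)
  write_bed12(sim$genes, paths$bed)
  readr::write_tsv(sim$sites, paths$sites, progress = FALSE)
  invisible(paths)
}
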