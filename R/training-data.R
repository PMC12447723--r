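#' Extract annotated splice sites from gene models
#'
#' Every intron of every transcript contributes one donor and one acceptor
#' candidate. A candidate is kept as a positive site only when its genomic
#' dinucleotide, read on the transcript strand, is GT (donor) or AG
#' (acceptor); non-canonical sites are dropped and counted. Sites shared by
#' overlapping transcripts are deduplicated genome-wide by
#' (chrom, pos, strand, site_type).
#'
#' @param genes Gene-model tibble ([read_bed12()] shape).
#' @param genome Genome tibble ([read_fasta()] shape).
#' @return Tibble with `chrom`, `pos` (boundary offset, see
#'   [write_score_file()] for the convention), `strand`, `site_type`
#'   (`D`/`A`), `gene_id`, `label = "positive"`. The number of dropped
#'   non-canonical sites is attached as attribute `n_noncanonical`.
#' @export
extract_annotated_sites <- function(genes, genome) {
  introns <- gene_introns(genes)
  missing_chrom <- setdiff(unique(introns$chrom), genome$name)
  if (length(missing_chrom) > 0L) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  empty <- tibble(chrom = character(), pos = integer(), strand = character(),
                  site_type = character(), gene_id = character(),
                  label = character())
  if (nrow(introns) == 0L) {
    attr(empty, "n_noncanonical") <- 0L
    return(empty)
  }
  seqs <- setNames(genome$seq, genome$name)
  left_dinuc <- substring(seqs[introns$chrom], introns$start + 1L, introns$start + 2L)
  right_dinuc <- substring(seqs[introns$chrom], introns$end - 1L, introns$end)
  plus <- introns$strand == "+"
  donors <- tibble(
    chrom = introns$chrom,
    pos = ifelse(plus, introns$start, introns$end),
    strand = introns$strand,
    site_type = "D",
    gene_id = introns$gene_id,
    dinuc = ifelse(plus, left_dinuc, revcomp(right_dinuc))
  )
  acceptors <- tibble(
    chrom = introns$chrom,
    pos = ifelse(plus, introns$end, introns$start),
    strand = introns$strand,
    site_type = "A",
    gene_id = introns$gene_id,
    dinuc = ifelse(plus, right_dinuc, revcomp(left_dinuc))
  )
  all <- dplyr::bind_rows(donors, acceptors)
  canonical <- (all$site_type == "D" & all$dinuc == "GT") |
    (all$site_type == "A" & all$dinuc == "AG")
  n_drop <- sum(!canonical)
  out <- all[canonical, ] %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$strand, .data$site_type,
                    .keep_all = TRUE) %>%
    dplyr::mutate(pos = as.integer(.data$pos), label = "positive") %>%
    dplyr::select(-"dinuc") %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$strand, .data$site_type)
  attr(out, "n_noncanonical") <- n_drop
  out
}

# Per-chromosome strand coverage of gene bodies; returns IRanges per strand.
strand_coverage <- function(genes, chrom) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  lapply(c("+" = "+", "-" = "-"), function(st) {
    gg <- g[g$strand == st, , drop = FALSE]
    if (nrow(gg) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(start = gg$tx_start + 1L, end = gg$tx_end))
  })
}

#' Extract negative splice-site candidates
#'
#' Annotation is rarely complete, so an unannotated GT is only trusted as a
#' negative donor when it lies on the strand opposite to an annotated gene
#' body (and similarly for AG/acceptors). Regions covered by genes on both
#' strands are excluded entirely, and any position occupied by an annotated
#' site is never emitted as a negative.
#'
#' @param genes Gene-model tibble.
#' @param genome Genome tibble.
#' @param annotated Positive-site tibble from [extract_annotated_sites()];
#'   computed on the fly if `NULL`.
#' @return Tibble of negative sites in the same shape as
#'   [extract_annotated_sites()] (with `label = "negative"`); `gene_id` is
#'   the opposite-strand gene whose body hosts the site.
#' @export
extract_negative_sites <- function(genes, genome, annotated = NULL) {
  if (is.null(annotated)) annotated <- extract_annotated_sites(genes, genome)
  out <- list()
  for (chrom in unique(genes$chrom)) {
    seq <- genome$seq[match(chrom, genome$name)]
    cov <- strand_coverage(genes, chrom)
    both <- BiocGenerics::intersect(cov[["+"]], cov[["-"]])
    # region where negatives on strand st are allowed: gene bodies on the
    # opposite strand, minus dual-strand overlap
    allowed <- list(
      "-" = BiocGenerics::setdiff(cov[["+"]], both),
      "+" = BiocGenerics::setdiff(cov[["-"]], both)
    )
    ann_pos <- annotated$pos[annotated$chrom == chrom]
    ann_genes <- genes[genes$chrom == chrom, , drop = FALSE]
    for (st in c("+", "-")) {
      if (length(allowed[[st]]) == 0L) next
      # forward-strand dinucleotides realizing a donor/acceptor on strand st
      pats <- if (st == "+") c(D = "GT", A = "AG") else c(D = "AC", A = "CT")
      for (ty in c("D", "A")) {
        hits <- find_dinuc(seq, pats[[ty]])  # 0-based starts
        if (length(hits) == 0L) next
        inside <- IRanges::overlapsAny(
          IRanges::IRanges(start = hits + 1L, width = 2L), allowed[[st]],
          type = "within")
        hits <- hits[inside]
        if (length(hits) == 0L) next
        offs <- site_offset(hits, st, ty)
        keep <- !(offs %in% ann_pos)
        if (!any(keep)) next
        offs <- offs[keep]
        host <- host_gene(ann_genes, offs, opposite_of = st)
        out[[length(out) + 1L]] <- tibble(
          chrom = chrom, pos = as.integer(offs), strand = st, site_type = ty,
          gene_id = host, label = "negative"
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  site_type = character(), gene_id = character(),
                  label = character()))
  }
  dplyr::bind_rows(out) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$strand, .data$site_type)
}

# 0-based start positions of a fixed dinucleotide on the forward strand.
find_dinuc <- function(seq, pat) {
  m <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# Boundary offset of a site whose forward dinucleotide starts at p (0-based):
# the rightward-base rule puts left boundaries at the dinucleotide start and
# right boundaries one past its end.
site_offset <- function(p, strand, site_type) {
  left <- (strand == "+" & site_type == "D") | (strand == "-" & site_type == "A")
  if (left) p else p + 2L
}

# Gene (on the strand opposite to `opposite_of`) whose body contains each offset.
host_gene <- function(genes, offsets, opposite_of) {
  g <- genes[genes$strand != opposite_of, , drop = FALSE]
  if (nrow(g) == 0L) return(rep(NA_character_, length(offsets)))
  ir <- IRanges::IRanges(start = g$tx_start + 1L, end = g$tx_end)
  qr <- IRanges::IRanges(start = offsets + 1L, width = 1L)
  hit <- IRanges::findOverlaps(qr, ir, select = "first")
  g$gene_id[hit]
}

#' Downsample negatives to a positive:negative target ratio
#'
#' Keeps exactly `min(nrow(negatives), floor(ratio * nrow(positives)))`
#' negatives, chosen uniformly without replacement; deterministic for a fixed
#' seed.
#'
#' @param positives,negatives Site tibbles.
#' @param ratio Negatives kept per positive (default 3, the 1:3 rule).
#' @param seed Integer seed.
#' @return Subset of `negatives`, in (chrom, pos) order.
#' @export
downsample_negatives <- function(positives, negatives, ratio = 3, seed = 1L) {
  stopifnot(ratio > 0)
  n_keep <- min(nrow(negatives), floor(ratio * nrow(positives)))
  negatives <- dplyr::arrange(negatives, .data$chrom, .data$pos, .data$strand,
                              .data$site_type)
  set.seed(derive_seed(seed, "downsample"))
  idx <- sort(sample.int(nrow(negatives), n_keep))
  negatives[idx, , drop = FALSE]
}

#' One-hot encode a splice-site window
#'
#' The window is read on the site's strand (reverse-complemented for `-`)
#' with the invariant GT/AG occupying the two central columns; rows are
#' ordered A, C, G, T and `N` columns are all zero.
#'
#' @param site One-row site tibble (`chrom`, `pos`, `strand`, `site_type`).
#' @param genome Genome tibble.
#' @param flank Bases on each side of the central dinucleotide (default 100,
#'   giving a 202-bp window; 50 and 150 are also supported).
#' @return A 4 x (2*flank + 2) numeric matrix, or `NULL` when the window
#'   extends past the sequence end.
#' @export
make_window <- function(site, genome, flank = 100L) {
  w <- build_windows(site, genome, flank = flank, pad = FALSE)
  if (length(w$kept) == 0L) return(NULL)
  w$x[, , 1L]
}

# Batched window construction. Returns list(x = 4 x W x n array, kept =
# indices of sites retained). pad = TRUE zero-pads windows that run past the
# sequence ends (used by the genome scan); pad = FALSE skips them (training).
build_windows <- function(sites, genome, flank = 100L, pad = FALSE) {
  W <- 2L * flank + 2L
  n <- nrow(sites)
  seqs <- setNames(genome$seq, genome$name)
  lens <- setNames(nchar(genome$seq), genome$name)
  core_start <- ifelse(
    (sites$strand == "+" & sites$site_type == "D") |
      (sites$strand == "-" & sites$site_type == "A"),
    sites$pos, sites$pos - 2L)
  from <- core_start - flank          # 0-based inclusive
  to <- core_start + 2L + flank       # 0-based exclusive
  inb <- from >= 0L & to <= lens[sites$chrom]
  kept <- if (pad) seq_len(n) else which(inb)
  if (length(kept) == 0L) {
    return(list(x = array(0, dim = c(4L, W, 0L)), kept = integer(0),
                n_skipped = n))
  }
  f <- pmax(from[kept], 0L)
  t <- pmin(to[kept], lens[sites$chrom][kept])
  raw <- substring(seqs[sites$chrom[kept]], f + 1L, t)
  left_pad <- f - from[kept]
  right_pad <- to[kept] - t
  win <- paste0(strrep("N", left_pad), raw, strrep("N", right_pad))
  minus <- sites$strand[kept] == "-"
  if (any(minus)) win[minus] <- revcomp(win[minus])
  x <- one_hot(win, W)
  list(x = x, kept = kept, n_skipped = n - length(kept))
}

# One-hot encode equal-length strings into a 4 x W x n array (A,C,G,T rows;
# N and padding give zero columns). Vectorized over the concatenated bytes.
one_hot <- function(strings, W) {
  n <- length(strings)
  if (n == 0L) return(array(0, dim = c(4L, W, 0L)))
  v <- utf8ToInt(paste0(strings, collapse = ""))
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  code <- lut[v]
  x <- numeric(4L * W * n)
  hit <- which(!is.na(code))
  x[(hit - 1L) * 4L + code[hit]] <- 1
  array(x, dim = c(4L, W, n))
}

#' Split labeled examples by chromosome parity and gene
#'
#' Chromosomes at odd `index_in_file` feed training and validation; genes
#' (not individual sites) on those chromosomes are randomly partitioned so
#' that every site of a gene lands in the same split. Even-index chromosomes
#' are reserved for whole-genome testing.
#'
#' @param examples Site tibble with a `gene_id` column.
#' @param genome Genome tibble with `index_in_file`.
#' @param train_fraction Fraction of genes assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return A list of class `dataset_split`: `train`, `validation` (site
#'   tibbles) and `test_chromosomes` (character vector).
#' @export
split_by_chromosome <- function(examples, genome, train_fraction = 0.8, seed = 1L) {
  if (nrow(genome) < 2L) {
    abort("need at least 2 chromosomes to reserve even-index ones for testing; supply multi-chromosome input")
  }
  odd <- genome$name[genome$index_in_file %% 2L == 1L]
  even <- genome$name[genome$index_in_file %% 2L == 0L]
  pool <- examples[examples$chrom %in% odd, , drop = FALSE]
  gene_ids <- sort(unique(pool$gene_id))
  set.seed(derive_seed(seed, "split"))
  n_train <- round(train_fraction * length(gene_ids))
  train_genes <- sort(sample(gene_ids, n_train))
  structure(list(
    train = pool[pool$gene_id %in% train_genes, , drop = FALSE],
    validation = pool[!(pool$gene_id %in% train_genes), , drop = FALSE],
    test_chromosomes = even
  ), class = "dataset_split")
}

#' Build a complete labeled training dataset
#'
#' Runs the full data-generation recipe: positive donor/acceptor extraction,
#' opposite-strand negative extraction, 1:`neg_ratio` downsampling, and the
#' odd-chromosome gene-level train/validation split.
#'
#' @param genome Genome tibble.
#' @param genes Gene-model tibble.
#' @param flank Window flank (default 100).
#' @param neg_ratio Negatives kept per positive (default 3).
#' @param train_fraction Gene-level training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List of class `splice_dataset`: `sites` (all labeled sites),
#'   `split` (a `dataset_split`), `flank`, and bookkeeping counts.
#' @export
prepare_training_data <- function(genome, genes, flank = 100L, neg_ratio = 3,
                                  train_fraction = 0.8, seed = 1L) {
  pos <- extract_annotated_sites(genes, genome)
  neg_all <- extract_negative_sites(genes, genome, annotated = pos)
  neg <- downsample_negatives(pos, neg_all, ratio = neg_ratio, seed = seed)
  sites <- dplyr::bind_rows(pos, neg)
  split <- split_by_chromosome(sites, genome, train_fraction = train_fraction,
                               seed = seed)
  structure(list(
    sites = sites,
    split = split,
    flank = as.integer(flank),
    counts = c(
      n_positive = nrow(pos),
      n_negative_available = nrow(neg_all),
      n_negative_kept = nrow(neg),
      n_noncanonical_dropped = attr(pos, "n_noncanonical") %||% 0L
    )
  ), class = "splice_dataset")
}
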