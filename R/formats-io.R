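#' Read a FASTA file into a genome tibble
#'
#' Loads a (possibly gzip-compressed) FASTA file into memory. Sequences are
#' uppercased and any character outside `A`,`C`,`G`,`T`,`N` is mapped to `N`.
#' The 1-based ordinal of each record in the file is kept because downstream
#' train/test splitting assigns odd-index chromosomes to training and
#' even-index chromosomes to held-out testing.
#'
#' @param path Path to a FASTA file, plain or `.gz`.
#' @return A tibble with columns `name` (first whitespace-delimited token of
#'   the header), `seq` (uppercase ACGTN string) and `index_in_file`
#'   (1-based record ordinal).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  con <- file(path)  # file() transparently decompresses gzip
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    abort(paste0("empty FASTA file: ", path, " (line 1)"))
  }
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    abort(paste0("empty FASTA file: ", path, " (line 1)"))
  }
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    abort(paste0("malformed FASTA: expected '>' header at line ", first))
  }
  hdr_idx <- which(startsWith(lines, ">"))
  names <- sub("^>\\s*", "", lines[hdr_idx])
  names <- vapply(strsplit(names, "\\s+"), `[[`, character(1), 1L)
  if (any(!nzchar(names))) {
    bad <- hdr_idx[!nzchar(names)][1L]
    abort(paste0("malformed FASTA: empty header at line ", bad))
  }
  bounds <- c(hdr_idx, length(lines) + 1L)
  seqs <- character(length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    body <- lines[seq(bounds[k] + 1L, bounds[k + 1L] - 1L, length.out =
                        max(0L, bounds[k + 1L] - bounds[k] - 1L))]
    seqs[k] <- paste0(trimws(body), collapse = "")
    if (!nzchar(seqs[k])) {
      abort(paste0("malformed FASTA: record '", names[k],
                   "' has no sequence (line ", hdr_idx[k], ")"))
    }
  }
  tibble(
    name = names,
    seq = normalize_seq(seqs),
    index_in_file = seq_along(names)
  )
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble with `name` and `seq` columns.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  out <- unlist(purrr::map2(genome$name, genome$seq, function(nm, s) {
    body <- substring(s, seq(1L, nchar(s), by = width),
                      pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s)))
    c(paste0(">", nm), body)
  }))
  readr::write_lines(out, path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Parses 12-column BED into one row per transcript. All coordinates are kept
#' 0-based half-open, the BED-native convention; exon blocks are reconstructed
#' from `blockSizes`/`blockStarts` and the introns are the gaps between
#' consecutive exons. BED12 carries no gene grouping key, so `gene_id`
#' defaults to the transcript `name`.
#'
#' @param path Path to a BED12 file (plain or gzip).
#' @return A tibble with columns `chrom`, `tx_start`, `tx_end`, `name`,
#'   `strand`, `gene_id`, and list-columns `exon_starts`, `exon_ends`
#'   (0-based half-open, sorted, non-overlapping).
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) abort(paste0("BED12 file not found: ", path))
  con <- file(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  rows <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    ln <- keep[ii]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 12L) {
      abort(paste0("BED12 parse error at line ", ln, ": expected 12 columns, got ",
                   length(f)))
    }
    chrom <- f[1]
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    strand <- f[6]
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.integer(strsplit(sub(",$", "", f[11]), ",")[[1L]]))
    offs <- suppressWarnings(as.integer(strsplit(sub(",$", "", f[12]), ",")[[1L]]))
    if (anyNA(c(start, end, n_blocks)) || anyNA(sizes) || anyNA(offs)) {
      abort(paste0("BED12 parse error at line ", ln, ": non-numeric coordinate field"))
    }
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      abort(paste0("BED12 parse error at line ", ln, ": blockCount=", n_blocks,
                   " but ", length(sizes), " sizes / ", length(offs), " starts"))
    }
    if (!strand %in% c("+", "-")) {
      abort(paste0("BED12 parse error at line ", ln, ": strand must be + or -"))
    }
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    if (is.unsorted(ex_start, strictly = TRUE) ||
        any(ex_start[-1L] < ex_end[-n_blocks])) {
      abort(paste0("BED12 parse error at line ", ln,
                   ": exon blocks unsorted or overlapping"))
    }
    if (ex_start[1L] < start || ex_end[n_blocks] > end) {
      abort(paste0("BED12 parse error at line ", ln, ": block outside [chromStart, chromEnd)"))
    }
    rows[[ii]] <- tibble(
      chrom = chrom, tx_start = start, tx_end = end, name = f[4],
      strand = strand, gene_id = f[4],
      exon_starts = list(ex_start), exon_ends = list(ex_end)
    )
  }
  if (length(rows) == 0L) {
    return(tibble(chrom = character(), tx_start = integer(), tx_end = integer(),
                  name = character(), strand = character(), gene_id = character(),
                  exon_starts = list(), exon_ends = list()))
  }
  dplyr::bind_rows(rows)
}

#' Write gene models to BED12
#'
#' @param genes Gene-model tibble as returned by [read_bed12()].
#' @param path Output path; `.gz` supported.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  lines <- purrr::pmap_chr(
    list(genes$chrom, genes$tx_start, genes$tx_end, genes$name, genes$strand,
         genes$exon_starts, genes$exon_ends),
    function(chrom, s, e, nm, st, xs, xe) {
      paste(chrom, s, e, nm, 0L, st, s, e, 0L, length(xs),
            paste0(xe - xs, collapse = ","), paste0(xs - s, collapse = ","),
            sep = "\t")
    }
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Convert GTF or GFF3 annotation to gene models
#'
#' Reads `exon` features, groups them by transcript (`transcript_id` in GTF,
#' `Parent` in GFF3), converts the 1-based inclusive coordinates to 0-based
#' half-open, and merges/sorts exons per transcript. Exons without a transcript
#' grouping key are skipped and counted in a warning.
#'
#' @param path Path to a GTF or GFF3 file.
#' @param dialect `"GTF"` or `"GFF3"`. Defaults to guessing from the extension.
#' @return A gene-model tibble in the same shape as [read_bed12()].
#' @export
gxf_to_bed12 <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "GFF3" else "GTF"
  }
  dialect <- match.arg(toupper(dialect), c("GTF", "GFF3"))
  gr <- rtracklayer::import(path, format = if (dialect == "GTF") "gtf" else "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) {
    return(tibble(chrom = character(), tx_start = integer(), tx_end = integer(),
                  name = character(), strand = character(), gene_id = character(),
                  exon_starts = list(), exon_ends = list()))
  }
  md <- S4Vectors::mcols(gr)
  if (dialect == "GTF") {
    tx <- as.character(md$transcript_id)
    gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else NA_character_
  } else {
    par <- md$Parent
    tx <- vapply(as.list(par), function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, character(1))
    tx <- sub("^transcript:", "", tx)
    gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else NA_character_
  }
  if (length(gid) == 1L) gid <- rep(gid, length(gr))
  skipped <- is.na(tx) | !nzchar(tx)
  if (any(skipped)) {
    warn(paste0(sum(skipped), " exon feature(s) without a transcript grouping key were skipped"))
  }
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tx = tx, gene_id = gid
  )[!skipped, , drop = FALSE]
  df %>%
    dplyr::group_by(.data$tx) %>%
    dplyr::arrange(.data$start0, .by_group = TRUE) %>%
    dplyr::summarise(
      chrom = .data$chrom[1L],
      strand = if (all(.data$strand %in% c("+", "-"))) .data$strand[1L] else "+",
      gene_id = if (all(is.na(.data$gene_id))) .data$tx[1L] else .data$gene_id[1L],
      exon_starts = list(merge_blocks(.data$start0, .data$end0)$start),
      exon_ends = list(merge_blocks(.data$start0, .data$end0)$end),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      tx_start = purrr::map_int(.data$exon_starts, ~ as.integer(min(.x))),
      tx_end = purrr::map_int(.data$exon_ends, ~ as.integer(max(.x))),
      name = .data$tx
    ) %>%
    dplyr::select("chrom", "tx_start", "tx_end", "name", "strand", "gene_id",
                  "exon_starts", "exon_ends") %>%
    dplyr::arrange(.data$chrom, .data$tx_start, .data$name)
}

# Merge overlapping/adjacent blocks; returns sorted half-open intervals.
merge_blocks <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  list(start = as.integer(IRanges::start(ir) - 1L), end = as.integer(IRanges::end(ir)))
}

#' Introns of a gene-model tibble
#'
#' @param genes Gene-model tibble.
#' @return Tibble with one row per intron: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `name`, `gene_id`.
#' @export
gene_introns <- function(genes) {
  if (nrow(genes) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character(), gene_id = character()))
  }
  genes %>%
    dplyr::mutate(.introns = purrr::map2(.data$exon_starts, .data$exon_ends, function(xs, xe) {
      if (length(xs) < 2L) {
        return(tibble(start = integer(), end = integer()))
      }
      tibble(start = xe[-length(xe)], end = xs[-1L])
    })) %>%
    dplyr::select("chrom", "strand", "name", "gene_id", ".introns") %>%
    tidyr::unnest(".introns") %>%
    dplyr::select("chrom", "start", "end", "strand", "name", "gene_id")
}

#' Write splice-score records to the 5-column TAB format
#'
#' One line per record: `chrom`, `offset`, `strand`, `site_type` (`D`/`A`),
#' integer `score`, TAB-separated, LF-terminated. The offset column is the
#' 0-based forward-strand coordinate of the base immediately 3' (rightward)
#' of the exon|intron boundary: a `+` donor points at the first intronic base
#' (the G of GT), a `+` acceptor at the first exonic base after AG; `-` sites
#' use the same rightward rule on forward coordinates.
#'
#' @param records Tibble with `chrom`, `offset`, `strand`, `site_type`,
#'   `score`; must be sorted by (`chrom`, `offset`).
#' @param path Output path; `.gz` supported.
#' @return `path`, invisibly.
#' @export
write_score_file <- function(records, path) {
  req <- c("chrom", "offset", "strand", "site_type", "score")
  if (!all(req %in% names(records))) {
    abort(paste0("score records need columns: ", paste(req, collapse = ", ")))
  }
  key <- paste(records$chrom, records$offset, records$strand, records$site_type)
  if (anyDuplicated(key)) {
    abort("duplicate (chrom, offset, strand, site_type) in score records")
  }
  if (is.unsorted(order(records$chrom, records$offset)) ||
      !identical(order(records$chrom, records$offset), seq_len(nrow(records)))) {
    abort("score records must be sorted by (chrom, offset)")
  }
  lines <- sprintf("%s\t%d\t%s\t%s\t%d", records$chrom,
                   as.integer(records$offset), records$strand,
                   records$site_type, as.integer(records$score))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a splice-score file
#'
#' @param path Path to a 5-column score file (plain or gzip).
#' @return A tibble with `chrom`, `offset`, `strand`, `site_type`, `score`,
#'   of class `splice_scores`. Use [score_lookup()] for keyed access.
#' @export
read_score_file <- function(path) {
  if (!file.exists(path)) abort(paste0("score file not found: ", path))
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "offset", "strand", "site_type", "score"),
    col_types = readr::cols(
      chrom = readr::col_character(), offset = readr::col_integer(),
      strand = readr::col_character(), site_type = readr::col_character(),
      score = readr::col_integer()
    ),
    progress = FALSE
  )
  key <- paste(df$chrom, df$offset, df$strand, df$site_type)
  if (anyDuplicated(key)) {
    abort("duplicate (chrom, offset, strand, site_type) in score file")
  }
  class(df) <- c("splice_scores", class(df))
  df
}

#' Look up splice scores by site key
#'
#' @param scores A `splice_scores` tibble.
#' @param chrom,offset,strand,site_type Vectors (recycled) identifying sites.
#' @param default Value returned for sites absent from the file.
#' @return Numeric vector of scores.
#' @export
score_lookup <- function(scores, chrom, offset, strand, site_type, default = NA_real_) {
  key <- paste(scores$chrom, scores$offset, scores$strand, scores$site_type)
  qry <- paste(chrom, offset, strand, site_type)
  out <- scores$score[match(qry, key)]
  out[is.na(out)] <- default
  as.numeric(out)
}
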