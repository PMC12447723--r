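test_that("FASTA records are normalized, ordered, and gzip-transparent", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "acgtn", ">c2", "GGxGG"), fa)
  g <- read_fasta(fa)
  expect_equal(g$name, c("c1", "c2"))
  expect_equal(g$seq, c("ACGTN", "GGNGG"))  # case + unknown-char normalization
  expect_equal(g$index_in_file, 1:2)

  gz <- withr::local_tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "w")
  writeLines(c(">c1 some description", "acgtn", ">c2", "GGxGG"), con)
  close(con)
  expect_equal(read_fasta(gz), g)
})

test_that("malformed FASTA input fails with a line number", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT"), fa)
  expect_error(read_fasta(fa), "line 1")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty")
  writeLines(c(">ok", "ACGT", ">nobody"), fa)
  expect_error(read_fasta(fa), "line 3")
  expect_error(read_fasta(file.path(tempdir(), "no-such.fa")), "not found")
})

test_that("BED12 blocks decode to half-open exons and introns", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("c1", 10, 100, "tx1", 0, "+", 10, 100, 0, 2, "20,30", "0,60"),
                   collapse = "\t"), bed)
  g <- read_bed12(bed)
  expect_equal(g$exon_starts[[1]], c(10L, 70L))
  expect_equal(g$exon_ends[[1]], c(30L, 100L))
  introns <- gene_introns(g)
  expect_equal(nrow(introns), 1L)
  expect_equal(c(introns$start, introns$end), c(30L, 70L))

  # single block: no introns; minus strand: same coordinates
  writeLines(c(
    paste(c("c1", 5, 50, "tx2", 0, "+", 5, 50, 0, 1, "45", "0"), collapse = "\t"),
    paste(c("c1", 10, 100, "tx3", 0, "-", 10, 100, 0, 2, "20,30", "0,60"),
          collapse = "\t")), bed)
  g2 <- read_bed12(bed)
  expect_equal(nrow(gene_introns(g2[1, ])), 0L)
  expect_equal(g2$exon_starts[[2]], c(10L, 70L))
  expect_equal(g2$strand[2], "-")
})

test_that("BED12 parse errors carry the offending line number", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste(c("c1", 10, 100, "ok", 0, "+", 10, 100, 0, 1, "90", "0"), collapse = "\t"),
    paste(c("c1", 10, 100, "bad", 0, "+", 10, 100, 0, 2, "20", "0"), collapse = "\t")),
    bed)
  expect_error(read_bed12(bed), "line 2")
  writeLines(paste(c("c1", 10, 100, "bad", 0, "+", 10, 100, 0, 2, "30,30", "0,20"),
                   collapse = "\t"), bed)
  expect_error(read_bed12(bed), "overlapping")
  writeLines(paste(c("c1", 10, 100, "bad", 0, "+", 10, 100, 0, 2, "20,40", "0,60"),
                   collapse = "\t"), bed)
  expect_error(read_bed12(bed), "outside")
})

test_that("BED12 write/read round-trips and re-writes byte-identically", {
  sim <- fx_small_sim()
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed12(sim$genes, bed)
  back <- read_bed12(bed)
  expect_equal(back$chrom, sim$genes$chrom)
  expect_equal(back$exon_starts, sim$genes$exon_starts)
  expect_equal(back$exon_ends, sim$genes$exon_ends)
  expect_equal(back$strand, sim$genes$strand)
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_bed12(back, bed2)
  expect_identical(readLines(bed), readLines(bed2))
})

test_that("GTF and GFF3 encodings convert to identical gene models", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste(c("c1", "src", "exon", 11, 30, ".", "+", ".",
            'gene_id "g1"; transcript_id "tx1";'), collapse = "\t"),
    paste(c("c1", "src", "exon", 71, 100, ".", "+", ".",
            'gene_id "g1"; transcript_id "tx1";'), collapse = "\t")), gtf)
  g_gtf <- gxf_to_bed12(gtf, "GTF")
  expect_equal(g_gtf$exon_starts[[1]], c(10L, 70L))  # 1-based -> 0-based
  expect_equal(g_gtf$exon_ends[[1]], c(30L, 100L))
  expect_equal(g_gtf$gene_id, "g1")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste(c("c1", "src", "mRNA", 11, 100, ".", "+", ".", "ID=tx1"), collapse = "\t"),
    paste(c("c1", "src", "exon", 11, 30, ".", "+", ".", "Parent=tx1"), collapse = "\t"),
    paste(c("c1", "src", "exon", 71, 100, ".", "+", ".", "Parent=tx1"), collapse = "\t")),
    gff)
  g_gff <- gxf_to_bed12(gff, "GFF3")
  expect_equal(g_gff$exon_starts, g_gtf$exon_starts)
  expect_equal(g_gff$exon_ends, g_gtf$exon_ends)
  expect_equal(g_gff$tx_start, g_gtf$tx_start)
  expect_equal(g_gff$name, g_gtf$name)

  # single-exon transcript -> one block
  writeLines(paste(c("c1", "src", "exon", 5, 25, ".", "-", ".",
                     'gene_id "g2"; transcript_id "tx9";'), collapse = "\t"), gtf)
  g1 <- gxf_to_bed12(gtf, "GTF")
  expect_equal(length(g1$exon_starts[[1]]), 1L)
  expect_equal(g1$strand, "-")
})

test_that("score file format matches the 5-column TAB listing exactly", {
  rec <- tibble::tibble(
    chrom = "chr2",
    offset = c(4184146L, 4184167L, 4184191L, 4184199L, 4184213L),
    strand = c("+", "+", "-", "+", "+"),
    site_type = c("A", "A", "D", "A", "D"),
    score = c(9L, -5L, 5L, -5L, 3L)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_file(rec, f)
  lines <- readLines(f)
  expect_identical(lines[1], "chr2\t4184146\t+\tA\t9")
  expect_identical(lines[3], "chr2\t4184191\t-\tD\t5")
  back <- read_score_file(f)
  expect_equal(tibble::as_tibble(back), rec)  # read o write == identity
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_score_file(back, f2)
  expect_identical(readLines(f), readLines(f2))

  expect_equal(score_lookup(back, "chr2", 4184191L, "-", "D"), 5)
  expect_true(is.na(score_lookup(back, "chr2", 1L, "+", "D")))
  expect_equal(score_lookup(back, "chr2", 1L, "+", "D", default = -30), -30)
})

test_that("score files support gzip and reject duplicates and unsorted input", {
  rec <- tibble::tibble(chrom = "c1", offset = c(5L, 5L), strand = "+",
                        site_type = "D", score = 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_score_file(rec, f), "duplicate")
  rec2 <- tibble::tibble(chrom = "c1", offset = c(9L, 5L), strand = "+",
                         site_type = "D", score = 1L)
  expect_error(write_score_file(rec2, f), "sorted")

  rec3 <- dplyr::arrange(rec2, offset)
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_score_file(rec3, gz)
  expect_equal(read_score_file(gz)$offset, c(5L, 9L))

  empty <- rec3[0, ]
  write_score_file(empty, f)
  expect_equal(nrow(read_score_file(f)), 0L)
})
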