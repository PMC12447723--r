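test_that("identical sequences align as all-match with the match score", {
  p <- align_params()
  a <- align_spliced("ACGTACGTAC", "ACGTACGTAC", p)
  expect_equal(a$score, 10 * p$match)
  expect_equal(a$cigar, "10M")
  expect_equal(nrow(a$junctions), 0L)
  expect_equal(a$identity, 1)
})

test_that("with unscored boundaries made prohibitive, the DP equals plain affine-gap alignment", {
  # Biostrings::pairwiseAlignment as the independent affine-gap oracle
  p <- align_params(noncanonical_cost = 1e7)
  mat <- matrix(p$mismatch, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                  c("A", "C", "G", "T")))
  diag(mat) <- p$match
  set.seed(41)
  for (i in 1:25) {
    r <- random_dna(sample(10:40, 1))
    q <- random_dna(sample(8:35, 1))
    mine <- align_spliced(r, q, p)$score
    # Biostrings charges gapOpening + gapExtension per gapped position
    ref <- Biostrings::pairwiseAlignment(
      pattern = q, subject = r, type = "global",
      substitutionMatrix = mat, gapOpening = p$gap_open,
      gapExtension = p$gap_ext, scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("a favorably scored planted intron is recovered exactly", {
  set.seed(43)
  p <- align_params()
  exon1 <- random_dna(30); exon2 <- random_dna(30)
  intron <- paste0("GT", random_dna(16), "AG")  # length 20
  ref <- paste0(exon1, intron, exon2)
  query <- paste0(exon1, exon2)
  costs <- list(dcost = rep(p$noncanonical_cost, nchar(ref) + 1),
                acost = rep(p$noncanonical_cost, nchar(ref) + 1))
  costs$dcost[30 + 1] <- -10  # donor at offset 30 (first intron base)
  costs$acost[50 + 1] <- -10  # acceptor at offset 50 (one past intron end)
  a <- align_spliced(ref, query, p, costs)
  expect_equal(nrow(a$junctions), 1L)
  expect_equal(c(a$junctions$start, a$junctions$end), c(30L, 50L))
  expect_equal(a$cigar, "30M20N30M")
  expect_equal(a$score, 60 * p$match - (p$intron_open - 10 - 10))
})

test_that("align matches the exhaustive run-enumeration oracle on random tiny instances", {
  set.seed(47)
  p <- align_params(intron_open = 3, noncanonical_cost = 4)
  n_checked <- 0L
  for (i in 1:220) {
    nr <- sample(4:12, 1); nq <- sample(1:8, 1)
    r <- random_dna(nr); q <- random_dna(nq)
    costs <- list(dcost = sample(-6:6, nr + 1, replace = TRUE),
                  acost = sample(-6:6, nr + 1, replace = TRUE))
    expect_equal(align_spliced(r, q, p, costs)$score,
                 oracle_align(r, q, p, costs),
                 info = paste("instance", i, r, q))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 200L)
  expect_error(oracle_align(random_dna(20), "ACG", p), "<= 12")
})

test_that("oracle hand-checks: single bases and the minimum intron length", {
  p <- align_params(match = 2, mismatch = -4, gap_open = 4, gap_ext = 2,
                    intron_open = 1, noncanonical_cost = 0, min_intron = 4)
  expect_equal(oracle_align("A", "A", p), 2)
  # mismatch (-4) beats two gap runs (-(4+2) - (4+2) = -12)
  expect_equal(oracle_align("A", "C", p), -4)
  # ref ACGT vs query A: the best path bridges all four ref bases with one
  # minimum-length intron (cost 1) and emits the query base as an insertion
  # (4 + 2*1); matching A first leaves only 3 ref bases, too short to splice
  expect_equal(oracle_align("ACGT", "A", p), -(1 + 0 + 0) - (4 + 2 * 1))
  # with a 5-base tail the free-ish intron (cost 1) can bridge 4 of them
  expect_equal(oracle_align("ACGTT", "A", p), 2 - min(1 + 0 + 0, 4 + 2 * 4))
})

test_that("raising a junction's splice score never lowers the alignment score", {
  set.seed(53)
  p <- align_params()
  exon1 <- random_dna(20); exon2 <- random_dna(20)
  ref <- paste0(exon1, "GT", random_dna(10), "AG", exon2)
  query <- paste0(exon1, exon2)
  base <- list(dcost = rep(p$noncanonical_cost, nchar(ref) + 1),
               acost = rep(p$noncanonical_cost, nchar(ref) + 1))
  prev <- align_spliced(ref, query, p, base)$score
  for (bonus in c(0, 2, 6, 12, 20)) {
    costs <- base
    costs$dcost[20 + 1] <- -bonus
    costs$acost[34 + 1] <- -bonus
    sc <- align_spliced(ref, query, p, costs)$score
    expect_gte(sc, prev)
    prev <- sc
  }
})

test_that("among residue-equivalent placements the better-scored junction wins", {
  # ref offers the same intron content at two placements: ...AAA GTxxAG AAA...
  # shifting the junction left/right keeps the residue alignment score equal
  p <- align_params(min_intron = 4, intron_open = 12)
  ref <- paste0("CCCCC", "GTTTAG", "GTTTAG", "CCCCC")  # two candidate introns
  query <- paste0("CCCCC", "GTTTAG", "CCCCC")          # one copy spliced out
  mk <- function(d1, d2) {
    costs <- list(dcost = rep(p$noncanonical_cost, nchar(ref) + 1),
                  acost = rep(p$noncanonical_cost, nchar(ref) + 1))
    costs$dcost[5 + 1] <- -d1;  costs$acost[11 + 1] <- -d1
    costs$dcost[11 + 1] <- -d2; costs$acost[17 + 1] <- -d2
    costs
  }
  # second placement scored +4 higher -> chosen
  j <- consensus_preference_demo(ref, query, p, mk(0, 4))
  expect_equal(c(j$start, j$end), c(11L, 17L))
  # first placement favored
  j2 <- consensus_preference_demo(ref, query, p, mk(4, 0))
  expect_equal(c(j2$start, j2$end), c(5L, 11L))
  # equal scores: leftmost intron start wins
  j3 <- consensus_preference_demo(ref, query, p, mk(3, 3))
  expect_equal(c(j3$start, j3$end), c(5L, 11L))
})

test_that("a GT..AG junction outscores a non-canonical placement at finite cost gaps", {
  p <- align_params(noncanonical_cost = 30)
  set.seed(59)
  exon1 <- random_dna(15); exon2 <- random_dna(15)
  ref <- paste0(exon1, "GT", random_dna(16), "AG", exon2)
  query <- paste0(exon1, exon2)
  costs <- gtag_costs(ref, p)  # canonical boundaries cost 0, others 30
  a <- align_spliced(ref, query, p, costs)
  expect_equal(nrow(a$junctions), 1L)
  expect_equal(c(a$junctions$start, a$junctions$end), c(15L, 35L))
})

test_that("maximum intron length caps the bridged span", {
  p <- align_params(noncanonical_cost = 0, intron_open = 1, max_intron = 10)
  ref <- paste0("AAAA", strrep("G", 30), "TTTT")
  query <- "AAAATTTT"
  a <- align_spliced(ref, query, p)
  # a single 30-base intron is forbidden; the span is bridged by several
  # introns each within the cap (adjacent N runs merge in the cigar)
  expect_gt(nrow(a$junctions), 1L)
  expect_true(all(a$junctions$end - a$junctions$start <= 10))
  expect_equal(sum(a$junctions$end - a$junctions$start), 30L)
})

test_that("tidy/glance expose junctions and summary of an alignment", {
  a <- align_spliced("ACGTACGT", "ACGTACGT", align_params())
  expect_equal(nrow(tidy(a)), 0L)
  g <- glance(a)
  expect_equal(g$cigar, "8M")
  expect_equal(g$identity, 1)
  expect_equal(g$n_junctions, 0L)
})
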