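test_that("glocal alignment handles identity and exact substrings", {
  a <- glocal_align("ACGT", "ACGT")
  expect_identical(a$score, 20L)
  expect_identical(a$query_aligned, "ACGT")
  expect_identical(a$target_aligned, "ACGT")

  b <- glocal_align("AC", "TTTTACTTTT")
  expect_identical(b$score, 10L)
  expect_identical(b$target_interval, c(5L, 6L))

  expect_error(glocal_align("", "ACGT"), "empty query")
})

test_that("glocal alignment equals the exhaustive enumerator on short pairs", {
  set.seed(42)
  sc <- scoring_scheme()
  for (rep in 1:150) {
    q <- random_seq(sample(1:8, 1))
    t <- random_seq(sample(1:8, 1))
    a <- glocal_align(q, t, sc)
    expect_identical(a$score, as.integer(glocal_align_bruteforce(q, t, sc)),
                     info = paste(q, t))
    ## de-gapping invariants and self-consistent score
    expect_identical(degap_chr(a$query_aligned), q)
    if (a$target_interval[1] > 0)
      expect_identical(degap_chr(a$target_aligned),
                       substr(t, a$target_interval[1], a$target_interval[2]))
    expect_identical(score_alignment(a$query_aligned, a$target_aligned, sc),
                     as.numeric(a$score))
  }
})

test_that("the score is invariant under joint reverse complement", {
  set.seed(7)
  for (rep in 1:25) {
    q <- random_seq(sample(3:12, 1))
    t <- random_seq(sample(5:30, 1))
    expect_identical(glocal_align(q, t)$score,
                     glocal_align(revcomp(q), revcomp(t))$score)
  }
})

test_that("the score-scan plus windowed traceback equals the direct alignment", {
  set.seed(13)
  sc <- scoring_scheme()
  for (rep in 1:20) {
    q <- random_seq(40)
    t <- paste0(random_seq(200), q, random_seq(200))
    full <- glocal_align(q, t, sc)
    scan <- glocal_score(q, t, sc)
    expect_identical(scan$score, full$score)
  }
})

test_that("orthologue search finds verbatim and reverse-complemented copies", {
  set.seed(5)
  insert <- random_seq(60)
  genomes <- list(
    sp_fwd = c(chr1 = paste0(random_seq(100), insert, random_seq(100))),
    sp_rev = c(chr1 = paste0(random_seq(80), revcomp(insert), random_seq(80))))
  locus <- list(sequence = insert)
  os <- find_orthologue(locus, genomes)
  expect_identical(os$hits$sp_fwd$sequence, insert)
  expect_identical(os$hits$sp_fwd$strand, "+")
  expect_identical(os$hits$sp_fwd$start, 101L)
  expect_identical(os$hits$sp_fwd$end, 160L)
  ## minus-strand hit comes back in query orientation, forward coordinates
  expect_identical(os$hits$sp_rev$sequence, insert)
  expect_identical(os$hits$sp_rev$strand, "-")
  expect_identical(os$hits$sp_rev$start, 81L)
  expect_identical(os$hits$sp_rev$end, 140L)
})

test_that("equal-scoring hits resolve to the first chromosome and a score floor drops weak hits", {
  set.seed(9)
  q <- random_seq(30)
  genomes <- list(sp = c(chrB = paste0(random_seq(50), q, random_seq(50)),
                         chrA = paste0(random_seq(20), q, random_seq(20))))
  os <- find_orthologue(list(sequence = q), genomes)
  expect_identical(os$hits$sp$chrom, "chrA") # smallest chromosome name wins
  ## unrelated target falls below the default floor
  os2 <- find_orthologue(list(sequence = q),
                         list(sp = c(chr1 = paste(rep("A", 200), collapse = ""))))
  expect_null(os2$hits$sp)
  os3 <- find_orthologue(list(sequence = q),
                         list(sp = c(chr1 = paste(rep("A", 200), collapse = ""))),
                         score_floor = -Inf)
  expect_false(is.null(os3$hits$sp))
})
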