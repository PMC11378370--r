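test_that("inducing a pair removes only the columns gapped in both rows", {
  aln <- c(A1 = "AC-GT-", cerevisiae = "ACTG--")
  p <- induce_pair(aln, "A1", "cerevisiae")
  expect_identical(p$a, "AC-GT")
  expect_identical(p$b, "ACTG-")
  expect_identical(p$cols, c(1L, 2L, 3L, 4L, 5L))
  gapless <- induce_pair(c(x = "ACGT", y = "ACGT"), "x", "y")
  expect_identical(gapless$a, "ACGT")
  expect_error(induce_pair(aln, "A1", "nope"), "missing row")
})

test_that("mutation classification matches the worked example and identities", {
  p <- induce_pair(c(a = "ACGTACGT", b = "GCGTACGA"), "a", "b")
  m <- classify_mutations(p)
  expect_identical(unname(m$counts[c("transition", "transversion",
                                     "AT>GC", "AT>AT", "GC>AT", "GC>GC")]),
                   c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(m$freqs["transition"]), 12.5)
  expect_equal(unname(m$freqs["transversion"]), 12.5)

  same <- classify_mutations(induce_pair(c(a = "ACGT", b = "ACGT"), "a", "b"))
  expect_true(all(same$counts == 0))

  gap2 <- classify_mutations(induce_pair(c(a = "ACGTAA", b = "AC--AA"), "a", "b"))
  expect_identical(unname(gap2$counts["indel"]), 1L) # one 2-nt run, one event
  expect_identical(unname(gap2$denominators["indel"]), 6L)
})

test_that("mutation counts agree with a per-column oracle on random pairs", {
  set.seed(55)
  for (rep in 1:60) {
    p <- random_induced_pair(sample(5:50, 1))
    m <- classify_mutations(p)
    expect_identical(unname(m$counts), unname(as.integer(mutation_counts_oracle(p$a, p$b))),
                     info = paste(p$a, p$b))
    ## class identity: ts + tv = the four pressure classes
    expect_identical(m$counts[["transition"]] + m$counts[["transversion"]],
                     sum(m$counts[c("AT>GC", "GC>AT", "AT>AT", "GC>GC")]))
  }
})

test_that("no-indel truth tallies equal observed mutation counts exactly", {
  cfg <- sim_config(tree_spec = yeast_tree(FALSE),
                    n_loci_per_class = c(intergene = 20),
                    locus_length = 200, indel_rate = 0, seed = 77)
  sim <- simulate_catalogue(cfg)
  for (tr in sim$truth) {
    p <- induce_pair(c(a = tr$nodes$A1, b = tr$nodes$cerevisiae), "a", "b")
    m <- classify_mutations(p)
    tt <- truth_event_tally(tr, "A1->cerevisiae")
    expect_identical(unname(m$counts), unname(tt), info = tr$id)
  }
})

test_that("GC content follows the genic/non-genic definitions", {
  expect_equal(gc_content("ATGGCGTAA", "genic"), 2 / 3)
  expect_equal(gc_content("ATGGCGTAA", "nongenic"), 4 / 9)
  expect_error(gc_content("", "nongenic"), "empty")
  expect_error(gc_content("ATGG", "genic"), "divisible")
  ## reverse-complement invariance of whole-region GC
  set.seed(3)
  for (rep in 1:20) {
    s <- random_seq(sample(10:60, 1))
    expect_equal(gc_content(s, "nongenic"), gc_content(revcomp(s), "nongenic"))
  }
  ## Ns are excluded from numerator and denominator
  expect_equal(gc_content("GNNA", "nongenic"), 0.5)
})

test_that("ORF scanning finds stop-bounded segments with rule-dependent starts", {
  o <- scan_orfs("ATGGCGTAA")
  expect_identical(nrow(o), 1L)
  expect_identical(o$frame, 0L)
  expect_identical(o$length, 9L)
  expect_true(o$has_stop)

  expect_identical(nrow(scan_orfs("CCCCCCCCC")), 0L) # no ATG, no ORF

  ## Kozak rule rejects an ATG with T at -3, accepts the one with A at -3
  s <- "TTTATGAAAATGGCTTAA"
  o2 <- scan_orfs(s, rule = "A..ATG")
  expect_identical(o2$start[1], 10L)

  expect_identical(locate_start("AAAATGGC", 1, 8, "A..ATG"), 4L)
  expect_identical(locate_start("AAAATGGC", 1, 8, "A..ATG.C"), 4L)
  expect_identical(locate_start("CCCCCC", 1, 6, "ATG"), NA_integer_)
  ## context beyond the segment: -3 base can sit in the flank
  expect_identical(locate_start("AAAATGTAA", 4, 9, "A..ATG"), 4L)
})

test_that("an A..ATG.C match is always also an A..ATG match at the same ATG", {
  set.seed(91)
  for (rep in 1:40) {
    s <- random_seq(60)
    strong <- locate_start(s, 1, 60, "A..ATG.C")
    if (!is.na(strong)) {
      weak_ok <- !is.na(locate_start(s, 1, 60, "A..ATG"))
      expect_true(weak_ok)
      ## and the strong pattern's ATG matches the weak pattern at that position
      expect_identical(substr(s, strong - 3, strong - 3), "A")
    }
  }
})

test_that("ancestral ORFs map by frame-consistent maximal overlap", {
  ## recent: single ORF; ancestor: the same ORF plus an unrelated downstream one
  anc <- "TTATGGCGGCGTAATTTATGAAAGCGCCCTAA"
  rec <- "TTATGGCGGCGGCGTAATTT"
  m <- build_msa(c(cerevisiae = rec, paradoxus = anc), yeast_tree(FALSE))
  pair <- induce_pair(m, "paradoxus", "cerevisiae")
  ro <- scan_orfs(rec)[1, ]
  mapped <- map_ancestral_orf(ro, pair)
  expect_identical(mapped$start, 3L)   # the overlapping upstream ORF, not the distal one
  expect_identical(mapped$length, 12L) # positions 3..14 including the stop

  ## no overlap -> none
  pair2 <- structure(list(a = paste0(strrep("-", 20), "ATGAAATAA"),
                          b = paste0("ATGCCCTAA", strrep("-", 9)),
                          cols = 1:29), class = "induced_pair")
  ro2 <- scan_orfs("ATGCCCTAA")[1, ]
  expect_null(map_ancestral_orf(ro2, pair2))
})

test_that("length changes and Kozak transitions use the documented categories", {
  a90 <- data.frame(length = 90); r120 <- data.frame(length = 120)
  expect_identical(classify_length_change(a90, r120), "Extend")
  expect_identical(classify_length_change(r120, a90), "Shrink")
  expect_identical(classify_length_change(a90, data.frame(length = 90)), "NoChange")
  expect_true(is.na(classify_length_change(NULL, r120)))

  expect_identical(classify_kozak_transition(FALSE, FALSE), "No")
  expect_identical(classify_kozak_transition(TRUE, TRUE), "Retain")
  expect_identical(classify_kozak_transition(TRUE, FALSE), "Disappear")
  expect_identical(classify_kozak_transition(FALSE, TRUE), "Appear")
})
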