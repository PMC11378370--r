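three_taxon_tree <- function(bl) {
  ape::read.tree(text = sprintf(
    "((cerevisiae:%g,paradoxus:%g)A1:%g,mikatae:%g)A2;", bl, bl, bl, bl))
}

test_that("HKY transition probabilities match matrix exponentiation", {
  skip_if_not_installed("Matrix")
  set.seed(2)
  for (rep in 1:20) {
    kappa <- runif(1, 0.5, 5)
    pi <- as.numeric(stats::runif(4, 0.1, 1)); pi <- pi / sum(pi)
    Q <- genebirth:::hky_rate_matrix(kappa, pi)
    t <- runif(1, 0, 2)
    P1 <- genebirth:::hky_prob_matrix(Q, t)
    P2 <- as.matrix(Matrix::expm(Q * t))
    expect_lt(max(abs(P1 - P2)), 1e-9)
    expect_lt(max(abs(rowSums(P1) - 1)), 1e-9)
    ## stationarity: pi Q = 0 and mean rate 1
    expect_lt(max(abs(pi %*% Q)), 1e-12)
    expect_lt(abs(-sum(pi * diag(Q)) - 1), 1e-12)
  }
})

test_that("vanishing branches give certain ancestors; symmetric tips tie A and G", {
  m <- structure(c(cerevisiae = "AAAA", paradoxus = "AAAA", mikatae = "AAAA"),
                 class = "msa")
  anc <- reconstruct_ancestors(m, three_taxon_tree(1e-9),
                               sub_model(kappa = 1, base_freqs = rep(0.25, 4)))
  expect_true(all(anc$A1$posteriors[, "A"] > 0.999))
  expect_gt(anc$A1$confidence, 0.999)

  ## two informative tips disagreeing A vs G: the ancestor is torn between
  ## them, and under kappa = 1 with uniform frequencies C and T are below
  m2 <- structure(c(cerevisiae = "A", paradoxus = "G", mikatae = "-"),
                  class = "msa")
  anc2 <- reconstruct_ancestors(m2, three_taxon_tree(0.2),
                                sub_model(kappa = 1, base_freqs = rep(0.25, 4)))
  p <- anc2$A1$posteriors[1, ]
  expect_equal(unname(p["A"]), unname(p["G"]), tolerance = 1e-12)
  expect_equal(unname(p["C"]), unname(p["T"]), tolerance = 1e-12)
  expect_gt(p[["A"]], p[["C"]])
})

test_that("pruning posteriors equal explicit summation over internal states", {
  skip_if_not_installed("Matrix")
  set.seed(17)
  for (rep in 1:25) {
    ncol <- sample(1:5, 1)
    bl <- runif(4, 0.01, 0.6)
    tree <- ape::read.tree(text = sprintf(
      "((cerevisiae:%g,paradoxus:%g)A1:%g,mikatae:%g)A2;",
      bl[1], bl[2], bl[3], bl[4]))
    pi <- as.numeric(runif(4, 0.1, 1)); pi <- pi / sum(pi)
    model <- sub_model(kappa = runif(1, 0.5, 4), base_freqs = pi)
    msa <- structure(
      c(cerevisiae = random_seq(ncol), paradoxus = random_seq(ncol),
        mikatae = random_seq(ncol)), class = "msa")
    anc <- reconstruct_ancestors(msa, tree, model)
    ref <- ancestral_posteriors_bruteforce(msa, tree, model)
    for (node in c("A1", "A2"))
      expect_lt(max(abs(anc[[node]]$posteriors - ref[[node]])), 1e-8)
  }
})

test_that("longer branches lower the certainty on a discordant pattern", {
  model <- sub_model(kappa = 2, base_freqs = rep(0.25, 4))
  msa <- structure(c(cerevisiae = "A", paradoxus = "G", mikatae = "C"),
                   class = "msa")
  confs <- vapply(c(0.05, 0.1, 0.3, 0.6, 1.2), function(bl) {
    reconstruct_ancestors(msa, three_taxon_tree(bl), model)$A1$confidence
  }, 1)
  expect_true(all(diff(confs) < 0))
})

test_that("the confidence filter averages max posteriors and defaults to 0.80", {
  anc <- structure(list(node = "A1", sequence = "ACGT",
                        posteriors = matrix(0.25, 4, 4),
                        confidence = mean(c(0.9, 0.7, 0.8, 0.6))),
                   class = "ancestral_sequence")
  expect_identical(anc$confidence, 0.75)
  expect_false(confidence_filter(anc))        # 0.75 < 0.80 default
  expect_true(confidence_filter(anc, 0.75))
  expect_identical(formals(confidence_filter)$threshold, 0.80)
})

test_that("gap states follow parsimony with ties resolved toward bases", {
  ## cer/par gapped, mik base: A1 is gap, A2 is tied -> base
  msa <- structure(c(cerevisiae = "-A", paradoxus = "-A", mikatae = "AA"),
                   class = "msa")
  anc <- reconstruct_ancestors(msa, three_taxon_tree(0.1),
                               sub_model(base_freqs = rep(0.25, 4)))
  expect_identical(substr(anc$A1$sequence, 1, 1), "-")
  expect_identical(substr(anc$A2$sequence, 1, 1), "A")
  ## posterior rows are normalised wherever present
  for (node in c("A1", "A2")) {
    p <- anc[[node]]$posteriors
    ok <- !is.na(p[, 1])
    if (any(ok)) expect_lt(max(abs(rowSums(p[ok, , drop = FALSE]) - 1)), 1e-9)
    expect_gte(anc[[node]]$confidence, 0.25)
    expect_lte(anc[[node]]$confidence, 1)
  }
})

test_that("birth edges are assigned by parsimony and stop at A2", {
  expect_identical(assign_birth_edge("S0+"), list(parent = "A1", child = "cerevisiae"))
  expect_identical(assign_birth_edge("S1"), list(parent = "A1", child = "cerevisiae"))
  expect_identical(assign_birth_edge("S2"), list(parent = "A2", child = "A1"))
  expect_error(assign_birth_edge("S3"), "unsupported")
  expect_error(assign_birth_edge("intergene"), "unsupported")
})

test_that("missing non-bayanus leaves are rejected, bayanus is optional", {
  msa <- structure(c(cerevisiae = "ACGT", paradoxus = "ACGT", mikatae = "ACGT"),
                   class = "msa")
  anc <- reconstruct_ancestors(msa, yeast_tree(bayanus = TRUE))
  expect_named(anc, c("A1", "A2"))
  expect_error(reconstruct_ancestors(
    structure(c(cerevisiae = "ACGT", mikatae = "ACGT"), class = "msa"),
    yeast_tree()), "paradoxus")
})

test_that("short-branch simulations are recovered almost exactly", {
  set.seed(4)
  cfg <- sim_config(tree_spec = yeast_tree(FALSE),
                    n_loci_per_class = c(intergene = 30),
                    locus_length = 200, indel_rate = 0, seed = 31)
  sim <- simulate_catalogue(cfg)
  ti <- tree_info(sim$tree)
  ident <- numeric(0); confs <- numeric(0)
  for (i in seq_len(nrow(sim$catalogue))) {
    entry <- sim$catalogue[i, ]
    locus <- extract_locus(sim$genomes$cerevisiae, entry, 0)
    ortho <- find_orthologue(locus, sim$genomes[c("paradoxus", "mikatae")])
    if (any(vapply(ortho$hits, is.null, TRUE))) next
    msa <- build_msa(c(list(cerevisiae = locus$sequence),
                       lapply(ortho$hits, `[[`, "sequence")), sim$tree)
    anc <- reconstruct_ancestors(msa, sim$tree)
    rec <- degap_chr(anc$A1$sequence)
    tr <- sim$truth[[entry$id]]$nodes$A1
    L <- min(nchar(rec), nchar(tr))
    ident <- c(ident, mean(strsplit(substr(rec, 1, L), "")[[1]] ==
                           strsplit(substr(tr, 1, L), "")[[1]]))
    confs <- c(confs, anc$A1$confidence)
  }
  expect_gte(mean(ident), 0.95)
  expect_gte(mean(confs), 0.9)
})
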