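test_that("root sequences have the requested composition", {
  expect_identical(simulate_root(0, 0.5), "")
  set.seed(1)
  s <- simulate_root(100, 1.0)
  expect_true(all(strsplit(s, "")[[1]] %in% c("G", "C")))
  set.seed(1)
  s <- simulate_root(10000, 0.40)
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.40), 0.015) # 3 binomial SD
  expect_error(simulate_root(-1, 0.5), "non-negative")
})

test_that("branch evolution has the expected event load and stationarity", {
  s <- "ACGTACGT"
  r <- evolve_branch(s, 0)
  expect_identical(r$seq, s)
  expect_identical(nrow(r$events), 0L)
  expect_error(evolve_branch(s, -0.1), "non-negative")

  set.seed(7)
  root <- simulate_root(10000, 0.4)
  r <- evolve_branch(root, 0.05, evo_model(kappa = 2, indel_rate = 0))
  expect_lt(abs(nrow(r$events) - 500), 3 * sqrt(500)) # Poisson mean t*L

  set.seed(3)
  r2 <- evolve_branch(simulate_root(10000, 0.1), 50,
                      evo_model(gc_equilibrium = 0.6, indel_rate = 0))
  gc <- mean(strsplit(r2$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.60), 0.02) # saturation at the stationary composition
})

test_that("under a Jukes-Cantor regime transversions are twice transitions", {
  set.seed(11)
  root <- simulate_root(120000, 0.5)
  r <- evolve_branch(root, 0.15, evo_model(kappa = 1, gc_equilibrium = 0.5,
                                           indel_rate = 0))
  ev <- r$events
  ts <- sum((ev$old %in% c("A", "G") & ev$new %in% c("A", "G")) |
            (ev$old %in% c("C", "T") & ev$new %in% c("C", "T")))
  tv <- nrow(ev) - ts
  expect_lte(abs(ts - tv / 2), 4 * sqrt(nrow(ev)))
})

test_that("event logs replay exactly and catalogues match the configuration", {
  cfg <- sim_config(tree_spec = yeast_tree(FALSE),
                    n_loci_per_class = c(`S0+` = 3, S1 = 3, S2 = 3, intergene = 5),
                    locus_length = 150, seed = 99)
  sim <- simulate_catalogue(cfg)
  expect_identical(as.vector(table(sim$catalogue$class)[c("S0+", "S1", "S2", "intergene")]),
                   c(3L, 3L, 3L, 5L))
  for (tr in sim$truth) {
    for (e in names(tr$events)) {
      pa <- sub("->.*", "", e); ch <- sub(".*->", "", e)
      expect_identical(apply_events(tr$nodes[[pa]], tr$events[[e]]),
                       tr$nodes[[ch]])
    }
  }
  ## catalogue coordinates index the focal genome correctly
  g <- sim$genomes$cerevisiae[["chr1"]]
  for (i in seq_len(nrow(sim$catalogue))) {
    ent <- sim$catalogue[i, ]
    got <- substr(g, ent$start, ent$end)
    want <- sim$truth[[ent$id]]$nodes$cerevisiae
    if (ent$strand == "-") want <- revcomp(want)
    expect_identical(got, want)
  }
})

test_that("the same seed reproduces the simulation byte for byte", {
  cfg <- sim_config(tree_spec = yeast_tree(FALSE),
                    n_loci_per_class = c(S1 = 3, intergene = 3),
                    locus_length = 120, seed = 5)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_catalogue(cfg, out_dir = d1)
  simulate_catalogue(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("zero loci give empty genomes, catalogue and truth log", {
  cfg <- sim_config(tree_spec = yeast_tree(FALSE),
                    n_loci_per_class = c(S1 = 0, intergene = 0), seed = 2)
  sim <- simulate_catalogue(cfg)
  expect_identical(nrow(sim$catalogue), 0L)
  expect_length(sim$truth, 0)
  expect_true(all(vapply(sim$genomes, function(g) nchar(g[["chr1"]]), 1) == 0))
})

test_that("stop removal lengthens the most upstream ORF in the focal species", {
  cfg <- sim_config(tree_spec = yeast_tree(FALSE),
                    n_loci_per_class = c(S1 = 50),
                    locus_length = 300, indel_rate = 0, seed = 8)
  sim <- simulate_catalogue(cfg)
  longer <- vapply(sim$truth, function(tr) {
    len <- function(s) {
      o <- scan_orfs(s, rule = "ATG")
      if (nrow(o) == 0) return(NA_integer_)
      o$length[1]
    }
    lc <- len(tr$nodes$cerevisiae); la <- len(tr$nodes$A1)
    if (is.na(lc) || is.na(la)) NA else lc > la
  }, TRUE)
  expect_gte(mean(longer, na.rm = TRUE), 0.8)
})
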