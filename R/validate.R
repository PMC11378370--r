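## Reference implementations used to validate the fast paths. They share no
## code with the implementations they check: alignment scores come from
## exhaustive enumeration of monotone matchings, ancestral posteriors from
## explicit summation over internal-state assignments, and distribution
## tails from exact rational / arbitrary-precision arithmetic.

#' Exhaustive reference for pairwise affine-gap alignment scores
#'
#' Enumerates every monotone matching between query and target positions
#' and scores it directly (matched pairs by match/mismatch, each maximal
#' one-sided gap run by `gap_open + len * gap_extend`), returning the
#' maximum. With `global_target = FALSE` the target's end gaps are free
#' (glocal mode); with `TRUE` they are costed (global mode). Feasible for
#' sequences up to ~10 nt; intended as an independent test oracle.
#'
#' @param query,target DNA strings (short).
#' @param scoring a [scoring_scheme()].
#' @param global_target cost the target's end gaps.
#' @return the optimal score (numeric).
#' @export
glocal_align_bruteforce <- function(query, target, scoring = scoring_scheme(),
                                    global_target = FALSE) {
  q <- chars(query); t <- chars(target)
  m <- length(q); n <- length(t)
  if (m == 0) stop("empty query")
  if (m > 10 || n > 10) stop("brute-force oracle is for sequences <= 10 nt")
  gap <- function(len) if (len > 0) scoring$gap_open + len * scoring$gap_extend else 0
  best <- -Inf
  for (k in 0:min(m, n)) {
    if (k == 0) {
      sc <- gap(m) + if (global_target) gap(n) else 0
      best <- max(best, sc)
      next
    }
    qsets <- utils::combn(m, k)
    tsets <- utils::combn(n, k)
    for (iq in seq_len(ncol(qsets))) {
      qi <- qsets[, iq]
      base_q <- gap(qi[1] - 1) + gap(m - qi[k])
      if (k > 1) base_q <- base_q + sum(vapply(diff(qi) - 1, gap, 1))
      for (it in seq_len(ncol(tsets))) {
        tj <- tsets[, it]
        sc <- sum(ifelse(q[qi] == t[tj], scoring$match, scoring$mismatch)) + base_q
        if (k > 1) sc <- sc + sum(vapply(diff(tj) - 1, gap, 1))
        if (global_target) sc <- sc + gap(tj[1] - 1) + gap(n - tj[k])
        if (sc > best) best <- sc
      }
    }
  }
  best
}

#' Reference marginal ancestral posteriors by explicit summation
#'
#' Computes per-column posteriors at every internal node by summing the
#' joint likelihood over all 4^(number of internal nodes) state
#' assignments, with transition matrices obtained by matrix exponentiation
#' (`Matrix::expm`), independently of the pruning implementation. Leaves
#' showing a gap or N are treated as missing data. Feasible for a handful
#' of tips and columns; intended as an independent test oracle.
#'
#' @param msa named gapped rows covering the tree's tips.
#' @param tree species tree with branch lengths (phylo).
#' @param model a [sub_model()] with explicit `base_freqs`.
#' @return named list (internal node label) of columns x 4 posterior
#'   matrices.
#' @export
ancestral_posteriors_bruteforce <- function(msa, tree, model) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("the brute-force posterior oracle needs the Matrix package")
  if (is.null(model$base_freqs))
    stop("the oracle needs explicit base frequencies")
  pi <- model$base_freqs
  Q <- hky_rate_matrix(model$kappa, pi)
  ntip <- length(tree$tip.label)
  nI <- tree$Nnode
  if (nI > 4) stop("oracle is for <= 4 internal nodes")
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    stop("tree must have internal node labels")
  rows <- lapply(msa[tree$tip.label], chars)
  ncols <- length(rows[[1]])
  P <- lapply(tree$edge.length,
              function(t) as.matrix(Matrix::expm(Q * t)))
  states <- as.matrix(expand.grid(rep(list(1:4), nI)))
  lik <- matrix(0, nrow(states), ncols)
  for (a in seq_len(nrow(states))) {
    st <- function(node) {
      if (node <= ntip) NA_integer_ else states[a, node - ntip]
    }
    l <- rep(pi[st(ntip + 1L)], ncols)
    for (e in seq_len(nrow(tree$edge))) {
      pa <- st(tree$edge[e, 1]); ch <- tree$edge[e, 2]
      if (ch <= ntip) {
        b <- match(rows[[tree$tip.label[ch]]], BASES)
        f <- ifelse(is.na(b), 1, P[[e]][pa, ifelse(is.na(b), 1, b)])
        l <- l * f
      } else {
        l <- l * P[[e]][pa, st(ch)]
      }
    }
    lik[a, ] <- l
  }
  out <- list()
  for (v in seq_len(nI)) {
    post <- matrix(0, ncols, 4, dimnames = list(NULL, BASES))
    for (x in 1:4) post[, x] <- colSums(lik[states[, v] == x, , drop = FALSE])
    out[[tree$node.label[v]]] <- post / rowSums(post)
  }
  out
}

run_python <- function(code, input_lines) {
  inf <- tempfile(); outf <- tempfile()
  writeLines(input_lines, inf)
  scriptf <- tempfile(fileext = ".py")
  writeLines(code, scriptf)
  status <- system2("python", scriptf, stdout = outf, stdin = inf)
  if (status != 0) stop("python reference computation failed")
  on.exit(unlink(c(inf, outf, scriptf)))
  readLines(outf)
}

#' Exact binomial upper tails by rational arithmetic
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, num/den)` with exact rational
#' arithmetic (Python's `fractions`), as the arbitrary-precision reference
#' for the trend tests. Vectorised over `k`, `n`.
#'
#' @param k,n successes and trials (integer vectors, recycled).
#' @param num,den numerator and denominator of the success probability.
#' @return numeric vector of exact tail probabilities (rounded only by the
#'   final conversion to double).
#' @export
binom_tail_reference <- function(k, n, num, den) {
  df <- data.frame(k = k, n = n, num = num, den = den)
  code <- c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in sys.stdin:",
    "    k, n, num, den = (int(x) for x in line.split())",
    "    p = Fraction(num, den)",
    "    tail = sum(comb(n, i) * p**i * (1 - p)**(n - i) for i in range(k, n + 1))",
    "    print(repr(float(tail)))")
  out <- run_python(code, sprintf("%d %d %d %d", df$k, df$n, df$num, df$den))
  as.numeric(out)
}

#' Arbitrary-precision reference for Welch's t-test
#'
#' Recomputes t, the Welch-Satterthwaite degrees of freedom and the
#' two-sided p-value at 50 significant digits (mpmath's regularised
#' incomplete beta), as the high-precision reference for [welch_test()].
#'
#' @param n1,m1,s1,n2,m2,s2 summary statistics (vectors, recycled).
#' @return data frame with columns `t`, `df`, `p`.
#' @export
welch_reference <- function(n1, m1, s1, n2, m2, s2) {
  df <- data.frame(n1 = n1, m1 = m1, s1 = s1, n2 = n2, m2 = m2, s2 = s2)
  code <- c(
    "import sys",
    "import mpmath as mp",
    "mp.mp.dps = 50",
    "for line in sys.stdin:",
    "    n1, m1, s1, n2, m2, s2 = (mp.mpf(x) for x in line.split())",
    "    va, vb = s1**2 / n1, s2**2 / n2",
    "    t = (m1 - m2) / mp.sqrt(va + vb)",
    "    df = (va + vb)**2 / (va**2 / (n1 - 1) + vb**2 / (n2 - 1))",
    "    x = df / (df + t**2)",
    "    p = mp.betainc(df / 2, mp.mpf(1) / 2, 0, x, regularized=True)",
    "    print(repr(float(t)), repr(float(df)), repr(float(p)))")
  lines <- sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                   df$n1, df$m1, df$s1, df$n2, df$m2, df$s2)
  out <- run_python(code, lines)
  parts <- do.call(rbind, lapply(strsplit(out, " "), as.numeric))
  data.frame(t = parts[, 1], df = parts[, 2], p = parts[, 3])
}

#' Parameter-recovery evaluation on simulated intergenic loci
#'
#' Simulates indel-free intergenic loci on a short-branch three-species
#' tree (all branches at most 0.1 substitutions/site), runs the full
#' mapping-alignment-reconstruction pipeline, and compares the
#' pipeline-estimated substitution-class frequencies on the
#' A1-to-cerevisiae edge, and the argmax ancestral sequences at A1, with
#' the simulator's ground truth. Loci are simulated in independent batches
#' so the quadratic genome scan stays tractable.
#'
#' @param seed integer seed driving all randomness.
#' @param n_loci total number of intergenic loci (default 500).
#' @param locus_length locus length, nt (default 300).
#' @param batch_size loci per simulated genome (default 25).
#' @param flank flank length used by the pipeline, nt.
#' @return list with per-class estimated and true frequencies (percent),
#'   `transition_rel_err`, `transversion_rel_err`, `site_match` (fraction
#'   of A1 sites recovered), `mean_confidence`, `n_loci_used`.
#' @export
evaluate_recovery <- function(seed, n_loci = 500, locus_length = 300,
                              batch_size = 25, flank = 50) {
  set.seed(seed)
  batches <- ceiling(n_loci / batch_size)
  batch_seeds <- sample.int(.Machine$integer.max - 1, batches)
  tree <- yeast_tree(bayanus = FALSE)
  est_counts <- setNames(numeric(7), MUTATION_CLASSES); est_denom <- 0
  true_counts <- est_counts; true_denom <- 0
  match_sites <- 0; total_sites <- 0; confs <- c(); used <- 0
  for (b in seq_len(batches)) {
    nb <- min(batch_size, n_loci - (b - 1) * batch_size)
    cfg <- sim_config(tree_spec = tree,
                      n_loci_per_class = c(intergene = nb),
                      locus_length = locus_length,
                      indel_rate = 0, seed = batch_seeds[b])
    sim <- simulate_catalogue(cfg)
    related <- sim$genomes[c("paradoxus", "mikatae")]
    ti <- tree_info(sim$tree)
    for (i in seq_len(nrow(sim$catalogue))) {
      entry <- sim$catalogue[i, ]
      locus <- extract_locus(sim$genomes[["cerevisiae"]], entry, flank)
      ortho <- find_orthologue(locus, related)
      if (any(vapply(ortho$hits, is.null, TRUE))) next
      seqs <- c(list(cerevisiae = locus$sequence),
                lapply(ortho$hits, `[[`, "sequence"))
      msa <- build_msa(seqs, guide = ti$tree)
      anc <- reconstruct_ancestors(msa, ti$tree)
      a1 <- anc[[ti$a1_label]]
      aug <- c(unclass(msa), setNames(list(a1$sequence), ti$a1_label))
      gr <- gene_region(locus)
      cer_cols <- which(chars(aug[["cerevisiae"]]) != "-")
      gcols <- cer_cols[gr[1]:gr[2]]
      pair <- induce_pair_cols(aug, ti$a1_label, "cerevisiae", gcols)
      mut <- classify_mutations(pair)
      est_counts <- est_counts + mut$counts
      est_denom <- est_denom + mut$denominators["sub"]
      truth <- sim$truth[[entry$id]]
      tt <- truth_event_tally(truth, paste0(ti$a1_label, "->cerevisiae"))
      true_counts <- true_counts + tt
      true_denom <- true_denom + nchar(truth$nodes[[ti$a1_label]])
      rec_a1 <- degap(paste(chars(aug[[ti$a1_label]])[gcols], collapse = ""))
      tr_a1 <- truth$nodes[[ti$a1_label]]
      L <- min(nchar(rec_a1), nchar(tr_a1))
      match_sites <- match_sites +
        sum(chars(substr(rec_a1, 1, L)) == chars(substr(tr_a1, 1, L)))
      total_sites <- total_sites + nchar(tr_a1)
      confs <- c(confs, a1$confidence)
      used <- used + 1
    }
  }
  est_freq <- 100 * est_counts / est_denom
  true_freq <- 100 * true_counts / true_denom
  rel <- function(cl) abs(est_freq[cl] - true_freq[cl]) / true_freq[cl]
  list(est_freq = est_freq, true_freq = true_freq,
       transition_rel_err = unname(rel("transition")),
       transversion_rel_err = unname(rel("transversion")),
       site_match = match_sites / total_sites,
       mean_confidence = mean(confs),
       n_loci_used = used)
}

#' Scenario-order evaluation on simulated gene-birth loci
#'
#' Simulates cerevisiae-specific (S1-like) loci that received a
#' stop-removal on the A1-to-cerevisiae edge but no Kozak creation, plus
#' intergenic background loci, runs the full pipeline, and returns the
#' pooled extension and Kozak-appearance trend tests. A faithful
#' reconstruction shows a strong extension trend and no Kozak trend: ORFs
#' are extended on the birth edge, the translation signature is recruited
#' later.
#'
#' @param seed integer seed.
#' @param batches number of independent simulated genomes.
#' @param s1_per_batch,intergene_per_batch loci per batch.
#' @param locus_length locus length, nt.
#' @param flank flank length used by the pipeline, nt.
#' @return list with `extension` and `kozak` (`trend_test` objects or NULL),
#'   the pooled `features` table and the per-class tallies.
#' @export
evaluate_scenario_order <- function(seed, batches = 7, s1_per_batch = 12,
                                    intergene_per_batch = 29,
                                    locus_length = 240, flank = 50) {
  set.seed(seed)
  batch_seeds <- sample.int(.Machine$integer.max - 1, batches)
  tree <- yeast_tree(bayanus = FALSE)
  feats <- list()
  for (b in seq_len(batches)) {
    cfg <- sim_config(tree_spec = tree,
                      n_loci_per_class = c(S1 = s1_per_batch,
                                           intergene = intergene_per_batch),
                      locus_length = locus_length,
                      indel_rate = 0.02,
                      seed = batch_seeds[b])
    sim <- simulate_catalogue(cfg)
    scen <- denovo_scenario(sim$genomes, sim$catalogue, sim$tree,
                            flank = flank)
    if (!is.null(scen$features)) feats[[b]] <- scen$features
  }
  features <- do.call(rbind, feats)
  pooled <- pool_scenario(features, a1 = "A1", a2 = "A2")
  list(extension = pooled$tests$orf_changes[["S1 ATG"]],
       kozak = pooled$tests$kozak[["S1 A..ATG"]],
       features = features,
       orf_summary = pooled$summaries$orf_changes,
       kozak_summary = pooled$summaries$kozak)
}
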