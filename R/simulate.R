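#' Neutral evolution model for the simulator
#'
#' HKY substitutions (kappa, stationary G+C) plus a Poisson indel process
#' with geometric lengths, insertions and deletions equally likely and
#' inserted bases drawn at the stationary composition. Defaults emulate the
#' observed mutation spectrum between the ancestral and extant genomes: a
#' transition excess of roughly 1.6x and an AT>GC/GC>AT flux ratio of about
#' 1.5 when the current composition sits near 31% G+C.
#'
#' @param kappa transition/transversion rate ratio.
#' @param gc_equilibrium stationary G+C fraction.
#' @param indel_rate indel events per site per unit branch length.
#' @param indel_mean_len mean indel length (geometric, >= 1).
#' @return list of class `evo_model`.
#' @export
evo_model <- function(kappa = 3, gc_equilibrium = 0.40,
                      indel_rate = 0.1, indel_mean_len = 2) {
  stopifnot(kappa >= 0, gc_equilibrium >= 0, gc_equilibrium <= 1,
            indel_rate >= 0, indel_mean_len >= 1)
  structure(list(kappa = kappa, gc_equilibrium = gc_equilibrium,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len),
            class = "evo_model")
}

#' Draw a root sequence of given length and G+C content
#'
#' Bases are independent with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#' Randomness comes from the R session RNG; set a seed for reproducibility.
#'
#' @param length sequence length in nt (>= 0).
#' @param gc G+C fraction in `[0, 1]`.
#' @return a single DNA string.
#' @examples
#' set.seed(1); simulate_root(12, 0.4)
#' @export
simulate_root <- function(length, gc) {
  if (!is.numeric(length) || length(length) != 1 || length < 0)
    stop("length must be a single non-negative number")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (length == 0) return("")
  paste(sample(BASES, length, replace = TRUE, prob = gc_base_freqs(gc)),
        collapse = "")
}

## one substitution event per row; indels carry len and the affected string.
## Positions of substitutions refer to the branch-start sequence (no shifts
## before indels are applied); indel positions refer to the sequence state at
## application time. Replaying rows in order reproduces the child exactly.
empty_events <- function() {
  data.frame(type = character(), pos = integer(), old = character(),
             new = character(), len = integer(), note = character(),
             stringsAsFactors = FALSE)
}

sub_events_df <- function(pos, old, new, note = "") {
  n <- length(pos)
  data.frame(type = rep("sub", n), pos = pos, old = old, new = new,
             len = rep(NA_integer_, n), note = rep(note, n),
             stringsAsFactors = FALSE)
}

## Gillespie per-site substitution process, vectorised over sites in rounds
## (round k holds each still-active site's k-th jump, so per-site event
## order is chronological).
evolve_substitutions <- function(seq, t, Q) {
  idx <- match(chars(seq), BASES)
  n <- length(idx)
  ev_pos <- integer(0); ev_old <- character(0); ev_new <- character(0)
  rate_out <- -diag(Q)
  jump <- Q; diag(jump) <- 0
  jump_cum <- t(apply(jump / rowSums(jump), 1, cumsum))
  tcur <- numeric(n)
  active <- seq_len(n)
  while (length(active)) {
    dt <- rexp(length(active), rate_out[idx[active]])
    tcur[active] <- tcur[active] + dt
    hit <- active[tcur[active] <= t]
    if (length(hit)) {
      u <- runif(length(hit))
      cum <- jump_cum[idx[hit], , drop = FALSE]
      newb <- 1L + rowSums(cum < u)
      ev_pos <- c(ev_pos, hit)
      ev_old <- c(ev_old, BASES[idx[hit]])
      ev_new <- c(ev_new, BASES[newb])
      idx[hit] <- newb
    }
    active <- hit
  }
  list(seq = paste(BASES[idx], collapse = ""),
       events = sub_events_df(ev_pos, ev_old, ev_new))
}

evolve_indels <- function(seq, t, model) {
  L0 <- nchar(seq)
  events <- empty_events()
  n_ev <- rpois(1, t * model$indel_rate * L0)
  if (n_ev == 0) return(list(seq = seq, events = events))
  pi <- gc_base_freqs(model$gc_equilibrium)
  rows <- vector("list", n_ev)
  for (k in seq_len(n_ev)) {
    L <- nchar(seq)
    len <- 1L + rgeom(1, 1 / model$indel_mean_len)
    if (runif(1) < 0.5 || L == 0) { # insertion
      pos <- sample.int(L + 1L, 1) - 1L  # insert after pos (0 = prepend)
      ins <- paste(sample(BASES, len, replace = TRUE, prob = pi), collapse = "")
      seq <- paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1, L))
      rows[[k]] <- data.frame(type = "ins", pos = pos, old = "", new = ins,
                              len = len, note = "", stringsAsFactors = FALSE)
    } else { # deletion
      start <- sample.int(L, 1)
      len <- min(len, L - start + 1L)
      delseq <- substr(seq, start, start + len - 1L)
      seq <- paste0(substr(seq, 1, start - 1L), substr(seq, start + len, L))
      rows[[k]] <- data.frame(type = "del", pos = start, old = delseq, new = "",
                              len = len, note = "", stringsAsFactors = FALSE)
    }
  }
  list(seq = seq, events = do.call(rbind, rows))
}

#' Evolve a sequence along one branch
#'
#' Substitutions follow the HKY process site by site (exact stochastic
#' simulation, so every event is logged); indel events are then drawn from a
#' Poisson process with geometric lengths. The returned event list replays
#' exactly: applying rows in order to the parent sequence (see
#' [apply_events()]) reproduces the child sequence.
#'
#' @param seq parent DNA string.
#' @param t branch length in expected substitutions per site (>= 0).
#' @param model an [evo_model()].
#' @return list with `seq` (child sequence) and `events` (data frame).
#' @export
evolve_branch <- function(seq, t, model = evo_model()) {
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("branch length t must be a single non-negative number")
  if (t == 0 || nchar(seq) == 0)
    return(list(seq = seq, events = empty_events()))
  Q <- hky_rate_matrix(model$kappa, gc_base_freqs(model$gc_equilibrium))
  s <- evolve_substitutions(seq, t, Q)
  i <- evolve_indels(s$seq, t, model)
  list(seq = i$seq, events = rbind(s$events, i$events))
}

#' Replay a logged event list
#'
#' Applies substitution/insertion/deletion rows in order; substitution `old`
#' bases are checked against the current sequence, so a corrupted log fails
#' loudly instead of silently diverging.
#'
#' @param seq parent DNA string.
#' @param events event data frame as produced by [evolve_branch()].
#' @return the descendant sequence.
#' @export
apply_events <- function(seq, events) {
  if (is.null(events) || nrow(events) == 0) return(seq)
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    if (e$type == "sub") {
      if (substr(seq, e$pos, e$pos) != e$old)
        stop("event log replay mismatch at position ", e$pos)
      substr(seq, e$pos, e$pos) <- e$new
    } else if (e$type == "ins") {
      seq <- paste0(substr(seq, 1, e$pos), e$new,
                    substr(seq, e$pos + 1, nchar(seq)))
    } else if (e$type == "del") {
      seq <- paste0(substr(seq, 1, e$pos - 1),
                    substr(seq, e$pos + e$len, nchar(seq)))
    } else stop("unknown event type: ", e$type)
  }
  seq
}

## ---- gene-birth operations -------------------------------------------------

## remove the stop codon of the most upstream-starting ORF so it extends
inject_stop_removal <- function(seq) {
  orfs <- scan_orfs(seq, rule = "ATG")
  orfs <- orfs[orfs$has_stop, , drop = FALSE]
  if (nrow(orfs) == 0) return(list(seq = seq, events = empty_events()))
  o <- orfs[which.min(orfs$start), ]
  pos <- o$end - 2L # first base of the stop codon, always T
  ev <- sub_events_df(pos, substr(seq, pos, pos), "C", note = "stop_removal")
  substr(seq, pos, pos) <- "C"
  list(seq = seq, events = ev)
}

## give the most upstream ORF's start codon a Kozak context
## (A at -3; if that already holds, C at +4)
inject_kozak_creation <- function(seq) {
  orfs <- scan_orfs(seq, rule = "ATG")
  orfs <- orfs[orfs$start >= 4L, , drop = FALSE]
  if (nrow(orfs) == 0) return(list(seq = seq, events = empty_events()))
  o <- orfs[which.min(orfs$start), ]
  p3 <- o$start - 3L
  if (substr(seq, p3, p3) != "A") {
    ev <- sub_events_df(p3, substr(seq, p3, p3), "A", note = "kozak_creation")
    substr(seq, p3, p3) <- "A"
    return(list(seq = seq, events = ev))
  }
  p4 <- o$start + 4L
  if (p4 <= nchar(seq) && substr(seq, p4, p4) != "C") {
    ev <- sub_events_df(p4, substr(seq, p4, p4), "C", note = "kozak_creation")
    substr(seq, p4, p4) <- "C"
    return(list(seq = seq, events = ev))
  }
  list(seq = seq, events = empty_events())
}

inject_birth_op <- function(seq, op) {
  switch(op,
         stop_removal = inject_stop_removal(seq),
         kozak_creation = inject_kozak_creation(seq),
         orf_fusion = inject_stop_removal(seq), # fusing = removing the stop between two ORFs
         stop("unknown birth operation: ", op))
}

## evolve one edge, injecting the listed operations at their time fractions
evolve_edge <- function(seq, t, model, ops = list()) {
  if (length(ops) == 0) return(evolve_branch(seq, t, model))
  times <- vapply(ops, function(o) if (is.null(o$time)) 0.5 else o$time, 1)
  ord <- order(times)
  ops <- ops[ord]; times <- times[ord]
  events <- empty_events()
  prev <- 0
  for (k in seq_along(ops)) {
    seg <- evolve_branch(seq, t * (times[k] - prev), model)
    inj <- inject_birth_op(seg$seq, ops[[k]]$op)
    events <- rbind(events, seg$events, inj$events)
    seq <- inj$seq
    prev <- times[k]
  }
  seg <- evolve_branch(seq, t * (1 - prev), model)
  rbind_ev <- rbind(events, seg$events)
  list(seq = seg$seq, events = rbind_ev)
}

## ---- simulation configuration ----------------------------------------------

#' Default gene-birth operations per conservation class
#'
#' Cerevisiae-specific classes get a stop-removal on the A1-to-cerevisiae
#' edge; class S2 gets it on the A2-to-A1 edge; intergene loci get none.
#' A Kozak creation can be added to synthesise "extend now, Kozak later"
#' orderings explicitly.
#'
#' @param kozak also inject `kozak_creation` late (time 0.9) on the same
#'   edge for the gene classes (default FALSE: the Kozak signature is
#'   expected to be recruited after the birth edge).
#' @return named list of per-class operation lists.
#' @export
default_birth_ops <- function(kozak = FALSE) {
  mk <- function(edge) {
    ops <- list(list(op = "stop_removal", edge = edge, time = 0.5))
    if (kozak) ops <- c(ops, list(list(op = "kozak_creation", edge = edge, time = 0.9)))
    ops
  }
  list(`S0+` = mk(c("A1", "cerevisiae")),
       S1 = mk(c("A1", "cerevisiae")),
       S2 = mk(c("A2", "A1")),
       intergene = list())
}

#' Simulation configuration
#'
#' Bundles everything [simulate_catalogue()] needs. Defaults are the study
#' conditions the downstream analysis assumes: de-novo-locus roots at 38%
#' G+C versus intergene roots at 31% (the extant contrast is 37-40% vs
#' 30-33%), per-branch substitution loads of roughly 4-10% split across the
#' six substitution classes, and stop-removal birth events on each class's
#' birth edge.
#'
#' @param tree_spec species tree (phylo, Newick text or path).
#' @param n_loci_per_class named counts for `S0+`, `S1`, `S2`, `intergene`.
#' @param locus_length locus length at the root, nt.
#' @param flank_length flank length the downstream analysis will extract, nt
#'   (recorded for the pipeline; the simulator itself separates loci with
#'   spacers).
#' @param spacer_length length of the inter-locus spacer run, nt.
#' @param root_gc named per-class root G+C fractions.
#' @param kappa,gc_equilibrium,indel_rate,indel_mean_len see [evo_model()].
#' @param birth_ops per-class operation lists, see [default_birth_ops()].
#' @param neg_strand_prob probability a locus is placed on the minus strand.
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tree_spec = yeast_tree(),
                       n_loci_per_class = c(`S0+` = 50, S1 = 50, S2 = 50,
                                            intergene = 150),
                       locus_length = 300,
                       flank_length = 500,
                       spacer_length = 200,
                       root_gc = c(`S0+` = 0.38, S1 = 0.38, S2 = 0.38,
                                   intergene = 0.31),
                       kappa = 3, gc_equilibrium = 0.40,
                       indel_rate = 0.1, indel_mean_len = 2,
                       birth_ops = default_birth_ops(),
                       neg_strand_prob = 0.5,
                       seed = 1) {
  stopifnot(locus_length > 0, spacer_length > 0, flank_length >= 0,
            all(n_loci_per_class >= 0), all(root_gc >= 0 & root_gc <= 1),
            neg_strand_prob >= 0, neg_strand_prob <= 1)
  ti <- tree_info(tree_spec)
  structure(list(tree = ti$tree, n_loci_per_class = n_loci_per_class,
                 locus_length = locus_length, flank_length = flank_length,
                 spacer_length = spacer_length, root_gc = root_gc,
                 model = evo_model(kappa, gc_equilibrium, indel_rate,
                                   indel_mean_len),
                 birth_ops = birth_ops,
                 neg_strand_prob = neg_strand_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## spacer unit: stop codons in all three frames on both strands, no ATG,
## zero G+C -- ORFs terminate cleanly at locus boundaries and the spacer
## cannot seed spurious starts
SPACER_UNIT <- "TAATTAATTAA"

spacer_seq <- function(len) {
  substr(strrep(SPACER_UNIT, ceiling(len / nchar(SPACER_UNIT))), 1, len)
}

#' Simulate genomes, a gene catalogue and a ground-truth log
#'
#' Draws a root sequence per locus, evolves it down the species tree under
#' the neutral model, injects the configured gene-birth operations on each
#' class's birth edge, and assembles per-species genomes as loci separated
#' by fixed spacer runs. The truth log keeps every node's true sequence and
#' the complete per-edge event lists, so downstream stages can be scored
#' against ground truth.
#'
#' @param config a [sim_config()].
#' @param out_dir if non-NULL, write one FASTA per species (60-char lines),
#'   `catalogue.tsv` and `truth.json` there.
#' @return object of class `gene_birth_sim`: list with `genomes` (species ->
#'   named chromosome vector), `catalogue` (data frame), `truth` (per-locus
#'   list with `nodes` and per-edge `events`), `tree`, `config`.
#' @export
simulate_catalogue <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  ## fill unlabelled internal nodes so edges are addressable
  blank <- which(is.na(tree$node.label) | tree$node.label == "")
  if (length(blank)) tree$node.label[blank] <- paste0("N", blank + ntip)
  classes <- intersect(CONSERVATION_CLASSES, names(config$n_loci_per_class))
  classes <- classes[config$n_loci_per_class[classes] > 0]

  ## edges ordered so every parent is visited before its children
  edges <- tree$edge
  elens <- tree$edge.length
  ord <- integer(0)
  known <- ntip + 1L
  while (length(ord) < nrow(edges)) {
    nxt <- setdiff(which(edges[, 1] %in% known), ord)
    ord <- c(ord, nxt)
    known <- c(known, edges[nxt, 2])
  }
  preorder_edges <- edges[ord, , drop = FALSE]
  preorder_lens <- elens[ord]
  root_label <- node_label(tree, ntip + 1L)

  truth <- list()
  loci <- list()   # per locus: list(id, class, strand, species -> seq)
  for (cls in classes) {
    n <- config$n_loci_per_class[[cls]]
    ops_cls <- config$birth_ops[[cls]]
    if (is.null(ops_cls)) ops_cls <- list()
    for (i in seq_len(n)) {
      id <- sprintf("%s_%04d", cls, i)
      root_seq <- simulate_root(config$locus_length, config$root_gc[[cls]])
      nodes <- setNames(list(root_seq), root_label)
      events <- list()
      for (k in seq_len(nrow(preorder_edges))) {
        pa <- node_label(tree, preorder_edges[k, 1])
        ch <- node_label(tree, preorder_edges[k, 2])
        t_edge <- preorder_lens[k]
        ops_here <- Filter(function(o) identical(unname(o$edge), c(pa, ch)), ops_cls)
        res <- evolve_edge(nodes[[pa]], t_edge, config$model, ops_here)
        nodes[[ch]] <- res$seq
        events[[paste0(pa, "->", ch)]] <- res$events
      }
      strand <- if (runif(1) < config$neg_strand_prob) "-" else "+"
      truth[[id]] <- list(id = id, class = cls, strand = strand,
                          nodes = nodes, events = events)
      loci[[id]] <- list(id = id, class = cls, strand = strand,
                         seqs = nodes[tree$tip.label])
    }
  }

  spacer <- spacer_seq(config$spacer_length)
  genomes <- list()
  for (sp in tree$tip.label) {
    parts <- character(2 * length(loci) + 1)
    parts[1] <- spacer
    for (k in seq_along(loci)) {
      s <- loci[[k]]$seqs[[sp]]
      if (loci[[k]]$strand == "-") s <- revcomp(s)
      parts[2 * k] <- s
      parts[2 * k + 1] <- spacer
    }
    genomes[[sp]] <- c(chr1 = paste(parts, collapse = ""))
  }

  if (length(loci)) {
    lens <- vapply(loci, function(l) nchar(l$seqs[["cerevisiae"]]), 1L)
    starts <- integer(length(loci)); pos <- nchar(spacer)
    for (k in seq_along(loci)) {
      starts[k] <- pos + 1L
      pos <- pos + lens[k] + nchar(spacer)
    }
    catalogue <- data.frame(
      id = vapply(loci, `[[`, "", "id"),
      chrom = "chr1",
      start = starts,
      end = starts + lens - 1L,
      strand = vapply(loci, `[[`, "", "strand"),
      class = vapply(loci, `[[`, "", "class"),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    genomes <- lapply(setNames(tree$tip.label, tree$tip.label),
                      function(sp) c(chr1 = ""))
    catalogue <- data.frame(id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), class = character(),
                            stringsAsFactors = FALSE)
  }

  sim <- structure(list(genomes = genomes, catalogue = catalogue,
                        truth = truth, tree = tree, config = config),
                   class = "gene_birth_sim")
  if (!is.null(out_dir)) write_sim(sim, out_dir)
  sim
}

#' Write a simulation to disk
#' @param sim a `gene_birth_sim` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes))
    write_genome(sim$genomes[[sp]], file.path(dir, paste0(sp, ".fa")))
  write_catalogue(sim$catalogue, file.path(dir, "catalogue.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Net substitution tallies from a truth log
#'
#' Collapses the logged substitution events on one edge to the observable
#' per-site change (first old base to last new base; back-mutations cancel)
#' and classifies them with the same seven mutation classes the pipeline
#' reports. Only valid for indel-free edges, where site coordinates are
#' stable.
#'
#' @param truth_locus one element of `gene_birth_sim$truth`.
#' @param edge edge name, e.g. `"A1->cerevisiae"`.
#' @return named integer vector of counts (transition, transversion, AT>GC,
#'   GC>AT, AT>AT, GC>GC, indel).
#' @export
truth_event_tally <- function(truth_locus, edge) {
  ev <- truth_locus$events[[edge]]
  if (is.null(ev)) stop("no such edge in truth log: ", edge)
  out <- setNames(integer(7), MUTATION_CLASSES)
  if (nrow(ev) == 0) return(out)
  subs <- ev[ev$type == "sub", , drop = FALSE]
  out["indel"] <- sum(ev$type %in% c("ins", "del"))
  if (nrow(subs)) {
    first_old <- tapply(seq_len(nrow(subs)), subs$pos,
                        function(ix) subs$old[ix[1]])
    last_new <- tapply(seq_len(nrow(subs)), subs$pos,
                       function(ix) subs$new[ix[length(ix)]])
    changed <- first_old != last_new
    out[1:6] <- classify_substitutions(first_old[changed], last_new[changed])
  }
  out
}
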