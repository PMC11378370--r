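## Fitch parsimony on the binary gap/base character, ties resolved toward
## "base present" so sites stay available for the likelihood pass.
## leaf_gap: leaves x columns logical matrix. Returns internal-node gap
## states (internal nodes x columns logical matrix, TRUE = gap).
fitch_gap_states <- function(tree, leaf_gap) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ncols <- ncol(leaf_gap)
  ## state sets coded as 1=base, 2=gap, 3=both
  sets <- matrix(0L, ntip + nnode, ncols)
  sets[1:ntip, ] <- ifelse(leaf_gap[tree$tip.label, , drop = FALSE], 2L, 1L)
  depth <- node_depths(tree)
  up_order <- order(depth[(ntip + 1):(ntip + nnode)], decreasing = TRUE) + ntip
  for (nd in up_order) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    s <- sets[kids[1], ]
    for (k in kids[-1]) {
      sk <- sets[k, ]
      inter <- bitwAnd(s, sk)
      s <- ifelse(inter > 0L, inter, bitwOr(s, sk))
    }
    sets[nd, ] <- s
  }
  ## down pass: root prefers base on ties; children follow the parent when
  ## possible, otherwise prefer base
  final <- matrix(NA, ntip + nnode, ncols)
  root <- ntip + 1L
  final[root, ] <- sets[root, ] == 2L   # TRUE = gap only if set == {gap}
  for (nd in rev(up_order)) {
    if (nd == root) next
    pa <- tree$edge[tree$edge[, 2] == nd, 1]
    pstate <- ifelse(final[pa, ], 2L, 1L)
    s <- sets[nd, ]
    final[nd, ] <- ifelse(bitwAnd(s, pstate) > 0L, pstate == 2L, s == 2L)
  }
  out <- final[(ntip + 1):(ntip + nnode), , drop = FALSE]
  rownames(out) <- tree$node.label
  out
}

#' Marginal maximum-likelihood ancestral sequences
#'
#' Per alignment column, the posterior distribution over A, C, G, T at each
#' internal node up to A2 is computed with the pruning algorithm under an
#' HKY model with the tree's branch lengths; the reported base is the
#' argmax. Gap/base status at internal nodes is decided first by Fitch
#' parsimony on the binary gap character (ties toward "base"), and the
#' likelihood is computed on base-bearing columns with gapped or ambiguous
#' leaves treated as missing data. A bayanus row, when present, adds signal
#' to the likelihood but no ancestor above A2 is reported.
#'
#' @param msa alignment (named gapped rows, e.g. from [build_msa()]) covering
#'   cerevisiae, paradoxus and mikatae; bayanus optional.
#' @param tree species tree (see [tree_info()]); branch lengths are used as
#'   given, not re-estimated.
#' @param model a [sub_model()]; `NULL` base frequencies are estimated from
#'   the alignment (pooled counts with one pseudo-count per base).
#' @return named list of `ancestral_sequence` objects for A1 and A2, each
#'   with `node`, `sequence` (gapped, on the alignment's columns),
#'   `posteriors` (columns x 4 matrix, NA rows at gap columns) and
#'   `confidence` (mean over base columns of the max posterior).
#' @export
reconstruct_ancestors <- function(msa, tree = yeast_tree(), model = sub_model()) {
  ti <- tree_info(tree)
  have <- names(msa)
  need <- c("cerevisiae", "paradoxus", "mikatae")
  if (!all(need %in% have))
    stop("alignment must cover cerevisiae, paradoxus and mikatae")
  keep <- intersect(ti$leaves, have)
  tr <- ti$tree
  if (length(keep) < length(ti$leaves)) {
    missing_sp <- setdiff(ti$leaves, keep)
    if (!all(missing_sp %in% "bayanus"))
      stop("tree leaf missing from alignment: ",
           paste(setdiff(missing_sp, "bayanus"), collapse = ", "))
    tr <- ape::keep.tip(tr, keep)
  }
  ti <- tree_info(tr)
  tr <- ti$tree
  ntip <- length(tr$tip.label)
  if (is.null(tr$node.label)) tr$node.label <- paste0("N", seq_len(tr$Nnode) + ntip)
  blank <- which(is.na(tr$node.label) | tr$node.label == "")
  if (length(blank)) tr$node.label[blank] <- paste0("N", blank + ntip)

  rows <- lapply(msa[tr$tip.label], chars)
  ncols <- nchar(msa[[1]])
  if (any(vapply(rows, length, 1L) != ncols)) stop("ragged alignment")

  pi <- model$base_freqs
  if (is.null(pi)) {
    cnt <- rep(1, 4)
    for (r in rows) cnt <- cnt + vapply(BASES, function(b) sum(r == b), 1)
    pi <- cnt / sum(cnt)
  }
  Q <- hky_rate_matrix(model$kappa, pi)

  leaf_gap <- do.call(rbind, lapply(rows, function(r) r == "-"))
  rownames(leaf_gap) <- tr$tip.label
  gap_state <- fitch_gap_states(tr, leaf_gap)

  ## per-branch transition matrices
  edges <- tr$edge
  elen <- tr$edge.length
  P <- lapply(elen, function(t) hky_prob_matrix(Q, t))

  nn <- ntip + tr$Nnode
  ## post-order conditional likelihoods D, and child->parent messages M
  D <- vector("list", nn)
  for (i in seq_len(ntip)) {
    r <- rows[[tr$tip.label[i]]]
    m <- matrix(1, ncols, 4)
    known <- r %in% BASES
    m[known, ] <- 0
    m[cbind(which(known), match(r[known], BASES))] <- 1
    D[[i]] <- m
  }
  depth <- node_depths(tr)
  up_order <- order(depth[(ntip + 1):nn], decreasing = TRUE) + ntip
  Msg <- vector("list", nrow(edges))  # message through edge k (child -> parent)
  child_edges <- lapply(seq_len(nn), function(nd) which(edges[, 1] == nd))
  for (nd in up_order) {
    ce <- child_edges[[nd]]
    m <- matrix(1, ncols, 4)
    for (k in ce) {
      ch <- edges[k, 2]
      Msg[[k]] <- D[[ch]] %*% t(P[[k]])
      m <- m * Msg[[k]]
    }
    D[[nd]] <- m
  }
  ## pre-order outside likelihoods O
  O <- vector("list", nn)
  root <- ntip + 1L
  O[[root]] <- matrix(pi, ncols, 4, byrow = TRUE)
  for (nd in rev(up_order)) {
    for (k in child_edges[[nd]]) {
      ch <- edges[k, 2]
      others <- matrix(1, ncols, 4)
      for (k2 in setdiff(child_edges[[nd]], k)) others <- others * Msg[[k2]]
      O[[ch]] <- (O[[nd]] * others) %*% P[[k]]
    }
  }

  result <- list()
  for (lbl in c(ti$a1_label, ti$a2_label)) {
    nd <- ntip + match(lbl, tr$node.label)
    post <- D[[nd]] * O[[nd]]
    norm <- rowSums(post)
    ok <- norm > 0 & !gap_state[lbl, ]
    post <- post / ifelse(norm > 0, norm, 1)
    post[!ok, ] <- NA_real_
    colnames(post) <- BASES
    seq_chars <- rep("-", ncols)
    if (any(ok)) seq_chars[ok] <- BASES[max.col(post[ok, , drop = FALSE],
                                                ties.method = "first")]
    conf <- if (any(ok)) mean(apply(post[ok, , drop = FALSE], 1, max)) else NA_real_
    result[[lbl]] <- structure(
      list(node = lbl, sequence = paste(seq_chars, collapse = ""),
           posteriors = post, confidence = conf),
      class = "ancestral_sequence")
  }
  result
}

#' Confidence filter for an ancestral sequence
#'
#' The confidence of a reconstruction is the mean over its base-bearing
#' columns of the maximum posterior base probability; sequences below the
#' threshold (default 0.80) are discarded as unreliable.
#'
#' @param anc an `ancestral_sequence` (from [reconstruct_ancestors()]).
#' @param threshold minimum confidence kept.
#' @return TRUE (keep) or FALSE (discard).
#' @export
confidence_filter <- function(anc, threshold = 0.80) {
  stopifnot(inherits(anc, "ancestral_sequence"))
  !is.na(anc$confidence) && anc$confidence >= threshold
}

#' @export
print.ancestral_sequence <- function(x, ...) {
  cat("ancestral sequence at ", x$node, ": ", nchar(degap(x$sequence)),
      " bases, confidence ", round(x$confidence, 4), "\n", sep = "")
  invisible(x)
}
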