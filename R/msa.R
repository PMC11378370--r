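## sequences/alignment rows as character matrices of single characters
row_chars <- function(aln) lapply(aln, chars)

## 4 x L base-count profile of a set of gapped rows
profile_counts <- function(rows) {
  L <- nchar(rows[[1]])
  cnt <- matrix(0L, 4, L)
  for (r in rows) {
    cc <- chars(r)
    for (b in 1:4) cnt[b, ] <- cnt[b, ] + (cc == BASES[b])
  }
  cnt
}

## merge two aligned blocks along a profile-alignment op path
merge_blocks <- function(blockA, blockB, ops) {
  L <- length(ops)
  ia <- cumsum(ops != 3L); ib <- cumsum(ops != 2L)
  out <- c(
    lapply(blockA, function(r) {
      cc <- rep("-", L); take <- ops != 3L
      cc[take] <- chars(r)[ia[take]]
      paste(cc, collapse = "")
    }),
    lapply(blockB, function(r) {
      cc <- rep("-", L); take <- ops != 2L
      cc[take] <- chars(r)[ib[take]]
      paste(cc, collapse = "")
    }))
  out
}

#' Progressive multiple sequence alignment
#'
#' Aligns the sequences following the guide tree's topology: tips are merged
#' bottom-up, each merge being an affine-gap global profile-profile
#' alignment. Once a gap is introduced it is never removed ("once a gap,
#' always a gap"). Sequences whose names are not in the guide tree are
#' appended last.
#'
#' @param seqs named character vector of (ungapped) sequences, names are
#'   species.
#' @param guide guide tree (defaults to the species tree); anything
#'   [ape::read.tree()] produced or Newick text.
#' @param scoring a [scoring_scheme()].
#' @return object of class `msa`: named character vector of equal-length
#'   gapped rows.
#' @examples
#' build_msa(c(cerevisiae = "ACGTACGT", paradoxus = "ACGACGT",
#'             mikatae = "ACGTACGT"), yeast_tree())
#' @export
build_msa <- function(seqs, guide = yeast_tree(), scoring = scoring_scheme()) {
  seqs <- seqs[!vapply(seqs, is.null, TRUE)]
  if (length(seqs) == 0) stop("no sequences to align")
  seqs <- unlist(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in MSA input")
  if (length(seqs) == 1) {
    out <- seqs
    class(out) <- "msa"
    return(out)
  }
  if (is.character(guide)) guide <- ape::read.tree(text = guide)
  in_tree <- names(seqs)[names(seqs) %in% guide$tip.label]
  extra <- setdiff(names(seqs), in_tree)

  align_pair <- function(ba, bb) {
    res <- profile_align_cpp(profile_counts(ba), profile_counts(bb),
                             scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend)
    merge_blocks(ba, bb, res$ops)
  }

  if (length(in_tree) >= 2) {
    ## merge bottom-up over the guide tree restricted to present tips
    gt <- ape::keep.tip(guide, in_tree)
    ntip <- length(gt$tip.label)
    node_block <- vector("list", ntip + gt$Nnode)
    node_names <- vector("list", ntip + gt$Nnode)
    for (i in seq_len(ntip)) {
      node_block[[i]] <- list(seqs[[gt$tip.label[i]]])
      node_names[[i]] <- gt$tip.label[i]
    }
    depth <- node_depths(gt)
    for (nd in order(depth[(ntip + 1):(ntip + gt$Nnode)], decreasing = TRUE) + ntip) {
      kids <- gt$edge[gt$edge[, 1] == nd, 2]
      blk <- node_block[[kids[1]]]; nm <- node_names[[kids[1]]]
      for (k in kids[-1]) {
        blk <- align_pair(blk, node_block[[k]])
        nm <- c(nm, node_names[[k]])
      }
      node_block[[nd]] <- blk
      node_names[[nd]] <- nm
    }
    cur <- node_block[[ntip + 1L]]
    cur_names <- node_names[[ntip + 1L]]
  } else {
    cur <- list(seqs[[1]])
    cur_names <- names(seqs)[1]
    extra <- names(seqs)[-1]
  }
  for (nm in extra) {
    cur <- align_pair(cur, list(seqs[[nm]]))
    cur_names <- c(cur_names, nm)
  }
  out <- setNames(unlist(cur), cur_names)[names(seqs)]
  class(out) <- "msa"
  out
}

## depth (root = 0) of every node in an ape tree
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- rep(NA_real_, ntip + tree$Nnode)
  depth[ntip + 1L] <- 0
  edges <- tree$edge
  repeat {
    todo <- which(is.na(depth[edges[, 2]]) & !is.na(depth[edges[, 1]]))
    if (!length(todo)) break
    depth[edges[todo, 2]] <- depth[edges[todo, 1]] + 1
  }
  depth
}
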