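#' Default species tree for the sensu stricto clade
#'
#' A rooted tree over cerevisiae, paradoxus, mikatae and (optionally) bayanus
#' with branch lengths in expected substitutions per site, and the two
#' internal nodes of interest labelled: `A1` is the most recent common
#' ancestor (MRCA) of cerevisiae and paradoxus, `A2` the MRCA of cerevisiae,
#' paradoxus and mikatae. Ancestral reconstruction never goes above `A2`
#' because the bayanus branch is much longer than the others.
#'
#' @param bayanus include the bayanus outgroup branch (default TRUE).
#' @return an [ape::phylo] object with labelled internal nodes.
#' @examples
#' tr <- yeast_tree()
#' tree_info(tr)$a1_label
#' @export
yeast_tree <- function(bayanus = TRUE) {
  nwk <- if (bayanus) {
    "(((cerevisiae:0.06,paradoxus:0.06)A1:0.05,mikatae:0.12)A2:0.08,bayanus:0.20)R;"
  } else {
    "((cerevisiae:0.05,paradoxus:0.05)A1:0.04,mikatae:0.09)A2;"
  }
  ape::read.tree(text = nwk)
}

#' Resolve the A1/A2 structure of a species tree
#'
#' Accepts a Newick string, a file path, or an `phylo` object; checks that the
#' tree is rooted, has branch lengths, contains the three core species, and
#' that A1 (MRCA of cerevisiae+paradoxus) is a child of A2 (MRCA of
#' cerevisiae+paradoxus+mikatae). Missing internal labels are filled in.
#'
#' @param tree tree input (phylo, Newick text, or path).
#' @return list with elements `tree` (phylo, labelled), `a1`, `a2` (node ids),
#'   `a1_label`, `a2_label`, `root` (node id), `leaves` (tip labels).
#' @export
tree_info <- function(tree) {
  if (is.character(tree)) {
    tree <- if (grepl("(", tree, fixed = TRUE)) ape::read.tree(text = tree)
            else ape::read.tree(tree)
  }
  if (is.null(tree) || !inherits(tree, "phylo")) stop("cannot parse species tree")
  if (is.null(tree$edge.length)) stop("species tree must have branch lengths")
  core <- c("cerevisiae", "paradoxus", "mikatae")
  if (!all(core %in% tree$tip.label))
    stop("species tree must contain cerevisiae, paradoxus and mikatae")
  ntip <- length(tree$tip.label)
  a1 <- ape::getMRCA(tree, c("cerevisiae", "paradoxus"))
  a2 <- ape::getMRCA(tree, core)
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  lab <- function(node) {
    l <- tree$node.label[node - ntip]
    if (is.na(l) || l == "") NULL else l
  }
  if (is.null(lab(a1))) tree$node.label[a1 - ntip] <- "A1"
  if (is.null(lab(a2))) tree$node.label[a2 - ntip] <- "A2"
  parent_of <- function(node) {
    e <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(e)) e else NA_integer_
  }
  if (!identical(parent_of(a1), a2))
    stop("A1 (MRCA of cerevisiae+paradoxus) must be a child of A2")
  root <- ntip + 1L
  list(tree = tree,
       a1 = a1, a2 = a2,
       a1_label = tree$node.label[a1 - ntip],
       a2_label = tree$node.label[a2 - ntip],
       root = root,
       leaves = tree$tip.label)
}

node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node] else tree$node.label[node - ntip]
}

#' Assign the birth edge of a conservation class by parsimony
#'
#' The child end of the birth edge is the MRCA of the species possessing the
#' gene, and the parent end is that node's parent: cerevisiae-specific genes
#' (classes `S0+` and `S1`) were born on the edge from A1 to the cerevisiae
#' tip, while genes conserved to paradoxus (class `S2`) were born on the edge
#' from A2 to A1. Reconstruction stops at A2, so classes `S3`/`S4` (and
#' `intergene` without a reference class) are not assignable.
#'
#' @param conservation_class one of `"S0+"`, `"S1"`, `"S2"`.
#' @param tree species tree (anything [tree_info()] accepts).
#' @return list with `parent` and `child` node labels.
#' @examples
#' assign_birth_edge("S2", yeast_tree())
#' @export
assign_birth_edge <- function(conservation_class, tree = yeast_tree()) {
  ti <- tree_info(tree)
  if (!conservation_class %in% c("S0+", "S1", "S2"))
    stop("unsupported conservation class '", conservation_class,
         "': birth edges are assigned only for S0+, S1 and S2 ",
         "(reconstruction stops at A2)")
  if (conservation_class %in% c("S0+", "S1"))
    list(parent = ti$a1_label, child = "cerevisiae")
  else
    list(parent = ti$a2_label, child = ti$a1_label)
}
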