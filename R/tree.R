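#' Read a rooted species tree from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: the file must contain
#' exactly one rooted tree with unique leaf labels. Internal branches are
#' addressable afterwards through [tree_branches()], which identifies each
#' branch by its subtended leaf set.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) abort("file contains more than one tree")
  if (is.null(tr)) abort("no tree could be parsed from file")
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("duplicate leaf label(s): ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", ")))
  }
  if (!ape::is.rooted(tr)) abort("tree is unrooted; a rooted species tree is required")
  tr
}

#' Enumerate the branches of a tree with their subtended leaf sets
#'
#' Every node except the root defines the branch above it. Terminal branches
#' are labelled by their leaf; internal branches take the Newick node label
#' when present, otherwise `"node<N>"`.
#'
#' @param tree An [ape::phylo] object.
#' @return Tibble with columns `node`, `label`, `is_tip`, `leaves`
#'   (list-column of leaf label character vectors), `n_leaves`.
#' @export
tree_branches <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  nodes <- setdiff(seq_len(ntip + nnode), root)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  leaves <- lapply(desc, function(i) sort(tree$tip.label[i]))
  labels <- vapply(nodes, function(n) {
    if (n <= ntip) return(tree$tip.label[n])
    lbl <- tree$node.label[n - ntip]
    if (is.null(lbl) || is.na(lbl) || !nzchar(lbl)) paste0("node", n) else lbl
  }, character(1))
  tibble(
    node = nodes,
    label = labels,
    is_tip = nodes <= ntip,
    leaves = leaves,
    n_leaves = lengths(leaves)
  )
}
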