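# Species tree simulation.

#' Simulate (or load) the species tree
#'
#' Yule mode draws a pure-birth tree with `n_species` leaves, renames the
#' leaves `sp01...spNN`, scales branch lengths so the maximum root-to-tip
#' depth is 1, and labels internal nodes `n1...` (root first, in ape node
#' order). Fixture mode returns a shipped 16-leaf damselfish-clade-shaped
#' topology with named species.
#'
#' @param config A `sim_config` (or a list with `n_species`, `tree_mode`,
#'   `seed`).
#' @return A `phylo` tree with unique leaf names and internal node labels.
#' @export
simulate_species_tree <- function(config) {
  if (config$n_species < 3) stop("n_species must be >= 3")
  if (config$tree_mode == "fixed_fixture") {
    path <- system.file("extdata", "pomacentridae16.nwk",
                        package = "prohoscan")
    tree <- parse_newick(paste(readLines(path), collapse = ""))
  } else {
    set.seed(config$seed)
    tree <- ape::rphylo(config$n_species, birth = 1, death = 0)
    ord <- as.integer(sub("^t", "", tree$tip.label))
    tree$tip.label <- sprintf("sp%02d", ord)
    depth <- max(ape::node.depth.edgelength(tree))
    if (depth > 0) tree$edge.length <- tree$edge.length / depth
  }
  tree$node.label <- paste0("n", seq_len(tree$Nnode))
  tree
}

#' Leaves descending from a named internal node
#'
#' @param tree `phylo` with `node.label` set.
#' @param node_label Internal node label (e.g. `"n3"`).
#' @return Character vector of tip labels in the clade.
#' @export
clade_leaves <- function(tree, node_label) {
  idx <- match(node_label, tree$node.label)
  if (is.na(idx)) stop("unknown internal node label: ", node_label)
  node <- length(tree$tip.label) + idx
  if (idx == 1) return(tree$tip.label)  # root
  sub <- ape::extract.clade(tree, node)
  sub$tip.label
}
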