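# Species tree plumbing on top of ape's phylo. Internal nodes carry taxon
# names (Eumetazoa, Nephrozoa, ...) used by the acquisition assignment.

.DEFAULT_TREE_NEWICK <- paste0(
  "(Nvectensis,",
  "(((Dmelanogaster,Celegans)Ecdysozoa,Lgigantea)Protostomia,",
  "((Spurpuratus,Skowalevskii)Ambulacraria,",
  "(Bfloridae,",
  "((Pmarinus,(Drerio,(Xtropicalis,(Ggallus,(Hsapiens,Mmusculus)Mammalia)",
  "Amniota)Tetrapoda)Gnathostomata)Vertebrata,",
  "(Odioica,(Hroretzi,(Cintestinalis,Csavignyi)Ciona)Ascidiacea)Tunicata)",
  "Olfactores)Chordata)Deuterostomia)Nephrozoa)Eumetazoa;")

#' Default 17-species metazoan tree with named internal taxa
#'
#' A conventional rooted topology spanning a cnidarian outgroup,
#' protostomes, ambulacrarians, amphioxus, vertebrates and tunicates
#' (including Ciona savignyi), with internal nodes named for the taxa at
#' whose origin miRNA families can be assigned (Eumetazoa, Nephrozoa,
#' Deuterostomia, Chordata, Olfactores, Tunicata, Ciona, ...). The exact
#' topology is replaceable input: any rooted newick tree with named
#' internal nodes works.
#'
#' @return an [ape::read.tree()] `phylo` object.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = .DEFAULT_TREE_NEWICK)
}

# node id -> display name. Tips use tip.label; unnamed internals fall back
# to "node<N>".
node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- if (is.null(tree$node.label)) NA_character_ else
    tree$node.label[node - ntip]
  if (is.na(lab) || !nzchar(lab)) paste0("node", node) else lab
}

node_names <- function(tree) {
  vapply(seq_len(length(tree$tip.label) + tree$Nnode),
         function(v) node_name(tree, v), character(1))
}

# name (tip or internal label) -> node id, NA if absent
node_by_name <- function(tree, name) {
  all <- node_names(tree)
  match(name, all)
}

# children list indexed by node id (empty integer for tips)
tree_children <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nn)) kids[[i]] <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  kids
}

# parent vector indexed by node id (NA at root)
tree_parents <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  par <- rep(NA_integer_, nn)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

tree_root <- function(tree) {
  length(tree$tip.label) + 1L
}

# list, per node, of tip ids in that node's subtree
subtree_tips <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  kids <- tree_children(tree)
  tips <- vector("list", nn)
  fill <- function(v) {
    if (length(kids[[v]]) == 0L) {
      tips[[v]] <<- v
      return(v)
    }
    out <- sort(unlist(lapply(kids[[v]], fill)))
    tips[[v]] <<- out
    out
  }
  fill(tree_root(tree))
  tips
}

# all descendant node ids of `node` (excluding node itself)
descendants <- function(tree, node, kids = tree_children(tree)) {
  out <- integer(0)
  stack <- kids[[node]]
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  out
}

validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2L) {
    stop("degenerate species tree: need at least 2 leaves")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  if (!is.null(tree$node.label)) {
    labs <- tree$node.label[nzchar(tree$node.label)]
    if (anyDuplicated(labs)) stop("duplicate internal node names in tree")
  }
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  invisible(tree)
}
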