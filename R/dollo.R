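# Dollo parsimony reconstruction of miRNA family histories. Under a
# single gain, the optimal gain node is the MRCA of the present leaves and
# the optimal losses are one event per maximal absent clade below it.

#' Reconstruct family gain/loss histories under Dollo parsimony
#'
#' For each family (row of the presence/absence matrix) the gain node is
#' the most recent common ancestor of the present leaves (the terminal
#' branch for single-species families) and losses are placed on the
#' branches subtending the maximal subtrees below the gain that contain no
#' present leaf. This minimizes the loss count over all single-gain
#' assignments.
#'
#' @param mat binary matrix, rows = families, columns = species matching
#'   the tree's leaves. Every row must have at least one 1.
#' @param tree rooted `phylo` species tree with named internal nodes.
#' @return object of class `dollo_reconstruction`: per-family list with
#'   `gain` (node id), `gain_name`, `losses` (child node ids of loss
#'   branches), `loss_names`, `n_losses`; plus `tree` and `matrix`.
#' @export
dollo_reconstruct <- function(mat, tree) {
  validate_species_tree(tree)
  if (is.null(colnames(mat)) || is.null(rownames(mat))) {
    stop("matrix must have family rownames and species colnames")
  }
  if (!setequal(colnames(mat), tree$tip.label)) {
    stop("matrix species do not match tree leaves")
  }
  mat <- mat[, tree$tip.label, drop = FALSE]
  if (any(rowSums(mat) == 0)) {
    stop("family present in zero species: ",
         paste(rownames(mat)[rowSums(mat) == 0], collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  kids <- tree_children(tree)
  par <- tree_parents(tree)
  subt <- subtree_tips(tree)
  families <- lapply(rownames(mat), function(f) {
    present <- unname(which(mat[f, ] == 1L))  # tip ids (tip order)
    gain <- if (length(present) == 1L) present else
      ape::getMRCA(tree, present)
    # present-leaf count per node, restricted to this family
    below <- descendants(tree, gain, kids)
    cnt <- vapply(seq_along(subt), function(v)
      length(intersect(subt[[v]], present)), integer(1))
    losses <- below[cnt[below] == 0L & cnt[par[below]] > 0L]
    list(family = f, gain = gain, gain_name = node_name(tree, gain),
         losses = losses,
         loss_names = vapply(losses, function(v) node_name(tree, v),
                             character(1)),
         n_losses = length(losses))
  })
  names(families) <- rownames(mat)
  structure(list(families = families, tree = tree, matrix = mat),
            class = "dollo_reconstruction")
}

#' Assign each family's acquisition to a named taxon
#'
#' A family is acquired at the origin of taxon T when its gain node is T's
#' origin node, its present leaves fall in at least two daughter lineages
#' of T, and no species outside T possesses it ("absent in ancestor and
#' sister lineages", read over extant species since ancestors are
#' unobservable). With the gain at the MRCA of the present leaves both
#' side conditions hold by construction; they are asserted anyway.
#' Single-species families are terminal-branch gains and report the leaf.
#'
#' @param rec a [dollo_reconstruct()] result.
#' @return data.frame: `family`, `gain_node` (id), `taxon` (node name),
#'   `type` (`"taxon"`, `"terminal"` or `"unnamed"`), `n_losses`.
#' @export
assign_acquisition <- function(rec) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  tree <- rec$tree
  ntip <- length(tree$tip.label)
  kids <- tree_children(tree)
  subt <- subtree_tips(tree)
  rows <- lapply(rec$families, function(fam) {
    gain <- fam$gain
    present <- which(rec$matrix[fam$family, ] == 1L)
    if (gain <= ntip) {
      type <- "terminal"
    } else {
      # present leaves must span >= 2 daughter lineages of the gain node
      # and none may lie outside its subtree (both guaranteed at the MRCA)
      span <- sum(vapply(kids[[gain]], function(ch)
        length(intersect(subt[[ch]], present)) > 0L, logical(1)))
      outside <- length(setdiff(present, subt[[gain]]))
      stopifnot(span >= 2L, outside == 0L)
      named <- !startsWith(fam$gain_name, "node")
      type <- if (named) "taxon" else "unnamed"
    }
    data.frame(family = fam$family, gain_node = gain,
               taxon = fam$gain_name, type = type,
               n_losses = fam$n_losses, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-node acquisition / loss / retention summary
#'
#' Counts, for every tree node, the families acquired at its origin, the
#' loss events on the branch subtending it, and the families acquired
#' there that are still present in a focal species. Acquisition counts sum
#' to the number of families.
#'
#' @param rec a [dollo_reconstruct()] result.
#' @param focal_species leaf name used for the retention column.
#' @return data.frame: `node`, `name`, `is_leaf`, `acquired`, `lost`,
#'   `retained_in_focal`.
#' @export
node_summary <- function(rec, focal_species = NULL) {
  stopifnot(inherits(rec, "dollo_reconstruction"))
  tree <- rec$tree
  nn <- length(tree$tip.label) + tree$Nnode
  acquired <- lost <- retained <- integer(nn)
  focal_present <- if (!is.null(focal_species)) {
    if (!focal_species %in% tree$tip.label) {
      stop("focal species not a tree leaf: ", focal_species)
    }
    rec$matrix[, focal_species] == 1L
  } else rep(FALSE, nrow(rec$matrix))
  for (fam in rec$families) {
    acquired[fam$gain] <- acquired[fam$gain] + 1L
    for (v in fam$losses) lost[v] <- lost[v] + 1L
    if (focal_present[[fam$family]]) {
      retained[fam$gain] <- retained[fam$gain] + 1L
    }
  }
  data.frame(node = seq_len(nn),
             name = node_names(tree),
             is_leaf = seq_len(nn) <= length(tree$tip.label),
             acquired = acquired, lost = lost,
             retained_in_focal = retained, stringsAsFactors = FALSE)
}
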