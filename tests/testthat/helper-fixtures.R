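# Shared fixtures and independent oracles. Everything is built in code.

# small rooted trees with named internal nodes
tree4 <- function() {
  ape::read.tree(text = "((A,B)AB,(C,D)CD)Root;")
}

tree6 <- function() {
  ape::read.tree(text = "(((A,B)AB,C)ABC,((D,E)DE,F)DEF)Root;")
}

tree8 <- function() {
  ape::read.tree(
    text = "(((A,B)AB,(C,D)CD)ABCD,((E,F)EF,(G,H)GH)EFGH)Root;")
}

# presence/absence row helper
pa_row <- function(tree, present, family = "fam1") {
  m <- matrix(0L, nrow = 1, ncol = length(tree$tip.label),
              dimnames = list(family, tree$tip.label))
  m[1, present] <- 1L
  m
}

# Independent Dollo oracle: enumerate every single-gain assignment (gain
# node ancestral to all present leaves) and every loss-branch subset, by
# increasing subset size, and return the minimum loss count that exactly
# reproduces the presence row. Exponential; small trees only.
dollo_oracle <- function(tree, present_tips) {
  par <- mirmeta:::tree_parents(tree)
  subt <- mirmeta:::subtree_tips(tree)
  nn <- length(tree$tip.label) + tree$Nnode
  best <- Inf
  best_gains <- integer(0)
  for (g in seq_len(nn)) {
    if (!all(present_tips %in% subt[[g]])) next
    below <- mirmeta:::descendants(tree, g)
    found <- FALSE
    for (k in 0:length(below)) {
      if (k >= best) break
      combos <- if (k == 0) list(integer(0)) else
        utils::combn(below, k, simplify = FALSE)
      for (loss in combos) {
        pres <- Filter(function(tip) {
          v <- tip
          while (!is.na(v) && v != g) {
            if (v %in% loss) return(FALSE)
            v <- par[v]
          }
          TRUE
        }, subt[[g]])
        if (setequal(pres, present_tips)) {
          if (k < best) {
            best <- k
            best_gains <- g
          } else if (k == best) {
            best_gains <- union(best_gains, g)
          }
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  list(min_losses = best, gains = best_gains)
}

# independent connected components by BFS over an adjacency matrix
bfs_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# tiny read table builder
make_reads <- function(seqs, phred = 35L) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = mirmeta:::phred_string(phred, nchar(seqs)),
             stringsAsFactors = FALSE)
}

ADAPTER3 <- "AGATCGGAAGAGCACACGTCT"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
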