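# Presence/absence mapping of miRNA binding sites on gene-family trees and
# Fitch small parsimony. States are binary (0 = site absent, 1 = present);
# the parsimony pass is the classic bottom-up intersection/union followed by
# a deterministic top-down resolution with ties broken toward absence.

#' Map miRNA-family target states onto tree leaves
#'
#' @param tree an `ape::phylo` tree whose tip labels are gene ids.
#' @param target_sets named list of per-gene miRNA family sets (see
#'   [target_sets()]).
#' @param families families to map; defaults to every family observed.
#' @param max_missing maximum tolerated fraction of leaves absent from
#'   `target_sets` (they get state 0 with a warning); above this, an error.
#' @return binary matrix with one row per leaf and one column per family.
#' @export
map_states <- function(tree, target_sets, families = NULL, max_missing = 0.1) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- tree$tip.label
  if (anyDuplicated(leaves)) stop("duplicate leaf labels")
  absent <- setdiff(leaves, names(target_sets))
  if (length(absent) / length(leaves) > max_missing) {
    stop(length(absent), " of ", length(leaves),
         " leaves missing from target_sets (above the ",
         round(100 * max_missing), "% threshold)")
  }
  if (length(absent)) {
    warning(length(absent), " leaf/leaves without target sets; state set to 0")
  }
  families <- families %||% sort(unique(unlist(target_sets[leaves])))
  m <- vapply(families, function(f) {
    as.integer(vapply(leaves, function(g) {
      f %in% (target_sets[[g]] %||% character(0))
    }, logical(1)))
  }, integer(length(leaves)))
  m <- matrix(m, nrow = length(leaves),
              dimnames = list(leaves, families))
  m
}

#' Fitch small parsimony for a binary character
#'
#' Returns the minimal number of state changes on the tree and one
#' most-parsimonious internal labeling (deterministic: ambiguous nodes are
#' resolved toward state 0, i.e. site absent). Non-binary trees are
#' resolved arbitrarily with zero-length branches before the pass (with a
#' message); the score is unaffected by the arbitrary resolution order for
#' the bottom-up count on a binary refinement.
#'
#' @param tree an `ape::phylo` tree (rooted; unrooted trees are rooted at
#'   the first internal node).
#' @param states binary (0/1) vector of leaf states, named by tip label or
#'   ordered as `tree$tip.label`.
#' @param method `"fitch"` (unordered, reversible; the default, since both
#'   gains and losses are plausible for binding sites) or `"dollo"` (a
#'   single gain at the ancestor of all present leaves, losses only below
#'   it).
#' @return list with `score`, `labeling` (0/1 vector over all nodes, tips
#'   first in `tip.label` order) and the tree used.
#' @export
min_changes <- function(tree, states, method = c("fitch", "dollo")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) {
    message("non-binary tree resolved arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree)
  }
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, outgroup = tree$tip.label[1],
                                               resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  if (!is.null(names(states))) {
    miss <- setdiff(tree$tip.label, names(states))
    if (length(miss)) stop("no state for leaf '", miss[1], "'")
    states <- states[tree$tip.label]
  }
  stopifnot(length(states) == ntip, all(states %in% c(0, 1)))
  if (method == "dollo") return(.dollo_changes(tree, states))
  nnode <- ntip + tree$Nnode
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  set <- integer(nnode)
  set[seq_len(ntip)] <- ifelse(states == 1, 2L, 1L)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  score <- 0L
  kids <- split(edge[, 2], edge[, 1])
  for (node in unique(edge[, 1])) {  # postorder: children before parents
    ch <- kids[[as.character(node)]]
    inter <- Reduce(bitwAnd, set[ch])
    if (inter != 0L) {
      set[node] <- inter
    } else {
      set[node] <- Reduce(bitwOr, set[ch])
      score <- score + 1L
    }
  }
  # top-down resolution, ties toward state 0 (absent)
  lab <- integer(nnode)
  root <- ntip + 1L
  lab[root] <- if (bitwAnd(set[root], 1L) != 0L) 0L else 1L
  for (i in rev(seq_len(nrow(edge)))) {  # preorder: parents before children
    parent <- edge[i, 1]; child <- edge[i, 2]
    pbit <- bitwShiftL(1L, lab[parent])
    lab[child] <- if (bitwAnd(set[child], pbit) != 0L) lab[parent]
                  else if (bitwAnd(set[child], 1L) != 0L) 0L else 1L
  }
  names(lab) <- c(tree$tip.label, rep("", tree$Nnode))
  list(score = score, labeling = lab, tree = tree)
}

# Dollo parsimony: one gain at the MRCA of all present leaves, then count
# the minimal number of losses (edges from the gained region to maximal
# all-absent clades)
.dollo_changes <- function(tree, states) {
  ntip <- length(tree$tip.label)
  present <- which(states == 1)
  lab <- integer(ntip + tree$Nnode)
  lab[seq_len(ntip)] <- as.integer(states)
  if (length(present) == 0) {
    names(lab) <- c(tree$tip.label, rep("", tree$Nnode))
    return(list(score = 0L, labeling = lab, tree = tree))
  }
  mrca <- if (length(present) == 1) present else ape::getMRCA(tree, present)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  # all-absent flag per node
  absent <- c(states == 0, rep(NA, tree$Nnode))
  kids <- split(edge[, 2], edge[, 1])
  for (node in unique(edge[, 1])) {
    absent[node] <- all(absent[kids[[as.character(node)]]])
  }
  # nodes inside the subtree rooted at the MRCA
  inside <- logical(ntip + tree$Nnode)
  inside[mrca] <- TRUE
  for (i in rev(seq_len(nrow(edge)))) {
    if (inside[edge[i, 1]]) inside[edge[i, 2]] <- TRUE
  }
  losses <- sum(inside[edge[, 1]] & !absent[edge[, 1]] & absent[edge[, 2]])
  # internal labeling: present inside the gained region unless all-absent
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  lab[internal] <- as.integer(inside[internal] & !absent[internal])
  names(lab) <- c(tree$tip.label, rep("", tree$Nnode))
  list(score = 1L + as.integer(losses), labeling = lab, tree = tree)
}

#' Parsimony summary of binding-site gains/losses per miRNA family
#'
#' @param tree an `ape::phylo` tree.
#' @param target_sets named list of per-gene family sets.
#' @param families see [map_states()].
#' @return data.frame with columns `family`, `parsimony_score`,
#'   `n_present_leaves`, `n_leaves`.
#' @export
family_parsimony <- function(tree, target_sets, families = NULL) {
  m <- map_states(tree, target_sets, families)
  rows <- lapply(colnames(m), function(f) {
    data.frame(family = f,
               parsimony_score = min_changes(tree, m[, f])$score,
               n_present_leaves = sum(m[, f]),
               n_leaves = nrow(m))
  })
  if (length(rows) == 0) {
    return(data.frame(family = character(0), parsimony_score = integer(0),
                      n_present_leaves = integer(0), n_leaves = integer(0)))
  }
  do.call(rbind, rows)
}
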