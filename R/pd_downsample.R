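#' Phylogenetic diversity of a leaf subset
#'
#' Unrooted convention: the sum of branch lengths of the minimal connected
#' subtree spanning the subset. A singleton subset has PD 0; the full leaf
#' set has PD equal to the total tree length.
#'
#' @param tree An `ape::phylo`.
#' @param leaf_subset Character vector of tip labels (>= 1).
#' @return Total spanned branch length.
#' @export
phylogenetic_diversity <- function(tree, leaf_subset) {
  unknown <- setdiff(leaf_subset, tree$tip.label)
  if (length(unknown)) stop("unknown leaf id(s): ", paste(unknown, collapse = ", "))
  if (length(leaf_subset) < 1L) stop("leaf_subset must be non-empty")
  if (length(leaf_subset) == 1L) return(0)
  # an edge is spanned iff the subset has leaves on both sides of it
  below <- descendant_tips(tree)
  sel <- match(leaf_subset, tree$tip.label)
  nsel <- length(sel)
  spanned <- vapply(seq_len(nrow(tree$edge)), function(e) {
    k <- sum(below[[tree$edge[e, 2]]] %in% sel)
    k > 0L && k < nsel
  }, logical(1))
  sum(tree$edge.length[spanned])
}

#' Greedy maximum-phylogenetic-diversity leaf selection
#'
#' Initializes with the leaf pair of maximal path distance (ties broken by
#' lexicographic leaf id), then repeatedly adds the leaf whose attachment
#' path to the current spanned subtree is longest. For the PD objective
#' this greedy procedure attains the optimum over all size-`k` subsets.
#'
#' @param tree An `ape::phylo` (>= 2 leaves).
#' @param k Target subset size (>= 2; `k >= n` returns all leaves).
#' @return An object of class `pd_selection`: list with `kept_ids` and
#'   `pd_score` (branch length of the spanned subtree).
#' @export
greedy_max_pd <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k >= n) {
    return(structure(list(kept_ids = sort(tree$tip.label),
                          pd_score = sum(tree$edge.length)),
                     class = "pd_selection"))
  }
  if (k < 2L) stop("k must be >= 2")
  # work on a tree rooted at the lexicographically preferred endpoint of
  # the maximal-distance pair, so the spanned subtree always contains the
  # root and attachment paths run strictly upward
  labs_sorted <- sort(tree$tip.label)
  dm <- ape::cophenetic.phylo(tree)[labs_sorted, labs_sorted]
  idx <- which(dm == max(dm), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  a <- labs_sorted[idx[1, 1]]; b <- labs_sorted[idx[1, 2]]
  wt <- ape::root(ape::unroot(tree), outgroup = a, resolve.root = TRUE)
  ntip <- length(wt$tip.label)
  nn <- ntip + wt$Nnode
  parent <- integer(nn); elen <- numeric(nn)
  for (e in seq_len(nrow(wt$edge))) {
    parent[wt$edge[e, 2]] <- wt$edge[e, 1]
    elen[wt$edge[e, 2]] <- wt$edge.length[e]
  }
  root <- ntip + 1L
  pre_nodes <- ape::reorder.phylo(wt, "postorder")$edge[, 2]
  pre_nodes <- rev(pre_nodes)                       # parents before children
  marked <- rep(FALSE, nn)
  marked[root] <- TRUE
  mark_path <- function(leaf, marked) {
    v <- leaf; added <- 0
    while (!marked[v]) {
      marked[v] <- TRUE
      added <- added + elen[v]
      v <- parent[v]
    }
    list(marked = marked, added = added)
  }
  pd <- 0
  # seed with the initial pair
  for (lf in c(a, b)) {
    res <- mark_path(match(lf, wt$tip.label), marked)
    marked <- res$marked; pd <- pd + res$added
  }
  kept <- c(a, b)
  leaf_idx <- setNames(seq_len(ntip), wt$tip.label)
  cand_order <- sort(setdiff(wt$tip.label, kept))    # lexicographic tie-break
  d <- numeric(nn)
  while (length(kept) < k) {
    # distance from every node up to the marked subtree
    d[root] <- 0
    for (v in pre_nodes) {
      d[v] <- if (marked[v]) 0 else d[parent[v]] + elen[v]
    }
    inc <- d[leaf_idx[cand_order]]
    best <- cand_order[which.max(inc)]
    res <- mark_path(leaf_idx[best], marked)
    marked <- res$marked; pd <- pd + res$added
    kept <- c(kept, best)
    cand_order <- setdiff(cand_order, best)
  }
  structure(list(kept_ids = sort(kept), pd_score = pd),
            class = "pd_selection")
}

#' @export
print.pd_selection <- function(x, ...) {
  cat("PD selection:", length(x$kept_ids), "leaves, spanned length",
      format(x$pd_score), "\n")
  invisible(x)
}

#' Downsample a database by phylogenetic diversity, per group
#'
#' Exempt groups pass through untouched. Every other group whose record
#' count exceeds its cap is reduced to the cap by [greedy_max_pd()] on its
#' guide tree; groups at or below their cap are untouched.
#'
#' @param db A [protein_db()].
#' @param per_group_trees Named list of guide trees (`ape::phylo`), one
#'   per over-cap group, whose tips cover the group's record ids.
#' @param caps Named numeric vector mapping group -> cap. Groups without a
#'   cap entry are untouched.
#' @param exempt Character vector of exempt group names.
#' @return The downsampled [protein_db()] (original record order).
#' @export
downsample_groups <- function(db, per_group_trees = list(), caps = numeric(0),
                              exempt = character(0)) {
  keep <- rep(TRUE, nrow(db))
  for (grp in names(caps)) {
    if (grp %in% exempt) next
    members <- which(db$group == grp)
    cap <- caps[[grp]]
    if (length(members) <= cap) next
    tr <- per_group_trees[[grp]]
    if (is.null(tr)) stop("no guide tree for over-cap group: ", grp)
    missing_tips <- setdiff(db$id[members], tr$tip.label)
    if (length(missing_tips)) {
      stop("guide tree for group ", grp, " does not cover: ",
           paste(head(missing_tips, 5), collapse = ", "))
    }
    sel <- greedy_max_pd(ape::keep.tip(tr, db$id[members]), cap)
    keep[members] <- db$id[members] %in% sel$kept_ids
  }
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(db)
  out
}
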