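#' Supported clades of one tree
#'
#' Returns one entry per internal node whose support is strictly greater
#' than `min_support` and whose descendant leaf count is at least
#' `min_size`. The tree must be rooted, or an outgroup must be supplied to
#' root it; with neither, bipartitions are used as a fallback (each
#' split's smaller side treated as the clade) with a message.
#'
#' @param tree `ape::phylo` with supports in `node.label` (percent scale).
#' @param min_support Strict support threshold (default 70).
#' @param min_size Minimum clade size, inclusive (default 100).
#' @param outgroup Optional character vector of outgroup tip labels used
#'   to root an unrooted tree.
#' @return List of clades, each `list(leaves, support)`; the tree's leaf
#'   universe is attached as `attr(, "universe")`.
#' @export
supported_clades <- function(tree, min_support = 70, min_size = 100,
                             outgroup = NULL) {
  use_bipartitions <- FALSE
  if (!ape::is.rooted(tree)) {
    if (!is.null(outgroup)) {
      og <- intersect(outgroup, tree$tip.label)
      if (length(og) == 0L) stop("outgroup labels not found in tree")
      tree <- root_on_outgroup(tree, og)
    } else {
      message("unrooted tree with no outgroup: using bipartitions ",
              "(smaller side of each split)")
      use_bipartitions <- TRUE
    }
  }
  ntip <- length(tree$tip.label)
  sup <- tree_supports(tree)
  # the two children of the root carry the same bipartition; if only one
  # side has a support label (usual after outgroup rooting), share it
  root_children <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
  rci <- root_children[root_children > ntip] - ntip
  if (length(rci) == 2L && sum(is.na(sup[rci])) == 1L) {
    sup[rci[is.na(sup[rci])]] <- sup[rci[!is.na(sup[rci])]]
  }
  below <- descendant_tips(tree)
  out <- list()
  for (nd in seq_len(tree$Nnode)) {
    node <- ntip + nd
    leaves <- tree$tip.label[below[[node]]]
    if (use_bipartitions && length(leaves) > ntip / 2) {
      leaves <- setdiff(tree$tip.label, leaves)
    }
    if (length(leaves) < min_size || length(leaves) == ntip) next
    if (is.na(sup[nd]) || sup[nd] <= min_support) next
    out[[length(out) + 1L]] <- list(leaves = sort(leaves), support = sup[nd])
  }
  attr(out, "universe") <- sort(tree$tip.label)
  out
}

# Root an unrooted tree on the split separating the outgroup from the
# rest. Whichever side of the split forms a subtree in the tree's current
# arbitrary representation is usable as ape's outgroup argument; if the
# outgroup is not a split at all (e.g. broken in one replicate), fall
# back to rooting on its first member's pendant edge.
root_on_outgroup <- function(tree, og) {
  labs <- tree$tip.label
  comp <- setdiff(labs, og)
  below <- descendant_tips(tree)
  is_subtree <- function(side) {
    idx <- match(side, labs)
    any(vapply(below, function(b) length(b) == length(idx) &&
                 setequal(b, idx), logical(1)))
  }
  for (side in list(og, comp)) {
    if (length(side) >= 1L && is_subtree(side)) {
      return(ape::root(tree, outgroup = side, resolve.root = TRUE,
                       edgelabel = TRUE))
    }
  }
  ape::root(tree, outgroup = og[1], resolve.root = TRUE, edgelabel = TRUE)
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Match supported clades across replicate trees
#'
#' Candidates are the union of supported clades over all trees. For a
#' candidate from tree `t0` and each tree `t`, the best match is the
#' supported clade of `t` maximizing Jaccard similarity with the
#' candidate (ties: higher support, then smaller clade, then
#' lexicographic by member ids). The candidate is reproduced in `t` iff
#' the best-match Jaccard is >= `j_min`; it survives iff it is reproduced
#' in >= `min_trees` trees (its own tree counts itself). Candidates with
#' identical leaf sets are merged.
#'
#' @param clade_lists List (one per tree) of [supported_clades()] outputs.
#' @param j_min Jaccard threshold for "found in" a tree (default 0.5).
#' @param min_trees Minimum number of reproducing trees (default 3).
#' @return List of surviving candidates, each
#'   `list(leaves, source_tree, matches)` where `matches` is a per-tree
#'   list `list(clade, jaccard, support, reproduced)`.
#' @export
match_across_trees <- function(clade_lists, j_min = 0.5, min_trees = 3L) {
  n_trees <- length(clade_lists)
  universes <- lapply(clade_lists, attr, "universe")
  for (t in seq_len(n_trees)) {
    if (!setequal(universes[[1]], universes[[t]])) {
      diff <- c(setdiff(universes[[1]], universes[[t]]),
                setdiff(universes[[t]], universes[[1]]))
      stop("trees have different leaf universes; symmetric difference: ",
           paste(head(diff, 10), collapse = ", "))
    }
  }
  cands <- list(); seen <- character(0)
  for (t0 in seq_len(n_trees)) {
    for (cl in clade_lists[[t0]]) {
      key <- paste(cl$leaves, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- list(leaves = cl$leaves, source_tree = t0)
    }
  }
  out <- list()
  for (cand in cands) {
    matches <- vector("list", n_trees)
    n_rep <- 0L
    for (t in seq_len(n_trees)) {
      best <- NULL
      for (cl in clade_lists[[t]]) {
        j <- jaccard(cand$leaves, cl$leaves)
        if (is.null(best)) { best <- cl; best$j <- j; next }
        better <- j > best$j ||
          (j == best$j && (cl$support > best$support ||
             (cl$support == best$support &&
                (length(cl$leaves) < length(best$leaves) ||
                   (length(cl$leaves) == length(best$leaves) &&
                      paste(cl$leaves, collapse = "\r") <
                        paste(best$leaves, collapse = "\r"))))))
        if (better) { best <- cl; best$j <- j }
      }
      if (is.null(best)) {
        matches[[t]] <- list(clade = character(0), jaccard = 0,
                             support = NA_real_, reproduced = FALSE)
      } else {
        matches[[t]] <- list(clade = best$leaves, jaccard = best$j,
                             support = best$support,
                             reproduced = best$j >= j_min)
      }
      if (matches[[t]]$reproduced) n_rep <- n_rep + 1L
    }
    if (n_rep >= min_trees) {
      out[[length(out) + 1L]] <- list(leaves = cand$leaves,
                                      source_tree = cand$source_tree,
                                      matches = matches, n_reproduced = n_rep)
    }
  }
  attr(out, "universe") <- universes[[1]]
  attr(out, "min_trees") <- min_trees
  out
}

#' Prune candidate members lacking cross-tree co-support
#'
#' A member is retained iff it belongs to the candidate's matched
#' supported clade in at least `min_trees` of the reproducing trees (the
#' candidate's own tree counts itself).
#'
#' @param candidate One element of [match_across_trees()] output.
#' @param min_trees Minimum number of trees (default 3).
#' @return Character vector of retained member ids.
#' @export
prune_members <- function(candidate, min_trees = 3L) {
  counts <- setNames(integer(length(candidate$leaves)), candidate$leaves)
  for (m in candidate$matches) {
    if (!m$reproduced) next
    inm <- candidate$leaves %in% m$clade
    counts[inm] <- counts[inm] + 1L
  }
  sort(names(counts)[counts >= min_trees])
}

#' Report consensus clades
#'
#' Applies the pruning rule to every surviving candidate, keeps candidates
#' whose retained member count is strictly greater than `min_retained`,
#' merges identical retained sets, and sorts by retained size
#' (descending; ties by mean support then smallest member id). Nesting
#' relations among reported clades are recorded; with `disjoint = TRUE`
#' clades are accepted in order and any clade sharing a member with an
#' accepted one is discarded. Leaves in no reported clade are listed as
#' unassigned.
#'
#' @param candidates Output of [match_across_trees()].
#' @param min_retained Strict minimum retained size (default 20).
#' @param min_trees Passed to [prune_members()].
#' @param disjoint Apply the disjoint post-filter (default `FALSE`).
#' @return An object of class `tir_clades`: list with `clades` (each
#'   `list(clade_id, retained, n_retained, mean_support, n_reproduced,
#'   per_tree, nested_in)`), and `unassigned`.
#' @export
report_clades <- function(candidates, min_retained = 20L, min_trees = 3L,
                          disjoint = FALSE) {
  recs <- list(); seen <- character(0)
  for (cand in candidates) {
    retained <- prune_members(cand, min_trees = min_trees)
    if (length(retained) <= min_retained) next
    key <- paste(retained, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    sups <- vapply(cand$matches, function(m)
      if (m$reproduced) m$support else NA_real_, numeric(1))
    recs[[length(recs) + 1L]] <- list(
      retained = retained, n_retained = length(retained),
      mean_support = mean(sups, na.rm = TRUE),
      n_reproduced = cand$n_reproduced,
      per_tree = lapply(cand$matches, function(m)
        list(jaccard = m$jaccard, support = m$support,
             reproduced = m$reproduced, members = m$clade)))
  }
  if (length(recs)) {
    ord <- order(-vapply(recs, `[[`, 0L, "n_retained"),
                 -vapply(recs, `[[`, 0, "mean_support"),
                 vapply(recs, function(r) r$retained[1], character(1)))
    recs <- recs[ord]
  }
  if (disjoint && length(recs)) {
    used <- character(0); keep <- logical(length(recs))
    for (i in seq_along(recs)) {
      if (!any(recs[[i]]$retained %in% used)) {
        keep[i] <- TRUE
        used <- c(used, recs[[i]]$retained)
      }
    }
    recs <- recs[keep]
  }
  for (i in seq_along(recs)) {
    recs[[i]]$clade_id <- sprintf("clade_%02d", i)
    recs[[i]]$nested_in <- NA_character_
  }
  # nesting: the smallest strictly containing reported clade
  for (i in seq_along(recs)) {
    best <- NA_character_; best_size <- Inf
    for (j in seq_along(recs)) {
      if (i == j) next
      if (all(recs[[i]]$retained %in% recs[[j]]$retained) &&
          recs[[j]]$n_retained > recs[[i]]$n_retained &&
          recs[[j]]$n_retained < best_size) {
        best <- recs[[j]]$clade_id; best_size <- recs[[j]]$n_retained
      }
    }
    recs[[i]]$nested_in <- best
  }
  universe <- attr(candidates, "universe")
  assigned <- unique(unlist(lapply(recs, `[[`, "retained")))
  structure(list(clades = recs,
                 unassigned = sort(setdiff(universe, assigned))),
            class = "tir_clades")
}

#' @export
print.tir_clades <- function(x, ...) {
  cat("Consensus clades:", length(x$clades), "reported;",
      length(x$unassigned), "unassigned leaves\n")
  for (cl in x$clades) {
    cat(sprintf("  %s: %d members, mean support %.1f, %d/%d trees%s\n",
                cl$clade_id, cl$n_retained, cl$mean_support,
                cl$n_reproduced, length(cl$per_tree),
                if (!is.na(cl$nested_in)) paste0(" (within ", cl$nested_in, ")")
                else ""))
  }
  invisible(x)
}

#' Consensus clades across replicate trees (wrapper)
#'
#' Chains [supported_clades()], [match_across_trees()] and
#' [report_clades()] over a list of replicate trees.
#'
#' @param trees List of `ape::phylo` trees over the same leaf universe.
#' @param min_support,min_size Per-tree supported-clade thresholds.
#' @param j_min,min_trees Cross-tree matching thresholds.
#' @param min_retained Strict minimum retained clade size.
#' @param outgroup Optional outgroup tip labels for rooting.
#' @param disjoint Apply the disjoint post-filter.
#' @return A `tir_clades` object.
#' @export
consensus_clades <- function(trees, min_support = 70, min_size = 100,
                             j_min = 0.5, min_trees = 3L, min_retained = 20L,
                             outgroup = NULL, disjoint = FALSE) {
  clade_lists <- lapply(trees, supported_clades, min_support = min_support,
                        min_size = min_size, outgroup = outgroup)
  cands <- match_across_trees(clade_lists, j_min = j_min, min_trees = min_trees)
  report_clades(cands, min_retained = min_retained, min_trees = min_trees,
                disjoint = disjoint)
}
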