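#' Dollo reconstruction of a gene family's origin and losses
#'
#' Imposes a single gain (the family originates once, at the most recent
#' common ancestor of the species carrying it) and finds the minimal set
#' of loss branches explaining all absences: a branch is a loss iff its
#' subtree contains no present species while its parent lineage is
#' inferred present.
#'
#' @param species_tree Rooted `ape::phylo`.
#' @param presence Named logical/0-1 vector over the tree's tip labels.
#' @return An object of class `gainloss`: list with `origin` (node id),
#'   `origin_label`, `loss_branches` (child-node ids), `n_losses`,
#'   `present_nodes` (node ids inferred present).
#' @export
dollo_reconstruct <- function(species_tree, presence) {
  tr <- species_tree
  ntip <- length(tr$tip.label)
  pv <- as.logical(presence[tr$tip.label])
  if (anyNA(pv)) stop("presence vector must cover every species in the tree")
  if (!any(pv)) stop("no-origin error: family absent from every species")
  present_tips <- which(pv)
  origin <- if (length(present_tips) == 1L) present_tips else
    ape::getMRCA(tr, tr$tip.label[present_tips])
  below <- descendant_tips(tr)
  # nodes inside the origin subtree
  in_origin <- vapply(seq_len(ntip + tr$Nnode), function(v)
    all(below[[v]] %in% below[[origin]]) && length(below[[v]]) > 0L, logical(1))
  in_origin[origin] <- TRUE
  # a node is "occupied" iff its subtree contains a present species
  occupied <- vapply(seq_len(ntip + tr$Nnode), function(v)
    any(pv[below[[v]]]), logical(1))
  parent <- integer(ntip + tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) parent[tr$edge[e, 2]] <- tr$edge[e, 1]
  # loss on the branch above v iff v is unoccupied but its parent is an
  # occupied node inside the origin subtree (parent inferred present)
  loss <- which(vapply(seq_len(ntip + tr$Nnode), function(v) {
    v != origin && in_origin[v] && !occupied[v] &&
      parent[v] != 0L && in_origin[parent[v]] && occupied[parent[v]]
  }, logical(1)))
  present_nodes <- which(in_origin & occupied)
  structure(list(origin = origin,
                 origin_label = if (origin <= ntip) tr$tip.label[origin]
                                else paste0("node", origin),
                 loss_branches = loss, n_losses = length(loss),
                 present_nodes = present_nodes, tree = tr),
            class = "gainloss")
}

#' @export
print.gainloss <- function(x, ...) {
  cat("Dollo reconstruction: origin at", x$origin_label, "with",
      x$n_losses, "loss(es)\n")
  invisible(x)
}

#' Minimal-event duplication/loss counting from gene counts
#'
#' Integer parsimony over per-node copy-number states (dynamic
#' programming, unit cost per +/-1 change along a branch). Duplications
#' are the total positive increments excluding the single origin gain;
#' losses the total decrements. Ties are resolved toward later
#' (tip-ward) events: the root takes the smallest minimal state, and each
#' child takes the state closest to its parent's (smaller on ties).
#'
#' @param species_tree Rooted `ape::phylo`.
#' @param counts Named nonnegative integer vector over tip labels
#'   (max 10).
#' @param max_state Largest copy number considered (defaults to the
#'   observed maximum).
#' @return List with `n_duplications`, `n_losses`, `node_states` (per
#'   node inferred count), `total_cost`.
#' @export
count_parsimony <- function(species_tree, counts, max_state = NULL) {
  tr <- species_tree
  ntip <- length(tr$tip.label)
  cv <- as.integer(counts[tr$tip.label])
  if (anyNA(cv) || any(cv < 0L)) stop("counts must be nonnegative over all species")
  if (max(cv) > 10L) stop("counts above 10 are not supported")
  S <- if (is.null(max_state)) max(cv, 1L) else as.integer(max_state)
  states <- 0:S
  nn <- ntip + tr$Nnode
  cost <- matrix(Inf, nn, S + 1L)
  for (i in seq_len(ntip)) cost[i, ] <- ifelse(states == cv[i], 0, Inf)
  po <- ape::reorder.phylo(tr, "postorder")
  children <- split(po$edge[, 2], po$edge[, 1])
  for (p in unique(po$edge[, 1])) {
    acc <- numeric(S + 1L)
    for (ch in children[[as.character(p)]]) {
      # min over child state of cost[ch, s_c] + |s_p - s_c|
      best <- vapply(states, function(sp)
        min(cost[ch, ] + abs(sp - states)), numeric(1))
      acc <- acc + best
    }
    cost[p, ] <- acc
  }
  root <- ntip + 1L
  node_states <- integer(nn)
  node_states[root] <- states[which.min(cost[root, ])]  # smallest on ties
  pre_nodes <- rev(po$edge[, 2])
  parent <- integer(nn)
  for (e in seq_len(nrow(tr$edge))) parent[tr$edge[e, 2]] <- tr$edge[e, 1]
  for (v in pre_nodes) {
    sp <- node_states[parent[v]]
    tot <- cost[v, ] + abs(sp - states)
    best <- min(tot)
    # closest to the parent state on ties (pushes events tip-ward),
    # smaller state if still tied
    cand <- states[tot == best]
    node_states[v] <- cand[order(abs(cand - sp), cand)][1]
  }
  inc <- 0L; dec <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    d <- node_states[tr$edge[e, 2]] - node_states[tr$edge[e, 1]]
    if (d > 0L) inc <- inc + d else dec <- dec - d
  }
  gains_total <- inc + node_states[root]
  n_dup <- if (any(cv > 0L)) gains_total - 1L else 0L
  list(n_duplications = n_dup, n_losses = dec,
       node_states = setNames(node_states,
                              c(tr$tip.label, paste0("node", (ntip + 1L):nn))),
       total_cost = min(cost[root, ]))
}

#' Recover simulated gain/loss histories
#'
#' Applies [dollo_reconstruct()] to each family of a simulated
#' presence/absence history and compares against the generator's truth.
#' Parsimony is a lower bound on the true event count: the inferred loss
#' count equals the simulated one when the simulated losses are
#' phylogenetically independent, and can be smaller when losses are
#' collapsible (e.g. two sister losses explained by one deeper loss).
#' The inferred origin equals the true origin whenever the true losses do
#' not sever the MRCA of the surviving species (flagged otherwise).
#'
#' @param species_tree Rooted `ape::phylo`.
#' @param sims List of [simulate_presence_matrix()] results.
#' @return Data frame with one row per family: inferred origin, true
#'   origin, `origin_recovered`, inferred and true loss counts.
#' @export
recover_simulated_history <- function(species_tree, sims) {
  rows <- lapply(sims, function(sim) {
    gl <- dollo_reconstruct(species_tree, sim$counts > 0L)
    data.frame(family = sim$family,
               origin = gl$origin, true_origin = sim$truth$origin,
               origin_recovered = gl$origin == sim$truth$origin,
               n_losses = gl$n_losses,
               true_losses = length(sim$truth$losses),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
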