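#' Simulation configuration
#'
#' Defines the study conditions for the synthetic atlas: a set of divergent
#' domain families ("clades") evolved from a common root ancestor, embedded
#' in host proteins with random flanks, plus composition-matched decoys.
#' Defaults are the desk-scale profile the package is exercised on:
#' 6 clades x 40 sequences with 600 decoys.
#'
#' @param n_clades Number of domain families (>= 1).
#' @param seqs_per_clade Sequences per family.
#' @param domain_length Ancestral domain length in residues (>= 20).
#' @param subst_rate Expected substitutions per site per unit branch length.
#' @param indel_rate Expected indel events per site per unit branch length.
#' @param flank_length_range Min/max host-flank length (residues).
#' @param n_decoys Number of residue-shuffled decoy records.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_clades = 6L, seqs_per_clade = 40L, domain_length = 120L,
                       subst_rate = 0.05, indel_rate = 0.002,
                       flank_length_range = c(30L, 80L), n_decoys = 600L,
                       seed = 1L) {
  cfg <- list(n_clades = as.integer(n_clades),
              seqs_per_clade = as.integer(seqs_per_clade),
              domain_length = as.integer(domain_length),
              subst_rate = as.numeric(subst_rate),
              indel_rate = as.numeric(indel_rate),
              flank_length_range = as.integer(flank_length_range),
              n_decoys = as.integer(n_decoys),
              seed = as.integer(seed))
  if (cfg$n_clades < 1L) stop("invalid config: n_clades must be >= 1")
  if (cfg$seqs_per_clade < 1L) stop("invalid config: seqs_per_clade must be >= 1")
  if (cfg$domain_length < 20L) stop("invalid config: domain_length must be >= 20")
  if (cfg$subst_rate < 0 || cfg$indel_rate < 0) {
    stop("invalid config: rates must be nonnegative")
  }
  if (length(cfg$flank_length_range) != 2L ||
      any(cfg$flank_length_range < 0L) ||
      cfg$flank_length_range[1] > cfg$flank_length_range[2]) {
    stop("invalid config: flank_length_range must be 0 <= min <= max")
  }
  if (cfg$n_decoys < 0L) stop("invalid config: n_decoys must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Intra-clade branch lengths are U(0.5, 1.5) (mean 1); inter-clade backbone
# branches are fixed at 10, i.e. 10x the intra-clade mean, which keeps the
# planted families well separated (spec of the generator: >= 5x).
INTRA_BL <- c(0.5, 1.5)
INTER_BL <- 10

# Random rooted binary tree over the given labels, returned as a Newick
# fragment (no trailing ";"). Joins random subtree pairs; branch lengths
# drawn U(INTRA_BL).
rand_subtree_newick <- function(labels) {
  frags <- labels
  while (length(frags) > 1L) {
    pick <- sample.int(length(frags), 2L)
    bl <- runif(2L, INTRA_BL[1], INTRA_BL[2])
    merged <- sprintf("(%s:%.6f,%s:%.6f)", frags[pick[1]], bl[1],
                      frags[pick[2]], bl[2])
    frags <- c(frags[-pick], merged)
  }
  frags
}

#' Simulate the family tree of the synthetic atlas
#'
#' A rooted binary tree whose leaves fall into `n_clades` monophyletic
#' groups (labels `c<i>_s<j>`) separated by long internal branches
#' (backbone branch length 10 vs intra-clade mean 1).
#'
#' @param cfg A [sim_config()].
#' @return An `ape::phylo` rooted binary tree.
#' @export
simulate_family_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  clades <- lapply(seq_len(cfg$n_clades), function(i) {
    rand_subtree_newick(sprintf("c%d_s%d", i, seq_len(cfg$seqs_per_clade)))
  })
  if (cfg$n_clades == 1L) {
    if (cfg$seqs_per_clade == 1L) {
      nwk <- sprintf("(%s:%.6f);", clades[[1]], INTER_BL)
    } else {
      nwk <- paste0(clades[[1]], ";")
    }
  } else {
    t <- sprintf("%s:%.6f", clades[[1]], INTER_BL)
    for (i in 2:cfg$n_clades) {
      t <- sprintf("(%s,%s:%.6f)", t, clades[[i]], INTER_BL)
      if (i < cfg$n_clades) t <- sprintf("%s:%.6f", t, INTER_BL)
    }
    nwk <- paste0(t, ";")
  }
  ape::read.tree(text = nwk)
}

# Draw a random amino-acid index vector from the canonical background.
random_aa <- function(n) {
  sample.int(20L, n, replace = TRUE, prob = AA_BACKGROUND)
}

# Evolve a (residues, root-column) state along one branch. Substitutions
# are uniform over the 19 alternatives; indel events are geometric length
# (mean 2), insertion or deletion with equal probability. Inserted
# residues carry root-column 0 (no homologous ancestor column).
evolve_branch <- function(state, bl, cfg) {
  res <- state$res
  col <- state$col
  L <- length(res)
  nsub <- rpois(1L, cfg$subst_rate * bl * L)
  if (nsub > 0L) {
    pos <- sample.int(L, nsub, replace = TRUE)
    for (p in pos) {
      res[p] <- sample(setdiff(seq_len(20L), res[p]), 1L)
    }
  }
  nind <- rpois(1L, cfg$indel_rate * bl * L)
  for (k in seq_len(nind)) {
    len <- 1L + rgeom(1L, 0.5)
    if (runif(1) < 0.5 && length(res) - len >= 20L) {     # deletion
      start <- sample.int(length(res) - len + 1L, 1L)
      keep <- setdiff(seq_along(res), start:(start + len - 1L))
      res <- res[keep]; col <- col[keep]
    } else {                                              # insertion
      at <- sample.int(length(res) + 1L, 1L)
      res <- append(res, random_aa(len), after = at - 1L)
      col <- append(col, rep(0L, len), after = at - 1L)
    }
  }
  list(res = res, col = col)
}

#' Evolve domain sequences down the family tree
#'
#' A root ancestor is drawn from the canonical background and evolved along
#' every branch by Poisson substitutions (uniform over the 19 alternatives)
#' and geometric-length indels, both scaled by branch length. Each clade's
#' ancestral domain (the state at the clade root) is recorded, and each
#' leaf sequence carries its residue-to-root-column homology map so a true
#' multiple alignment can be reconstructed.
#'
#' @param tree Tree from [simulate_family_tree()].
#' @param cfg The same [sim_config()].
#' @return An object of class `tir_domains`: list with `db` (domain-only
#'   [protein_db()]), `truth` (record_id, clade), `cols` (per-record
#'   root-column maps), `clade_ancestors`, `root_ancestor`.
#' @export
evolve_domain_sequences <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- list(res = random_aa(cfg$domain_length),
                         col = seq_len(cfg$domain_length))
  pre <- preorder_edges(tree)
  for (e in seq_len(nrow(tree$edge))) {
    ei <- pre[e]
    parent <- tree$edge[ei, 1]; child <- tree$edge[ei, 2]
    states[[child]] <- evolve_branch(states[[parent]], tree$edge.length[ei], cfg)
  }
  leaves <- tree$tip.label
  seqs <- vapply(seq_len(ntip), function(i) decode_aa(states[[i]]$res), character(1))
  cols <- lapply(seq_len(ntip), function(i) states[[i]]$col)
  names(cols) <- leaves
  clade <- sub("^c(\\d+)_.*$", "\\1", leaves)
  # per-clade ancestor = state at the clade's MRCA
  anc <- vapply(sort(unique(as.integer(clade))), function(ci) {
    members <- leaves[clade == as.character(ci)]
    node <- if (length(members) == 1L) match(members, leaves)
            else ape::getMRCA(tree, members)
    decode_aa(states[[node]]$res)
  }, character(1))
  names(anc) <- paste0("clade", sort(unique(as.integer(clade))))
  out <- list(db = protein_db(leaves, seqs),
              truth = data.frame(record_id = leaves,
                                 clade = paste0("clade", clade),
                                 stringsAsFactors = FALSE),
              cols = cols,
              clade_ancestors = anc,
              root_ancestor = decode_aa(states[[root]]$res))
  class(out) <- "tir_domains"
  out
}

# Edge indices of a phylo tree in preorder (root-to-tip) order.
preorder_edges <- function(tree) {
  rt <- ape::reorder.phylo(tree, "postorder")
  # reversed postorder = parents before children; map back to the
  # original edge indices
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  match(rev(paste(rt$edge[, 1], rt$edge[, 2])), key)
}

#' True multiple alignment of simulated domain sequences
#'
#' Reconstructs the alignment implied by the generator's homology
#' bookkeeping: one column per root-ancestor position (insertions relative
#' to the root ancestor are dropped).
#'
#' @param domains A `tir_domains` object.
#' @param ids Optional subset of record ids (default all).
#' @return An [msa()].
#' @export
true_alignment <- function(domains, ids = NULL) {
  stopifnot(inherits(domains, "tir_domains"))
  if (is.null(ids)) ids <- domains$db$id
  L <- nchar(domains$root_ancestor)
  rows <- vapply(ids, function(id) {
    res <- strsplit(domains$db$sequence[domains$db$id == id], "")[[1]]
    col <- domains$cols[[id]]
    row <- rep("-", L)
    keep <- col > 0L
    row[col[keep]] <- res[keep]
    paste0(row, collapse = "")
  }, character(1))
  msa(ids, unname(rows))
}

#' Embed domains in host proteins and add decoys
#'
#' Each domain is flanked left and right by random-composition host
#' sequence with lengths drawn uniformly from `flank_length_range`.
#' Decoys are residue-shuffled copies of randomly chosen embedded records
#' (composition preserved, no planted domain). Clades are assigned
#' taxonomic-group labels cyclically from the standard atlas groups.
#'
#' @param domains A `tir_domains` object.
#' @param cfg The same [sim_config()].
#' @return An object of class `tir_sim`: list with `db` (full-length
#'   [protein_db()]), `truth` (record_id, clade, dom_start, dom_end;
#'   1-based inclusive, `NA` for decoys), and the source `domains`.
#' @export
embed_domains <- function(domains, cfg) {
  stopifnot(inherits(domains, "tir_domains"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  groups <- c("Metazoa", "Amoebozoa", "other-eukaryote", "Bacteria", "Archaea")
  fr <- cfg$flank_length_range
  n <- nrow(domains$db)
  left <- sample(seq(fr[1], fr[2]), n, replace = TRUE)
  right <- sample(seq(fr[1], fr[2]), n, replace = TRUE)
  seqs <- character(n); starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    dom <- domains$db$sequence[i]
    seqs[i] <- paste0(decode_aa(random_aa(left[i])), dom,
                      decode_aa(random_aa(right[i])))
    starts[i] <- left[i] + 1L
    ends[i] <- left[i] + nchar(dom)
  }
  clade_no <- as.integer(sub("^clade", "", domains$truth$clade))
  grp <- groups[((clade_no - 1L) %% length(groups)) + 1L]
  ids <- domains$db$id
  # decoys: shuffle residues of randomly chosen embedded records
  dseqs <- character(cfg$n_decoys)
  if (cfg$n_decoys > 0L) {
    src <- sample.int(n, cfg$n_decoys, replace = TRUE)
    for (j in seq_len(cfg$n_decoys)) {
      ch <- strsplit(seqs[src[j]], "")[[1]]
      dseqs[j] <- paste0(sample(ch), collapse = "")
    }
  }
  dids <- if (cfg$n_decoys > 0L) sprintf("decoy_%04d", seq_len(cfg$n_decoys)) else character(0)
  dgrp <- if (cfg$n_decoys > 0L) groups[((seq_len(cfg$n_decoys) - 1L) %% length(groups)) + 1L] else character(0)
  db <- protein_db(c(ids, dids), c(seqs, dseqs),
                   taxon = c(paste("synthetic", domains$truth$clade),
                             rep("synthetic decoy", cfg$n_decoys)),
                   group = c(grp, dgrp))
  truth <- data.frame(
    record_id = c(ids, dids),
    clade = c(domains$truth$clade, rep("decoy", cfg$n_decoys)),
    dom_start = c(starts, rep(NA_integer_, cfg$n_decoys)),
    dom_end = c(ends, rep(NA_integer_, cfg$n_decoys)),
    stringsAsFactors = FALSE)
  out <- list(db = db, truth = truth, domains = domains)
  class(out) <- "tir_sim"
  out
}

#' @export
print.tir_sim <- function(x, ...) {
  npl <- sum(x$truth$clade != "decoy")
  cat("Synthetic atlas db:", nrow(x$db), "records (", npl, "planted domains,",
      sum(x$truth$clade == "decoy"), "decoys )\n")
  invisible(x)
}

#' Simulate a full synthetic atlas
#'
#' Convenience wrapper chaining [simulate_family_tree()],
#' [evolve_domain_sequences()] and [embed_domains()].
#'
#' @param cfg A [sim_config()].
#' @return A `tir_sim` object with the family `tree` attached.
#' @export
simulate_atlas <- function(cfg = sim_config()) {
  tree <- simulate_family_tree(cfg)
  domains <- evolve_domain_sequences(tree, cfg)
  sim <- embed_domains(domains, cfg)
  sim$tree <- tree
  # the first family is designated the known outgroup set (the curated
  # outgroup records an analyst supplies for rooting, not a discovery)
  sim$outgroup_ids <- sim$truth$record_id[sim$truth$clade == "clade1"]
  sim
}

#' Seed alignments for the iterative search
#'
#' Builds one seed alignment per planted family from the true alignment of
#' its first `n_seed` members, restricted to columns with at least one
#' residue among the chosen members.
#'
#' @param sim A `tir_sim` object.
#' @param n_seed Members per seed alignment.
#' @return Named list of [msa()] objects (one per clade, in clade order).
#' @export
seed_alignments <- function(sim, n_seed = 5L) {
  stopifnot(inherits(sim, "tir_sim"))
  clades <- unique(sim$domains$truth$clade)
  out <- lapply(clades, function(cl) {
    members <- sim$domains$truth$record_id[sim$domains$truth$clade == cl]
    sel <- head(members, n_seed)
    aln <- true_alignment(sim$domains, sel)
    m <- msa_matrix(aln)
    keep <- colSums(m != "-") > 0L
    msa(aln$ids, apply(m[, keep, drop = FALSE], 1, paste0, collapse = ""))
  })
  setNames(out, clades)
}

#' Simulate per-candidate secondary-structure strings
#'
#' Emulates the structure-prediction input the fold gate consumes: each
#' planted family member receives a TIR-like topology (five helices and
#' five strands, alternating, with randomized element and linker
#' lengths), while decoys receive an impoverished topology (default two
#' helices, one strand) that fails the fold rule.
#'
#' @param sim A `tir_sim` object.
#' @param seed Integer seed.
#' @param member_topology,decoy_topology `(n_helices, n_strands)` pairs.
#' @return Named list of SS strings over `{H, E, C}`, one per db record.
#' @export
simulate_structures <- function(sim, seed = 1L,
                                member_topology = c(5L, 5L),
                                decoy_topology = c(2L, 1L)) {
  stopifnot(inherits(sim, "tir_sim"))
  set.seed(seed)
  build_ss <- function(nh, ne) {
    types <- character(0)
    h <- nh; e <- ne
    while (h > 0L || e > 0L) {
      if (h > 0L) { types <- c(types, "H"); h <- h - 1L }
      if (e > 0L) { types <- c(types, "E"); e <- e - 1L }
    }
    parts <- paste0(rep("C", sample(3:6, 1L)), collapse = "")
    for (t in types) {
      n <- if (t == "H") sample(8:12, 1L) else sample(4:7, 1L)
      parts <- paste0(parts, paste0(rep(t, n), collapse = ""),
                      paste0(rep("C", sample(3:6, 1L)), collapse = ""))
    }
    parts
  }
  is_decoy <- sim$truth$clade == "decoy"
  ss <- vector("list", nrow(sim$db))
  names(ss) <- sim$db$id
  for (i in seq_len(nrow(sim$db))) {
    topo <- if (is_decoy[i]) decoy_topology else member_topology
    ss[[i]] <- build_ss(topo[1], topo[2])
  }
  ss
}

#' Simulate a presence/absence (gene count) matrix on a species tree
#'
#' Plants a single-origin history: the family is gained on the branch
#' above `origin`, lost on `n_losses` disjoint branches below the origin,
#' and duplicated on `dup_branches`. Species below a loss have count 0;
#' species below a duplication (and no loss) have their count incremented;
#' species outside the origin subtree have count 0.
#'
#' @param species_tree Rooted `ape::phylo`.
#' @param origin Node defining the origin: `"root"`, a tip label, or an
#'   internal node number.
#' @param n_losses Number of losses to place on randomly chosen disjoint
#'   branches below the origin (ignored if `loss_branches` given).
#' @param dup_branches Child-node ids (or tip labels) of duplication
#'   branches; must lie below the origin.
#' @param seed Integer seed for random loss placement.
#' @param loss_branches Optional explicit child-node ids (or tip labels)
#'   of loss branches.
#' @param family Family name for bookkeeping.
#' @return List with `counts` (named integer vector per species), `truth`
#'   (origin node id, loss branch ids, duplication branch ids).
#' @export
simulate_presence_matrix <- function(species_tree, origin = "root",
                                     n_losses = 0L, dup_branches = integer(0),
                                     seed = 1L, loss_branches = NULL,
                                     family = "fam1") {
  tr <- species_tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  node_id <- function(x) {
    if (identical(x, "root")) return(root)
    if (is.character(x)) {
      i <- match(x, tr$tip.label)
      if (is.na(i)) stop("unknown node label: ", x)
      return(i)
    }
    as.integer(x)
  }
  origin_id <- node_id(origin)
  below <- descendant_tips(tr)
  in_origin <- below[[origin_id]]
  subtree_nodes <- which(vapply(seq_len(ntip + tr$Nnode),
                                function(v) all(below[[v]] %in% in_origin) &&
                                  length(below[[v]]) > 0L, logical(1)))
  subtree_nodes <- setdiff(subtree_nodes, origin_id)
  if (!is.null(loss_branches)) {
    loss_ids <- vapply(loss_branches, node_id, integer(1))
  } else if (n_losses > 0L) {
    set.seed(seed)
    # choose disjoint branches: tip sets must not overlap
    cand <- sample(subtree_nodes)
    loss_ids <- integer(0)
    used <- integer(0)
    for (v in cand) {
      tips_v <- below[[v]]
      if (!any(tips_v %in% used) && length(tips_v) < length(in_origin)) {
        loss_ids <- c(loss_ids, v)
        used <- c(used, tips_v)
        if (length(loss_ids) >= n_losses) break
      }
    }
    if (length(loss_ids) < n_losses) stop("could not place ", n_losses,
                                          " disjoint losses below the origin")
  } else {
    loss_ids <- integer(0)
  }
  dup_ids <- vapply(dup_branches, node_id, integer(1))
  if (length(dup_ids)) dup_ids <- as.integer(dup_ids)
  for (v in c(loss_ids, dup_ids)) {
    if (!(v %in% subtree_nodes || v == origin_id)) {
      stop("event branch ", v, " lies outside the origin subtree")
    }
  }
  counts <- setNames(integer(ntip), tr$tip.label)
  counts[in_origin] <- 1L
  lost <- unique(unlist(below[loss_ids]))
  for (v in dup_ids) counts[below[[v]]] <- counts[below[[v]]] + 1L
  counts[lost] <- 0L
  list(counts = counts, family = family,
       truth = list(origin = origin_id, losses = sort(loss_ids),
                    duplications = sort(dup_ids)))
}

# Tip indices below each node (for tips: the tip itself).
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- i
  pt <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(pt$edge))) {
    p <- pt$edge[e, 1]; ch <- pt$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# Ideal backbone geometry (angstrom / degrees).
BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7)

# Place atom D given A, B, C and the internal coordinates of D relative to
# the B-C bond (NeRF construction).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * sin(pi - ang) * cos(dih),
          bond * sin(pi - ang) * sin(dih))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, pracma_cross(n, bc), n)
  c + as.vector(m %*% d2)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Synthesize an idealized protein backbone of given topology
#'
#' Builds N/CA/C coordinates from ideal bond geometry and canonical
#' dihedrals (helix phi = -60, psi = -45; strand phi = -120, psi = +120;
#' coil randomized outside both regions), alternating helix and strand
#' elements joined by coil linkers. Returns the backbone together with its
#' ideal per-residue secondary-structure truth string.
#'
#' @param n_helices Number of alpha-helical elements.
#' @param n_strands Number of beta-strand elements.
#' @param helix_len,strand_len Element lengths (residues).
#' @param linker_len Coil linker length between elements (>= 3).
#' @param seed Integer seed (coil dihedrals are randomized).
#' @return List with `backbone` (a `backbone` object) and `ss` (truth
#'   string over `{H,E,C}`).
#' @export
synthesize_backbone <- function(n_helices, n_strands, helix_len = 10L,
                                strand_len = 6L, linker_len = 4L, seed = 1L) {
  stopifnot(n_helices >= 0L, n_strands >= 0L)
  if (helix_len < 4L && n_helices > 0L) {
    warning("helix_len below the assigner's minimum element length (4)")
  }
  if (strand_len < 3L && n_strands > 0L) {
    warning("strand_len below the assigner's minimum element length (3)")
  }
  linker_len <- max(3L, as.integer(linker_len))
  set.seed(seed)
  types <- character(0)
  h <- n_helices; e <- n_strands
  while (h > 0L || e > 0L) {
    if (h > 0L) { types <- c(types, "H"); h <- h - 1L }
    if (e > 0L) { types <- c(types, "E"); e <- e - 1L }
  }
  sschars <- rep("C", linker_len)
  for (t in types) {
    n <- if (t == "H") helix_len else strand_len
    sschars <- c(sschars, rep(t, n), rep("C", linker_len))
  }
  nres <- length(sschars)
  coil_phi <- function() 60 + runif(1, -20, 20)
  coil_psi <- function() 40 + runif(1, -25, 25)
  phis <- numeric(nres); psis <- numeric(nres)
  for (i in seq_len(nres)) {
    if (sschars[i] == "H") { phis[i] <- -60; psis[i] <- -45 }
    else if (sschars[i] == "E") { phis[i] <- -120; psis[i] <- 120 }
    else { phis[i] <- coil_phi(); psis[i] <- coil_psi() }
  }
  N <- matrix(NA_real_, nres, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB_GEOM$b_n_ca, 0, 0)
  ang <- BB_GEOM$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + BB_GEOM$b_ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in 2:nres) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BB_GEOM$b_c_n, BB_GEOM$a_ca_c_n, psis[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BB_GEOM$b_n_ca, BB_GEOM$a_c_n_ca, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BB_GEOM$b_ca_c, BB_GEOM$a_n_ca_c, phis[i])
  }
  bb <- structure(list(n = N, ca = CA, c = C,
                       assignable = rep(TRUE, nres)), class = "backbone")
  list(backbone = bb, ss = paste0(sschars, collapse = ""))
}
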