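# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct dynamic
# programming, and direct recounts.

# Brute-force PD of a leaf subset: an edge is spanned iff the subset has
# leaves on both sides (computed from scratch on the edge list).
oracle_pd <- function(tree, subset) {
  if (length(subset) <= 1L) return(0)
  ntip <- length(tree$tip.label)
  sel <- match(subset, tree$tip.label)
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_below))
  }
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    b <- tips_below(tree$edge[e, 2])
    k <- sum(b %in% sel)
    if (k > 0L && k < length(sel)) total <- total + tree$edge.length[e]
  }
  total
}

# Exhaustive optimum PD over all subsets of size k.
oracle_best_pd <- function(tree, k) {
  labs <- tree$tip.label
  best <- -Inf
  for (s in utils::combn(length(labs), k, simplify = FALSE)) {
    best <- max(best, oracle_pd(tree, labs[s]))
  }
  best
}

# Brute-force longest-first overlap selection on one target's hits,
# implemented independently of resolve_overlaps (explicit loop over the
# totally ordered hit list).
oracle_overlap_select <- function(env_start, env_end, e_value = NULL) {
  n <- length(env_start)
  if (is.null(e_value)) e_value <- rep(0, n)
  len <- env_end - env_start + 1L
  ord <- order(-len, e_value, env_start)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (env_start[i] <= env_end[j] && env_end[i] >= env_start[j]) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# Global affine-gap alignment DP with BLOSUM62, matching the convention
# where a gap of length L costs open + L * extend. Returns the two
# aligned strings. Independent of Biostrings.
oracle_global_align <- function(a, b, open = 11, extend = 1) {
  sub <- blosum62_matrix()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) X[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) Y[i, 1] <- -open - extend * (i - 1)
  tbM <- matrix(0L, n + 1, m + 1); tbX <- tbM; tbY <- tbM
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[A[i - 1], B[j - 1]]
      opts <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(opts)
      M[i, j] <- opts[k] + s; tbM[i, j] <- k
      optsx <- c(M[i, j - 1] - open - extend, X[i, j - 1] - extend)
      kx <- which.max(optsx)
      X[i, j] <- optsx[kx]; tbX[i, j] <- c(1L, 2L)[kx]
      optsy <- c(M[i - 1, j] - open - extend, Y[i - 1, j] - extend)
      ky <- which.max(optsy)
      Y[i, j] <- optsy[ky]; tbY[i, j] <- c(1L, 3L)[ky]
    }
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(finals)
  score <- finals[state]
  outA <- character(0); outB <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (i == 1) state <- 2L
    if (j == 1 && i > 1) state <- 3L
    if (state == 1L) {
      outA <- c(A[i - 1], outA); outB <- c(B[j - 1], outB)
      state <- tbM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      outA <- c("-", outA); outB <- c(B[j - 1], outB)
      state <- tbX[i, j]; j <- j - 1
    } else {
      outA <- c(A[i - 1], outA); outB <- c("-", outB)
      state <- tbY[i, j]; i <- i - 1
    }
  }
  list(a = paste0(outA, collapse = ""), b = paste0(outB, collapse = ""),
       score = score)
}

blosum62_matrix <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

# Identity convention shared with pairwise_identity, applied to two
# aligned strings.
oracle_identity_from_alignment <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  both <- a != "-" & b != "-"
  100 * sum(a[both] == b[both]) / sum(both)
}

# Brute-force minimal Dollo losses: smallest set of branches below the
# origin whose removal explains the absences, by enumerating branch
# subsets of increasing size.
oracle_dollo_losses <- function(tree, presence) {
  ntip <- length(tree$tip.label)
  pv <- as.logical(presence[tree$tip.label])
  present <- which(pv)
  origin <- if (length(present) == 1L) present else
    ape::getMRCA(tree, tree$tip.label[present])
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_below))
  }
  in_origin_tips <- tips_below(origin)
  cand_branches <- which(vapply(seq_len(nrow(tree$edge)), function(e) {
    all(tips_below(tree$edge[e, 2]) %in% in_origin_tips)
  }, logical(1)))
  explains <- function(branches) {
    lost <- unique(unlist(lapply(tree$edge[branches, 2], tips_below)))
    covered <- setdiff(in_origin_tips, lost)
    setequal(covered, present)
  }
  for (size in 0:length(cand_branches)) {
    subs <- if (size == 0L) list(integer(0)) else
      utils::combn(cand_branches, size, simplify = FALSE)
    for (s in subs) if (explains(s)) return(size)
  }
  stop("no explanation found")
}

# Brute-force count parsimony: exhaustive minimum cost over all internal
# labelings with states 0..S.
oracle_count_parsimony_cost <- function(tree, counts, S) {
  ntip <- length(tree$tip.label)
  cv <- as.integer(counts[tree$tip.label])
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  grid <- expand.grid(rep(list(0:S), length(internal)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(cv, as.integer(grid[r, ]))
    cost <- sum(abs(lab[tree$edge[, 2]] - lab[tree$edge[, 1]]))
    best <- min(best, cost)
  }
  best
}

# Direct recount of the consensus-clade retention rule: how many
# reproducing trees contain the member inside the candidate's matched
# clade.
oracle_retention_count <- function(candidate, member) {
  sum(vapply(candidate$matches, function(m)
    m$reproduced && member %in% m$clade, logical(1)))
}

# Sample k terminal branches that are phylogenetically independent: no
# two are sisters, and the survivors still span both sides of the root
# (so terminal losses are neither collapsible nor origin-severing).
sample_independent_tips <- function(tree, k) {
  ntip <- length(tree$tip.label)
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  root_kids <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
  side <- function(tip) {
    v <- tip
    while (!v %in% root_kids) v <- parent[[as.character(v)]]
    v
  }
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(tree$edge[tree$edge[, 1] == v, 2], tips_below))
  }
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  repeat {
    tips <- sample(seq_len(ntip), k)
    pars <- vapply(tips, function(t) parent[[as.character(t)]], numeric(1))
    if (anyDuplicated(pars)) next
    # no internal subtree may be entirely lost (that would collapse)
    if (any(vapply(internal, function(v) all(tips_below(v) %in% tips),
                   logical(1)))) next
    sides <- vapply(setdiff(seq_len(ntip), tips), side, numeric(1))
    if (length(unique(sides)) < 2L) next
    return(tree$tip.label[tips])
  }
}

# Small deterministic random tree as Newick (pure string construction).
random_tree <- function(n, seed) {
  set.seed(seed)
  frags <- paste0("t", seq_len(n))
  while (length(frags) > 1L) {
    pick <- sample.int(length(frags), 2L)
    bl <- round(runif(2, 0.1, 2), 4)
    merged <- sprintf("(%s:%s,%s:%s)", frags[pick[1]], bl[1],
                      frags[pick[2]], bl[2])
    frags <- c(frags[-pick], merged)
  }
  ape::read.tree(text = paste0(frags, ";"))
}
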