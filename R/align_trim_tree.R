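#' Trim alignment columns by gap threshold
#'
#' A column is kept iff its fraction of non-gap residues is at least `gt`
#' (the gap-threshold convention of standard alignment trimmers).
#'
#' @param alignment An [msa()].
#' @param gt Minimum fraction of non-gap residues in a kept column,
#'   in `[0, 1]`.
#' @return An [msa()] with attribute `kept_cols`: indices of the retained
#'   columns in the input alignment (back-projection map).
#' @export
trim_columns <- function(alignment, gt) {
  stopifnot(inherits(alignment, "msa"), gt >= 0, gt <= 1)
  m <- msa_matrix(alignment)
  frac <- colMeans(m != "-")
  keep <- which(frac >= gt)
  if (length(keep) == 0L) stop("all columns removed at gt = ", gt)
  out <- msa(alignment$ids,
             apply(m[, keep, drop = FALSE], 1, paste0, collapse = ""))
  attr(out, "kept_cols") <- keep
  out
}

#' Percent identity of two sequences under global alignment
#'
#' Sequences are globally aligned (BLOSUM62, affine gaps, defaults fixed
#' here) and identity is computed as
#' `100 * identical aligned pairs / mutually ungapped aligned columns`.
#'
#' @param seq_a,seq_b Amino-acid strings (non-empty).
#' @param gap_open,gap_extend Affine gap penalties (a gap of length k
#'   costs `gap_open + k * gap_extend`).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) stop("no mutually ungapped columns in the alignment")
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Pairwise p-distances of an alignment
#'
#' `d(i, j)` is the mismatch fraction over columns where neither row is
#' gapped (pairwise deletion). Pairs with no comparable columns are an
#' error.
#'
#' @param alignment An [msa()] with >= 2 rows.
#' @return Symmetric numeric matrix with zero diagonal, row/col names =
#'   sequence ids.
#' @export
p_distances <- function(alignment) {
  stopifnot(inherits(alignment, "msa"))
  m <- msa_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 rows")
  # comparable-column and match counts via indicator-matrix products
  ng <- (m != "-") * 1
  n_comp <- tcrossprod(ng)
  matches <- matrix(0, n, n)
  for (letter in unique(as.vector(m))) {
    if (letter == "-") next
    ind <- (m == letter) * 1
    matches <- matches + tcrossprod(ind)
  }
  off <- n_comp == 0 & !diag(TRUE, n)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stop("no comparable columns between ", alignment$ids[bad[1]], " and ",
         alignment$ids[bad[2]])
  }
  d <- (n_comp - matches) / pmax(n_comp, 1)
  diag(d) <- 0
  dimnames(d) <- list(alignment$ids, alignment$ids)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via `ape::nj`); negative branch lengths are
#' clamped to 0 with the deficit moved to the sibling edge (the path
#' lengths through the parent node are preserved).
#'
#' @param dm Symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return Unrooted `ape::phylo` with nonnegative branch lengths.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor joining requires >= 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  tr <- ape::nj(stats::as.dist(dm))
  # clamp negative branch lengths to 0; the sibling edge absorbs the
  # deficit (floored at 0), preserving the path length through the
  # shared parent node
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- max(0, tr$edge.length[sibs[1]] - deficit)
    }
  }
  tr
}

#' Nonparametric bootstrap supports on the internal tree engine
#'
#' Builds the point-estimate tree by neighbor joining on p-distances,
#' then resamples alignment columns with replacement `n_reps` times,
#' rebuilds a tree per replicate, and attaches to each internal branch the
#' percentage of replicates containing the same bipartition.
#'
#' @param alignment An [msa()] with >= 4 rows.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return Unrooted `ape::phylo` with supports (0-100) in `node.label`.
#' @export
bootstrap_support <- function(alignment, n_reps = 200L, seed = 1L) {
  stopifnot(inherits(alignment, "msa"))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- msa_matrix(alignment)
  point <- nj_tree(p_distances(alignment))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    alnb <- msa(alignment$ids, apply(mb, 1, paste0, collapse = ""))
    reps[[r]] <- nj_tree(p_distances(alnb))
  }
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- 100 * counts / n_reps
  # the "root" pseudo-node of an unrooted phylo carries no bipartition
  point$node.label <- format(sup, trim = TRUE)
  point$node.label[1] <- ""
  point
}
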