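test_that("gap-threshold trimming follows the column rule exactly", {
  aln <- msa(c("a", "b", "c", "d"), c("AC-D", "A--D", "A-CD", "AC-D"))
  expect_identical(trim_columns(aln, 0)$seqs, aln$seqs)
  t1 <- trim_columns(aln, 1)
  expect_equal(attr(t1, "kept_cols"), c(1L, 4L))     # only gapless survive
  # 20-row alignment: a column with 1 non-gap residue fails gt = 0.1
  rows <- c(paste0("AA"), rep("A-", 19))
  t2 <- trim_columns(msa(paste0("s", 1:20), rows), 0.1)
  expect_equal(attr(t2, "kept_cols"), 1L)
  expect_error(trim_columns(msa(c("a", "b"), c("--", "--")), 0.5), "removed")
})

test_that("trimming matches a direct per-column recount on random alignments", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:12, 1); L <- sample(10:40, 1)
    m <- matrix(sample(c("A", "C", "G", "-"), n * L, TRUE,
                       prob = c(0.3, 0.3, 0.2, 0.2)), n, L)
    keepable <- colSums(m != "-") > 0
    m <- m[, keepable, drop = FALSE]
    aln <- msa(paste0("s", 1:n), apply(m, 1, paste0, collapse = ""))
    gt <- runif(1)
    want <- which(colSums(m != "-") / n >= gt)
    if (length(want) == 0) {
      expect_error(trim_columns(aln, gt), "removed")
    } else {
      got <- trim_columns(aln, gt)
      expect_equal(attr(got, "kept_cols"), want)
      expect_equal(got$n_columns, length(want))
    }
  }
})

test_that("pairwise identity follows the mutually-ungapped convention", {
  expect_equal(pairwise_identity("MKVLIT", "MKVLIT"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  expect_error(pairwise_identity("", "AAA"), "empty")
  # regression fixture: value computed once by the independent DP oracle
  # with the shipped default parameters (BLOSUM62, open 11, extend 1)
  expect_equal(pairwise_identity("HEAGAWGHEE", "PAWHEAE"), 300 / 7,
               tolerance = 1e-9)
  oa <- oracle_global_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(oracle_identity_from_alignment(oa$a, oa$b), 300 / 7,
               tolerance = 1e-9)
})

test_that("implementation and DP oracle agree on optimal global scores", {
  set.seed(42)
  for (i in 1:10) {
    a <- tiratlas:::decode_aa(tiratlas:::random_aa(sample(8:25, 1)))
    b <- tiratlas:::decode_aa(tiratlas:::random_aa(sample(8:25, 1)))
    oa <- oracle_global_align(a, b)
    sc <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", type = "global",
      gapOpening = 11, gapExtension = 1))
    expect_equal(oa$score, sc)
  }
})

test_that("p-distances use pairwise deletion and are symmetric", {
  aln <- msa(c("a", "b"), c("AAAA", "AATT"))
  expect_equal(p_distances(aln)["a", "b"], 0.5)
  expect_equal(unname(p_distances(msa(c("a", "b"),
                                      c("AAAA", "AAAA")))["a", "b"]), 0)
  set.seed(3)
  m <- matrix(sample(c("A", "C", "-"), 60, TRUE), 6, 10)
  m[, 1] <- "A"
  aln3 <- msa(paste0("s", 1:6), apply(m, 1, paste0, collapse = ""))
  d <- p_distances(aln3)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  # direct recount for one pair
  i <- 2; j <- 5
  comp <- m[i, ] != "-" & m[j, ] != "-"
  expect_equal(d[i, j], sum(m[i, comp] != m[j, comp]) / sum(comp))
  expect_error(p_distances(msa(c("a", "b"), c("A-", "-A"))), "comparable")
})

test_that("neighbor joining recovers additive trees exactly", {
  nwk <- "((A:1,B:2):3,(C:4,D:5):0);"
  dm <- ape::cophenetic.phylo(read_newick(text = nwk))
  tr <- nj_tree(dm)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)] -
                         dm)), 0, tolerance = 1e-9)
  # three taxa: unique resolution via the three-point formulas
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  d3hat <- ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(d3hat), unname(d3), tolerance = 1e-9)
  expect_error(nj_tree(d3[1:2, 1:2]), ">= 3")
})

test_that("neighbor joining is invariant to taxon input order", {
  tr0 <- random_tree(8, seed = 4)
  dm <- ape::cophenetic.phylo(tr0)
  perm <- sample(rownames(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("clamped branch lengths stay nonnegative, path lengths preserved", {
  # a non-additive matrix that induces negative NJ branch estimates
  set.seed(4)
  n <- 6
  dm <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  dm[upper.tri(dm)] <- runif(n * (n - 1) / 2, 0.1, 1)
  dm <- dm + t(dm)
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
  raw <- ape::nj(stats::as.dist(dm))
  expect_true(any(raw$edge.length < 0))          # the clamp actually fired
  # the sibling absorbs each deficit: the path length through the shared
  # parent is preserved, so the total length matches the raw tree's
  # wherever no sibling was floored at zero
  neg <- which(raw$edge.length < 0)
  sib_ok <- all(vapply(neg, function(e) {
    sibs <- setdiff(which(raw$edge[, 1] == raw$edge[e, 1]), e)
    raw$edge.length[sibs[1]] >= -raw$edge.length[e]
  }, logical(1)))
  if (sib_ok) {
    expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
  }
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  cfg <- sim_config(n_clades = 2, seqs_per_clade = 6, n_decoys = 0, seed = 31)
  aln <- true_alignment(evolve_domain_sequences(simulate_family_tree(cfg),
                                                cfg))
  b1 <- bootstrap_support(aln, n_reps = 150, seed = 2)
  b2 <- bootstrap_support(aln, n_reps = 150, seed = 2)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- tree_supports(b1)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the inter-clade split is conflict-free: support >= 95
  og <- grep("^c1_", aln$ids, value = TRUE)
  rt <- tiratlas:::root_on_outgroup(b1, og)
  sc <- suppressMessages(supported_clades(rt, min_support = 95, min_size = 6))
  expect_true(any(vapply(sc, function(x) setequal(x$leaves, sort(og)),
                         logical(1))))
  expect_error(bootstrap_support(aln, 0), "n_reps")
})

test_that("repeating one identical column gives every branch 100 support", {
  base <- msa(paste0("s", 1:5),
              vapply(c("A", "C", "D", "E", "F"), strrep, "", 6))
  bt <- bootstrap_support(base, n_reps = 50, seed = 1)
  sup <- tree_supports(bt)
  expect_true(all(sup[!is.na(sup)] == 100))
})
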