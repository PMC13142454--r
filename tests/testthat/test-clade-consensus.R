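# Hand-built supported-clade lists: each tree's list carries its leaf
# universe, exactly as supported_clades() produces.
mk_clade_list <- function(clades, universe) {
  out <- lapply(clades, function(cl) list(leaves = sort(cl$leaves),
                                          support = cl$support))
  attr(out, "universe") <- sort(universe)
  out
}

test_that("supported clades respect the strict support and size thresholds", {
  # three nested internal nodes with supports 95, 70, 60
  tr <- read_newick(text = "(((A:1,B:1)60:1,C:1)70:1,((D:1,E:1)95:1,F:1)100:1);")
  sc <- supported_clades(tr, min_support = 70, min_size = 2)
  sets <- lapply(sc, `[[`, "leaves")
  expect_true(list(c("D", "E")) %in% sets)           # 95 > 70
  expect_false(list(c("A", "B")) %in% sets)          # 60 fails
  expect_false(list(c("A", "B", "C")) %in% sets)     # 70 fails strictly
  # star tree: no supported clades
  star <- read_newick(text = "(A,B,C,D);")
  expect_length(suppressMessages(supported_clades(star, 0, 2)), 0L)
})

test_that("a fully supported resolved tree yields one clade per internal node", {
  tr <- read_newick(text = "((A:1,B:1)100:1,(C:1,D:1)100:1)100;")
  sc <- supported_clades(tr, min_support = 70, min_size = 2)
  # every non-root internal node (the root clade is the whole leaf set)
  expect_length(sc, 2L)
})

test_that("identical trees reproduce every clade 4/4 with Jaccard 1", {
  uni <- paste0("s", 1:30)
  one <- mk_clade_list(list(list(leaves = paste0("s", 1:10), support = 90),
                            list(leaves = paste0("s", 11:30), support = 85)),
                       uni)
  cands <- match_across_trees(list(one, one, one, one), min_trees = 3)
  expect_length(cands, 2L)
  for (cand in cands) {
    expect_equal(cand$n_reproduced, 4L)
    expect_true(all(vapply(cand$matches, function(m) m$jaccard == 1,
                           logical(1))))
    expect_identical(prune_members(cand, 3), cand$leaves)
  }
})

test_that("a clade found in only 2 of 4 trees does not survive", {
  uni <- paste0("s", 1:40)
  with_clade <- mk_clade_list(list(list(leaves = paste0("s", 1:12),
                                        support = 95)), uni)
  without <- mk_clade_list(list(list(leaves = paste0("s", 20:40),
                                     support = 95)), uni)
  cands <- match_across_trees(list(with_clade, with_clade, without, without),
                              min_trees = 3)
  sets <- lapply(cands, `[[`, "leaves")
  expect_false(list(sort(paste0("s", 1:12))) %in% sets)
})

test_that("a planted 3-of-4 clade survives with reproduced count 3", {
  uni <- paste0("s", 1:150)
  shared <- list(leaves = paste0("s", 1:120), support = 88)
  breaker <- mk_clade_list(list(list(leaves = paste0("s", 1:40),
                                     support = 92)), uni)
  lists <- list(mk_clade_list(list(shared), uni),
                mk_clade_list(list(shared), uni),
                mk_clade_list(list(shared), uni),
                breaker)
  cands <- match_across_trees(lists, min_trees = 3)
  hit <- Filter(function(c) setequal(c$leaves, shared$leaves), cands)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$n_reproduced, 3L)
})

test_that("members missing cross-tree co-support are pruned", {
  uni <- paste0("s", 1:130)
  full <- paste0("s", 1:110)
  # 5 members wander in one tree, 5 others wander in two trees
  drop1 <- setdiff(full, paste0("s", 1:5))
  drop2 <- setdiff(full, paste0("s", 6:10))
  lists <- list(mk_clade_list(list(list(leaves = full, support = 90)), uni),
                mk_clade_list(list(list(leaves = drop1, support = 90)), uni),
                mk_clade_list(list(list(leaves = drop2, support = 90)), uni),
                mk_clade_list(list(list(leaves = drop2, support = 90)), uni))
  cands <- match_across_trees(lists, min_trees = 3)
  cand <- Filter(function(c) setequal(c$leaves, full), cands)[[1]]
  retained <- prune_members(cand, 3)
  expect_length(retained, 105L)                  # the two-tree wanderers go
  expect_true(all(paste0("s", 1:5) %in% retained))
  expect_false(any(paste0("s", 6:10) %in% retained))
  # independent recount oracle agrees member by member
  for (m in cand$leaves) {
    expect_equal(m %in% retained, oracle_retention_count(cand, m) >= 3)
  }
})

test_that("reporting applies the strict retained-size rule", {
  uni <- paste0("s", 1:60)
  mk <- function(n) mk_clade_list(list(
    list(leaves = paste0("s", 1:n), support = 90)), uni)
  for (n in c(20, 21)) {
    cands <- match_across_trees(list(mk(n), mk(n), mk(n), mk(n)),
                                min_trees = 3)
    rep <- report_clades(cands, min_retained = 20)
    expect_length(rep$clades, if (n == 20) 0L else 1L)
  }
})

test_that("disjoint mode drops overlapping clades in priority order", {
  uni <- paste0("s", 1:100)
  big <- list(leaves = paste0("s", 1:60), support = 90)
  nested <- list(leaves = paste0("s", 1:30), support = 95)
  lists <- replicate(4, mk_clade_list(list(big, nested), uni),
                     simplify = FALSE)
  cands <- match_across_trees(lists, min_trees = 3)
  nested_rep <- report_clades(cands, min_retained = 5)
  expect_length(nested_rep$clades, 2L)
  expect_equal(nested_rep$clades[[2]]$nested_in, "clade_01")
  disj <- report_clades(cands, min_retained = 5, disjoint = TRUE)
  expect_length(disj$clades, 1L)
  expect_equal(disj$clades[[1]]$n_retained, 60L)
  expect_equal(sort(disj$unassigned), sort(paste0("s", 61:100)))
})

test_that("differing leaf universes are rejected with the symmetric difference", {
  a <- mk_clade_list(list(list(leaves = c("x", "y"), support = 90)),
                     c("x", "y", "z"))
  b <- mk_clade_list(list(list(leaves = c("x", "y"), support = 90)),
                     c("x", "y", "w"))
  expect_error(match_across_trees(list(a, b)), "symmetric difference")
})

test_that("lowering thresholds never removes retained members", {
  cfg <- sim_config(n_clades = 3, seqs_per_clade = 8, n_decoys = 0, seed = 13)
  aln <- true_alignment(evolve_domain_sequences(simulate_family_tree(cfg),
                                                cfg))
  trees <- lapply(c(11, 22, 33, 44), function(s)
    bootstrap_support(aln, n_reps = 60, seed = s))
  og <- grep("^c1_", aln$ids, value = TRUE)
  strict <- suppressMessages(consensus_clades(
    trees, min_support = 80, min_size = 4, j_min = 0.7, min_retained = 3,
    outgroup = og))
  loose <- suppressMessages(consensus_clades(
    trees, min_support = 70, min_size = 4, j_min = 0.5, min_retained = 3,
    outgroup = og))
  for (cl in strict$clades) {
    match_loose <- Filter(function(x) all(cl$retained %in% x$retained),
                          loose$clades)
    expect_gte(length(match_loose), 1L)
  }
})
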