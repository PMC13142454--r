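test_that("single-sequence profile scores the observed residue highest", {
  p <- build_profile(msa("s1", "ACD"))
  expect_equal(p$length, 3L)
  for (c_idx in 1:3) {
    obs <- match(substr("ACD", c_idx, c_idx), tiratlas:::AA20)
    expect_equal(which.max(p$scores[c_idx, 1:20]), obs)
  }
})

test_that("duplicating every alignment row leaves the profile unchanged", {
  aln <- msa(c("a", "b", "c"), c("ACDEF", "ACDFF", "AADEF"))
  dup <- msa(c("a", "b", "c", "a2", "b2", "c2"), rep(aln$seqs, 2))
  expect_equal(build_profile(aln)$scores, build_profile(dup)$scores)
})

test_that("match scores follow the pseudocount log-odds formula", {
  # 10 single-column rows: 9 x A, 1 x C; Henikoff weights give f(A) = f(C)
  # = 0.5; w = number of distinct rows = 2; alpha = 1; uniform background
  rows <- c(rep("A", 9), "C")
  p <- build_profile(msa(paste0("s", 1:10), rows), alpha = 1,
                     background = rep(1 / 20, 20))
  f <- 0.5; w <- 2; alpha <- 1; bg <- 1 / 20
  expected_A <- log2((w * f + alpha * bg) / ((w + alpha) * bg))
  expected_W <- log2((alpha * bg) / ((w + alpha) * bg))
  expect_equal(p$scores[1, match("A", tiratlas:::AA20)], expected_A)
  expect_equal(p$scores[1, match("C", tiratlas:::AA20)], expected_A)
  expect_equal(p$scores[1, match("W", tiratlas:::AA20)], expected_W)
  expect_gt(expected_A, 0)
  expect_lt(expected_W, 0)
})

test_that("mostly-gapped columns are dropped; all-gap profiles error", {
  aln <- msa(c("a", "b", "c"), c("AACD", "A--D", "A-AD"))
  expect_message(p <- build_profile(aln), "dropped")
  expect_equal(p$length, 3L)            # column 2 has 2/3 gaps
  expect_equal(p$keep_cols, c(1L, 3L, 4L))
  expect_error(suppressMessages(build_profile(
    msa(c("a", "b", "c"), c("A--", "-A-", "--A")))), "degenerate")
})

test_that("calibration is reproducible and produces a positive Gumbel fit", {
  p <- build_profile(seed_fixture_alignment(), profile_id = "fix")
  c1 <- calibrate(p, n_decoys = 120, decoy_length = 150, seed = 5)
  c2 <- calibrate(p, n_decoys = 120, decoy_length = 150, seed = 5)
  expect_identical(c1$calibration, c2$calibration)
  expect_gt(c1$calibration$lambda, 0)
  expect_gt(c1$calibration$K, 0)
  expect_error(calibrate(p, n_decoys = 50), "100")
})

test_that("longer decoys raise the mean optimal score (extreme-value growth)", {
  p <- build_profile(seed_fixture_alignment())
  mean_score <- function(len, seed) {
    set.seed(seed)
    decoys <- lapply(1:80, function(i) tiratlas:::random_aa(len))
    mean(tiratlas:::.pssm_best_scores(p$scores, decoys, p$gap_open,
                                      p$gap_extend))
  }
  expect_gt(mean_score(400, 7), mean_score(100, 7))
})

test_that("E-values have frequency semantics on fresh decoys", {
  p <- calibrate(build_profile(seed_fixture_alignment()), seed = 1)
  set.seed(31)
  n_pass <- replicate(4, {
    decoys <- vapply(1:150, function(i)
      tiratlas:::decode_aa(tiratlas:::random_aa(200)), character(1))
    db <- protein_db(paste0("d", 1:150), decoys)
    hits <- scan_database(p, db, e_threshold = 1)
    nrow(hits)
  })
  # expected ~1 passing hit per replicate at E <= 1
  expect_lte(abs(mean(n_pass) - 1), 3)
})

test_that("scanning recovers a verbatim seed copy at its planted interval", {
  aln <- seed_fixture_alignment()
  p <- calibrate(build_profile(aln))
  domain <- gsub("-", "", aln$seqs[1])
  target <- paste0(strrep("G", 40), domain, strrep("S", 35))
  db <- protein_db(c("hit1", "bg1"),
                   c(target, tiratlas:::decode_aa(tiratlas:::random_aa(150))))
  hits <- scan_database(p, db)
  h <- hits[hits$target_id == "hit1", ]
  expect_equal(nrow(h), 1L)
  expect_lte(h$e_value, 1e-3)
  expect_lte(abs(h$env_start - 41), 3)
  expect_lte(abs(h$env_end - (40 + nchar(domain))), 3)
  # empty database gives an empty table
  empty <- scan_database(p, protein_db(character(0), character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("overlap resolution keeps the longest and is order-independent", {
  mk <- function(s, e, ev = 0) tiratlas:::domain_hit_table(
    rep("t", length(s)), "p", rep(10, length(s)), rep(ev, length(s)), s, e)
  r1 <- resolve_overlaps(mk(c(1, 50), c(100, 130)))
  expect_equal(r1$env_start, 1L)
  expect_equal(r1$env_end, 100L)
  r2 <- resolve_overlaps(mk(c(1, 150), c(100, 260)))
  expect_equal(nrow(r2), 2L)
  r3 <- resolve_overlaps(mk(c(1, 90, 160), c(100, 170, 240)))
  expect_equal(r3$env_start, c(1L, 160L))
  # row order never matters
  h <- mk(c(90, 160, 1), c(170, 240, 100))
  expect_equal(resolve_overlaps(h)$env_start, c(1L, 160L))
})

test_that("overlap resolution matches brute-force longest-first selection", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    s <- sample(1:150, n, replace = TRUE)
    e <- s + sample(10:80, n, replace = TRUE)
    ev <- round(runif(n), 6)
    hits <- tiratlas:::domain_hit_table(rep("t", n), "p", rep(1, n), ev, s, e)
    got <- resolve_overlaps(hits)
    want <- oracle_overlap_select(s, e, ev)
    expect_equal(nrow(got), length(want))
    expect_setequal(paste(got$env_start, got$env_end),
                    paste(s[want], e[want]))
  }
})

test_that("iteration saturates immediately when the db holds only the seeds", {
  aln <- seed_fixture_alignment()
  db <- protein_db(aln$ids, gsub("-", "", aln$seqs))
  st <- iterate_search(aln, db, min_env_len = 30)
  expect_equal(st$n_iterations, 2L)
  expect_equal(st$per_iteration_new, c(0L, 0L))
  expect_equal(st$stop_reason, "no-new-hits")
})

test_that("a reject-all fold gate stops iteration with the gate reason", {
  aln <- seed_fixture_alignment()
  extra <- tiratlas:::decode_aa(tiratlas:::encode_aa(gsub("-", "", aln$seqs[1])))
  db <- protein_db(c("new1"), paste0(strrep("G", 30), extra))
  st <- iterate_search(aln, db, fold_gate = function(id) FALSE,
                       min_env_len = 30)
  expect_equal(st$stop_reason, "all-new-rejected-by-fold-gate")
  expect_equal(nrow(st$accepted), 0L)
})

test_that("iterative broadening reaches remote members only via a bridge", {
  set.seed(99)
  mut <- function(s, frac) {
    idx <- tiratlas:::encode_aa(s)
    pos <- sample(length(idx), round(frac * length(idx)))
    for (p in pos) idx[p] <- sample(setdiff(1:20, idx[p]), 1)
    tiratlas:::decode_aa(idx)
  }
  anc <- tiratlas:::decode_aa(tiratlas:::random_aa(120))
  seed_aln <- msa(c("sA", "sB"), c(mut(anc, 0.05), mut(anc, 0.05)))
  bridge1 <- mut(anc, 0.45); bridge2 <- mut(bridge1, 0.05)
  remote1 <- mut(bridge1, 0.45); remote2 <- mut(remote1, 0.05)
  decoys <- vapply(1:100, function(i)
    paste0(sample(strsplit(anc, "")[[1]]), collapse = ""), character(1))
  db <- protein_db(c("b1", "b2", "r1", "r2", paste0("d", 1:100)),
                   c(bridge1, bridge2, remote1, remote2, decoys))
  st <- suppressMessages(iterate_search(seed_aln, db, min_env_len = 50))
  expect_gte(st$n_iterations, 3L)
  expect_setequal(st$accepted$target_id, c("b1", "b2", "r1", "r2"))
  # the remote pair entered at iteration 2 or later: first-iteration
  # acceptances are the bridge pair only
  expect_equal(st$per_iteration_new[1], 2L)
  # accepted sets are nested across iterations by construction
  expect_true(all(st$per_iteration_new >= 0L))
})

test_that("multi-seed orchestration recovers disjoint families once each", {
  cfg <- sim_config(n_clades = 2, seqs_per_clade = 12, n_decoys = 80,
                    seed = 21)
  sim <- simulate_atlas(cfg)
  seeds <- seed_alignments(sim, 4)
  res <- suppressMessages(orchestrate_multi_seed(seeds, sim$db))
  planted <- sim$truth[sim$truth$clade != "decoy", ]
  hit_ids <- unique(res$hits$target_id)
  expect_gte(mean(planted$record_id %in% hit_ids), 0.95)
  expect_equal(sum(grepl("^decoy", hit_ids)), 0L)
  # overlap rule deduplicates: one envelope per record even with 2 seeds
  expect_equal(anyDuplicated(res$hits$target_id), 0L)
  expect_equal(nrow(res$trimmed), nrow(res$hits))
  # collector bookkeeping matches the per-iteration state exactly
  for (st in res$states) {
    rows <- res$collector[res$collector$seed_id == st$seed_id, ]
    expect_equal(rows$new_hits, st$per_iteration_new)
  }
})
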