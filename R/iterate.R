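# Reciprocal-overlap identity of two envelopes: TRUE when the shared
# residues cover >= frac of BOTH envelopes.
same_envelope <- function(a_start, a_end, b_start, b_end, frac = 0.5) {
  ov <- min(a_end, b_end) - max(a_start, b_start) + 1L
  if (ov <= 0L) return(FALSE)
  ov >= frac * (a_end - a_start + 1L) && ov >= frac * (b_end - b_start + 1L)
}

#' Iterative profile search to saturation
#'
#' Implements the discovery loop: build a profile from the seed alignment,
#' scan the database, fold accepted envelope hits back into the profile
#' (stacked by their profile-aligned coordinates), and rescan, until
#' saturation. A hit is accepted when it passes the E-value threshold, the
#' minimum envelope length, and the fold gate (when provided). A hit is
#' "new" when no already-accepted envelope on the same record matches it
#' at >= 50% reciprocal overlap.
#'
#' Stopping rule: at least `min_iterations` scans are always performed;
#' the loop then stops when a scan finds no new hits (`"no-new-hits"`) or
#' when every new hit was rejected by the fold gate
#' (`"all-new-rejected-by-fold-gate"`).
#'
#' @param seed_alignment An [msa()] of seed domain sequences.
#' @param db A [protein_db()] to search.
#' @param e_threshold Inclusion/reporting E-value threshold (default 1e-3).
#' @param min_iterations Minimum number of scans (default 2).
#' @param min_env_len Minimum accepted envelope length in residues.
#' @param fold_gate Optional predicate `function(record_id) -> logical`;
#'   new hits failing it are rejected.
#' @param max_iterations Safety cap on iterations.
#' @param seed_id Identifier for bookkeeping (defaults to the profile id).
#' @param alpha Pseudocount weight for profile construction.
#' @param calib_seed Seed for E-value calibration decoys.
#' @return An object of class `tir_iteration`: list with `seed_id`,
#'   `accepted` (hit table of accepted envelopes), `per_iteration_new`,
#'   `n_iterations`, `stop_reason`, `profile` (final calibrated profile),
#'   and `stacked` (the final stacked alignment).
#' @export
iterate_search <- function(seed_alignment, db, e_threshold = 1e-3,
                           min_iterations = 2L, min_env_len = 50L,
                           fold_gate = NULL, max_iterations = 25L,
                           seed_id = "seed1", alpha = 1, calib_seed = 1L) {
  stopifnot(inherits(seed_alignment, "msa"))
  profile <- build_profile(seed_alignment, alpha = alpha, profile_id = seed_id)
  # stacked alignment lives in the coordinate system of the first profile
  L0 <- profile$length
  stack_ids <- paste0("seed/", seed_alignment$ids)
  m0 <- msa_matrix(seed_alignment)[, profile$keep_cols, drop = FALSE]
  stack_rows <- apply(m0, 1, paste0, collapse = "")
  # accepted envelopes: seed members present in the db enter with their
  # full span (A0 = seed members)
  acc <- data.frame(target_id = character(0), profile_id = character(0),
                    score = numeric(0), e_value = numeric(0),
                    env_start = integer(0), env_end = integer(0),
                    stringsAsFactors = FALSE)
  seed_in_db <- intersect(seed_alignment$ids, db$id)
  if (length(seed_in_db)) {
    lens <- nchar(db$sequence[match(seed_in_db, db$id)])
    acc <- data.frame(target_id = seed_in_db, profile_id = seed_id,
                      score = NA_real_, e_value = NA_real_,
                      env_start = 1L, env_end = lens,
                      stringsAsFactors = FALSE)
  }
  per_new <- integer(0)
  stop_reason <- NA_character_
  # keep_map: current profile column -> column of the stacked alignment
  keep_map <- seq_len(L0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    profile <- calibrate(profile, seed = calib_seed)
    hits <- scan_database(profile, db, e_threshold = e_threshold)
    paths <- attr(hits, "paths")
    is_new <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (hits$env_end[i] - hits$env_start[i] + 1L < min_env_len) next
      dup <- FALSE
      prev <- which(acc$target_id == hits$target_id[i])
      for (j in prev) {
        if (same_envelope(hits$env_start[i], hits$env_end[i],
                          acc$env_start[j], acc$env_end[j])) { dup <- TRUE; break }
      }
      is_new[i] <- !dup
    }
    new_idx <- which(is_new)
    gated_idx <- new_idx
    if (!is.null(fold_gate) && length(new_idx)) {
      ok <- vapply(hits$target_id[new_idx], fold_gate, logical(1))
      gated_idx <- new_idx[ok]
    }
    per_new <- c(per_new, length(gated_idx))
    if (length(gated_idx)) {
      acc <- rbind(acc, hits[gated_idx, , drop = FALSE])
      for (i in gated_idx) {
        al <- paths[[i]]$aligned            # length = current profile length
        row <- rep("-", L0)
        covered <- al > 0L
        row[keep_map[covered]] <- c(AA20, "X")[al[covered]]
        stack_rows <- c(stack_rows, paste0(row, collapse = ""))
        stack_ids <- c(stack_ids,
                       sprintf("%s/%d-%d", hits$target_id[i],
                               hits$env_start[i], hits$env_end[i]))
      }
    }
    if (iter >= min_iterations) {
      if (length(new_idx) == 0L) { stop_reason <- "no-new-hits"; break }
      if (length(gated_idx) == 0L) {
        stop_reason <- "all-new-rejected-by-fold-gate"; break
      }
    }
    if (iter >= max_iterations) { stop_reason <- "no-new-hits"; break }
    # rebuild the profile from all accepted envelopes (stacked alignment)
    stacked <- msa(stack_ids, stack_rows)
    profile <- build_profile(stacked, alpha = alpha, profile_id = seed_id)
    keep_map <- profile$keep_cols
  }
  structure(list(seed_id = seed_id, accepted = acc,
                 per_iteration_new = per_new, n_iterations = iter,
                 stop_reason = stop_reason, profile = profile,
                 stacked = msa(stack_ids, stack_rows)),
            class = "tir_iteration")
}

#' @export
print.tir_iteration <- function(x, ...) {
  cat("Iterative search", x$seed_id, ":", x$n_iterations, "iterations,",
      nrow(x$accepted), "accepted envelopes; stop:", x$stop_reason, "\n")
  cat("New hits per iteration:", paste(x$per_iteration_new, collapse = ", "), "\n")
  invisible(x)
}

#' Run multiple seeds in order and call final domain boundaries
#'
#' Seeds are processed in the given order, each run to saturation with
#' [iterate_search()]. A final boundary pass then rescans every accepted
#' record with all final profiles; the union of hits is overlap-resolved
#' (longest kept) and each record is trimmed to its final envelope(s).
#'
#' @param seeds Named, ordered list of seed [msa()] alignments.
#' @param db A [protein_db()].
#' @param e_threshold E-value threshold used both for iteration inclusion
#'   and boundary calling.
#' @param min_iterations,min_env_len,fold_gate,calib_seed Passed to
#'   [iterate_search()].
#' @return An object of class `tir_search`: list with `hits` (combined,
#'   overlap-resolved hit table), `trimmed` (a [protein_db()] of domain
#'   sequences, ids `record/start-end`), `states` (per-seed
#'   `tir_iteration` objects), `collector` (per-seed per-iteration new-hit
#'   counts, the collector's curve).
#' @export
orchestrate_multi_seed <- function(seeds, db, e_threshold = 1e-3,
                                   min_iterations = 2L, min_env_len = 50L,
                                   fold_gate = NULL, calib_seed = 1L) {
  stopifnot(length(seeds) >= 1L)
  if (is.null(names(seeds))) names(seeds) <- paste0("seed", seq_along(seeds))
  states <- vector("list", length(seeds))
  names(states) <- names(seeds)
  for (s in seq_along(seeds)) {
    states[[s]] <- iterate_search(seeds[[s]], db, e_threshold = e_threshold,
                                  min_iterations = min_iterations,
                                  min_env_len = min_env_len,
                                  fold_gate = fold_gate,
                                  seed_id = names(seeds)[s],
                                  calib_seed = calib_seed)
  }
  accepted_ids <- unique(unlist(lapply(states, function(st)
    st$accepted$target_id)))
  accepted_ids <- intersect(db$id, accepted_ids)
  sub <- db[db$id %in% accepted_ids, , drop = FALSE]
  class(sub) <- class(db)
  all_hits <- list()
  for (s in seq_along(states)) {
    h <- scan_database(states[[s]]$profile, sub, e_threshold = e_threshold)
    attr(h, "paths") <- NULL
    if (nrow(h)) all_hits[[length(all_hits) + 1L]] <- h
  }
  combined <- if (length(all_hits)) do.call(rbind, all_hits) else domain_hit_table()
  combined <- combined[combined$env_end - combined$env_start + 1L >= min_env_len, ,
                       drop = FALSE]
  final <- resolve_overlaps(combined)
  trimmed <- if (nrow(final)) {
    seqs <- substr(db$sequence[match(final$target_id, db$id)],
                   final$env_start, final$env_end)
    meta <- db[match(final$target_id, db$id), ]
    protein_db(sprintf("%s/%d-%d", final$target_id, final$env_start,
                       final$env_end),
               seqs, taxon = meta$taxon, group = meta$group)
  } else {
    protein_db(character(0), character(0))
  }
  collector <- do.call(rbind, lapply(states, function(st) {
    data.frame(seed_id = st$seed_id,
               iteration = seq_along(st$per_iteration_new),
               new_hits = st$per_iteration_new,
               stringsAsFactors = FALSE)
  }))
  rownames(collector) <- NULL
  structure(list(hits = final, trimmed = trimmed, states = states,
                 collector = collector),
            class = "tir_search")
}

#' @export
print.tir_search <- function(x, ...) {
  cat("Multi-seed search:", length(x$states), "seeds,",
      nrow(x$hits), "final domain calls on",
      length(unique(x$hits$target_id)), "records\n")
  invisible(x)
}
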