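#' Build a position-specific search profile from an alignment
#'
#' Columns with gap fraction > 0.5 are dropped from the match model.
#' Sequences are weighted with Henikoff position-based weights, so
#' duplicating every row leaves the profile unchanged. The match score for
#' residue `a` at column `c` is
#' `log2((w * f_c(a) + alpha * p(a)) / ((w + alpha) * p(a)))`
#' where `f_c` are the weighted residue frequencies, `p` the background,
#' `alpha` the pseudocount weight, and `w` the effective observation count
#' (number of distinct rows). `X` scores 0 at every column.
#'
#' E-value calibration is performed lazily on first scan (see
#' [calibrate()]).
#'
#' @param alignment An [msa()] (>= 1 row).
#' @param alpha Pseudocount weight (default 1).
#' @param background Background frequencies (default [aa_background()]).
#' @param profile_id Identifier for the profile.
#' @param gap_open,gap_extend Affine gap penalties in bits: a gap of
#'   length `k` costs `gap_open + (k - 1) * gap_extend`.
#' @return An object of class `search_profile`.
#' @export
build_profile <- function(alignment, alpha = 1, background = aa_background(),
                          profile_id = "profile1",
                          gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(alignment, "msa"))
  stopifnot(abs(sum(background) - 1) < 1e-9)
  m <- msa_matrix(alignment)
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= 0.5)
  if (length(keep) == 0L) {
    stop("degenerate profile: all columns dropped by the gap-fraction rule")
  }
  if (length(keep) < ncol(m)) {
    message(ncol(m) - length(keep), " column(s) dropped (gap fraction > 0.5)")
  }
  mk <- m[, keep, drop = FALSE]
  wts <- henikoff_weights(mk)
  wts <- wts / sum(wts)
  w <- length(unique(alignment$seqs))
  L <- length(keep)
  scores <- matrix(0, L, 21L)
  p <- as.numeric(background)
  for (cidx in seq_len(L)) {
    colc <- mk[, cidx]
    ok <- colc != "-" & colc != "X"
    f <- numeric(20L)
    if (any(ok)) {
      ww <- wts[ok] / sum(wts[ok])
      ai <- match(colc[ok], AA20)
      for (r in seq_along(ai)) f[ai[r]] <- f[ai[r]] + ww[r]
    }
    scores[cidx, 1:20] <- log2((w * f + alpha * p) / ((w + alpha) * p))
  }
  structure(list(profile_id = profile_id, length = L, scores = scores,
                 gap_open = gap_open, gap_extend = gap_extend,
                 background = p, alpha = alpha, keep_cols = keep,
                 calibration = NULL),
            class = "search_profile")
}

# Henikoff position-based sequence weights over a character matrix
# (gaps ignored). Raw weights; caller normalizes.
henikoff_weights <- function(m) {
  nseq <- nrow(m)
  wts <- numeric(nseq)
  for (cidx in seq_len(ncol(m))) {
    colc <- m[, cidx]
    ok <- colc != "-"
    if (!any(ok)) next
    counts <- table(colc[ok])
    r <- length(counts)
    wts[ok] <- wts[ok] + 1 / (r * as.numeric(counts[colc[ok]]))
  }
  if (all(wts == 0)) wts[] <- 1
  wts
}

#' @export
print.search_profile <- function(x, ...) {
  cat("Search profile", x$profile_id, ":", x$length, "match columns")
  if (!is.null(x$calibration)) {
    cat(sprintf(" (calibrated: lambda=%.4f, K=%.4g)",
                x$calibration$lambda, x$calibration$K))
  }
  cat("\n")
  invisible(x)
}

#' Calibrate a profile's score-to-E-value map
#'
#' Scores the profile against `n_decoys` random sequences drawn from the
#' background composition and fits a Gumbel (extreme value) distribution
#' to the optimal local scores by maximum likelihood. The E-value of a
#' score `S` against a database of `n` residues is
#' `E(S) = K * m * n * exp(-lambda * S)` with `m` the profile length.
#'
#' @param profile A `search_profile`.
#' @param n_decoys Number of calibration decoys (>= 100).
#' @param decoy_length Length of each decoy sequence.
#' @param seed Integer seed.
#' @return The profile with `calibration = list(lambda, K, ...)` filled in.
#' @export
calibrate <- function(profile, n_decoys = 200L, decoy_length = 200L, seed = 1L) {
  stopifnot(inherits(profile, "search_profile"))
  if (n_decoys < 100L) stop("calibration requires n_decoys >= 100")
  set.seed(seed)
  decoys <- lapply(seq_len(n_decoys), function(i) random_aa(decoy_length))
  x <- .pssm_best_scores(profile$scores, decoys,
                         profile$gap_open, profile$gap_extend)
  if (stats::var(x) <= 0) {
    stop("calibration error: degenerate decoy score distribution")
  }
  fit <- gumbel_ml(x)
  lambda <- 1 / fit$beta
  K <- exp(lambda * fit$mu) / (profile$length * decoy_length)
  profile$calibration <- list(lambda = lambda, K = K, n_decoys = n_decoys,
                              decoy_length = decoy_length, seed = seed)
  profile
}

# Maximum-likelihood Gumbel fit: solves the profile likelihood equation
# for the scale beta, then the closed form for the location mu.
gumbel_ml <- function(x) {
  xbar <- mean(x)
  xmin <- min(x)
  g <- function(beta) {
    e <- exp(-(x - xmin) / beta)   # shifted to the minimum: no overflow
    beta - xbar + sum(x * e) / sum(e)
  }
  lo <- 1e-3
  hi <- max(2, 10 * stats::sd(x))
  while (g(hi) < 0) hi <- hi * 2
  beta <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- xmin - beta * log(mean(exp(-(x - xmin) / beta)))
  list(mu = mu, beta = beta)
}

#' E-value of a bit score against a database
#'
#' @param profile Calibrated `search_profile`.
#' @param score Bit score(s).
#' @param n_res Total residues in the searched database.
#' @return E-value(s).
#' @export
profile_evalue <- function(profile, score, n_res) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated")
  cal$K * profile$length * n_res * exp(-cal$lambda * score)
}

#' Scan a protein database with a calibrated profile
#'
#' Performs local profile-sequence alignment with affine gaps against each
#' target. The envelope of a hit is the target interval of the optimal
#' local alignment; multiple non-overlapping envelopes per target are
#' found by iterated optimal-subalignment extraction (each re-scored).
#' Rows with E-value <= `e_threshold` (inclusive) are reported.
#'
#' If the profile is not yet calibrated it is calibrated first with
#' default settings (lazy calibration).
#'
#' @param profile A `search_profile`.
#' @param db A [protein_db()].
#' @param e_threshold Reporting E-value threshold (default `1e-3`).
#' @param max_hits_per_target Max envelopes extracted per target.
#' @return A domain hit table (data frame with columns `target_id`,
#'   `profile_id`, `score`, `e_value`, `env_start`, `env_end`), with the
#'   per-hit profile-alignment paths in `attr(, "paths")`.
#' @export
scan_database <- function(profile, db, e_threshold = 1e-3,
                          max_hits_per_target = 4L) {
  stopifnot(inherits(profile, "search_profile"))
  if (is.null(profile$calibration)) profile <- calibrate(profile)
  if (nrow(db) == 0L) {
    out <- domain_hit_table()
    attr(out, "paths") <- list()
    attr(out, "profile") <- profile
    return(out)
  }
  n_res <- sum(nchar(db$sequence))
  cal <- profile$calibration
  min_score <- log(cal$K * profile$length * n_res / e_threshold) / cal$lambda
  min_score <- max(min_score, 1e-9)
  rows <- list(); paths <- list(); k <- 0L
  for (i in seq_len(nrow(db))) {
    enc <- encode_aa(db$sequence[i])
    hits <- .pssm_scan_seq(profile$scores, enc, profile$gap_open,
                           profile$gap_extend, as.integer(max_hits_per_target),
                           min_score)
    for (h in hits) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        target_id = db$id[i], profile_id = profile$profile_id,
        score = h$score,
        e_value = profile_evalue(profile, h$score, n_res),
        env_start = h$t_start, env_end = h$t_end,
        stringsAsFactors = FALSE)
      paths[[k]] <- list(aligned = h$aligned, p_start = h$p_start,
                         p_end = h$p_end)
    }
  }
  out <- if (k == 0L) domain_hit_table() else do.call(rbind, rows)
  attr(out, "paths") <- paths
  attr(out, "profile") <- profile
  out
}

#' Resolve overlapping domain calls, keeping the longest
#'
#' Within each target, hits are taken greedily by decreasing envelope
#' length (ties: lower E-value, then lower envelope start); a hit is kept
#' iff it shares no residue with any already-kept hit. The output is
#' pairwise non-overlapping and independent of input row order.
#'
#' @param hits A domain hit table.
#' @return The filtered hit table, sorted by target and envelope start;
#'   `attr(, "paths")` is subset accordingly when present.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  paths <- attr(hits, "paths")
  len <- hits$env_end - hits$env_start + 1L
  ord <- order(hits$target_id, -len, hits$e_value, hits$env_start)
  keep_idx <- integer(0)
  occupied <- list()
  for (i in ord) {
    tid <- hits$target_id[i]
    iv <- occupied[[tid]]
    a <- hits$env_start[i]; b <- hits$env_end[i]
    clash <- FALSE
    if (!is.null(iv)) {
      for (r in seq_len(nrow(iv))) {
        if (a <= iv[r, 2] && b >= iv[r, 1]) { clash <- TRUE; break }
      }
    }
    if (!clash) {
      keep_idx <- c(keep_idx, i)
      occupied[[tid]] <- rbind(iv, c(a, b))
    }
  }
  keep_idx <- keep_idx[order(hits$target_id[keep_idx], hits$env_start[keep_idx])]
  out <- hits[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(paths)) attr(out, "paths") <- paths[keep_idx]
  attr(out, "profile") <- attr(hits, "profile")
  out
}
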