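# Signed dihedral angle (degrees) of four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  -atan2(y, x) * 180 / pi
}

#' Backbone phi/psi angles
#'
#' @param bb A `backbone` object.
#' @return Data frame with `phi`, `psi` per residue (`NA` at the chain
#'   ends and around unassignable residues).
#' @export
backbone_dihedrals <- function(bb) {
  nres <- nrow(bb$ca)
  phi <- rep(NA_real_, nres); psi <- rep(NA_real_, nres)
  ok <- bb$assignable
  for (i in seq_len(nres)) {
    if (!ok[i]) next
    if (i > 1L && ok[i - 1L]) {
      phi[i] <- dihedral(bb$c[i - 1L, ], bb$n[i, ], bb$ca[i, ], bb$c[i, ])
    }
    if (i < nres && ok[i + 1L]) {
      psi[i] <- dihedral(bb$n[i, ], bb$ca[i, ], bb$c[i, ], bb$n[i + 1L, ])
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Assign secondary structure from backbone geometry
#'
#' Classifies each residue by its (phi, psi) dihedrals: `H` in the helical
#' region (phi from -100 to -30, psi from -80 to -5), `E` in the extended
#' region (phi from -170 to -70, psi from 90 to 180 or below -170), else
#' `C`. Single-residue label islands are smoothed to their flanking
#' label; residues with undefined dihedrals (chain ends, unassignable)
#' are coil.
#'
#' @param bb A `backbone` object with >= 5 assignable residues.
#' @return Secondary-structure string over `{H, E, C}`.
#' @export
assign_secondary_structure <- function(bb) {
  if (sum(bb$assignable) < 5L) {
    stop("too few assignable residues for secondary-structure assignment")
  }
  if (any(!bb$assignable)) {
    warning("unassignable residues labeled C")
  }
  dh <- backbone_dihedrals(bb)
  lab <- rep("C", nrow(dh))
  helix <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi >= -100 & dh$phi <= -30 & dh$psi >= -80 & dh$psi <= -5
  strand <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi >= -170 & dh$phi <= -70 &
    ((dh$psi >= 90 & dh$psi <= 180) | (dh$psi >= -180 & dh$psi <= -170))
  lab[strand] <- "E"
  lab[helix] <- "H"
  # smooth single-residue islands to their neighbors
  n <- length(lab)
  for (i in seq_len(n)) {
    left <- if (i > 1L) lab[i - 1L] else NA_character_
    right <- if (i < n) lab[i + 1L] else NA_character_
    if (!is.na(left) && !is.na(right) && left == right && lab[i] != left) {
      lab[i] <- left
    }
  }
  paste0(lab, collapse = "")
}

#' Segment a secondary-structure string into elements
#'
#' Maximal runs of `H` of length at least `min_helix_len` and of `E` of
#' length at least `min_strand_len` become elements; shorter runs
#' dissolve to coil.
#'
#' @param ss String over `{H, E, C}`.
#' @param min_helix_len Minimum helix element length (default 4).
#' @param min_strand_len Minimum strand element length (default 3).
#' @return Data frame with columns `type`, `start`, `end` (1-based
#'   inclusive), in sequence order.
#' @export
segment_elements <- function(ss, min_helix_len = 4L, min_strand_len = 3L) {
  chars <- strsplit(ss, "")[[1]]
  if (any(!chars %in% c("H", "E", "C"))) stop("ss must be over {H,E,C}")
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- (r$values == "H" & r$lengths >= min_helix_len) |
          (r$values == "E" & r$lengths >= min_strand_len)
  data.frame(type = r$values[keep], start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' TIR fold acceptance check
#'
#' The canonical TIR fold has five alpha helices wrapping five beta
#' strands; a model passes when it shows at least `min_h` helix elements
#' and `min_e` strand elements (defaults 4 and 3 of the expected 5 and
#' 5). The rule is a lower bound: extra elements never cause failure.
#'
#' @param elements Element table from [segment_elements()].
#' @param min_h Minimum helix element count (default 4).
#' @param min_e Minimum strand element count (default 3).
#' @return An object of class `fold_verdict`: list with
#'   `n_helix_elements`, `n_strand_elements`, `pass`, `elements`.
#' @export
tir_fold_check <- function(elements, min_h = 4L, min_e = 3L) {
  nh <- sum(elements$type == "H")
  ne <- sum(elements$type == "E")
  structure(list(n_helix_elements = nh, n_strand_elements = ne,
                 pass = nh >= min_h && ne >= min_e, elements = elements),
            class = "fold_verdict")
}

#' @export
print.fold_verdict <- function(x, ...) {
  cat(sprintf("Fold verdict: %d helices, %d strands -> %s\n",
              x$n_helix_elements, x$n_strand_elements,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Build a fold-gate predicate over candidate structures
#'
#' Each candidate maps to a backbone model or a precomputed
#' secondary-structure string; the gate passes a record iff
#' [tir_fold_check()] passes on its (assigned) secondary structure.
#' Candidates with no structure follow the `missing` policy.
#'
#' @param candidates Named list mapping record id -> `backbone` object or
#'   SS string over `{H, E, C}`.
#' @param min_h,min_e Fold-rule thresholds.
#' @param min_helix_len,min_strand_len Element segmentation minima.
#' @param missing Policy for records with no structure: `"pass"`
#'   (pass-through with warning, the default) or `"fail"`.
#' @return A predicate `function(record_id) -> logical` with the verdict
#'   table in `attr(, "verdicts")` (built lazily, memoized).
#' @export
gate_candidates <- function(candidates, min_h = 4L, min_e = 3L,
                            min_helix_len = 4L, min_strand_len = 3L,
                            missing = c("pass", "fail")) {
  missing <- match.arg(missing)
  cache <- new.env(parent = emptyenv())
  verdict_of <- function(id) {
    if (exists(id, envir = cache, inherits = FALSE)) {
      return(get(id, envir = cache))
    }
    obj <- candidates[[id]]
    v <- if (is.null(obj)) {
      warning("no structure for candidate ", id, "; policy = ", missing)
      missing == "pass"
    } else {
      ss <- if (inherits(obj, "backbone")) assign_secondary_structure(obj)
            else as.character(obj)
      tir_fold_check(segment_elements(ss, min_helix_len, min_strand_len),
                     min_h, min_e)$pass
    }
    assign(id, v, envir = cache)
    v
  }
  gate <- function(record_id) verdict_of(record_id)
  attr(gate, "verdict_table") <- function() {
    ids <- names(candidates)
    data.frame(record_id = ids,
               pass = vapply(ids, verdict_of, logical(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  gate
}
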