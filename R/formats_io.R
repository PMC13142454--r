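#' Construct a protein database
#'
#' A protein database is the search universe of the atlas: a data frame of
#' uniquely identified amino-acid sequences, each carrying a free-text taxon
#' and a taxonomic-group label (e.g. "Metazoa", "Amoebozoa", "Bacteria")
#' used later for per-group downsampling.
#'
#' Sequence letters outside the 20 canonical amino acids are mapped to `X`
#' with a warning.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param taxon Free-text taxon labels (recycled).
#' @param group Taxonomic-group labels (recycled).
#' @return An object of class `protein_db` (a data frame with columns
#'   `id`, `taxon`, `group`, `sequence`).
#' @export
protein_db <- function(id, sequence, taxon = "", group = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(id))) stop("empty record id")
  if (any(!nzchar(sequence))) stop("zero-length sequence")
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), sequence)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-canonical letters; mapped to X")
    sequence[bad] <- vapply(sequence[bad], function(s) decode_aa(encode_aa(s)),
                            character(1))
  }
  db <- data.frame(id = id,
                   taxon = rep_len(as.character(taxon), length(id)),
                   group = rep_len(as.character(group), length(id)),
                   sequence = sequence,
                   stringsAsFactors = FALSE)
  class(db) <- c("protein_db", "data.frame")
  db
}

#' @export
print.protein_db <- function(x, ...) {
  cat("Protein database:", nrow(x), "records,",
      sum(nchar(x$sequence)), "residues\n")
  grp <- table(x$group)
  if (length(grp) > 1L || any(nzchar(names(grp)))) {
    cat("Groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Headers are parsed as `id|taxon|group`; missing fields default to the
#' empty string. Order is preserved. Duplicate ids are a hard error.
#'
#' @param path Path to a FASTA file (plain text).
#' @return A [protein_db()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_db(character(0), character(0)))
  }
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  taxon <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[[2]]) else "",
                  character(1))
  group <- vapply(parts, function(p) if (length(p) >= 3) trimws(p[[3]]) else "",
                  character(1))
  protein_db(id, as.character(set), taxon = taxon, group = group)
}

#' Write a protein database as FASTA
#'
#' @param db A [protein_db()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(db, path, width = 60L) {
  header <- ifelse(nzchar(db$group), paste(db$id, db$taxon, db$group, sep = "|"),
                   ifelse(nzchar(db$taxon), paste(db$id, db$taxon, sep = "|"),
                          db$id))
  set <- Biostrings::BStringSet(setNames(db$sequence, header))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Construct a multiple alignment
#'
#' Rows are gapped sequences over the amino-acid alphabet plus `-`; `.` is
#' normalized to `-`. All rows must have equal length.
#'
#' @param ids Row identifiers.
#' @param seqs Gapped sequences (equal lengths).
#' @return An object of class `msa` with elements `ids`, `seqs`,
#'   `n_columns`.
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(gsub(".", "-", as.character(seqs), fixed = TRUE))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (length(seqs) == 0L) stop("empty alignment")
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L) stop("alignment rows differ in length")
  structure(list(ids = ids, seqs = seqs, n_columns = nc), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple alignment:", length(x$ids), "rows x", x$n_columns, "columns\n")
  invisible(x)
}

# Character matrix view of an alignment (rows = sequences).
msa_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' @param path Path to aligned FASTA.
#' @return An [msa()].
#' @export
read_alignment <- function(path) {
  db <- suppressWarnings(read_fasta(path))
  msa(db$id, db$sequence)
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param aln An [msa()].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a Stockholm-format alignment (read-only)
#'
#' Minimal Stockholm 1.0 reader: sequence lines are accumulated across
#' blocks; `#` annotation and `//` terminator lines are ignored.
#'
#' @param path Path to a Stockholm file.
#' @return An [msa()].
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  seqlines <- lines[!startsWith(lines, "#") & !startsWith(trimws(lines), "//")]
  if (length(seqlines) == 0L) stop("no sequence lines in Stockholm file: ", path)
  toks <- regmatches(seqlines, regexpr("^\\S+", seqlines))
  rest <- trimws(sub("^\\S+\\s+", "", seqlines))
  agg <- tapply(rest, factor(toks, levels = unique(toks)), paste0, collapse = "")
  msa(names(agg), unname(agg))
}

#' Read a Newick tree with internal-node supports
#'
#' Internal-node labels are interpreted as bootstrap-style support values.
#' In `auto` mode, if every support is <= 1 the values are taken to be
#' fractions and multiplied by 100 (with a message); otherwise they are
#' taken as percentages. Re-reading a written percent-scale tree is a
#' no-op (auto-scaling is idempotent).
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param support_scale One of `"auto"`, `"percent"`, `"fraction"`.
#' @param text Optional Newick text instead of a file.
#' @return An `ape::phylo` tree; supports (percent scale) are stored in
#'   `node.label` and retrievable with [tree_supports()].
#' @export
read_newick <- function(path, support_scale = c("auto", "percent", "fraction"),
                        text = NULL) {
  support_scale <- match.arg(support_scale)
  tr <- if (is.null(text)) {
    raw <- paste(readLines(path, warn = FALSE), collapse = "")
    check_parens(raw)
    ape::read.tree(text = raw)
  } else {
    check_parens(text)
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  sup <- suppressWarnings(as.numeric(tr$node.label))
  if (!is.null(tr$node.label) && any(!is.na(sup))) {
    scale_up <- switch(support_scale,
      percent = FALSE,
      fraction = TRUE,
      auto = all(sup[!is.na(sup)] <= 1))
    if (scale_up) {
      message("supports read as fractions; scaled to percent")
      sup <- sup * 100
    }
    if (any(sup[!is.na(sup)] < 0 | sup[!is.na(sup)] > 100)) {
      stop("support values outside [0, 100] after scaling")
    }
    tr$node.label <- ifelse(is.na(sup), "", format(sup, trim = TRUE))
  }
  tr
}

check_parens <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at character ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unclosed at end of input")
  invisible(TRUE)
}

#' Internal-node support values of a tree
#'
#' @param tree An `ape::phylo` tree whose `node.label` holds supports.
#' @return Numeric vector of length `tree$Nnode` (percent scale; `NA`
#'   where absent).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Write a tree to Newick
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); `N` is excluded from both numerator
#' and denominator.
#'
#' @param seq Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return Fraction in `[0, 1]`.
#' @export
compute_gc <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains letters outside {A,C,G,T,N}")
  }
  denom <- sum(chars %in% c("A", "C", "G", "T"))
  if (denom == 0L) stop("GC content undefined: no unambiguous bases")
  sum(chars %in% c("G", "C")) / denom
}

#' Read a backbone model from a minimal PDB file
#'
#' Expects ATOM records with N, CA and C atoms for each residue of a single
#' chain. Residues missing any of the three backbone atoms are flagged
#' unassignable.
#'
#' @param path Path to a PDB file.
#' @return An object of class `backbone`: list with `n`, `ca`, `c`
#'   (n x 3 coordinate matrices, angstrom) and logical `assignable`.
#' @export
read_backbone <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  resnos <- sort(unique(atoms$resno))
  get_xyz <- function(elety) {
    m <- matrix(NA_real_, length(resnos), 3)
    sel <- atoms[atoms$elety == elety, , drop = FALSE]
    idx <- match(sel$resno, resnos)
    m[idx, ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  }
  bb <- list(n = get_xyz("N"), ca = get_xyz("CA"), c = get_xyz("C"))
  bb$assignable <- stats::complete.cases(cbind(bb$n, bb$ca, bb$c))
  if (!all(bb$assignable)) {
    warning(sum(!bb$assignable), " residue(s) missing backbone atoms; ",
            "flagged unassignable")
  }
  class(bb) <- "backbone"
  bb
}

#' Write a backbone model as a minimal PDB file
#'
#' Emits fixed-column ATOM records for N, CA, C of each residue (GLY
#' residue names; single chain A).
#'
#' @param bb A `backbone` object.
#' @param path Output path.
#' @export
write_backbone <- function(bb, path) {
  nres <- nrow(bb$ca)
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(nres)) {
    for (atom in c("N", "CA", "C")) {
      xyz <- bb[[tolower(atom)]][i, ]
      if (anyNA(xyz)) next
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial, paste0(" ", atom), "GLY", i, xyz[1], xyz[2], xyz[3], 1, 0))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @export
print.backbone <- function(x, ...) {
  cat("Backbone model:", nrow(x$ca), "residues,",
      sum(x$assignable), "assignable\n")
  invisible(x)
}

# Domain hit table contract: data.frame(target_id, profile_id, score,
# e_value, env_start, env_end), 1-based inclusive envelopes.
domain_hit_table <- function(target_id = character(0), profile_id = character(0),
                             score = numeric(0), e_value = numeric(0),
                             env_start = integer(0), env_end = integer(0)) {
  stopifnot(all(env_start >= 1L), all(env_end >= env_start), all(e_value >= 0))
  data.frame(target_id = as.character(target_id),
             profile_id = as.character(profile_id),
             score = as.numeric(score), e_value = as.numeric(e_value),
             env_start = as.integer(env_start), env_end = as.integer(env_end),
             stringsAsFactors = FALSE)
}

#' Write / read a domain hit table as TSV
#'
#' Fixed-header TSV mirroring the subset of per-domain tabular search
#' output the pipeline uses (target, profile, bit score, E-value, envelope).
#'
#' @param hits Data frame of hits.
#' @param path File path.
#' @return `read_hits` returns the hit data frame.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  h <- read.delim(path, stringsAsFactors = FALSE)
  domain_hit_table(h$target_id, h$profile_id, h$score, h$e_value,
                   h$env_start, h$env_end)
}

#' Write / read a species-by-family presence matrix as TSV
#'
#' Rows are species, columns gene families, entries nonnegative integer
#' gene counts.
#'
#' @param mat Integer matrix with species row names and family column names.
#' @param path File path.
#' @export
write_presence_matrix <- function(mat, path) {
  df <- data.frame(species = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read secondary-structure strings as FASTA-like text
#'
#' Strings over the alphabet `{H, E, C}` (helix, strand, coil).
#'
#' @param ss Named character vector of SS strings.
#' @param path File path.
#' @export
write_ss <- function(ss, path) {
  writeLines(as.vector(rbind(paste0(">", names(ss)), unname(ss))), path)
  invisible(path)
}

#' @rdname write_ss
#' @export
read_ss <- function(path) {
  db <- suppressWarnings(Biostrings::readBStringSet(path))
  ss <- toupper(as.character(db))
  if (any(grepl("[^HEC]", ss))) stop("secondary-structure strings must be over {H,E,C}")
  setNames(ss, names(db))
}
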