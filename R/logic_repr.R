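# The 16 physico-chemical groups (memberships as published, including
# the unusual "charged" set), plus the single/pair ratio predicates.
PROPERTY_GROUPS <- list(
  small                  = c("A", "G", "S", "T"),
  polar                  = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y"),
  polarUncharged         = c("N", "Q"),
  aromatic               = c("F", "H", "W", "Y"),
  charged                = c("D", "E", "H", "I", "K", "L", "R", "V"),
  positivelyCharged      = c("H", "K", "R"),
  negativelyCharged      = c("D", "E"),
  tiny                   = c("A", "G"),
  bulky                  = c("F", "H", "R", "W", "Y"),
  aliphatic              = c("I", "L", "V"),
  hydrophobic            = c("I", "L", "M", "V"),
  hydrophilicBasic       = c("K", "R", "H"),
  hydrophilicAcidic      = c("E", "D", "N", "Q"),
  neutralWeakHydrophobic = c("A", "G", "P", "S", "T"),
  hydrophobicAromatic    = c("F", "W", "Y"),
  acidic                 = c("E", "D")
)

#' Physico-chemical property groups
#'
#' The 16 amino acid property groups used by the sequential and
#' conserved-physico-chemical-position representations.
#'
#' @return named list of character vectors (group -> member residues).
#' @export
property_groups <- function() PROPERTY_GROUPS

#' Decile binning of a percentage
#'
#' Maps a percentage `y` in `[0, 100]` to `floor(y / 10) + 1`, i.e. bins
#' 1..11 where bin 2 means "between 10 and 20 percent" and bin 11 is
#' exactly 100 percent.
#'
#' @param y numeric vector of percentages in `[0, 100]`.
#' @return integer bin(s) in `[1, 11]`.
#' @examples
#' bin_percentage(c(0, 15, 100))  # 1 2 11
#' @export
bin_percentage <- function(y) {
  if (any(is.na(y)) || any(y < 0 | y > 100))
    stop("percentage out of range [0, 100]")
  as.integer(floor(y / 10) + 1)
}

# predicate of a literal key like "col(v,12)" -> "col"
literal_predicate <- function(lit) sub("\\(.*$", "", lit)

# representation a predicate belongs to
predicate_representation <- function(pred) {
  ifelse(pred == "col", "Aln_cons",
         ifelse(pred == "colProp", "Aln_pc", "Seq"))
}

#' Sequential (composition) atoms for one sequence
#'
#' Emits, as literal keys with the example variable implicit, exactly 16
#' property-percentage atoms (one per group; the percentage of residues
#' in the group, decile-binned), one `aminoacidRatio` atom per canonical
#' residue present, and one `aminoacidPairRatio` atom per distinct
#' overlapping ordered dimer present (percentage relative to
#' `length - 1`).  Non-standard residues (B, Z, X, U, O) count toward
#' length but never toward a numerator, and dimers containing them are
#' skipped.
#'
#' @param residues unaligned residue string (canonicalized).
#' @return character vector of literal keys, e.g. `"hydrophobic(2)"`,
#'   `"aminoacidRatio(a,3)"`, `"aminoacidPairRatio(cg,1)"`.
#' @export
sequential_atoms <- function(residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  L <- length(chars)
  if (L == 0L) stop("empty sequence")
  canon <- chars[chars %in% AA_CANONICAL]

  group_bins <- vapply(PROPERTY_GROUPS, function(members) {
    bin_percentage(100 * sum(canon %in% members) / L)
  }, integer(1))
  lits <- sprintf("%s(%d)", names(PROPERTY_GROUPS), group_bins)

  if (length(canon)) {
    tab <- table(canon)
    lits <- c(lits, sprintf("aminoacidRatio(%s,%d)",
                            tolower(names(tab)),
                            bin_percentage(100 * as.integer(tab) / L)))
  }
  if (L >= 2L) {
    a <- chars[-L]; b <- chars[-1L]
    ok <- a %in% AA_CANONICAL & b %in% AA_CANONICAL
    if (any(ok)) {
      dimers <- table(paste0(a[ok], b[ok]))
      lits <- c(lits, sprintf("aminoacidPairRatio(%s,%d)",
                              tolower(names(dimers)),
                              bin_percentage(100 * as.integer(dimers) / (L - 1))))
    }
  }
  sort(unique(lits))
}

#' Alignment-column atoms for the training rows
#'
#' One `col(residue, column)` literal per non-gap cell of the positive
#' training alignment, columns 1-based, residue constants lower-cased.
#'
#' @param alignment an [as_alignment()] object.
#' @return named list (sequence id -> character vector of literal keys).
#' @export
alignment_atoms_train <- function(alignment) {
  stopifnot(inherits(alignment, "msa"))
  lapply(alignment$rows, function(row) {
    chars <- strsplit(row, "")[[1]]
    j <- which(chars != "-")
    sort(sprintf("col(%s,%d)", tolower(chars[j]), j))
  })
}

#' Alignment-column atoms for a query sequence
#'
#' Viterbi-decodes the query through the profile HMM built from the
#' positive training alignment and emits one `col(residue, column)`
#' literal per match-mapped residue.  Insert-state residues have no
#' training-alignment column and emit nothing.
#'
#' @param phmm a [build_phmm()] model.
#' @param residues query residue string.
#' @return character vector of literal keys.
#' @export
alignment_atoms_query <- function(phmm, residues) {
  path <- viterbi(phmm, residues)
  map <- residue_to_column_map(path, phmm, residues)
  chars <- strsplit(toupper(residues), "")[[1]]
  keep <- !is.na(map)
  sort(sprintf("col(%s,%d)", tolower(chars[keep]), map[keep]))
}

#' Conserved physico-chemical column atoms
#'
#' For each `col(w, z)` literal and each property group containing `w`,
#' derives a `colProp(group, z)` literal.  A rule mined over these
#' derived atoms is equivalent to the two-literal form
#' `col(A, B, z), group(B)` and is rendered that way on output.
#'
#' @param col_atoms character vector of `col/2` literal keys.
#' @return character vector of `colProp` literal keys.
#' @export
physchem_column_atoms <- function(col_atoms) {
  if (length(col_atoms) == 0L) return(character(0))
  m <- regmatches(col_atoms,
                  regexec("^col\\(([a-z]),([0-9]+)\\)$", col_atoms))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("not a col/2 literal: ", col_atoms[bad][1])
  res <- toupper(vapply(m, `[`, character(1), 2L))
  cols <- vapply(m, `[`, character(1), 3L)
  out <- character(0)
  for (g in names(PROPERTY_GROUPS)) {
    hit <- res %in% PROPERTY_GROUPS[[g]]
    if (any(hit))
      out <- c(out, sprintf("colProp(%s,%s)", g, cols[hit]))
  }
  sort(unique(out))
}

#' Build a knowledge base of ground atoms
#'
#' Computes, per sequence, the union of the atoms of the selected
#' representations: `Seq` (composition predicates), `Aln_cons`
#' (alignment-column predicates; training rows read the columns off the
#' alignment, other sequences are projected through the profile HMM) and
#' `Aln_pc` (derived conserved physico-chemical column predicates).
#'
#' @param sequences data.frame with columns `id`, `residues`.
#' @param representations subset of `c("Seq", "Aln_cons", "Aln_pc")`.
#' @param phmm profile HMM for query projection (required for alignment
#'   representations when some sequence is not an alignment row).
#' @param alignment the positive-training [as_alignment()] (optional;
#'   used for sequences that are rows of it).
#' @param labels optional named vector (id -> "positive"/"negative").
#' @param atom_cache optional environment used to memoize per-sequence
#'   atom computations (notably Viterbi decoding) across calls.
#' @return object of class `knowledge_base`: `atoms` (named list id ->
#'   sorted literal keys), `examples`, `labels`.
#' @export
build_kb <- function(sequences,
                     representations = c("Seq", "Aln_cons", "Aln_pc"),
                     phmm = NULL, alignment = NULL, labels = NULL,
                     atom_cache = NULL) {
  representations <- match.arg(representations,
                               c("Seq", "Aln_cons", "Aln_pc"),
                               several.ok = TRUE)
  stopifnot(is.data.frame(sequences),
            all(c("id", "residues") %in% names(sequences)))
  need_aln <- any(c("Aln_cons", "Aln_pc") %in% representations)
  aln_ids <- if (!is.null(alignment)) names(alignment$rows) else character(0)
  if (need_aln && is.null(phmm) &&
      !all(sequences$id %in% aln_ids))
    stop("alignment representations need a phmm for query sequences ",
         "(or an alignment covering every sequence)")
  if (is.null(atom_cache)) atom_cache <- new.env(parent = emptyenv())
  train_col <- if (need_aln && !is.null(alignment))
    alignment_atoms_train(alignment) else list()

  atoms <- stats::setNames(vector("list", nrow(sequences)), sequences$id)
  for (i in seq_len(nrow(sequences))) {
    id <- sequences$id[i]
    res <- sequences$residues[i]
    lits <- character(0)
    if ("Seq" %in% representations) {
      key <- paste0("seq\r", id)
      if (is.null(atom_cache[[key]]))
        atom_cache[[key]] <- sequential_atoms(res)
      lits <- c(lits, atom_cache[[key]])
    }
    if (need_aln) {
      key <- paste0("col\r", id)
      if (is.null(atom_cache[[key]])) {
        atom_cache[[key]] <- if (id %in% names(train_col))
          train_col[[id]]
        else
          alignment_atoms_query(phmm, res)
      }
      col_lits <- atom_cache[[key]]
      if ("Aln_cons" %in% representations) lits <- c(lits, col_lits)
      if ("Aln_pc" %in% representations) {
        key2 <- paste0("colprop\r", id)
        if (is.null(atom_cache[[key2]]))
          atom_cache[[key2]] <- physchem_column_atoms(col_lits)
        lits <- c(lits, atom_cache[[key2]])
      }
    }
    atoms[[id]] <- sort(unique(lits))
  }
  if (!is.null(labels)) {
    labels <- labels[sequences$id]
    if (anyNA(labels)) stop("labels missing for some sequences")
  }
  structure(list(atoms = atoms, examples = sequences$id, labels = labels),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("knowledge_base:", length(x$examples), "examples,",
      sum(lengths(x$atoms)), "ground atoms\n")
  invisible(x)
}

# full ground-atom rendering: insert the sequence id as first argument
render_atom <- function(id, lit) {
  sub("\\(", paste0("(", id, ","), lit)
}

#' Write a knowledge base as Prolog-like ground atoms
#'
#' One atom per line, e.g. `col(s1,v,1).`; labels are emitted as
#' `label(s1,positive).` atoms so the file round-trips.
#'
#' @param kb a [build_kb()] knowledge base.
#' @param path output path.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  lines <- unlist(lapply(kb$examples, function(id)
    paste0(render_atom(id, kb$atoms[[id]]), ".")))
  if (!is.null(kb$labels))
    lines <- c(lines, sprintf("label(%s,%s).", names(kb$labels), kb$labels))
  writeLines(lines, path)
  invisible(path)
}

#' Read a knowledge base written by [write_kb()]
#'
#' @param path input path.
#' @return a `knowledge_base`.
#' @export
read_kb <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  m <- regmatches(lines, regexec("^([A-Za-z]+)\\(([^)]*)\\)\\.$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("unparseable atom line: ", lines[bad][1])
  preds <- vapply(m, `[`, character(1), 2L)
  argss <- strsplit(vapply(m, `[`, character(1), 3L), ",", fixed = TRUE)
  ids <- vapply(argss, `[`, character(1), 1L)
  is_label <- preds == "label"
  labels <- NULL
  if (any(is_label))
    labels <- stats::setNames(vapply(argss[is_label], `[`, character(1), 2L),
                              ids[is_label])
  lits <- sprintf("%s(%s)", preds[!is_label],
                  vapply(argss[!is_label], function(a)
                    paste(a[-1], collapse = ","), character(1)))
  ex_ids <- ids[!is_label]
  atoms <- split(lits, factor(ex_ids, levels = unique(ex_ids)))
  atoms <- lapply(atoms, function(v) sort(unique(v)))
  structure(list(atoms = atoms, examples = names(atoms), labels = labels),
            class = "knowledge_base")
}

# positive example ids of a KB (all examples when unlabeled)
positive_ids <- function(kb) {
  if (is.null(kb$labels)) kb$examples
  else kb$examples[kb$labels[kb$examples] == "positive"]
}
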