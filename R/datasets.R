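# 20 canonical residues; B/Z/X/U/O are tolerated in sequences (kept for
# length and alignment purposes) but never contribute to property counts.
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")

#' Canonicalize a residue string
#'
#' Upper-cases the sequence and validates that every character is one of
#' the 20 standard amino acid letters or a tolerated non-standard code
#' (B, Z, X, U, O).  Non-standard codes are retained: they count toward
#' sequence length but are excluded from all physico-chemical property
#' tallies downstream.
#'
#' @param residues character scalar, unaligned amino acid sequence.
#' @param id sequence identifier used in error messages.
#' @return upper-case residue string.
#' @keywords internal
canonicalize_residues <- function(residues, id = "<sequence>") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("residues must be a single character string (sequence ", id, ")")
  res <- toupper(residues)
  if (!nzchar(res))
    stop("empty sequence for record '", id, "'")
  chars <- strsplit(res, "")[[1]]
  bad <- setdiff(unique(chars), c(AA_CANONICAL, AA_AMBIGUOUS))
  if (length(bad))
    stop("record '", id, "' contains invalid residue letter(s): ",
         paste(bad, collapse = ", "))
  res
}

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file of unaligned protein sequences.
#' @return a data.frame with columns `id` and `residues` (canonicalized,
#'   upper case), one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "VCK", ">s2", "acd"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e)))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  residues <- vapply(seq_along(set), function(i)
    canonicalize_residues(as.character(set[[i]]), ids[i]), character(1))
  data.frame(id = ids, residues = residues, stringsAsFactors = FALSE)
}

#' Read a dataset manifest
#'
#' The manifest is a headerless (or headered) TSV with columns
#' `sequence_id`, `family`, `superfamily`.
#'
#' @param path path to the TSV manifest.
#' @return data.frame with columns `id`, `family`, `superfamily`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("sequence_id", first, fixed = TRUE)
  man <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(man) < 3L) stop("manifest must have 3 tab-separated columns")
  man <- man[, 1:3]
  names(man) <- c("id", "family", "superfamily")
  man
}

#' Construct a homology dataset
#'
#' Bundles sequences with their family/superfamily labels (a SCOP-style
#' two-level hierarchy).  Every family must map to exactly one
#' superfamily.
#'
#' @param sequences data.frame with columns `id`, `residues` and either
#'   `family`/`superfamily` columns or a separate `manifest`.
#' @param manifest optional data.frame with columns `id`, `family`,
#'   `superfamily` to be joined onto `sequences`.
#' @return an object of class `homology_dataset` with elements
#'   `sequences` (data.frame id/residues/family/superfamily) and
#'   `hierarchy` (named character vector family -> superfamily).
#' @export
homology_dataset <- function(sequences, manifest = NULL) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "residues") %in% names(sequences)))
  if (!is.null(manifest)) {
    m <- match(sequences$id, manifest$id)
    if (anyNA(m))
      stop("sequences missing from manifest: ",
           paste(utils::head(sequences$id[is.na(m)], 5), collapse = ", "))
    sequences$family <- manifest$family[m]
    sequences$superfamily <- manifest$superfamily[m]
  }
  if (!all(c("family", "superfamily") %in% names(sequences)))
    stop("sequences need family and superfamily labels (or a manifest)")
  if (anyDuplicated(sequences$id))
    stop("duplicate sequence ids in dataset")
  fam2sf <- unique(sequences[, c("family", "superfamily")])
  if (anyDuplicated(fam2sf$family))
    stop("a family maps to more than one superfamily")
  hierarchy <- stats::setNames(fam2sf$superfamily, fam2sf$family)
  rownames(sequences) <- NULL
  structure(list(sequences = sequences, hierarchy = hierarchy),
            class = "homology_dataset")
}

#' @export
print.homology_dataset <- function(x, ...) {
  cat("homology_dataset:", nrow(x$sequences), "sequences,",
      length(x$hierarchy), "families,",
      length(unique(x$hierarchy)), "superfamilies\n")
  invisible(x)
}

#' Number of balanced negative resamples
#'
#' Computes T, the number of balanced negative draws needed to cover the
#' remaining database in expectation:
#' `T = ceiling((D - (Tr+ + Te+)) / (Tr+ + Te+))`, where `D` is the total
#' database size and `Tr+`/`Te+` the positive training/test set sizes.
#'
#' @param D integer, total number of sequences in the database.
#' @param Tr_pos integer, positive training set size.
#' @param Te_pos integer, positive test set size.
#' @return integer T >= 1.
#' @examples
#' compute_T(100, 10, 10)  # 4
#' @export
compute_T <- function(D, Tr_pos, Te_pos) {
  pos <- Tr_pos + Te_pos
  if (pos <= 0) stop("positive set sizes must be positive")
  rem <- D - pos
  if (rem <= 0)
    stop("non-positive remaining pool: D = ", D, ", positives = ", pos)
  max(1L, as.integer(ceiling(rem / pos)))
}

#' Leave-one-family-out split
#'
#' Members of `target_family` become the positive test set; the other
#' members of its superfamily become the positive training set; every
#' sequence outside the superfamily forms the remaining pool from which
#' balanced negative sets are drawn.
#'
#' @param dataset a [homology_dataset()].
#' @param target_family family label to hold out.
#' @return an object of class `family_split` with fields `target_family`,
#'   `positive_test`, `positive_train`, `remaining_pool` (character id
#'   vectors) and `T` (number of negative resamples, see [compute_T()]).
#' @export
make_family_split <- function(dataset, target_family) {
  stopifnot(inherits(dataset, "homology_dataset"))
  seqs <- dataset$sequences
  if (!target_family %in% seqs$family)
    stop("unknown family: ", target_family)
  sf <- unname(dataset$hierarchy[[target_family]])
  in_fam <- seqs$family == target_family
  in_sf <- seqs$superfamily == sf
  positive_test <- seqs$id[in_fam]
  positive_train <- seqs$id[in_sf & !in_fam]
  remaining_pool <- seqs$id[!in_sf]
  if (length(positive_train) == 0L)
    stop("degenerate family '", target_family,
         "': no other sequences in superfamily '", sf, "'")
  T <- compute_T(nrow(seqs), length(positive_train), length(positive_test))
  structure(list(target_family = target_family,
                 superfamily = sf,
                 positive_test = positive_test,
                 positive_train = positive_train,
                 remaining_pool = remaining_pool,
                 T = T),
            class = "family_split")
}

#' @export
print.family_split <- function(x, ...) {
  cat("family_split for '", x$target_family, "': ",
      length(x$positive_test), " pos test, ",
      length(x$positive_train), " pos train, ",
      length(x$remaining_pool), " pool, T = ", x$T, "\n", sep = "")
  invisible(x)
}

# one master seed -> reproducible per-(family, run) stream, < 2^31
derive_seed <- function(master_seed, family, run_index) {
  h <- digest_string(paste(master_seed, family, run_index, sep = "\r"))
  h %% 2147483587L
}

# small deterministic string hash (FNV-1a-like, 31-bit)
digest_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Draw one balanced negative resample
#'
#' Samples, uniformly without replacement from the split's remaining
#' pool, a negative training set matched in size to the positive
#' training set and a disjoint negative test set matched to the positive
#' test set.  Deterministic given `(seed, run_index)`.
#'
#' @param split a [make_family_split()] result.
#' @param run_index integer in `[1, split$T]`.
#' @param seed integer master seed.
#' @return object of class `negative_resample` with `negative_train`,
#'   `negative_test`, `run_index`, `seed`.
#' @export
sample_negatives <- function(split, run_index, seed) {
  stopifnot(inherits(split, "family_split"))
  n_tr <- length(split$positive_train)
  n_te <- length(split$positive_test)
  pool <- split$remaining_pool
  if (length(pool) < n_tr + n_te)
    stop("remaining pool (", length(pool),
         ") smaller than balanced draw (", n_tr + n_te, ")")
  rs <- derive_seed(seed, split$target_family, run_index)
  drawn <- withr::with_seed(rs, sample(pool, n_tr + n_te))
  structure(list(run_index = as.integer(run_index),
                 seed = as.integer(seed),
                 negative_train = drawn[seq_len(n_tr)],
                 negative_test = drawn[n_tr + seq_len(n_te)]),
            class = "negative_resample")
}

#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment under BLOSUM62 with gap open 10
#' and gap extension 0.5; identity is the percentage of identical aligned
#' positions over the alignment length (a pairwise global alignment has
#' no dual-gap columns).  Symmetric in its arguments.
#'
#' @param a,b unaligned residue strings.
#' @return identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  as.numeric(Biostrings::pid(al, type = "PID1"))
}

blosum62_cache <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

#' Identity-filtered sub-database
#'
#' Greedy Hobohm-1-style reduction: sequences are visited in order of
#' decreasing length (ties by id) and kept iff their pairwise identity to
#' every already-kept sequence is below `threshold`.  Families left with
#' fewer than `min_family_size` members are dropped entirely.
#'
#' @param dataset a [homology_dataset()].
#' @param threshold identity percentage in `(0, 100]`.
#' @param min_family_size families smaller than this after filtering are
#'   removed (default 2: a split needs at least one test and one
#'   training candidate in the superfamily).
#' @return a filtered `homology_dataset`.
#' @export
filter_by_identity <- function(dataset, threshold, min_family_size = 2L) {
  stopifnot(inherits(dataset, "homology_dataset"))
  if (!(threshold > 0 && threshold <= 100))
    stop("threshold must be in (0, 100]")
  seqs <- dataset$sequences
  ord <- order(-nchar(seqs$residues), seqs$id)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(seqs$residues[i], seqs$residues[j]) >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- seqs[sort(kept), , drop = FALSE]
  tab <- table(out$family)
  keep_fam <- names(tab)[tab >= min_family_size]
  out <- out[out$family %in% keep_fam, , drop = FALSE]
  if (nrow(out) == 0L) stop("identity filter removed every sequence")
  homology_dataset(out)
}

#' Serialize a split and its resamples to JSON
#'
#' @param split a `family_split`.
#' @param resamples optional list of `negative_resample` objects.
#' @param path output path.
#' @export
write_split_json <- function(split, resamples = NULL, path) {
  obj <- unclass(split)
  if (!is.null(resamples)) obj$resamples <- lapply(resamples, unclass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
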