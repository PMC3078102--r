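#' Specification of a synthetic superfamily benchmark
#'
#' Describes one target superfamily of `n_families` families drawn from
#' a common ancestral sequence, with `n_conserved_columns` planted
#' columns that survive mutation (either a fixed residue, the
#' conserved-amino-acid signal, or a property group within which the
#' residue is resampled, the conserved-physico-chemical signal), plus
#' background-only decoy families forming the negative pool.  The
#' default substitution rate of 0.6 puts within-family identity around
#' 25 percent, i.e. inside the twilight zone the method targets; use
#' [calibrate_identity()] to hit a specific identity.
#'
#' @param n_families families in the target superfamily.
#' @param seqs_per_family sequences per family.
#' @param length sequence length (ancestral columns).
#' @param n_conserved_columns number of planted columns.
#' @param conserved_column_spec optional data.frame with columns
#'   `column`, `type` (`"fixed"`/`"group"`) and `value` (residue letter
#'   or group name); by default 60 percent fixed / 40 percent group
#'   columns are placed evenly, fixed residues cycling over C, K, W, H
#'   and groups cycling over small, hydrophobic, aromatic.
#' @param background residue probabilities (named, 20 canonical
#'   residues); default uniform.
#' @param substitution_rate per-site probability, outside planted
#'   columns, that a member's residue is replaced by a uniform draw
#'   from the 19 other residues.
#' @param indel_rate per-site probability of a single-residue deletion
#'   and, independently, of a single-residue insertion after the site
#'   (planted columns are never deleted); default 0.
#' @param n_decoy_families,decoy_seqs_per_family negative-pool decoys,
#'   each its own superfamily, drawn i.i.d. from the background.
#' @param seed integer seed; generation is fully deterministic.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(n_families = 2L,
                        seqs_per_family = 25L,
                        length = 100L,
                        n_conserved_columns = 10L,
                        conserved_column_spec = NULL,
                        background = NULL,
                        substitution_rate = 0.6,
                        indel_rate = 0,
                        n_decoy_families = 12L,
                        decoy_seqs_per_family = 15L,
                        seed = 42L) {
  if (n_conserved_columns > length)
    stop("n_conserved_columns must not exceed length")
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop("rates must lie in [0, 1]")
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_CANONICAL)
  if (!setequal(names(background), AA_CANONICAL) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be a probability vector over the 20 residues")
  if (is.null(conserved_column_spec) && n_conserved_columns > 0) {
    cols <- unique(round(seq(1, length,
                             length.out = n_conserved_columns + 2)))
    cols <- setdiff(cols, c(1L, as.integer(length)))
    while (length(cols) < n_conserved_columns)
      cols <- sort(union(cols, sample.int(length, 1)))
    cols <- sort(cols[seq_len(n_conserved_columns)])
    n_fixed <- ceiling(0.6 * n_conserved_columns)
    types <- rep(c("fixed", "group"),
                 c(n_fixed, n_conserved_columns - n_fixed))
    fixed_pool <- c("C", "K", "W", "H")
    group_pool <- c("small", "hydrophobic", "aromatic")
    vals <- character(n_conserved_columns)
    vals[types == "fixed"] <-
      rep_len(fixed_pool, sum(types == "fixed"))
    vals[types == "group"] <-
      rep_len(group_pool, sum(types == "group"))
    conserved_column_spec <- data.frame(column = cols, type = types,
                                        value = vals,
                                        stringsAsFactors = FALSE)
  }
  if (!is.null(conserved_column_spec)) {
    stopifnot(all(c("column", "type", "value") %in%
                    names(conserved_column_spec)))
    if (any(!conserved_column_spec$type %in% c("fixed", "group")))
      stop("conserved column types must be 'fixed' or 'group'")
    grp <- conserved_column_spec$type == "group"
    if (any(!conserved_column_spec$value[grp] %in% names(PROPERTY_GROUPS)))
      stop("unknown property group in conserved_column_spec")
    if (any(!toupper(conserved_column_spec$value[!grp]) %in% AA_CANONICAL))
      stop("fixed conserved residues must be canonical amino acids")
    if (any(conserved_column_spec$column < 1 |
            conserved_column_spec$column > length))
      stop("conserved columns out of range")
  }
  structure(list(n_families = as.integer(n_families),
                 seqs_per_family = as.integer(seqs_per_family),
                 length = as.integer(length),
                 n_conserved_columns = as.integer(n_conserved_columns),
                 conserved_column_spec = conserved_column_spec,
                 background = background,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 n_decoy_families = as.integer(n_decoy_families),
                 decoy_seqs_per_family = as.integer(decoy_seqs_per_family),
                 seed = as.integer(seed)),
            class = "family_spec")
}

draw_background <- function(n, background) {
  sample(names(background), n, replace = TRUE, prob = background)
}

# mutate: replace by a uniform draw among the 19 other residues
mutate_residues <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(ch)
      sample(setdiff(AA_CANONICAL, ch), 1), character(1))
  chars
}

#' Generate a labelled superfamily benchmark
#'
#' One ancestral sequence is drawn for the target superfamily; each
#' member mutates every non-planted position independently at the
#' substitution rate, keeps fixed planted residues unchanged and
#' resamples group planted columns within their property group.  Decoy
#' families (the negative pool) are drawn i.i.d. from the background
#' with no planted signal.  Also emits the true MSA of the target
#' superfamily (ancestral coordinates; with a non-zero indel rate,
#' deletions become gaps and single-residue insertions add
#' mostly-gap columns after their site).
#'
#' @param spec a [family_spec()].
#' @return list with `dataset` (a [homology_dataset()]), `msa` (an
#'   [as_alignment()] of the target superfamily), `truth` (planted
#'   columns incl. their MSA column indices, ancestor, seed) and `spec`.
#' @export
generate_superfamily <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, generate_superfamily_impl(spec))
}

generate_superfamily_impl <- function(spec) {
  L <- spec$length
  cc <- spec$conserved_column_spec
  planted <- if (is.null(cc)) integer(0) else cc$column
  ancestor <- draw_background(L, spec$background)
  if (length(planted)) {
    fixed <- cc$type == "fixed"
    ancestor[cc$column[fixed]] <- toupper(cc$value[fixed])
    for (i in which(!fixed))
      ancestor[cc$column[i]] <- sample(PROPERTY_GROUPS[[cc$value[i]]], 1)
  }
  free <- setdiff(seq_len(L), planted)

  ids <- character(0); fams <- character(0); sfs <- character(0)
  seqs <- character(0)
  rows <- list()   # per-member list(match = chars len L, ins = list)
  for (f in seq_len(spec$n_families)) {
    for (s in seq_len(spec$seqs_per_family)) {
      chars <- ancestor
      chars[free] <- mutate_residues(chars[free], spec$substitution_rate)
      if (length(planted)) {
        for (i in which(cc$type == "group"))
          chars[cc$column[i]] <- sample(PROPERTY_GROUPS[[cc$value[i]]], 1)
      }
      del <- rep(FALSE, L)
      ins <- vector("list", L)
      if (spec$indel_rate > 0) {
        del[free] <- stats::runif(length(free)) < spec$indel_rate
        ins_at <- which(stats::runif(L) < spec$indel_rate)
        for (j in ins_at)
          ins[[j]] <- draw_background(1, spec$background)
      }
      id <- sprintf("sf1_f%d_s%02d", f, s)
      ids <- c(ids, id)
      fams <- c(fams, sprintf("F%d", f))
      sfs <- c(sfs, "SF1")
      # unaligned sequence: surviving residues plus insertions in order
      parts <- character(0)
      for (j in seq_len(L)) {
        if (!del[j]) parts <- c(parts, chars[j])
        if (!is.null(ins[[j]])) parts <- c(parts, ins[[j]])
      }
      seqs <- c(seqs, paste(parts, collapse = ""))
      mrow <- chars
      mrow[del] <- "-"
      rows[[id]] <- list(match = mrow, ins = ins)
    }
  }

  # true MSA: ancestral columns, plus one insert column after site j
  # for each site where at least one member inserted
  has_ins <- if (spec$indel_rate > 0)
    Reduce(`|`, lapply(rows, function(r) !vapply(r$ins, is.null,
                                                 logical(1))))
  else rep(FALSE, L)
  # match column j lands at MSA position j + (#insert columns before j)
  ins_before <- cumsum(c(0L, as.integer(has_ins[-L])))
  msa_match_col <- seq_len(L) + ins_before
  msa_rows <- vapply(rows, function(r) {
    parts <- character(0)
    for (j in seq_len(L)) {
      parts <- c(parts, r$match[j])
      if (has_ins[j])
        parts <- c(parts, if (is.null(r$ins[[j]])) "-" else r$ins[[j]])
    }
    paste(parts, collapse = "")
  }, character(1))
  names(msa_rows) <- ids

  for (f in seq_len(spec$n_decoy_families)) {
    for (s in seq_len(spec$decoy_seqs_per_family)) {
      ids <- c(ids, sprintf("dec%d_s%02d", f, s))
      fams <- c(fams, sprintf("DF%d", f))
      sfs <- c(sfs, sprintf("DSF%d", f))
      seqs <- c(seqs, paste(draw_background(L, spec$background),
                            collapse = ""))
    }
  }

  dataset <- homology_dataset(data.frame(
    id = ids, residues = seqs, family = fams, superfamily = sfs,
    stringsAsFactors = FALSE))
  truth <- list(
    planted = if (is.null(cc)) cc else
      cbind(cc, msa_column = msa_match_col[cc$column]),
    ancestor = paste(ancestor, collapse = ""),
    seed = spec$seed)
  list(dataset = dataset,
       msa = as_alignment(msa_rows),
       truth = truth,
       spec = spec)
}

# mean within-family pairwise identity of a generated benchmark,
# measured on the true alignment coordinates (fraction of columns where
# both rows carry the same residue, over columns where neither is a gap)
mean_within_family_identity <- function(gen, max_pairs = 200L) {
  rows <- gen$msa$rows
  ids <- names(rows)
  fam <- gen$dataset$sequences$family[match(ids, gen$dataset$sequences$id)]
  pairs <- list()
  for (f in unique(fam)) {
    members <- ids[fam == f]
    if (length(members) < 2L) next
    cmb <- utils::combn(members, 2L)
    pairs <- c(pairs, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  if (length(pairs) > max_pairs)
    pairs <- pairs[round(seq(1, length(pairs), length.out = max_pairs))]
  idents <- vapply(pairs, function(p) {
    a <- strsplit(rows[[p[1]]], "")[[1]]
    b <- strsplit(rows[[p[2]]], "")[[1]]
    ok <- a != "-" & b != "-"
    100 * sum(a[ok] == b[ok]) / sum(ok)
  }, numeric(1))
  mean(idents)
}

#' Calibrate the substitution rate to a target identity
#'
#' Bisects the substitution rate so that the mean within-family pairwise
#' identity of the generated benchmark lands within +/- `tol` points of
#' `target`.  Fixed planted columns put a floor on attainable identity
#' (conserved positions always match); an unattainable target reports
#' that floor.
#'
#' @param spec a [family_spec()].
#' @param target identity percentage in `(0, 100)`.
#' @param tol acceptable deviation in identity points (default 5).
#' @param iterations bisection iterations (default 12).
#' @return the spec with `substitution_rate` set.
#' @export
calibrate_identity <- function(spec, target, tol = 5, iterations = 12L) {
  stopifnot(inherits(spec, "family_spec"))
  if (!(target > 0 && target < 100)) stop("target must be in (0, 100)")
  probe <- spec
  probe$n_families <- 1L
  probe$seqs_per_family <- min(spec$seqs_per_family, 10L)
  probe$n_decoy_families <- 0L
  ident_at <- function(rate) {
    probe$substitution_rate <- rate
    mean_within_family_identity(generate_superfamily(probe))
  }
  floor_id <- ident_at(1)
  if (target < floor_id - tol)
    stop(sprintf(
      "target %.1f%% unattainable: planted columns give a floor of %.1f%%",
      target, floor_id))
  lo <- 0; hi <- 1
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (ident_at(mid) > target) lo <- mid else hi <- mid
  }
  rate <- (lo + hi) / 2
  achieved <- ident_at(rate)
  if (abs(achieved - target) > tol)
    warning(sprintf("calibration reached %.1f%% (target %.1f%%)",
                    achieved, target))
  spec$substitution_rate <- rate
  spec
}

#' Write a generated benchmark to disk
#'
#' Emits unaligned FASTA, the true aligned FASTA of the target
#' superfamily, the dataset manifest TSV and a JSON truth file.
#'
#' @param gen a [generate_superfamily()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_benchmark <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- gen$dataset$sequences
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             msa = file.path(dir, "superfamily_msa.fasta"),
             manifest = file.path(dir, "manifest.tsv"),
             truth = file.path(dir, "truth.json"))
  writeLines(paste0(">", seqs$id, "\n", seqs$residues), paths["fasta"])
  writeLines(paste0(">", names(gen$msa$rows), "\n", gen$msa$rows),
             paths["msa"])
  utils::write.table(
    data.frame(sequence_id = seqs$id, family = seqs$family,
               superfamily = seqs$superfamily),
    paths["manifest"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted = gen$truth$planted, ancestor = gen$truth$ancestor,
         seed = gen$truth$seed,
         spec = unclass(gen$spec)[setdiff(names(unclass(gen$spec)),
                                          "conserved_column_spec")]),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
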