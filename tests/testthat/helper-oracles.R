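# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive: enumeration and pair counting,
# never the implementation paths under test.

# --- knowledge-base fixtures ----------------------------------------

# random KB over an artificial literal pool; examples e1..e<n>
random_kb <- function(n_examples, n_atoms, p_atom = 0.5, seed = 1) {
  pool <- c(sprintf("col(%s,%d)", letters[seq_len(max(1, n_atoms %/% 2))],
                    seq_len(max(1, n_atoms %/% 2))),
            sprintf("hydrophobic(%d)", seq_len(n_atoms)))[seq_len(n_atoms)]
  ids <- sprintf("e%d", seq_len(n_examples))
  atoms <- withr::with_seed(seed, lapply(ids, function(id)
    sort(pool[stats::runif(n_atoms) < p_atom])))
  names(atoms) <- ids
  structure(list(atoms = atoms, examples = ids, labels = NULL),
            class = "knowledge_base")
}

# toy KB from explicit atom lists
kb_from_list <- function(atom_list, labels = NULL) {
  structure(list(atoms = lapply(atom_list, sort),
                 examples = names(atom_list), labels = labels),
            class = "knowledge_base")
}

# --- miner oracle: exhaustive subset enumeration --------------------

brute_force_mine <- function(kb, bias) {
  pos <- if (is.null(kb$labels)) kb$examples else
    kb$examples[kb$labels[kb$examples] == "positive"]
  lits <- sort(unique(unlist(kb$atoms[pos], use.names = FALSE)),
               method = "radix")
  if (!is.null(bias$predicates))
    lits <- lits[sub("\\(.*$", "", lits) %in% bias$predicates]
  out <- list()
  for (k in seq_len(min(bias$max_length, length(lits)))) {
    for (body in utils::combn(lits, k, simplify = FALSE)) {
      cf <- mean(vapply(pos, function(id)
        all(body %in% kb$atoms[[id]]), logical(1)))
      if (cf >= bias$min_confidence - 1e-12)
        out[[length(out) + 1L]] <- list(body = body, confidence = cf)
    }
  }
  out
}

pattern_key <- function(body, confidence) {
  sprintf("%s|%.10f", paste(sort(body), collapse = ","), confidence)
}

mined_keys <- function(patterns) {
  sort(vapply(patterns, function(p)
    pattern_key(p$body, p$confidence), character(1)))
}

oracle_keys <- function(oracle) {
  sort(vapply(oracle, function(p)
    pattern_key(p$body, p$confidence), character(1)))
}

# --- Viterbi oracle: exhaustive path enumeration --------------------

# maximum log probability over all legal Begin-to-End state paths
enumerate_viterbi_logp <- function(phmm, query) {
  x <- strsplit(toupper(query), "")[[1]]
  L <- length(x)
  n <- phmm$n_nodes
  emis <- function(mat, row, ch)
    if (ch %in% colnames(mat)) mat[row, ch] else 1 / 20
  best <- -Inf
  rec <- function(kind, node, i, lp) {
    tr <- switch(kind, M = phmm$tM, I = phmm$tI, D = phmm$tD)[node + 1L, ]
    if (node == n) {
      if (i == L) best <<- max(best, lp + log(tr[["M"]]))
    } else {
      if (i < L)
        rec("M", node + 1L, i + 1L,
            lp + log(tr[["M"]]) +
              log(emis(phmm$match_emissions, node + 1L, x[i + 1L])))
      if (tr[["D"]] > 0)
        rec("D", node + 1L, i, lp + log(tr[["D"]]))
    }
    if (i < L)
      rec("I", node, i + 1L,
          lp + log(tr[["I"]]) +
            log(emis(phmm$insert_emissions, node + 1L, x[i + 1L])))
  }
  rec("M", 0L, 0L, 0)
  best
}

# random small alignment for model fixtures
random_alignment <- function(n_rows, n_cols, p_gap = 0.2, seed = 1) {
  withr::with_seed(seed, {
    rows <- vapply(seq_len(n_rows), function(r) {
      ch <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   n_cols, replace = TRUE)
      gap <- stats::runif(n_cols) < p_gap
      ch[gap] <- "-"
      paste(ch, collapse = "")
    }, character(1))
    # avoid all-gap rows
    rows[!grepl("[A-Z]", rows)] <- strrep("A", n_cols)
    names(rows) <- sprintf("r%d", seq_len(n_rows))
    as_alignment(rows)
  })
}

random_query <- function(len, seed = 1) {
  withr::with_seed(seed, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""))
}

# --- AUC oracle: explicit pair counting -----------------------------

pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# --- small shared benchmark (kept cheap for unit tests) -------------

small_benchmark <- function(seed = 5) {
  generate_superfamily(family_spec(
    n_families = 2L, seqs_per_family = 8L, length = 50L,
    n_conserved_columns = 6L, substitution_rate = 0.6,
    n_decoy_families = 6L, decoy_seqs_per_family = 6L, seed = seed))
}

# memoized full-scale benchmark + multi-config results shared by the
# acceptance criteria (computed once per test run)
.acceptance_env <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.acceptance_env$gen))
    .acceptance_env$gen <- generate_superfamily(family_spec())
  .acceptance_env$gen
}

acceptance_results <- function() {
  if (is.null(.acceptance_env$res)) {
    gen <- acceptance_benchmark()
    configs <- list(
      combined = run_config(seed = 11),
      seq_only = run_config(representations = "Seq", seed = 11),
      aln_cons = run_config(representations = "Aln_cons", seed = 11),
      aln_pc   = run_config(representations = "Aln_pc", seed = 11),
      tree     = run_config(classifier = "tree", seed = 11),
      shuffled = run_config(seed = 11, shuffle_labels = TRUE))
    .acceptance_env$res <- run_benchmark(gen$dataset, configs,
                                         alignment = gen$msa)
  }
  .acceptance_env$res
}
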