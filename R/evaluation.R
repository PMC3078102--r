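#' Rank-based AUC-ROC
#'
#' The Mann-Whitney statistic: the probability that a random positive
#' outscores a random negative, with ties counted half (midrank
#' convention, equal to trapezoidal ROC area).
#'
#' @param scores numeric vector.
#' @param labels logical vector (TRUE = positive) or a character vector
#'   with values `"positive"`/`"negative"`, same length as `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "positive"
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Two-sided Wilcoxon rank-sum comparison of per-family AUCs
#'
#' Exact enumeration for small untied samples (both sizes below 10),
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric vectors of per-family mean AUCs.
#' @return two-sided p-value.
#' @export
rank_sum_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) < 10L && length(b) < 10L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  # degenerate case: every observation tied -> zero rank variance; no
  # evidence of a difference, report the maximal p-value
  if (is.nan(p)) p <- 1
  p
}

#' AUC-versus-family-count curve
#'
#' For each threshold, the number of families whose mean AUC is at
#' least the threshold (a non-increasing step curve).
#'
#' @param result a `benchmark_result` (or a numeric vector of family
#'   mean AUCs).
#' @param thresholds AUC grid (default 0 to 1 by 0.05).
#' @return data.frame with columns `threshold`, `n_families`.
#' @export
auc_vs_family_curve <- function(result, thresholds = seq(0, 1, by = 0.05)) {
  means <- if (inherits(result, "benchmark_result"))
    vapply(result$families, function(f) f$mean_auc, numeric(1))
  else as.numeric(result)
  if (length(means) == 0L) stop("no families")
  data.frame(threshold = thresholds,
             n_families = vapply(thresholds,
                                 function(t) sum(means >= t), numeric(1)))
}

#' Pipeline run configuration
#'
#' Defaults mirror the method's reference settings: mining confidence
#' thresholds 25 percent for `Seq` and `Aln_cons`, 50 percent for
#' `Aln_pc`; rule bodies up to 3 literals; RBF-kernel SVM with C = 1 and
#' `gamma = 1/n_features`; chi-square selection off.
#'
#' @param representations subset of `c("Seq", "Aln_cons", "Aln_pc")`.
#' @param thresholds named per-representation confidence thresholds in
#'   `(0, 1]`.
#' @param max_length maximum rule body length.
#' @param classifier `"svm"` or `"tree"`.
#' @param delta chi-square significance level in `(0, 1)`, or NULL for
#'   no selection.
#' @param seed master seed; all per-family, per-run randomness is
#'   derived from it.
#' @param svm_C,svm_gamma SVM hyperparameters (`NULL` gamma means
#'   `1/n_features`).
#' @param shuffle_labels permute training labels per run (diagnostic
#'   null control; expected AUC 0.5).
#' @param n_runs optionally cap the number of negative resamples per
#'   family (default NULL: use the split's computed T).
#' @return object of class `run_config`.
#' @export
run_config <- function(representations = c("Seq", "Aln_cons", "Aln_pc"),
                       thresholds = c(Seq = 0.25, Aln_cons = 0.25,
                                      Aln_pc = 0.5),
                       max_length = 3L,
                       classifier = c("svm", "tree"),
                       delta = NULL,
                       seed = 1L,
                       svm_C = 1, svm_gamma = NULL,
                       shuffle_labels = FALSE,
                       n_runs = NULL) {
  problems <- character(0)
  reps_ok <- length(representations) > 0 &&
    all(representations %in% c("Seq", "Aln_cons", "Aln_pc"))
  if (!reps_ok)
    problems <- c(problems,
                  "representations must be a non-empty subset of Seq/Aln_cons/Aln_pc")
  classifier <- classifier[1]
  if (!classifier %in% c("svm", "tree"))
    problems <- c(problems, "classifier must be 'svm' or 'tree'")
  if (reps_ok && !all(representations %in% names(thresholds)))
    problems <- c(problems, "thresholds must name every representation")
  th <- suppressWarnings(as.numeric(thresholds))
  if (any(is.na(th)) || any(th <= 0 | th > 1))
    problems <- c(problems, "thresholds must lie in (0, 1]")
  if (!is.numeric(max_length) || max_length < 1)
    problems <- c(problems, "max_length must be >= 1")
  if (!is.null(delta) && !(is.numeric(delta) && delta > 0 && delta < 1))
    problems <- c(problems, "delta must be in (0, 1) or NULL")
  if (!is.numeric(seed) || is.na(seed))
    problems <- c(problems, "seed must be an integer")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(list(representations = representations,
                 thresholds = thresholds,
                 max_length = as.integer(max_length),
                 classifier = classifier,
                 delta = delta,
                 seed = as.integer(seed),
                 svm_C = svm_C, svm_gamma = svm_gamma,
                 shuffle_labels = isTRUE(shuffle_labels),
                 n_runs = if (is.null(n_runs)) NULL else as.integer(n_runs)),
            class = "run_config")
}

# training alignment for the positive training set: user-supplied MSA
# (subset to the training rows), mafft, or the trivial alignment when
# all training sequences have equal length
resolve_training_alignment <- function(dataset, split, alignment = NULL,
                                       aligner = c("provided", "mafft")) {
  aligner <- match.arg(aligner)
  ids <- split$positive_train
  seqs <- dataset$sequences
  if (!is.null(alignment)) {
    if (!all(ids %in% names(alignment$rows)))
      stop("supplied alignment is missing positive training rows")
    return(as_alignment(alignment$rows[ids]))
  }
  res <- seqs$residues[match(ids, seqs$id)]
  if (aligner == "mafft")
    return(align_with_mafft(data.frame(id = ids, residues = res)))
  if (length(unique(nchar(res))) == 1L)
    return(as_alignment(stats::setNames(res, ids)))
  stop("positive training sequences have unequal lengths; supply an ",
       "alignment or use aligner = 'mafft'")
}

#' Align sequences with the external mafft binary
#'
#' Optional adapter around a system `mafft` installation; the internal
#' trivial/provided-alignment paths are the tested defaults.
#'
#' @param sequences data.frame with `id`, `residues`.
#' @return an [as_alignment()] object.
#' @export
align_with_mafft <- function(sequences) {
  if (Sys.which("mafft") == "")
    stop("mafft binary not found on PATH")
  fa <- tempfile(fileext = ".fasta")
  out <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", sequences$id, "\n", sequences$residues), fa)
  status <- system2("mafft", c("--auto", "--quiet", "--anysymbol", fa),
                    stdout = out)
  if (status != 0L) stop("mafft failed with status ", status)
  read_alignment(out, "fasta")
}

# mine per representation with memoization across configurations
mine_cached <- function(kb_pos, rep, threshold, max_length, cache) {
  key <- paste(rep, threshold, max_length, sep = "\r")
  if (is.null(cache[[key]]))
    cache[[key]] <- mine_representations(kb_pos, rep,
                                         stats::setNames(threshold, rep),
                                         max_length)
  cache[[key]]
}

# build a feature matrix for a model's exact rule set
features_for_model <- function(model, kb) {
  fm <- propositionalize(model$rules, kb)
  fm$rule_ids <- model$rule_ids
  colnames(fm$values) <- model$rule_ids
  fm
}

# core engine: one family, several configurations sharing Viterbi
# decodes, atoms and per-representation rule sets
family_eval_multi <- function(dataset, target_family, configs,
                              alignment = NULL,
                              aligner = "provided") {
  stopifnot(inherits(dataset, "homology_dataset"), length(configs) >= 1L)
  if (is.null(names(configs)))
    names(configs) <- sprintf("config%d", seq_along(configs))
  split <- make_family_split(dataset, target_family)
  seqs <- dataset$sequences
  seq_df <- function(ids) seqs[match(ids, seqs$id), c("id", "residues")]

  train_aln <- resolve_training_alignment(dataset, split, alignment,
                                          aligner)
  phmm <- build_phmm(train_aln)
  atom_cache <- new.env(parent = emptyenv())
  rule_cache <- new.env(parent = emptyenv())
  all_reps <- unique(unlist(lapply(configs, `[[`, "representations")))

  # positive-training KB is negative-free: mine once per representation
  kb_pos_train <- build_kb(seq_df(split$positive_train), all_reps,
                           phmm = phmm, alignment = train_aln,
                           atom_cache = atom_cache)
  rules_of <- lapply(configs, function(cfg) {
    unlist(lapply(cfg$representations, function(rep)
      mine_cached(kb_pos_train, rep, cfg$thresholds[[rep]],
                  cfg$max_length, rule_cache)),
      recursive = FALSE)
  })

  n_runs <- vapply(configs, function(cfg)
    if (is.null(cfg$n_runs)) split$T else min(cfg$n_runs, split$T),
    integer(1))
  T_max <- max(n_runs)
  per_run <- lapply(configs, function(cfg) numeric(0))

  for (t in seq_len(T_max)) {
    active <- names(configs)[n_runs >= t]
    seeds <- vapply(configs[active], `[[`, integer(1), "seed")
    if (length(unique(seeds)) != 1L)
      stop("all configurations must share one master seed")
    resample <- sample_negatives(split, t, seeds[[1]])
    train_ids <- c(split$positive_train, resample$negative_train)
    test_ids <- c(split$positive_test, resample$negative_test)
    train_labels <- stats::setNames(
      rep(c("positive", "negative"),
          c(length(split$positive_train), length(resample$negative_train))),
      train_ids)
    test_labels <- stats::setNames(
      rep(c("positive", "negative"),
          c(length(split$positive_test), length(resample$negative_test))),
      test_ids)
    kb_train <- build_kb(seq_df(train_ids), all_reps, phmm = phmm,
                         alignment = train_aln, labels = train_labels,
                         atom_cache = atom_cache)
    kb_test <- build_kb(seq_df(test_ids), all_reps, phmm = phmm,
                        alignment = train_aln, labels = test_labels,
                        atom_cache = atom_cache)
    for (nm in active) {
      cfg <- configs[[nm]]
      rules <- rules_of[[nm]]
      if (length(rules) == 0L)
        stop("no rules mined for configuration '", nm, "' on family '",
             target_family, "'; lower the confidence threshold")
      fm_train <- propositionalize(rules, kb_train)
      if (!is.null(cfg$delta)) {
        fm_train <- chi_square_select(fm_train, cfg$delta)
        if (ncol(fm_train$values) == 0L)
          stop("chi-square at delta = ", cfg$delta, " removed every rule ",
               "for family '", target_family, "' (run ", t, ")")
      }
      if (cfg$shuffle_labels) {
        sseed <- derive_seed(cfg$seed + 1L, target_family, t)
        fm_train$labels <- withr::with_seed(
          sseed, stats::setNames(sample(unname(fm_train$labels)),
                                 names(fm_train$labels)))
      }
      model <- train_model(fm_train, cfg$classifier,
                           seed = derive_seed(cfg$seed, target_family, t),
                           C = cfg$svm_C, gamma = cfg$svm_gamma)
      fm_test <- features_for_model(model, kb_test)
      sc <- score_model(model, fm_test)
      per_run[[nm]] <- c(per_run[[nm]],
                         auc_roc(sc, test_labels[names(sc)] == "positive"))
    }
  }

  lapply(stats::setNames(names(configs), names(configs)), function(nm) {
    aucs <- per_run[[nm]]
    structure(list(family = target_family,
                   per_run_auc = aucs,
                   mean_auc = mean(aucs),
                   T = length(aucs),
                   n_rules = length(rules_of[[nm]])),
              class = "family_result")
  })
}

#' Evaluate one family under the resampling protocol
#'
#' Runs the full pipeline for one leave-one-family-out split: per run,
#' sample balanced negatives, build knowledge bases (the profile HMM is
#' built from the positive-training alignment only), mine rules on the
#' positive training KB, propositionalize, optionally chi-square select,
#' train, score the test examples and compute the AUC-ROC.  Fully
#' seeded: identical inputs give identical results.
#'
#' @param dataset a [homology_dataset()].
#' @param target_family family label to hold out.
#' @param config a [run_config()].
#' @param alignment optional [as_alignment()] covering (at least) the
#'   positive training sequences; without it, equal-length training
#'   sequences are stacked as-is, or set `aligner = "mafft"`.
#' @param aligner `"provided"` (default) or `"mafft"`.
#' @return object of class `family_result` with `per_run_auc`,
#'   `mean_auc`, `T` and `n_rules`.
#' @export
evaluate_family <- function(dataset, target_family, config = run_config(),
                            alignment = NULL, aligner = "provided") {
  family_eval_multi(dataset, target_family, list(run = config),
                    alignment, aligner)[[1]]
}

#' @export
print.family_result <- function(x, ...) {
  cat(sprintf("family_result '%s': mean AUC %.3f over %d runs (%d rules)\n",
              x$family, x$mean_auc, x$T, x$n_rules))
  invisible(x)
}

#' Run the benchmark protocol over families and configurations
#'
#' Evaluates every (or a chosen subset of) family under each
#' configuration, sharing sequence decoding and per-representation rule
#' mining across configurations, and averages mean AUCs over families.
#'
#' @param dataset a [homology_dataset()].
#' @param configs named list of [run_config()]s (all sharing one master
#'   seed).
#' @param alignment optional [as_alignment()] of the positive
#'   superfamily (rows are subset per split).
#' @param families family labels to evaluate (default: every family
#'   whose split is non-degenerate).
#' @param aligner see [evaluate_family()].
#' @return named list of `benchmark_result` objects (one per config):
#'   `method`, `families` (list of `family_result`) and `overall_auc`.
#' @export
run_benchmark <- function(dataset, configs, alignment = NULL,
                          families = NULL, aligner = "provided") {
  stopifnot(inherits(dataset, "homology_dataset"))
  if (inherits(configs, "run_config")) configs <- list(run = configs)
  if (is.null(families)) {
    families <- names(dataset$hierarchy)
    ok <- vapply(families, function(f) {
      sf <- dataset$hierarchy[[f]]
      sum(dataset$sequences$superfamily == sf &
            dataset$sequences$family != f) > 0
    }, logical(1))
    families <- families[ok]
  }
  per_family <- lapply(families, function(f)
    family_eval_multi(dataset, f, configs, alignment, aligner))
  names(per_family) <- families
  lapply(stats::setNames(names(configs), names(configs)), function(nm) {
    fams <- lapply(per_family, `[[`, nm)
    structure(list(method = nm,
                   families = fams,
                   overall_auc = mean(vapply(fams, `[[`, numeric(1),
                                             "mean_auc"))),
              class = "benchmark_result")
  })
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result '%s': overall AUC %.3f over %d families\n",
              x$method, x$overall_auc, length(x$families)))
  invisible(x)
}

#' Write benchmark results as TSV (family, run, auc) plus JSON summary
#'
#' @param result a `benchmark_result`.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @param config optional `run_config` recorded in the JSON summary.
#' @export
write_results <- function(result, tsv_path = NULL, json_path = NULL,
                          config = NULL) {
  stopifnot(inherits(result, "benchmark_result"))
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(result$families, function(f)
      data.frame(family = f$family, run = seq_along(f$per_run_auc),
                 auc = f$per_run_auc)))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    obj <- list(method = result$method,
                overall_auc = result$overall_auc,
                families = lapply(result$families, function(f)
                  list(family = f$family, mean_auc = f$mean_auc,
                       per_run_auc = f$per_run_auc,
                       n_rules = f$n_rules)))
    if (!is.null(config)) {
      obj$config <- unclass(config)
      obj$config_hash <- digest_string(
        paste(deparse(unclass(config)), collapse = ""))
    }
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(result)
}
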