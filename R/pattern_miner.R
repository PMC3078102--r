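#' Language bias for the pattern miner
#'
#' The mined language is the set of conjunctions of fully instantiated
#' literals (constants observed in the positive knowledge base), all
#' sharing the example variable.  A total canonical order over literals
#' (C-locale lexicographic on the rendered literal, i.e. predicate name
#' then arguments) makes candidate generation duplicate-free.
#'
#' @param max_length maximum body length (default 3, the longest rule
#'   shape the method needs).
#' @param min_confidence minimum fraction of positive examples a pattern
#'   must cover, in `(0, 1]`.
#' @param predicates optional character vector restricting the allowed
#'   predicate names (e.g. `"col"` for the conserved-column
#'   representation); NULL allows every predicate present.
#' @return object of class `language_bias`.
#' @export
language_bias <- function(max_length = 3L, min_confidence = 0.25,
                          predicates = NULL) {
  if (!(min_confidence > 0 && min_confidence <= 1))
    stop("min_confidence must be in (0, 1]")
  if (max_length < 1L) stop("max_length must be >= 1")
  structure(list(max_length = as.integer(max_length),
                 min_confidence = min_confidence,
                 predicates = predicates),
            class = "language_bias")
}

#' Construct a pattern
#'
#' @param body character vector of literal keys (sorted canonically).
#' @param confidence optional confidence in `[0, 1]`.
#' @return object of class `pattern`.
#' @export
pattern <- function(body = character(0), confidence = NA_real_) {
  body <- sort(unique(as.character(body)), method = "radix")
  structure(list(body = body, length = length(body),
                 confidence = confidence),
            class = "pattern")
}

#' @export
print.pattern <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Does a pattern cover an example?
#'
#' A pattern covers an example iff every literal of its body, with the
#' example variable bound to the example id, is a ground atom of that
#' example.  The empty body covers everything.
#'
#' @param pattern a [pattern()].
#' @param kb a [build_kb()] knowledge base.
#' @param example_id example identifier present in `kb`.
#' @return logical.
#' @export
covers <- function(pattern, kb, example_id) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (!example_id %in% kb$examples)
    stop("unknown example: ", example_id)
  all(pattern$body %in% kb$atoms[[example_id]])
}

#' Confidence of a pattern
#'
#' Fraction of positive examples of the knowledge base covered by the
#' pattern (all examples when the KB is unlabeled, as in a
#' positive-training KB).
#'
#' @param pattern a [pattern()].
#' @param kb a knowledge base with at least one positive example.
#' @return fraction in `[0, 1]`.
#' @export
confidence <- function(pattern, kb) {
  pos <- positive_ids(kb)
  if (length(pos) == 0L) stop("knowledge base has no positive examples")
  mean(vapply(pos, function(id) covers(pattern, kb, id), logical(1)))
}

#' Refine a pattern by one literal
#'
#' Returns all length+1 extensions obtained by appending one literal
#' observed in the positive examples, canonically greater than the last
#' literal of the body (so each conjunction is generated exactly once).
#'
#' @param pattern a [pattern()].
#' @param bias a [language_bias()].
#' @param kb the positive knowledge base supplying candidate literals.
#' @return list of `pattern`s (without confidences).
#' @export
refine <- function(pattern, bias, kb) {
  cand <- candidate_literals(kb, bias)
  if (length(pattern$body))
    cand <- cand[cand > pattern$body[pattern$length]]
  lapply(cand, function(l) {
    p <- structure(list(body = c(pattern$body, l),
                        length = pattern$length + 1L,
                        confidence = NA_real_),
                   class = "pattern")
    p
  })
}

# distinct literals over positive examples, bias-filtered, canonical order
candidate_literals <- function(kb, bias) {
  pos <- positive_ids(kb)
  lits <- sort(unique(unlist(kb$atoms[pos], use.names = FALSE)),
               method = "radix")
  if (!is.null(bias$predicates))
    lits <- lits[literal_predicate(lits) %in% bias$predicates]
  lits
}

#' Mine frequent patterns (level-wise, APRIORI-style)
#'
#' Finds exactly the conjunctive patterns of length 1..`max_length` over
#' the instantiated-literal language whose confidence on the positive
#' examples is at least `min_confidence`, using level-wise candidate
#' generation with anti-monotone support pruning.  Output order is
#' deterministic: by length, then canonical body order.
#'
#' @param kb_positive knowledge base of the positive training examples.
#' @param bias a [language_bias()].
#' @return list of `pattern`s with confidences.
#' @export
mine <- function(kb_positive, bias = language_bias()) {
  stopifnot(inherits(kb_positive, "knowledge_base"),
            inherits(bias, "language_bias"))
  pos <- positive_ids(kb_positive)
  if (length(pos) == 0L) stop("positive knowledge base is empty")
  lits <- candidate_literals(kb_positive, bias)
  if (length(lits) == 0L) return(list())
  npos <- length(pos)

  # coverage matrix: positives x literals
  cov <- vapply(lits, function(l)
    vapply(pos, function(id) l %in% kb_positive$atoms[[id]], logical(1)),
    logical(npos))
  cov <- matrix(cov, nrow = npos,
                dimnames = list(pos, lits))

  minc <- bias$min_confidence
  thr <- minc * npos - 1e-9  # minimum covered-positive count

  conf1 <- colMeans(cov)
  freq_idx <- which(conf1 >= minc - 1e-12)
  # frequent k-sets as a k x m integer matrix of literal indices
  # (columns canonically ordered), with per-set coverage and confidence
  level_sets <- matrix(freq_idx, nrow = 1)
  level_cov <- cov[, freq_idx, drop = FALSE]
  level_conf <- conf1[freq_idx]
  all_sets <- list(level_sets)
  all_conf <- list(level_conf)

  k <- 1L
  while (k < bias$max_length && ncol(level_sets) >= 2L) {
    final <- (k + 1L) == bias$max_length
    prefix_key <- if (k == 1L) rep("", ncol(level_sets)) else
      apply(level_sets[-k, , drop = FALSE], 2, paste, collapse = " ")
    groups <- split(seq_len(ncol(level_sets)), prefix_key)
    new_sets <- list(); new_cov <- list(); new_conf <- list()
    for (g in groups) {
      m <- length(g)
      if (m < 2L) next
      g <- g[order(level_sets[k, g])]
      V <- level_cov[, g, drop = FALSE]
      cnt <- crossprod(V * 1L)            # joint support of all pairs
      keep <- which(upper.tri(cnt) & cnt >= thr, arr.ind = TRUE)
      if (nrow(keep) == 0L) next
      sets <- rbind(level_sets[, g[keep[, 1L]], drop = FALSE],
                    level_sets[k, g[keep[, 2L]]])
      new_sets[[length(new_sets) + 1L]] <- sets
      new_conf[[length(new_conf) + 1L]] <- cnt[keep] / npos
      if (!final)
        new_cov[[length(new_cov) + 1L]] <-
          V[, keep[, 1L], drop = FALSE] & V[, keep[, 2L], drop = FALSE]
    }
    k <- k + 1L
    if (length(new_sets) == 0L) break
    level_sets <- do.call(cbind, new_sets)
    level_conf <- unlist(new_conf)
    level_cov <- if (final) NULL else do.call(cbind, new_cov)
    all_sets <- c(all_sets, list(level_sets))
    all_conf <- c(all_conf, list(level_conf))
    if (final) break
  }

  # materialize patterns in canonical order: length, then body
  out <- list()
  for (lev in seq_along(all_sets)) {
    sets <- all_sets[[lev]]
    confs <- all_conf[[lev]]
    if (ncol(sets) == 0L) next
    bodies <- lapply(seq_len(ncol(sets)), function(j) lits[sets[, j]])
    keys <- vapply(bodies, paste, character(1), collapse = " ")
    ord <- order(keys, method = "radix")
    out <- c(out, lapply(ord, function(j)
      structure(list(body = bodies[[j]], length = nrow(sets),
                     confidence = unname(confs[j])),
                class = "pattern")))
  }
  out
}

#' Mine each representation at its own threshold
#'
#' Runs the miner once per selected representation with its confidence
#' threshold (defaults: 25 percent for `Seq` and `Aln_cons`, 50 percent
#' for `Aln_pc`) and concatenates the rule sets.
#'
#' @param kb_positive positive-training knowledge base holding atoms of
#'   all selected representations.
#' @param representations subset of `c("Seq", "Aln_cons", "Aln_pc")`.
#' @param thresholds named numeric vector of per-representation
#'   confidence thresholds.
#' @param max_length maximum body length.
#' @return list of `pattern`s.
#' @export
mine_representations <- function(kb_positive,
                                 representations = c("Seq", "Aln_cons",
                                                     "Aln_pc"),
                                 thresholds = c(Seq = 0.25,
                                                Aln_cons = 0.25,
                                                Aln_pc = 0.5),
                                 max_length = 3L) {
  representations <- match.arg(representations,
                               c("Seq", "Aln_cons", "Aln_pc"),
                               several.ok = TRUE)
  preds_of <- list(
    Seq = c(names(PROPERTY_GROUPS), "aminoacidRatio", "aminoacidPairRatio"),
    Aln_cons = "col",
    Aln_pc = "colProp")
  out <- list()
  for (rep in representations) {
    bias <- language_bias(max_length = max_length,
                          min_confidence = thresholds[[rep]],
                          predicates = preds_of[[rep]])
    out <- c(out, mine(kb_positive, bias))
  }
  out
}

# render a pattern Prolog-style; colProp literals are expanded into the
# two-literal col/group form with fresh variables
format_rule <- function(pattern, pretty_colprop = TRUE) {
  body <- pattern$body
  if (length(body) == 0L) body_str <- "true"
  else {
    vcount <- 0L
    parts <- vapply(body, function(lit) {
      m <- regexec("^colProp\\(([A-Za-z]+),([0-9]+)\\)$", lit)
      g <- regmatches(lit, m)[[1]]
      if (pretty_colprop && length(g) == 3L) {
        vcount <<- vcount + 1L
        v <- paste0("B", vcount)
        sprintf("col(A,%s,%s), %s(%s)", v, g[3], g[2], v)
      } else {
        render_atom("A", lit)
      }
    }, character(1))
    body_str <- paste(parts, collapse = ", ")
  }
  conf <- if (is.na(pattern$confidence)) "" else
    sprintf(" %% %.2f", pattern$confidence)
  sprintf("homologous(A) :- %s.%s", body_str, conf)
}

#' Write mined rules to a text file
#'
#' One rule per line in Prolog-like syntax with the confidence as a
#' trailing comment, e.g.
#' `homologous(A) :- col(A,c,24), col(A,c,27). % 1.00`.
#' Conserved physico-chemical patterns are rendered in their two-literal
#' `col(A,B,z), group(B)` form.
#'
#' @param rules list of `pattern`s.
#' @param path output path.
#' @param header optional comment lines (each prefixed with `%`).
#' @export
write_rules <- function(rules, path, header = NULL) {
  lines <- vapply(rules, format_rule, character(1))
  if (!is.null(header)) lines <- c(paste("%", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write mined rules as JSON (machine-readable, round-trippable)
#' @param rules list of `pattern`s.
#' @param path output path.
#' @export
write_rules_json <- function(rules, path) {
  obj <- lapply(rules, function(p)
    list(body = as.list(p$body), confidence = p$confidence))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read rules written by [write_rules_json()]
#' @param path input path.
#' @return list of `pattern`s.
#' @export
read_rules_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(o)
    pattern(unlist(o$body), confidence = o$confidence))
}
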