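#' Multiple sequence alignment container
#'
#' @param rows named character vector of gapped rows (gap character `-`),
#'   all of equal length; at least two rows.
#' @return object of class `msa` with elements `rows` and `length`.
#' @export
as_alignment <- function(rows) {
  if (is.list(rows)) rows <- unlist(rows)
  stopifnot(is.character(rows))
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by sequence id")
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  structure(list(rows = rows, length = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$rows), "rows x", x$length, "columns\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and CLUSTAL format (auto-detected from the
#' first non-blank line).
#'
#' @param path file path.
#' @param format one of "auto", "fasta", "clustal".
#' @return an [as_alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    first <- ""
    for (l in readLines(path, n = 20L)) {
      if (nzchar(trimws(l))) { first <- l; break }
    }
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
              else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    rows <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  } else {
    rows <- parse_clustal(readLines(path))
  }
  as_alignment(rows)
}

# CLUSTAL block parser: "<name><ws><segment>[<ws><count>]" lines,
# conservation lines start with whitespace and are skipped.
parse_clustal <- function(lines) {
  acc <- list()
  for (l in lines) {
    if (grepl("^CLUSTAL", l, ignore.case = TRUE)) next
    if (!nzchar(trimws(l))) next
    if (grepl("^\\s", l)) next  # conservation annotation row
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(parts) < 2L) next
    name <- parts[1]
    seg <- parts[2]
    acc[[name]] <- paste0(if (is.null(acc[[name]])) "" else acc[[name]], seg)
  }
  if (length(acc) < 2L) stop("could not parse CLUSTAL alignment")
  unlist(acc)
}

#' Build a profile HMM from a positive-training alignment
#'
#' Columns with gap fraction below `max_gap_frac` become match states
#' (HMMER-style heuristic); the remaining columns are modeled by the
#' flanking insert states.  Emission and transition probabilities are
#' maximum-likelihood estimates with Laplace add-`pseudocount`
#' smoothing; the background distribution is uniform over the 20
#' canonical residues.  Architecture is global (begin-to-end): node `k`
#' offers transitions to `M[k+1]`, self-insert `I[k]` and `D[k+1]`
#' (to End at the last node).
#'
#' @param alignment an [as_alignment()] object.
#' @param pseudocount Laplace pseudocount added to every emission and
#'   legal transition count (default 1).
#' @param max_gap_frac a column is a match column iff its gap fraction is
#'   strictly below this value (default 0.5).
#' @return object of class `profile_hmm` with fields `n_nodes`,
#'   `match_columns`, `match_emissions` (n x 20), `insert_emissions`
#'   ((n+1) x 20, node 0 = N-terminal insert), `tM`, `tI`, `tD`
#'   ((n+1) x 3 transition matrices over successors M/I/D, rows are
#'   source nodes 0..n; at the last node the "M" slot is the End
#'   transition and "D" is impossible) and `background`.
#' @export
build_phmm <- function(alignment, pseudocount = 1, max_gap_frac = 0.5) {
  stopifnot(inherits(alignment, "msa"))
  rows <- alignment$rows
  W <- alignment$length
  nr <- length(rows)
  chr <- matrix(unlist(strsplit(rows, "")), nrow = nr, byrow = TRUE)
  gap_frac <- colMeans(chr == "-")
  match_cols <- which(gap_frac < max_gap_frac)
  n <- length(match_cols)
  if (n == 0L)
    stop("no match columns: every column has gap fraction >= ",
         max_gap_frac)
  aa <- AA_CANONICAL
  a <- pseudocount

  eM <- matrix(a, n, 20, dimnames = list(NULL, aa))
  eI <- matrix(a, n + 1, 20, dimnames = list(NULL, aa))
  # transition counts, rows = source node 0..n, cols = successor M/I/D
  cM <- matrix(0, n + 1, 3, dimnames = list(NULL, c("M", "I", "D")))
  cI <- cM
  cD <- cM

  is_match <- logical(W)
  is_match[match_cols] <- TRUE
  node_of_col <- cumsum(is_match)  # node index a column belongs to/preceding

  for (r in seq_len(nr)) {
    prev_kind <- "M"  # Begin acts as M at node 0
    prev_node <- 0L
    for (j in seq_len(W)) {
      ch <- chr[r, j]
      if (is_match[j]) {
        k <- node_of_col[j]
        kind <- if (ch == "-") "D" else "M"
        if (kind == "M" && ch %in% aa) eM[k, ch] <- eM[k, ch] + 1
        tc <- switch(prev_kind, M = "cM", I = "cI", D = "cD")
        m <- get(tc)
        m[prev_node + 1L, kind] <- m[prev_node + 1L, kind] + 1
        assign(tc, m)
        prev_kind <- kind
        prev_node <- k
      } else if (ch != "-") {
        k <- node_of_col[j]  # insert after node k
        if (ch %in% aa) eI[k + 1L, ch] <- eI[k + 1L, ch] + 1
        tc <- switch(prev_kind, M = "cM", I = "cI", D = "cD")
        m <- get(tc)
        m[prev_node + 1L, "I"] <- m[prev_node + 1L, "I"] + 1
        assign(tc, m)
        prev_kind <- "I"
        prev_node <- k
      }
    }
    # transition to End, recorded in the "M" slot of the last node
    tc <- switch(prev_kind, M = "cM", I = "cI", D = "cD")
    m <- get(tc)
    m[n + 1L, "M"] <- m[n + 1L, "M"] + 1
    assign(tc, m)
  }

  norm_trans <- function(cnt) {
    out <- matrix(0, n + 1, 3, dimnames = list(NULL, c("M", "I", "D")))
    for (k in 0:n) {
      legal <- if (k == n) c("M", "I") else c("M", "I", "D")
      v <- cnt[k + 1L, legal] + a
      out[k + 1L, legal] <- v / sum(v)
    }
    out
  }

  phmm <- structure(list(
    n_nodes = n,
    match_columns = match_cols,
    match_emissions = eM / rowSums(eM),
    insert_emissions = eI / rowSums(eI),
    tM = norm_trans(cM),
    tI = norm_trans(cI),
    tD = norm_trans(cD),
    background = stats::setNames(rep(1 / 20, 20), aa),
    pseudocount = a,
    max_gap_frac = max_gap_frac
  ), class = "profile_hmm")
  phmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm:", x$n_nodes, "match nodes (columns",
      x$match_columns[1], "..", x$match_columns[x$n_nodes], ")\n")
  invisible(x)
}

#' Serialize a profile HMM to JSON
#' @param phmm a `profile_hmm`.
#' @param path output path.
#' @export
write_phmm_json <- function(phmm, path) {
  obj <- unclass(phmm)
  obj$match_emissions <- as.data.frame(obj$match_emissions)
  obj$insert_emissions <- as.data.frame(obj$insert_emissions)
  obj$tM <- as.data.frame(obj$tM)
  obj$tI <- as.data.frame(obj$tI)
  obj$tD <- as.data.frame(obj$tD)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# log emission for one residue: background (1/20) for non-canonical codes
log_emis <- function(emat, residues) {
  out <- matrix(log(1 / 20), length(residues), nrow(emat))
  known <- residues %in% colnames(emat)
  if (any(known))
    out[known, ] <- t(log(emat[, residues[known], drop = FALSE]))
  out
}

#' Viterbi decoding of a query against a profile HMM
#'
#' Global (begin-to-end) maximum-probability state path in log space.
#' Ties are broken deterministically preferring match over delete over
#' insert, which maximizes the number of mapped columns.
#'
#' @param phmm a [build_phmm()] model.
#' @param query residue string or a one-row data.frame with `residues`.
#' @return object of class `state_path`: `states` (data.frame with
#'   columns `kind` in M/I/D and `node`) and `log_probability` (natural
#'   log of the joint probability of path and sequence).
#' @export
viterbi <- function(phmm, query) {
  stopifnot(inherits(phmm, "profile_hmm"))
  if (is.data.frame(query)) query <- query$residues[1]
  if (!is.character(query) || !nzchar(query)) stop("query must be non-empty")
  x <- strsplit(toupper(query), "")[[1]]
  L <- length(x)
  n <- phmm$n_nodes
  lM <- log(phmm$tM); lI <- log(phmm$tI); lD <- log(phmm$tD)
  # emission log-likelihood ratios are not used: plain log probabilities
  leM <- log_emis(phmm$match_emissions, x)    # L x n
  leI <- log_emis(phmm$insert_emissions, x)   # L x (n+1)

  NEG <- -Inf
  # value/backpointer arrays indexed [i+1, k+1], i = residues consumed,
  # k = node; backpointer codes: 1 = M, 2 = D, 3 = I (tie preference)
  vM <- matrix(NEG, L + 1, n + 1); bM <- matrix(0L, L + 1, n + 1)
  vI <- matrix(NEG, L + 1, n + 1); bI <- matrix(0L, L + 1, n + 1)
  vD <- matrix(NEG, L + 1, n + 1); bD <- matrix(0L, L + 1, n + 1)
  vM[1, 1] <- 0  # Begin

  pick3 <- function(cm, cd, ci) {
    best <- pmax(cm, cd, ci)
    kind <- ifelse(cm >= best, 1L, ifelse(cd >= best, 2L, 3L))
    kind[best == NEG] <- 0L
    list(v = best, b = kind)
  }

  for (i in 0:L) {
    ii <- i + 1L
    if (i > 0) {
      # M[i,k] for k = 1..n, from state at node k-1 with i-1 consumed
      ks <- 2:(n + 1)
      cm <- vM[ii - 1L, ks - 1L] + lM[ks - 1L, "M"]
      cd <- vD[ii - 1L, ks - 1L] + lD[ks - 1L, "M"]
      ci <- vI[ii - 1L, ks - 1L] + lI[ks - 1L, "M"]
      p <- pick3(cm, cd, ci)
      vM[ii, ks] <- p$v + leM[i, ]
      bM[ii, ks] <- p$b
      # I[i,k] for k = 0..n, from same node with i-1 consumed
      ks <- 1:(n + 1)
      cm <- vM[ii - 1L, ks] + lM[ks, "I"]
      cd <- vD[ii - 1L, ks] + lD[ks, "I"]
      ci <- vI[ii - 1L, ks] + lI[ks, "I"]
      p <- pick3(cm, cd, ci)
      vI[ii, ks] <- p$v + leI[i, ]
      bI[ii, ks] <- p$b
    }
    # D[i,k] for k = 1..n, from node k-1 with i consumed (chained in k)
    for (k in 2:(n + 1)) {
      cm <- vM[ii, k - 1L] + lM[k - 1L, "D"]
      cd <- vD[ii, k - 1L] + lD[k - 1L, "D"]
      ci <- vI[ii, k - 1L] + lI[k - 1L, "D"]
      best <- max(cm, cd, ci)
      vD[ii, k] <- best
      bD[ii, k] <- if (best == NEG) 0L else
        if (cm >= best) 1L else if (cd >= best) 2L else 3L
    }
  }

  # termination: node n state -> End (stored in the "M" slot)
  endc <- c(M = unname(vM[L + 1L, n + 1L] + lM[n + 1L, "M"]),
            D = unname(vD[L + 1L, n + 1L] + lD[n + 1L, "M"]),
            I = unname(vI[L + 1L, n + 1L] + lI[n + 1L, "M"]))
  logp <- max(endc)
  if (!is.finite(logp)) stop("no legal path (should not happen)")
  kind <- if (endc["M"] >= logp) "M" else if (endc["D"] >= logp) "D" else "I"

  # backtrace
  states_kind <- character(0)
  states_node <- integer(0)
  i <- L; k <- n
  code2kind <- c("M", "D", "I")
  while (!(i == 0 && k == 0 && kind == "M")) {
    states_kind <- c(kind, states_kind)
    states_node <- c(k, states_node)
    if (kind == "M") {
      prev <- bM[i + 1L, k + 1L]; i <- i - 1L; k <- k - 1L
    } else if (kind == "I") {
      prev <- bI[i + 1L, k + 1L]; i <- i - 1L
    } else {
      prev <- bD[i + 1L, k + 1L]; k <- k - 1L
    }
    if (i == 0 && k == 0) break
    kind <- code2kind[prev]
  }
  structure(list(states = data.frame(kind = states_kind,
                                     node = states_node,
                                     stringsAsFactors = FALSE),
                 log_probability = unname(logp)),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat("state_path:", nrow(x$states), "states, log P =",
      format(x$log_probability, digits = 6), "\n")
  invisible(x)
}

#' Map query residues to training-alignment columns
#'
#' Residues emitted by match states map to the corresponding alignment
#' column; insert-state residues are unaligned (NA); deleted nodes leave
#' their column unmapped for this query.
#'
#' @param path a [viterbi()] result for `(phmm, query)`.
#' @param phmm the model used.
#' @param query the decoded residue string.
#' @return integer vector of length `nchar(query)`: alignment column per
#'   residue, NA where unaligned.
#' @export
residue_to_column_map <- function(path, phmm, query) {
  stopifnot(inherits(path, "state_path"), inherits(phmm, "profile_hmm"))
  if (is.data.frame(query)) query <- query$residues[1]
  L <- nchar(query)
  emitting <- path$states$kind %in% c("M", "I")
  if (sum(emitting) != L)
    stop("path emits ", sum(emitting), " residues but query has ", L)
  map <- rep(NA_integer_, L)
  pos <- 0L
  for (s in seq_len(nrow(path$states))) {
    kind <- path$states$kind[s]
    if (kind == "D") next
    pos <- pos + 1L
    if (kind == "M")
      map[pos] <- phmm$match_columns[path$states$node[s]]
  }
  map
}
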