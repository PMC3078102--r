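#' Propositionalize mined rules into a binary feature matrix
#'
#' Attribute `a[e, r]` is 1 iff rule `r`'s conjunctive query succeeds on
#' example `e` (see [covers()]); labels are copied from the knowledge
#' base when present.
#'
#' @param rules non-empty list of [pattern()]s.
#' @param kb knowledge base holding every example to featurize.
#' @return object of class `feature_matrix`: `values` (integer 0/1
#'   matrix, rows = examples, columns = rules), `example_ids`,
#'   `rule_ids` (`r1`, `r2`, ... in rule order), `rules` (the patterns)
#'   and `labels` (or NULL).
#' @export
propositionalize <- function(rules, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (length(rules) == 0L)
    stop("no rules to propositionalize; lower the mining confidence ",
         "threshold or relax chi-square selection")
  if (length(kb$examples) == 0L) stop("knowledge base has no examples")
  rule_ids <- sprintf("r%d", seq_along(rules))
  # rule coverage via a sparse rule x literal incidence matrix: a rule
  # covers an example iff all its body literals are atoms of the example
  bodies <- lapply(rules, `[[`, "body")
  lits <- sort(unique(unlist(bodies, use.names = FALSE)), method = "radix")
  lit_cov <- if (length(lits) == 0L)
    matrix(FALSE, 0L, length(kb$examples))
  else matrix(vapply(kb$examples, function(id)
    lits %in% kb$atoms[[id]], logical(length(lits))),
    nrow = length(lits))                           # literals x examples
  lens <- lengths(bodies)
  A <- Matrix::sparseMatrix(
    i = rep(seq_along(rules), lens),
    j = match(unlist(bodies, use.names = FALSE), lits),
    x = 1, dims = c(length(rules), length(lits)))
  hits <- as.matrix(A %*% lit_cov)                 # rules x examples
  values <- t(hits == lens) * 1L
  dimnames(values) <- list(kb$examples, rule_ids)
  labels <- if (!is.null(kb$labels)) kb$labels[kb$examples] else NULL
  structure(list(values = values, example_ids = kb$examples,
                 rule_ids = rule_ids, rules = rules, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "examples x", ncol(x$values),
      "rules", if (!is.null(x$labels)) sprintf(
        "(%d positive)", sum(x$labels == "positive")) else "", "\n")
  invisible(x)
}

#' Chi-square feature selection
#'
#' Retains rule `r` iff the chi-square test of independence on the 2x2
#' table (feature value x class) yields `p <= delta` (no continuity
#' correction).  `delta` is the significance level: smaller `delta`
#' keeps fewer, more class-correlated features.  Column order is
#' preserved.
#'
#' @param matrix a labeled [propositionalize()] feature matrix.
#' @param delta significance level in `(0, 1]`.
#' @return a `feature_matrix` with the retained columns (possibly zero).
#' @export
chi_square_select <- function(matrix, delta) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!(delta > 0 && delta <= 1)) stop("delta must be in (0, 1]")
  if (is.null(matrix$labels)) stop("chi-square selection needs labels")
  positive <- matrix$labels == "positive"
  if (all(positive) || !any(positive))
    stop("chi-square selection needs both classes")
  a <- colSums(matrix$values[positive, , drop = FALSE] == 1L)
  b <- colSums(matrix$values[!positive, , drop = FALSE] == 1L)
  c_ <- sum(positive) - a
  d <- sum(!positive) - b
  n <- length(positive)
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stats_ <- ifelse(den == 0, 0, n * (a * d - b * c_)^2 / den)
  p <- stats::pchisq(stats_, df = 1, lower.tail = FALSE)
  keep <- which(p <= delta + 1e-15)
  matrix$values <- matrix$values[, keep, drop = FALSE]
  matrix$rule_ids <- matrix$rule_ids[keep]
  matrix$rules <- matrix$rules[keep]
  matrix
}

# ---- RBF-kernel soft-margin SVM via the dual QP (quadprog) ----------

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

svm_fit <- function(X, y, C = 1, gamma = NULL) {
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- rbf_kernel(X, X, gamma)
  Q <- (y %o% y) * K
  ridge <- 1e-8 * n
  Dmat <- Q + diag(ridge, n)
  dvec <- rep(1, n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  coef <- alpha * y
  f0 <- as.vector(K %*% coef)
  tol <- 1e-6 * C
  on_margin <- alpha > tol & alpha < C - tol
  b <- if (any(on_margin)) mean(y[on_margin] - f0[on_margin])
       else -(max(f0[y == -1]) + min(f0[y == 1])) / 2
  list(coef = coef, b = b, gamma = gamma, C = C, X = X)
}

svm_decision <- function(fit, Xnew) {
  as.vector(rbf_kernel(Xnew, fit$X, fit$gamma) %*% fit$coef) + fit$b
}

# ---- greedy Gini decision tree on binary features -------------------

gini <- function(pos, n) {
  if (n == 0) return(0)
  p <- pos / n
  2 * p * (1 - p)
}

tree_grow <- function(X, y, depth, max_depth, min_n) {
  n <- length(y)
  pos <- sum(y)
  if (depth >= max_depth || n < min_n || pos == 0 || pos == n)
    return(list(leaf = TRUE, prob = pos / n, n = n))
  parent <- gini(pos, n)
  # vectorized split search over all binary features
  nr <- colSums(X == 1L)
  pr <- colSums(X[y == 1L, , drop = FALSE] == 1L)
  nl <- n - nr
  pl <- pos - pr
  gr <- ifelse(nr == 0, 0, 2 * (pr / pmax(nr, 1)) * (1 - pr / pmax(nr, 1)))
  gl <- ifelse(nl == 0, 0, 2 * (pl / pmax(nl, 1)) * (1 - pl / pmax(nl, 1)))
  gain <- parent - (nr * gr + nl * gl) / n
  gain[nr == 0 | nr == n] <- -Inf
  best_f <- which.max(gain)  # first maximum: deterministic tie-break
  if (length(best_f) == 0L || gain[best_f] <= 1e-12)
    return(list(leaf = TRUE, prob = pos / n, n = n))
  right <- X[, best_f] == 1L
  list(leaf = FALSE, feature = best_f,
       left = tree_grow(X[!right, , drop = FALSE], y[!right],
                        depth + 1L, max_depth, min_n),
       right = tree_grow(X[right, , drop = FALSE], y[right],
                         depth + 1L, max_depth, min_n))
}

tree_predict_one <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] == 1L) node$right else node$left
  node$prob
}

#' Train a propositional classifier
#'
#' Fits either a soft-margin SVM with RBF kernel (solved exactly as the
#' dual quadratic program; features kept binary, no scaling) or a greedy
#' Gini decision tree, on the binary feature matrix.  Both fits are
#' deterministic; `seed` is recorded for provenance.
#'
#' @param matrix labeled [propositionalize()] feature matrix with both
#'   classes present and at least one feature.
#' @param kind `"svm"` or `"tree"`.
#' @param seed integer seed recorded in the model metadata.
#' @param C,gamma SVM hyperparameters; `gamma` defaults to
#'   `1 / n_features`.
#' @param max_depth,min_n decision-tree stopping parameters.
#' @return object of class `trained_model` carrying the fit, `kind` and
#'   the `rule_ids` the model was trained over (test matrices must be
#'   built over the identical rule set).
#' @export
train_model <- function(matrix, kind = c("svm", "tree"), seed = 1L,
                        C = 1, gamma = NULL,
                        max_depth = 12L, min_n = 2L) {
  kind <- match.arg(kind)
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.null(matrix$labels)) stop("training needs labels")
  y01 <- as.integer(matrix$labels == "positive")
  if (all(y01 == 1L) || all(y01 == 0L)) stop("training needs both classes")
  if (ncol(matrix$values) == 0L)
    stop("no features: relax the confidence threshold or chi-square delta")
  if (all(apply(matrix$values, 2, function(v) length(unique(v)) == 1L)))
    stop("degenerate feature matrix: every feature is constant")
  X <- matrix$values
  fit <- if (kind == "svm") svm_fit(X, ifelse(y01 == 1L, 1, -1),
                                    C = C, gamma = gamma)
         else tree_grow(X, y01, 0L, max_depth, min_n)
  structure(list(kind = kind, fit = fit, rule_ids = matrix$rule_ids,
                 rules = matrix$rules,
                 metadata = list(seed = as.integer(seed), C = C,
                                 gamma = if (kind == "svm") fit$gamma else NULL,
                                 n_train = nrow(X))),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model:", x$kind, "over", length(x$rule_ids), "rules\n")
  invisible(x)
}

#' Score examples with a trained model
#'
#' Higher score means more homologous-like: the SVM decision value, or
#' the tree's positive-class leaf probability.
#'
#' @param model a [train_model()] result.
#' @param matrix a `feature_matrix` built over exactly the model's
#'   `rule_ids` (same rules, same order).
#' @return named numeric vector of scores, one per example.
#' @export
score_model <- function(model, matrix) {
  stopifnot(inherits(model, "trained_model"),
            inherits(matrix, "feature_matrix"))
  if (!identical(model$rule_ids, matrix$rule_ids))
    stop("feature mismatch: the test matrix must be built over the ",
         "model's ", length(model$rule_ids), " rules")
  X <- matrix$values
  s <- if (model$kind == "svm") svm_decision(model$fit, X)
       else apply(X, 1, function(x) tree_predict_one(model$fit, x))
  stats::setNames(as.numeric(s), matrix$example_ids)
}

#' Write a feature matrix as TSV
#'
#' Header = rule ids, first column = example id, optional `label`
#' column.
#'
#' @param matrix a `feature_matrix`.
#' @param path output path.
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- data.frame(example_id = matrix$example_ids,
                   matrix$values, check.names = FALSE)
  if (!is.null(matrix$labels)) df$label <- unname(matrix$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path input path.
#' @return a `feature_matrix` (without the original pattern objects).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- stats::setNames(df$label, df$example_id)
    df$label <- NULL
  }
  ids <- df$example_id
  df$example_id <- NULL
  values <- as.matrix(df)
  storage.mode(values) <- "integer"
  rownames(values) <- ids
  structure(list(values = values, example_ids = ids,
                 rule_ids = colnames(values), rules = NULL,
                 labels = labels),
            class = "feature_matrix")
}
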