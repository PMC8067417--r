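#' Declare a random-intercept mixed-model specification
#'
#' A model specification names the response column, the fixed-effect terms and
#' the subject (grouping) column of a long-format repeated-measures table.
#' Terms are given as character strings: a bare column name is a main effect,
#' and names joined by `:` denote an interaction whose design column is the
#' elementwise product of the (uncentered) constituent columns.  The intercept
#' and the per-subject random intercept are always present and never listed.
#'
#' @param response Name of the response column (e.g. `"sbp_r"`).
#' @param terms Character vector of fixed-effect terms, e.g.
#'   `c("tertile", "cognition", "tertile:cognition")`.  May be empty, giving
#'   the unconditional (intercept-only) model.
#' @param subject Name of the subject identifier column.
#' @param random_intercept Logical; whether a per-subject random intercept is
#'   part of the model.  `TRUE` for every model considered here; `FALSE` is
#'   supported so that single-level limits can be fit and checked.
#' @return An object of class `"model_spec"`.
#' @examples
#' model_spec("sbp_r", c("tertile", "cognition", "tertile:cognition"))
#' @export
model_spec <- function(response, terms = character(), subject = "subject_id",
                       random_intercept = TRUE) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(terms), is.character(subject), length(subject) == 1L)
  terms <- normalize_terms(terms)
  if (anyDuplicated(terms))
    stop("duplicate fixed-effect terms: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  structure(list(response = response, terms = terms, subject = subject,
                 random_intercept = isTRUE(random_intercept)),
            class = "model_spec")
}

# Canonical term labels: factors of an interaction keep their given order but
# whitespace is stripped; "a : b" and "a:b" are the same term.
normalize_terms <- function(terms) {
  vapply(terms, function(tm) {
    paste(trimws(strsplit(tm, ":", fixed = TRUE)[[1L]]), collapse = ":")
  }, character(1L), USE.NAMES = FALSE)
}

term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]

#' @export
print.model_spec <- function(x, ...) {
  rhs <- if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"
  cat("Random-intercept model specification\n")
  cat("  ", x$response, " ~ ", rhs,
      if (x$random_intercept) paste0(" + (1 | ", x$subject, ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Convert a formula to a model specification
#'
#' Accepts formulas in the usual `*` / `:` notation, e.g.
#' `sbp_r ~ tertile * cognition + sbp_baseline`.  Random-effect bars are not
#' parsed; the subject column is given separately.
#'
#' @param formula A model formula.
#' @inheritParams model_spec
#' @return A `"model_spec"`.
#' @export
as_model_spec <- function(formula, subject = "subject_id",
                          random_intercept = TRUE) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  response <- deparse(formula[[2L]])
  trm <- stats::terms(formula)
  labels <- attr(trm, "term.labels")
  model_spec(response, labels, subject = subject,
             random_intercept = random_intercept)
}

#' Serialize / restore a model specification
#'
#' Model specifications round-trip through a small YAML config file with keys
#' `response`, `terms`, `subject`, `random_intercept`.
#'
#' @param spec A `"model_spec"`.
#' @param path File path.
#' @return `read_model_spec` returns a `"model_spec"`;
#'   `write_model_spec` returns `path` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  yaml::write_yaml(list(response = spec$response, terms = as.list(spec$terms),
                        subject = spec$subject,
                        random_intercept = spec$random_intercept), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("response", "subject"))
    if (is.null(cfg[[k]])) stop("model config is missing field '", k, "'")
  model_spec(cfg$response, unlist(cfg$terms) %||% character(),
             subject = cfg$subject,
             random_intercept = cfg$random_intercept %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write long-format analysis tables
#'
#' Analysis tables are plain comma-separated text with a header row: one row
#' per subject x wave x tertile carrying the responsivity score and the
#' person-level covariates.
#'
#' @param path File path.
#' @param table A data frame.
#' @return `read_analysis_table` returns a data frame;
#'   `write_analysis_table` returns `path` invisibly.
#' @export
read_analysis_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_analysis_table
#' @export
write_analysis_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Validate the invariants of a long-format analysis table
#'
#' Checks that tertile indices lie in 1..12 within each wave, that no subject
#' contributes more than 24 rows (2 waves x 12 tertiles), and that
#' person-level covariates are constant within subject.
#'
#' @param table A data frame.
#' @param subject Subject identifier column.
#' @param person_covariates Columns that must be constant within subject;
#'   defaults to every column matching the standard person-level names that
#'   is present.
#' @return `table`, invisibly, if valid; otherwise an error.
#' @export
validate_analysis_table <- function(table, subject = "subject_id",
                                    person_covariates = NULL) {
  stopifnot(is.data.frame(table))
  if (!subject %in% names(table))
    stop("column '", subject, "' not found in table")
  if ("tertile" %in% names(table)) {
    bad <- !is.na(table$tertile) & !(table$tertile %in% 1:12)
    if (any(bad)) stop("tertile indices outside 1..12 in ", sum(bad), " rows")
  }
  counts <- table(table[[subject]])
  if (any(counts > 24L))
    stop("subjects with more than 24 rows: ",
         paste(names(counts)[counts > 24L], collapse = ", "))
  if (is.null(person_covariates)) {
    # baseline SBP is re-measured at each wave, so it is not in this list
    std <- c("cognition", "physical_w1", "physical_w2",
             "mental_w1", "mental_w2", "log_cortisol_w1", "log_cortisol_w2")
    person_covariates <- intersect(std, names(table))
  }
  for (cv in person_covariates) {
    nun <- tapply(table[[cv]], table[[subject]],
                  function(v) length(unique(v[!is.na(v)])))
    if (any(nun > 1L, na.rm = TRUE))
      stop("person-level covariate '", cv, "' varies within subject")
  }
  invisible(table)
}

#' Realize a design from a table and a model specification
#'
#' Builds the response vector, the fixed-effects design matrix (intercept
#' first, then terms in specification order, interactions as raw elementwise
#' products), and the integer subject index.  Rows with missing values in any
#' referenced column are dropped with a message stating the count.
#'
#' @param table A long-format data frame.
#' @param spec A [model_spec()].
#' @return A list of class `"lmm_design"` with elements `y`, `X`, `group`
#'   (integer subject index), `group_sizes`, `term_map` (term -> column
#'   index), `n_dropped`, and the originating `spec`.
#' @export
build_design <- function(table, spec) {
  stopifnot(is.data.frame(table), inherits(spec, "model_spec"))
  needed_factors <- unique(unlist(lapply(spec$terms, term_factors)))
  needed <- unique(c(spec$response, needed_factors, spec$subject))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("unknown column(s) referenced by the model: ",
         paste(missing_cols, collapse = ", "))

  numeric_cols <- setdiff(needed, spec$subject)
  ok <- rep(TRUE, nrow(table))
  for (cl in numeric_cols) ok <- ok & !is.na(table[[cl]])
  ok <- ok & !is.na(table[[spec$subject]])
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message("build_design: dropped ", n_dropped,
            " row(s) with missing values in referenced columns")
  tab <- table[ok, , drop = FALSE]

  p <- length(spec$terms) + 1L
  n <- nrow(tab)
  if (length(unique(tab[[spec$subject]])) < 2L && spec$random_intercept)
    stop("at least 2 subjects are required")
  if (n <= p + 2L)
    stop("too few rows after dropping missing values (n = ", n,
         ", need > ", p + 2L, ")")

  X <- matrix(1, n, p)
  colnames(X) <- c("(Intercept)", spec$terms)
  for (j in seq_along(spec$terms)) {
    col <- rep(1, n)
    for (f in term_factors(spec$terms[j])) col <- col * as.numeric(tab[[f]])
    X[, j + 1L] <- col
  }
  if (qr(X)$rank < p) {
    stop("rank-deficient design; collinear terms among: ",
         paste(collinear_terms(X), collapse = ", "))
  }

  grp <- factor(tab[[spec$subject]], levels = unique(tab[[spec$subject]]))
  group <- as.integer(grp)
  structure(list(
    y = as.numeric(tab[[spec$response]]), X = X,
    group = group, group_sizes = as.integer(table(group)),
    group_labels = levels(grp),
    term_map = stats::setNames(seq_len(p), colnames(X)),
    n_dropped = n_dropped, spec = spec), class = "lmm_design")
}

# Columns involved in the rank deficiency: those whose removal restores
# full rank of the remainder.
collinear_terms <- function(X) {
  p <- ncol(X)
  inv <- vapply(seq_len(p), function(j) {
    qr(X[, -j, drop = FALSE])$rank == min(dim(X[, -j, drop = FALSE]))
  }, logical(1L))
  nm <- colnames(X)[inv]
  if (!length(nm)) nm <- colnames(X)
  nm
}

#' @export
print.lmm_design <- function(x, ...) {
  cat("Realized mixed-model design: n =", length(x$y),
      "rows, p =", ncol(x$X), "fixed-effect columns,",
      length(x$group_sizes), "subjects\n")
  invisible(x)
}

#' Bundle the parameters of the random-intercept model
#'
#' @param beta Fixed-effect coefficient vector (intercept first).
#' @param var_subject Random-intercept (between-person) variance, `>= 0`.
#' @param var_resid Residual (within-person) variance, `> 0`.
#' @return A list of class `"lmm_theta"`.
#' @export
lmm_theta <- function(beta, var_subject, var_resid) {
  beta <- as.numeric(beta)
  if (!all(is.finite(beta)) || !is.finite(var_subject) || !is.finite(var_resid))
    stop("non-finite parameter values")
  if (var_resid <= 0) stop("var_resid must be strictly positive")
  if (var_subject < 0) stop("var_subject must be non-negative")
  structure(list(beta = beta, var_subject = var_subject,
                 var_resid = var_resid), class = "lmm_theta")
}
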