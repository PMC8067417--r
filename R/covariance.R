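#' Block-structured marginal covariance of the random-intercept model
#'
#' The marginal covariance of the response is
#' `V = var_subject * S_a + var_resid * I_n`, where `S_a[i, j] = 1` when rows
#' `i` and `j` belong to the same subject.  Within a subject with `m` rows the
#' block is `var_resid * I + var_subject * 11'`, so solves and log-
#' determinants are available in O(n) by Sherman-Morrison per block.  The
#' handle returned here exposes those operations; `$dense()` materializes the
#' full matrix for testing.
#'
#' @param var_subject Between-subject variance (>= 0).
#' @param var_resid Residual variance (> 0).
#' @param group Integer vector mapping rows to subjects (1-based, any order).
#' @return A list of class `"block_cov"` with functions `solve(x)` (vector or
#'   matrix), `logdet()`, `sa_mult(x)` (multiplication by `S_a`, i.e.
#'   within-subject sums), `quad(r)` (the quadratic form `r' V^{-1} r`), and
#'   `dense()`.
#' @export
block_cov <- function(var_subject, var_resid, group) {
  if (!is.finite(var_resid) || var_resid <= 0)
    stop("var_resid must be strictly positive")
  if (!is.finite(var_subject) || var_subject < 0)
    stop("var_subject must be non-negative")
  group <- as.integer(group)
  n <- length(group)
  sizes <- tabulate(group)
  m_row <- sizes[group]                      # subject size per row
  denom <- var_resid + sizes * var_subject   # per subject
  # V^{-1} x = x / ve - (va / (ve * (ve + m va))) * 1 (1'x)   within block
  coef_row <- (var_subject / (var_resid * denom))[group]

  solve_fun <- function(x) {
    if (is.matrix(x)) {
      gs <- rowsum(x, group, reorder = TRUE)
      x / var_resid - coef_row * gs[group, , drop = FALSE]
    } else {
      gs <- unname(rowsum(x, group, reorder = TRUE)[, 1L])
      unname(x / var_resid - coef_row * gs[group])
    }
  }
  structure(list(
    var_subject = var_subject, var_resid = var_resid,
    group = group, sizes = sizes, n = n,
    solve = solve_fun,
    logdet = function() sum((sizes - 1) * log(var_resid) + log(denom)),
    sa_mult = function(x) {
      if (is.matrix(x)) rowsum(x, group, reorder = TRUE)[group, , drop = FALSE]
      else unname(rowsum(x, group, reorder = TRUE)[group, 1L])
    },
    quad = function(r) {
      gs <- rowsum(r, group, reorder = TRUE)[, 1L]
      sum(r * r) / var_resid - var_subject * sum(gs^2 / denom) / var_resid
    },
    dense = function() {
      same <- outer(group, group, "==")
      var_subject * same + diag(var_resid, n)
    }), class = "block_cov")
}

#' @export
print.block_cov <- function(x, ...) {
  cat("Block covariance handle: n =", x$n, ", subjects =", length(x$sizes),
      ", var_subject =", x$var_subject, ", var_resid =", x$var_resid, "\n")
  invisible(x)
}

#' Marginal Gaussian log-likelihood of the random-intercept model
#'
#' Computes `log N(y; X beta, V)` with
#' `V = var_subject * S_a + var_resid * I` through the block structure, in
#' O(n) time.
#'
#' @param theta A [lmm_theta()] (or list with `beta`, `var_subject`,
#'   `var_resid`).
#' @param design An `"lmm_design"` from [build_design()].
#' @return The log-likelihood (a finite scalar for valid `theta`).
#' @export
lmm_loglik <- function(theta, design) {
  if (!all(is.finite(theta$beta)) || !is.finite(theta$var_subject) ||
      !is.finite(theta$var_resid))
    stop("non-finite parameter values")
  V <- block_cov(theta$var_subject, theta$var_resid, design$group)
  r <- design$y - drop(design$X %*% theta$beta)
  n <- length(r)
  -0.5 * (n * log(2 * pi) + V$logdet() + V$quad(r))
}
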