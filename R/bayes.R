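#' Enumerate candidate fixed-effect subsets under marginality
#'
#' Produces every subset of the candidate terms that (a) contains the
#' `always_include` terms and (b) respects marginality: an interaction term
#' may appear only when every proper nonempty subset of its factors is also
#' present as a term.  The intercept and the per-subject random intercept are
#' implicit in every model (the empty subset is the intercept-only null).
#' The ordering of the returned list is canonical and deterministic
#' (binary-counting over the candidate order).
#'
#' @param candidate_terms Character vector of terms (see [model_spec()]).
#' @param always_include Terms forced into every model; must be a subset of
#'   `candidate_terms`.
#' @return A list of character vectors (each a fixed-effect term set; the
#'   first is `character(0)`, the null model, when permitted).
#' @examples
#' length(enumerate_models(c("tertile", "sbp_baseline", "cognition",
#'   "physical_w1", "tertile:cognition", "tertile:physical_w1")))  # 26
#' @export
enumerate_models <- function(candidate_terms, always_include = character()) {
  cand <- normalize_terms(candidate_terms)
  if (anyDuplicated(vapply(cand, function(tm)
        paste(sort(term_factors(tm)), collapse = ":"), character(1L))))
    stop("duplicate candidate terms")
  always <- normalize_terms(always_include)
  miss <- setdiff(always, cand)
  if (length(miss))
    stop("always_include term(s) not among candidates: ",
         paste(miss, collapse = ", "))
  k <- length(cand)
  fsets <- lapply(cand, term_factors)
  key <- vapply(fsets, function(f) paste(sort(f), collapse = ":"),
                character(1L))
  # precompute, per candidate, the indices of its required parent terms
  parents <- lapply(seq_len(k), function(i) {
    f <- fsets[[i]]
    if (length(f) < 2L) return(integer())
    subs <- proper_subsets(f)
    idx <- match(vapply(subs, function(s) paste(sort(s), collapse = ":"),
                        character(1L)), key)
    if (anyNA(idx))
      stop("interaction '", cand[i], "' has parent terms missing from the ",
           "candidate list")
    idx
  })
  always_idx <- match(vapply(always, function(tm)
    paste(sort(term_factors(tm)), collapse = ":"), character(1L)), key)
  out <- vector("list", 2^k)
  n_out <- 0L
  for (mask in 0:(2^k - 1L)) {
    inc <- bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L
    if (length(always_idx) && !all(inc[always_idx])) next
    ok <- TRUE
    for (i in which(inc)) {
      if (length(parents[[i]]) && !all(inc[parents[[i]]])) { ok <- FALSE; break }
    }
    if (!ok) next
    n_out <- n_out + 1L
    out[[n_out]] <- cand[inc]
  }
  out[seq_len(n_out)]
}

# All proper nonempty subsets of a factor vector.
proper_subsets <- function(f) {
  k <- length(f)
  masks <- setdiff(0:(2^k - 1L), c(0L, 2^k - 1L))
  lapply(masks, function(m) f[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L])
}

#' Default prior scales for the JZS construction
#'
#' Scales of the Cauchy-implied mixing priors on standardized effects:
#' `fixed` for categorical/binary effects (0.5, "medium"), `continuous` for
#' continuous covariates (sqrt(2)/4), and `random` for the random-intercept
#' block (1, "nuisance").
#'
#' @param fixed,continuous,random Positive scale values.
#' @return A named list.
#' @export
jzs_scales <- function(fixed = 0.5, continuous = sqrt(2) / 4, random = 1) {
  stopifnot(fixed > 0, continuous > 0, random > 0)
  list(fixed = fixed, continuous = continuous, random = random)
}

# Standardized model pieces shared by every candidate subset: the response
# (centered), per-term standardized columns, and the subject-indicator block.
# Main-effect covariates are z-scored; interaction columns are products of the
# standardized mains, re-centered and re-scaled, which makes the resulting
# Bayes factors invariant to affine changes of covariate units.
jzs_prepare <- function(table, response, candidate_terms, subject,
                        scales, random_intercept = TRUE) {
  cand <- normalize_terms(candidate_terms)
  factors <- unique(unlist(lapply(cand, term_factors)))
  needed <- c(response, factors, subject)
  miss <- setdiff(needed, names(table))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
  ok <- !Reduce(`|`, lapply(needed, function(cl) is.na(table[[cl]])))
  tab <- table[ok, , drop = FALSE]
  y <- as.numeric(tab[[response]])
  y <- (y - mean(y)) / stats::sd(y)    # Bayes factors are scale-free
  zmain <- lapply(stats::setNames(factors, factors), function(f) {
    v <- as.numeric(tab[[f]])
    s <- stats::sd(v)
    if (s == 0) stop("zero-variance covariate '", f, "'")
    (v - mean(v)) / s
  })
  cols <- lapply(stats::setNames(cand, cand), function(tm) {
    f <- term_factors(tm)
    col <- Reduce(`*`, zmain[f])
    if (length(f) > 1L) {
      s <- stats::sd(col)
      if (s == 0) stop("zero-variance interaction column '", tm, "'")
      col <- (col - mean(col)) / s
    }
    col
  })
  term_scale <- vapply(cand, function(tm) {
    f <- term_factors(tm)
    binary <- all(vapply(f, function(v)
      length(unique(tab[[v]])) <= 2L, logical(1L)))
    if (binary) scales$fixed else scales$continuous
  }, numeric(1L))
  Zr <- NULL
  if (random_intercept) {
    grp <- factor(tab[[subject]], levels = unique(tab[[subject]]))
    Zr <- stats::model.matrix(~ grp - 1)
    attr(Zr, "contrasts") <- NULL
  }
  list(y = y, cols = cols, term_scale = term_scale, Zr = Zr,
       r_random = scales$random, n = length(y))
}

# Log marginal likelihood conditional on the g vector, for the model with
# effect matrix Z and per-column prior variances d (beta | g ~ N(0, sigma2 D)),
# flat prior on the grand mean and Jeffreys prior on sigma2:
#   p(y | g) = Gamma((n-1)/2) / pi^((n-1)/2) *
#              (1'V^-1 1)^(-1/2) |V|^(-1/2) Q^(-(n-1)/2),
# with V = I + Z D Z' and Q the mean-profiled quadratic form. Everything is
# computed through the Woodbury identity from the precomputed cross-products.
jzs_condml <- function(d, pre) {
  n <- pre$n
  if (length(d) == 0L) {           # null: no effect columns at all
    Q <- pre$yy - pre$sy^2 / n
    return(lgamma((n - 1) / 2) - ((n - 1) / 2) * log(pi) - 0.5 * log(n) -
           ((n - 1) / 2) * log(Q))
  }
  P <- pre$ZtZ + diag(1 / d, length(d))
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch))) + sum(log(d))
  alpha <- backsolve(ch, forwardsolve(t(ch), pre$Zty))
  gamma <- backsolve(ch, forwardsolve(t(ch), pre$Zt1))
  yVy <- pre$yy - sum(pre$Zty * alpha)
  oVo <- n - sum(pre$Zt1 * gamma)
  oVy <- pre$sy - sum(pre$Zt1 * alpha)
  Q <- yVy - oVy^2 / oVo
  if (!is.finite(Q) || Q <= 0 || oVo <= 0) return(-Inf)
  lgamma((n - 1) / 2) - ((n - 1) / 2) * log(pi) - 0.5 * log(oVo) -
    0.5 * logdetV - ((n - 1) / 2) * log(Q)
}

# Cross-products for a given term subset. Blocks: one g per fixed term
# (single column each) plus one g shared by the subject-indicator block.
jzs_model_pre <- function(pre, terms) {
  Zlist <- c(unname(pre$cols[terms]),
             if (!is.null(pre$Zr)) list(pre$Zr))
  if (!length(Zlist)) {
    return(list(n = pre$n, yy = sum(pre$y^2), sy = sum(pre$y),
                ZtZ = NULL, Zty = NULL, Zt1 = NULL,
                block = integer(), scales = numeric()))
  }
  Z <- do.call(cbind, Zlist)
  ncols <- vapply(Zlist, function(z) if (is.matrix(z)) ncol(z) else 1L,
                  integer(1L))
  block <- rep(seq_along(Zlist), times = ncols)
  scales <- c(pre$term_scale[terms], if (!is.null(pre$Zr)) pre$r_random)
  list(n = pre$n, yy = sum(pre$y^2), sy = sum(pre$y),
       ZtZ = crossprod(Z), Zty = drop(crossprod(Z, pre$y)),
       Zt1 = drop(crossprod(Z, rep(1, pre$n))),
       block = block, scales = unname(scales))
}

# log InvGamma(1/2, r^2/2) density of g, plus the log-transform Jacobian
# term when integrating over u = log g.
log_g_prior <- function(g, r) {
  0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
}

# Joint log integrand over u = log g (one entry per block).
jzs_integrand <- function(u, mp) {
  g <- exp(u)
  d <- g[mp$block]                 # per-column prior variance
  jzs_condml(d, mp) + sum(log_g_prior(g, mp$scales)) + sum(u)
}

#' JZS log marginal likelihood of one candidate model
#'
#' Marginal likelihood of the standardized model under the
#' Jeffreys-Zellner-Siow prior structure: flat prior on the grand mean,
#' Jeffreys prior on the residual variance, and per-block
#' scaled-inverse-chi-square (Cauchy-implied) mixing on the variances of the
#' standardized effects, one `g` per fixed term plus one for the
#' random-intercept block.  Conditional on `g` the Gaussian marginal is
#' closed-form; the `g` integral uses adaptive quadrature in up to 2
#' dimensions and mode-centered multivariate-t importance sampling beyond
#' that.  An estimate of the numerical error (on the log scale) is returned;
#' if it exceeds `tol` the computation is retried with a four-fold budget
#' and then fails.
#'
#' @param table Long-format data frame.
#' @param terms Character vector of fixed-effect terms in the model (may be
#'   empty: the intercept-only null).
#' @param response,subject Column names.
#' @param candidate_terms All terms of the enclosing comparison (used so
#'   that standardization is shared across models); defaults to `terms`.
#' @param scales A [jzs_scales()] list.
#' @param budget Importance-sampling draw count.
#' @param seed Integer seed for the importance-sampling path.
#' @param tol Acceptable log-scale error estimate.
#' @param random_intercept Include the subject block (default `TRUE`).
#' @return A list with `log_marginal` and `error` (log-scale estimate).
#' @export
jzs_log_marginal <- function(table, terms, response = "sbp_r",
                             subject = "subject_id",
                             candidate_terms = terms,
                             scales = jzs_scales(), budget = 4000,
                             seed = 1, tol = 0.05,
                             random_intercept = TRUE) {
  pre <- jzs_prepare(table, response, unique(c(terms, candidate_terms)),
                     subject, scales, random_intercept)
  mp <- jzs_model_pre(pre, normalize_terms(terms))
  jzs_integrate(mp, budget = budget, seed = seed, tol = tol)
}

jzs_integrate <- function(mp, budget = 4000, seed = 1, tol = 0.05) {
  K <- if (length(mp$block)) max(mp$block) else 0L
  if (K == 0L)
    return(list(log_marginal = jzs_condml(numeric(), mp), error = 0))
  if (K == 1L) return(jzs_quad_1d(mp))
  if (K == 2L) return(jzs_quad_2d(mp))
  res <- jzs_importance(mp, budget, seed)
  if (!is.finite(res$error) || res$error > tol) {
    warning("importance-sampling error ", signif(res$error, 3),
            " above tolerance; retrying with a wider budget")
    res <- jzs_importance(mp, budget * 4L, seed + 1L)
    if (!is.finite(res$error) || res$error > tol)
      stop("JZS integration failed to reach the requested accuracy")
  }
  res
}

jzs_quad_1d <- function(mp) {
  h <- function(u) jzs_integrand(u, mp)
  opt <- stats::optimize(h, interval = c(-20, 20), maximum = TRUE)
  h0 <- opt$objective
  f <- Vectorize(function(u) exp(h(u) - h0))
  intr <- stats::integrate(f, opt$maximum - 40, opt$maximum + 40,
                           rel.tol = 1e-9, subdivisions = 400L)
  list(log_marginal = h0 + log(intr$value),
       error = intr$abs.error / intr$value)
}

jzs_quad_2d <- function(mp) {
  h <- function(u) jzs_integrand(u, mp)
  opt <- stats::optim(c(0, 0), function(u) -h(u), method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  h0 <- -opt$value
  ctr <- opt$par
  inner <- function(u1) {
    f2 <- Vectorize(function(u2) exp(h(c(u1, u2)) - h0))
    stats::integrate(f2, ctr[2] - 30, ctr[2] + 30, rel.tol = 1e-8,
                     subdivisions = 200L)$value
  }
  f1 <- Vectorize(inner)
  intr <- stats::integrate(f1, ctr[1] - 30, ctr[1] + 30, rel.tol = 1e-7,
                           subdivisions = 200L)
  list(log_marginal = h0 + log(intr$value),
       error = intr$abs.error / intr$value)
}

jzs_importance <- function(mp, budget, seed) {
  K <- max(mp$block)
  h <- function(u) jzs_integrand(u, mp)
  opt <- stats::optim(rep(0, K), function(u) -h(u), method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 5000))
  mode <- opt$par
  hess <- num_hessian(function(u) -h(u), mode)
  S <- tryCatch(solve(hess), error = function(e) diag(K))
  if (any(!is.finite(S)) || any(diag(S) <= 0)) S <- diag(K)
  ev <- eigen(S, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-6)
  L <- ev$vectors %*% diag(sqrt(ev$values * 1.3), K)
  df <- 5
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(as.integer(seed))
  Zs <- matrix(stats::rnorm(budget * K), budget, K)
  chi <- sqrt(stats::rchisq(budget, df) / df)
  U <- sweep(Zs, 1, chi, "/") %*% t(L)
  U <- sweep(U, 2, mode, "+")
  logq <- mvt_logpdf(U, mode, L, df)
  logw <- vapply(seq_len(budget), function(i) h(U[i, ]), numeric(1L)) - logq
  mx <- max(logw)
  w <- exp(logw - mx)
  est <- mean(w)
  se_log <- stats::sd(w) / (sqrt(budget) * est)
  list(log_marginal = mx + log(est), error = se_log)
}

num_hessian <- function(f, x, h = 1e-4) {
  K <- length(x)
  H <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in i:K) {
    ei <- ej <- numeric(K); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h^2)
  }
  H
}

# Multivariate-t log density with location mu and scale factor L (S = LL').
mvt_logpdf <- function(U, mu, L, df) {
  K <- length(mu)
  D <- sweep(U, 2, mu, "-")
  Z <- t(solve(L, t(D)))
  q <- rowSums(Z^2)
  lgamma((df + K) / 2) - lgamma(df / 2) - (K / 2) * log(df * pi) -
    sum(log(abs(diag(L)))) - ((df + K) / 2) * log1p(q / df)
}

#' All-subsets Bayes-factor comparison against the intercept-only null
#'
#' Enumerates the marginality-respecting subsets of the candidate terms
#' (see [enumerate_models()]), computes each model's JZS marginal
#' likelihood, and reports the Bayes factor `K` of every candidate against
#' the intercept-only null (which retains the random intercept as a
#' nuisance term, so the null is itself a multilevel model and its `K` is
#' identically 1).
#'
#' @inheritParams jzs_log_marginal
#' @param always_include Terms forced into every candidate.
#' @return An object of class `"jzs_comparison"`: a data frame with one row
#'   per model (`model`, `n_terms`, `log_K`, `log10_K`, `ratio_to_best`,
#'   `mc_error`) plus attributes `best_index` and `scales`.
#' @export
jzs_compare <- function(table, candidate_terms, response = "sbp_r",
                        subject = "subject_id",
                        always_include = character(),
                        scales = jzs_scales(), budget = 4000, seed = 1,
                        random_intercept = TRUE) {
  models <- enumerate_models(candidate_terms, always_include)
  pre <- jzs_prepare(table, response, candidate_terms, subject, scales,
                     random_intercept)
  null_mp <- jzs_model_pre(pre, character())
  null_ml <- jzs_integrate(null_mp, budget, seed)
  logk <- err <- numeric(length(models))
  for (i in seq_along(models)) {
    mp <- jzs_model_pre(pre, models[[i]])
    res <- jzs_integrate(mp, budget, seed + i)
    logk[i] <- res$log_marginal - null_ml$log_marginal
    err[i] <- sqrt(res$error^2 + null_ml$error^2)
  }
  best <- which.max(logk)
  out <- data.frame(
    model = vapply(models, function(tm)
      if (length(tm)) paste(tm, collapse = " + ") else "(intercept only)",
      character(1L)),
    n_terms = lengths(models),
    log_K = logk,
    log10_K = logk / log(10),
    ratio_to_best = exp(logk - logk[best]),
    mc_error = err,
    stringsAsFactors = FALSE)
  attr(out, "best_index") <- best
  attr(out, "scales") <- scales
  attr(out, "models") <- models
  class(out) <- c("jzs_comparison", "data.frame")
  out
}

#' @export
print.jzs_comparison <- function(x, n = 10, digits = 4, ...) {
  cat("JZS all-subsets comparison:", nrow(x),
      "candidate models vs the intercept-only null\n")
  ord <- order(x$log_K, decreasing = TRUE)
  top <- utils::head(ord, n)
  tab <- data.frame(model = x$model[top],
                    log10_K = signif(x$log10_K[top], digits),
                    ratio_to_best = signif(x$ratio_to_best[top], digits),
                    label = vapply(pmax(x$ratio_to_best[top], 1e-300),
                                   interpret_k_ratio, character(1L)))
  print(tab, row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more models\n")
  invisible(x)
}

#' Ratio of two Bayes factors
#'
#' @param k1,k2 Bayes factors (against a common null), or with
#'   `log = TRUE`, their logarithms.
#' @param log Interpret inputs as log Bayes factors.
#' @return The ratio `K1 / K2`.
#' @examples
#' k_ratio(2.2e55, 1.1e54)   # 20
#' @export
k_ratio <- function(k1, k2, log = FALSE) {
  if (log) exp(k1 - k2) else k1 / k2
}

#' Qualitative label for a Bayes-factor ratio
#'
#' Follows the common heuristic that ratios of `K` values above 10 or 20
#' indicate substantial or strong evidence for the better-fitting model.
#' Ratios below 1 are interpreted symmetrically through their reciprocal,
#' as evidence for the other model.
#'
#' @param ratio A positive Bayes-factor ratio.
#' @return `"strong"` (>= 20), `"substantial"` (>= 10) or `"anecdotal"`,
#'   with the suffix `" (for the other model)"` when `ratio < 1` and the
#'   reciprocal crosses the same thresholds.
#' @export
interpret_k_ratio <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("ratio must be a positive number")
  r <- max(ratio, 1 / ratio)
  lab <- if (r >= 20) "strong" else if (r >= 10) "substantial"
         else "anecdotal"
  if (ratio < 1 && lab != "anecdotal")
    lab <- paste0(lab, " (for the other model)")
  lab
}
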