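#' Jacobian matrix of the data-generating equation
#'
#' The model equation `Y = X beta + (var_subject S_a + var_resid I)^{1/2} U`
#' with standard-normal `U` has, after inverting for `U`, a parameter
#' gradient whose columns concatenate to
#' `M = [X, S_a V^{-1} r, V^{-1} r]` with `r = y - X beta` and
#' `V = var_subject S_a + var_resid I` (constant factors that do not depend
#' on the parameters are dropped; they cancel under normalization).  All
#' products use the per-subject block structure.
#'
#' @param theta A [lmm_theta()].
#' @param design An `"lmm_design"`.
#' @return An `n x (p + 2)` matrix (or `n x (p + 1)` when the model has no
#'   random intercept, in which case the `S_a V^{-1} r` column is absent).
#' @export
fid_jacobian <- function(theta, design) {
  V <- block_cov(theta$var_subject, theta$var_resid, design$group)
  r <- design$y - drop(design$X %*% theta$beta)
  b <- V$solve(r)
  if (design$spec$random_intercept %||% TRUE) {
    a <- V$sa_mult(b)
    cbind(design$X, sa_vinv_r = a, vinv_r = b, deparse.level = 0)
  } else {
    cbind(design$X, vinv_r = b, deparse.level = 0)
  }
}

#' Log Jacobian factor of the fiducial density
#'
#' Returns `0.5 * log det(M'M)` for the Jacobian matrix `M` (the
#' square-root convention `D(M) = sqrt(det(M'M))`); with `root = FALSE` the
#' non-root variant `log det(M'M)` is used instead.  A singular `M'M`
#' (e.g. a zero residual vector) yields `-Inf`, a rejectable log-density
#' value rather than an error.
#'
#' @inheritParams fid_jacobian
#' @param root Use the square-root convention (default `TRUE`).
#' @return A scalar; `-Inf` for degenerate configurations.
#' @export
fid_log_jacobian <- function(theta, design, root = TRUE) {
  M <- fid_jacobian(theta, design)
  ld <- determinant(crossprod(M), logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(-Inf)
  if (root) 0.5 * as.numeric(ld$modulus) else as.numeric(ld$modulus)
}

#' Unnormalized log fiducial density
#'
#' The generalized fiducial density is proportional to the likelihood times
#' the Jacobian factor, `r_y(theta) \propto f(y | theta) J(y, theta)`; the
#' normalizing integral is never computed.  Parameter values outside the
#' space (`var_resid <= 0` or `var_subject < 0`) return `-Inf` by
#' convention.
#'
#' @param theta A list with `beta`, `var_subject`, `var_resid` (need not be
#'   validated; invalid values give `-Inf`).
#' @inheritParams fid_log_jacobian
#' @return The unnormalized log density (possibly `-Inf`).
#' @export
fid_log_density <- function(theta, design, root = TRUE) {
  if (!is.finite(theta$var_resid) || theta$var_resid <= 0 ||
      !is.finite(theta$var_subject %||% 0) || (theta$var_subject %||% 0) < 0 ||
      !all(is.finite(theta$beta)))
    return(-Inf)
  lmm_loglik(theta, design) + fid_log_jacobian(theta, design, root = root)
}

# Fast closure evaluating the log fiducial target for the sampler.
# Parameterization: eta = (beta, log var_subject, log var_resid) (the
# log-variance dimension for var_subject is absent when the model has no
# random intercept); includes the log-transform Jacobian terms.
make_fid_target <- function(design, root = TRUE) {
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  group <- design$group
  sizes <- design$group_sizes
  XtX <- crossprod(X)
  has_ri <- design$spec$random_intercept %||% TRUE
  half <- if (root) 0.5 else 1

  if (has_ri) {
    function(eta) {
      beta <- eta[1:p]
      va <- exp(eta[p + 1L]); ve <- exp(eta[p + 2L])
      if (!is.finite(va) || !is.finite(ve) || ve <= 0) return(-Inf)
      r <- y - drop(X %*% beta)
      gs <- rowsum(r, group, reorder = TRUE)[, 1L]
      denom <- ve + sizes * va
      rss <- sum(r * r)
      quad <- rss / ve - (va / ve) * sum(gs^2 / denom)
      logdetV <- sum((sizes - 1) * log(ve) + log(denom))
      ll <- -0.5 * (n * log(2 * pi) + logdetV + quad)
      ag <- gs / denom                      # group value of S_a V^-1 r
      a <- ag[group]
      b <- r / ve - (va / ve) * a           # V^-1 r
      Xab <- crossprod(X, cbind(a, b))
      ata <- sum(sizes * ag^2)
      atb <- sum(a * b)
      btb <- sum(b * b)
      MtM <- rbind(cbind(XtX, Xab),
                   cbind(t(Xab), matrix(c(ata, atb, atb, btb), 2, 2)))
      ld <- determinant(MtM, logarithm = TRUE)
      if (ld$sign <= 0 || !is.finite(ld$modulus)) return(-Inf)
      # + log va + log ve: Jacobian of the log-variance reparameterization
      ll + half * as.numeric(ld$modulus) + log(va) + log(ve)
    }
  } else {
    function(eta) {
      beta <- eta[1:p]
      ve <- exp(eta[p + 1L])
      if (!is.finite(ve) || ve <= 0) return(-Inf)
      r <- y - drop(X %*% beta)
      rss <- sum(r * r)
      ll <- -0.5 * (n * log(2 * pi) + n * log(ve) + rss / ve)
      b <- r / ve
      Xb <- crossprod(X, b)
      MtM <- rbind(cbind(XtX, Xb), cbind(t(Xb), rss / ve^2))
      ld <- determinant(MtM, logarithm = TRUE)
      if (ld$sign <= 0 || !is.finite(ld$modulus)) return(-Inf)
      ll + half * as.numeric(ld$modulus) + log(ve)
    }
  }
}

#' Sample the generalized fiducial distribution of a random-intercept model
#'
#' Runs an adaptive Gaussian random-walk Metropolis sampler on the
#' transformed space `(beta, log var_subject, log var_resid)` targeting the
#' fiducial density (plus the log-transform Jacobian terms).  Chains start
#' from the REML estimates, jittered independently per chain; the proposal
#' covariance is seeded from the curvature of the target at the REML point
#' and its global scale is adapted during warmup toward an acceptance rate
#' of 0.25-0.40 (adaptation stops after warmup, so the kept draws target the
#' exact density).  Draws are returned on the natural scale.  Sampling
#' `log var_subject` keeps the boundary `var_subject = 0` unreachable, a
#' deliberate interior parameterization.
#'
#' @param object A formula, [model_spec()], or `"lmm_design"`.
#' @param data A data frame (when `object` is a formula or spec).
#' @param subject Subject identifier column (formula interface).
#' @param chains Number of chains (>= 2).
#' @param warmup,keep Warmup and kept iterations per chain.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   draws exactly.
#' @param level Interval level for summaries.
#' @param root Square-root Jacobian convention (see [fid_log_jacobian()]).
#' @param thin Keep every `thin`-th draw after warmup.
#' @return An object of class `"fidlmm"`: matrix `draws`
#'   (`chains * keep` rows; columns are the fixed effects plus
#'   `var_subject` and `var_resid`), `chain_id`, `diagnostics` (per-
#'   parameter split R-hat and effective sample size), the REML
#'   initialization, the acceptance rates, and the sampler configuration.
#'   Any split R-hat above 1.05 is recorded as a convergence warning in the
#'   diagnostics (not fatal).
#' @examples
#' sim <- simulate_dataset(synthetic_config(seed = 2))
#' fit <- fidlmm(sbp_r ~ tertile, sim$table, chains = 2, warmup = 200,
#'               keep = 300, seed = 7)
#' summary(fit)
#' @export
fidlmm <- function(object, data = NULL, subject = "subject_id",
                   chains = 4, warmup = 2000, keep = 5000, seed = 1,
                   level = 0.95, root = TRUE, thin = 1) {
  if (chains < 2) stop("at least 2 chains are required")
  if (warmup <= 0 || keep <= 0) stop("warmup and keep must be positive")
  design <- as_lmm_design(object, data, subject)
  has_ri <- design$spec$random_intercept
  p <- ncol(design$X)
  d <- p + 1L + as.integer(has_ri)

  reml <- fit_reml(design)
  target <- make_fid_target(design, root = root)

  va0 <- if (has_ri) max(reml$var_subject, reml$var_resid / 50) else NULL
  center <- c(reml$beta, if (has_ri) log(va0), log(reml$var_resid))
  Sigma0 <- proposal_covariance(target, center, reml, has_ri)
  chol0 <- tryCatch(chol(Sigma0), error = function(e)
    chol(diag(diag(Sigma0) + 1e-8, d)))

  par_names <- c(colnames(design$X), if (has_ri) "var_subject", "var_resid")
  draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    jit <- drop(crossprod(chol0, stats::rnorm(d))) * 0.3
    init <- center + jit
    k <- 0L
    while (!is.finite(target(init)) && k < 30L) {  # shrink toward center
      jit <- jit * 0.5; init <- center + jit; k <- k + 1L
    }
    res <- run_rwm_chain(target, init, chol0, warmup, keep, thin)
    accept[ch] <- res$accept_rate
    out <- res$draws
    # back-transform the variance dimensions
    out[, (p + 1L):d] <- exp(out[, (p + 1L):d, drop = FALSE])
    draws[[ch]] <- out
  }
  if (all(accept == 0)) stop("sampler failure: all proposals rejected")
  draw_mat <- do.call(rbind, draws)
  colnames(draw_mat) <- par_names
  chain_id <- rep(seq_len(chains), each = nrow(draws[[1L]]))
  diag_tab <- chain_diagnostics(draw_mat, chain_id)

  fit <- structure(list(
    draws = draw_mat, chain_id = chain_id,
    diagnostics = diag_tab,
    convergence_warning = any(diag_tab$rhat > 1.05, na.rm = TRUE),
    accept_rate = accept,
    reml_init = reml, design = design, spec = design$spec, level = level,
    sampler_config = list(chains = chains, warmup = warmup, keep = keep,
                          seed = seed, thin = thin, root = root),
    call = match.call()), class = "fidlmm")
  fit
}

# Proposal covariance from the numerical curvature of the target at the
# REML-based center, with the GLS coefficient covariance as fallback.
proposal_covariance <- function(target, center, reml, has_ri) {
  d <- length(center)
  H <- matrix(NA_real_, d, d)
  h <- pmax(abs(center) * 1e-4, 1e-5)
  f0 <- target(center)
  ok <- is.finite(f0)
  if (ok) {
    for (i in seq_len(d)) {
      for (j in i:d) {
        ei <- ej <- numeric(d); ei[i] <- h[i]; ej[j] <- h[j]
        fpp <- target(center + ei + ej); fpm <- target(center + ei - ej)
        fmp <- target(center - ei + ej); fmm <- target(center - ei - ej)
        H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
        if (!is.finite(H[i, j])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
  }
  fallback <- diag(c(pmax(reml$se_beta^2, 1e-10),
                     if (has_ri) 0.5, 0.05), d)
  if (!ok) return(fallback)
  S <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(S) || any(!is.finite(S)) || any(diag(S) <= 0)) return(fallback)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(fallback)
  S
}

# One adaptive random-walk Metropolis chain; scale adaptation (target
# acceptance 0.25-0.40) only during warmup.
run_rwm_chain <- function(target, init, chol0, warmup, keep, thin = 1) {
  d <- length(init)
  cur <- init
  f_cur <- target(cur)
  if (!is.finite(f_cur)) stop("could not initialize sampler chain")
  log_scale <- log(2.38 / sqrt(d))
  n_acc_total <- 0L
  n_total <- 0L
  batch_acc <- 0L
  batch_n <- 0L
  batch_idx <- 0L
  n_iter <- warmup + keep * thin
  out <- matrix(NA_real_, keep, d)
  kcount <- 0L
  for (it in seq_len(n_iter)) {
    z <- stats::rnorm(d)
    prop <- cur + exp(log_scale) * drop(crossprod(chol0, z))
    f_prop <- target(prop)
    u <- stats::runif(1)
    if (is.finite(f_prop) && log(u) < f_prop - f_cur) {
      cur <- prop; f_cur <- f_prop
      n_acc_total <- n_acc_total + 1L
      batch_acc <- batch_acc + 1L
    }
    n_total <- n_total + 1L
    batch_n <- batch_n + 1L
    if (it <= warmup && batch_n == 50L) {
      batch_idx <- batch_idx + 1L
      rate <- batch_acc / batch_n
      log_scale <- log_scale + (rate - 0.3) / sqrt(batch_idx)
      batch_acc <- 0L; batch_n <- 0L
    }
    if (it > warmup && (it - warmup) %% thin == 0L) {
      kcount <- kcount + 1L
      out[kcount, ] <- cur
    }
  }
  list(draws = out, accept_rate = n_acc_total / n_total)
}

# Split R-hat and a crude autocorrelation-based effective sample size.
chain_diagnostics <- function(draws, chain_id) {
  params <- colnames(draws)
  rhat <- ess <- numeric(length(params))
  for (j in seq_along(params)) {
    x <- draws[, j]
    by_chain <- split(x, chain_id)
    halves <- unlist(lapply(by_chain, function(v) {
      m <- length(v) %/% 2L
      list(v[seq_len(m)], v[m + seq_len(m)])
    }), recursive = FALSE)
    mns <- vapply(halves, mean, numeric(1L))
    vrs <- vapply(halves, stats::var, numeric(1L))
    m <- length(halves); n_h <- length(halves[[1L]])
    W <- mean(vrs); B <- n_h * stats::var(mns)
    rhat[j] <- if (W > 0) sqrt(((n_h - 1) / n_h * W + B / n_h) / W) else NA
    ess[j] <- sum(vapply(by_chain, function(v) {
      ac <- stats::acf(v, lag.max = min(200L, length(v) - 1L),
                       plot = FALSE, demean = TRUE)$acf[-1L]
      pos <- which(ac < 0.05)
      cut <- if (length(pos)) pos[1L] - 1L else length(ac)
      length(v) / (1 + 2 * sum(ac[seq_len(cut)]))
    }, numeric(1L)))
  }
  data.frame(parameter = params, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}

#' Summarize fiducial draws into point estimates and intervals
#'
#' Point estimates are means of the draws; intervals are equal-tailed
#' empirical quantiles at the requested level.  Variance components are
#' summarized exactly like the fixed effects — the fiducial distribution
#' provides intervals for all parameters.
#'
#' @param object A `"fidlmm"` fit (or a draw matrix with named columns).
#' @param level Interval level in (0, 1).
#' @return A data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper` (and `rhat`, `ess` when diagnostics are available).
#' @export
summarize_draws <- function(object, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  draws <- if (inherits(object, "fidlmm")) object$draws else as.matrix(object)
  if (nrow(draws) == 0L) stop("no draws to summarize")
  alpha <- (1 - level) / 2
  tab <- data.frame(
    parameter = colnames(draws),
    estimate = colMeans(draws),
    lower = apply(draws, 2, stats::quantile, probs = alpha, names = FALSE),
    upper = apply(draws, 2, stats::quantile, probs = 1 - alpha,
                  names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  if (inherits(object, "fidlmm")) {
    tab$rhat <- object$diagnostics$rhat[match(tab$parameter,
                                              object$diagnostics$parameter)]
    tab$ess <- object$diagnostics$ess[match(tab$parameter,
                                            object$diagnostics$parameter)]
  }
  tab
}

#' Decide on a null effect from a fiducial interval
#'
#' Following equivalence-test logic: an effect is declared `nonnull` when
#' its interval excludes 0; `null` when the interval contains 0 and lies
#' entirely inside `(-equivalence_bound, +equivalence_bound)` (it contains
#' no values far from 0); otherwise `inconclusive`.  The bound must be
#' supplied by the analyst — there is no silent default.
#'
#' @param object A `"fidlmm"` fit, a summary data frame from
#'   [summarize_draws()], or a numeric `c(lower, upper)` pair.
#' @param parameter Parameter name (when `object` is a fit or summary).
#' @param equivalence_bound Positive bound defining "far from 0".
#' @param level Interval level used when `object` is a fit.
#' @return One of `"null"`, `"nonnull"`, `"inconclusive"`.
#' @export
null_effect_decision <- function(object, parameter = NULL,
                                 equivalence_bound, level = 0.95) {
  if (!is.numeric(equivalence_bound) || equivalence_bound <= 0)
    stop("equivalence_bound must be a positive number")
  if (inherits(object, "fidlmm")) object <- summarize_draws(object, level)
  if (is.data.frame(object)) {
    if (is.null(parameter)) stop("'parameter' is required")
    row <- object[object$parameter == parameter, ]
    if (nrow(row) != 1L) stop("parameter '", parameter, "' not found")
    lo <- row$lower; hi <- row$upper
  } else {
    lo <- object[1L]; hi <- object[2L]
  }
  if (lo > 0 || hi < 0) return("nonnull")
  if (lo > -equivalence_bound && hi < equivalence_bound) return("null")
  "inconclusive"
}

#' @export
print.fidlmm <- function(x, digits = 4, ...) {
  cat("Generalized fiducial fit of a random-intercept mixed model\n")
  cat("  n =", length(x$design$y), "observations,",
      length(x$design$group_sizes), "subjects;",
      x$sampler_config$chains, "chains x", x$sampler_config$keep,
      "kept draws\n")
  if (x$convergence_warning)
    cat("  WARNING: split R-hat > 1.05 for some parameters\n")
  tab <- summarize_draws(x, x$level)
  tab[2:4] <- lapply(tab[2:4], signif, digits)
  print(tab[c("parameter", "estimate", "lower", "upper")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.fidlmm <- function(object, level = object$level, ...) {
  out <- summarize_draws(object, level)
  attr(out, "level") <- level
  attr(out, "accept_rate") <- object$accept_rate
  out
}

#' @export
coef.fidlmm <- function(object, ...) {
  p <- ncol(object$design$X)
  colMeans(object$draws[, seq_len(p), drop = FALSE])
}

#' @export
confint.fidlmm <- function(object, parm, level = 0.95, ...) {
  tab <- summarize_draws(object, level)
  ci <- as.matrix(tab[, c("lower", "upper")])
  rownames(ci) <- tab$parameter
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.fidlmm <- function(object, ...) {
  drop(object$design$X %*% coef(object))
}

#' @export
residuals.fidlmm <- function(object, ...) {
  object$design$y - fitted(object)
}

#' @export
predict.fidlmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  drop(build_X(newdata, object$spec) %*% coef(object))
}

#' @export
plot.fidlmm <- function(x, parameters = NULL, ...) {
  params <- parameters %||% colnames(x$draws)
  old <- graphics::par(mfrow = c(length(params), 2),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(old))
  for (pm in params) {
    v <- x$draws[, pm]
    graphics::plot(v, type = "l", col = "grey40", xlab = "draw", ylab = pm,
                   main = paste("trace:", pm))
    graphics::plot(stats::density(v), main = paste("fiducial density:", pm),
                   xlab = pm)
  }
  invisible(x)
}

#' @export
simulate.fidlmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  est <- summarize_draws(object, object$level)
  beta <- coef(object)
  va <- if ("var_subject" %in% est$parameter)
    est$estimate[est$parameter == "var_subject"] else 0
  ve <- est$estimate[est$parameter == "var_resid"]
  mu <- drop(des$X %*% beta)
  n_g <- length(des$group_sizes)
  out <- as.data.frame(replicate(nsim, {
    u <- stats::rnorm(n_g, 0, sqrt(va))
    mu + u[des$group] + stats::rnorm(length(mu), 0, sqrt(ve))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
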