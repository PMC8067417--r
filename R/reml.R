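#' Restricted maximum likelihood for the random-intercept model
#'
#' Fits the two-level model `y = X beta + u0[subject] + e`,
#' `u0 ~ N(0, var_subject)`, `e ~ N(0, var_resid)`, by REML.  The REML
#' criterion is profiled down to one dimension in the variance ratio
#' `phi = var_subject / var_resid`: for each `phi` the GLS coefficients and
#' the residual variance have closed forms, so the optimum is located by
#' golden-section search on `log(phi)` together with an explicit evaluation
#' of the `phi = 0` boundary (a zero between-subject variance is a permitted
#' solution).  Standard errors for the coefficients come from the GLS
#' covariance; coefficient t-tests use Satterthwaite degrees of freedom
#' (see [satterthwaite_tests()]).
#'
#' @param object A formula, a [model_spec()], or an `"lmm_design"` from
#'   [build_design()].
#' @param data A data frame (ignored when `object` is already a design).
#' @param subject Subject identifier column (used when `object` is a
#'   formula).
#' @return An object of class `"remlmm"` with components `beta`, `se_beta`,
#'   `satt_df`, `t_values`, `p_values`, `var_subject`, `var_resid`,
#'   `vcov_beta`, `varcomp_vcov`, `reml_criterion` (-2 restricted
#'   log-likelihood), and `converged`.
#' @examples
#' sim <- simulate_dataset(synthetic_config(seed = 1))
#' fit <- fit_reml(sbp_r ~ tertile, sim$table, subject = "subject_id")
#' coef(fit)
#' @export
fit_reml <- function(object, data = NULL, subject = "subject_id") {
  design <- as_lmm_design(object, data, subject)
  X <- design$X; y <- design$y; n <- length(y); p <- ncol(X)
  if (n <= p + 2L) stop("too few observations (n = ", n, ", p = ", p, ")")
  if (design$spec$random_intercept && length(design$group_sizes) < 2L)
    stop("at least 2 subjects are required")

  if (!design$spec$random_intercept) {
    fit0 <- stats::lm.fit(X, y)
    ve <- sum(fit0$residuals^2) / (n - p)
    res <- reml_profile_crit(0, design)   # phi = 0 gives the OLS pieces
    out <- finalize_reml(design, 0, res, boundary = TRUE)
    out$var_subject <- 0
    return(out)
  }

  crit_fun <- function(u) reml_profile_crit(exp(u), design)$crit
  opt <- stats::optimize(crit_fun, interval = c(-30, 15), tol = 1e-10)
  crit0 <- reml_profile_crit(0, design)
  boundary <- crit0$crit <= opt$objective + 1e-8 || opt$minimum < -29
  phi <- if (boundary) 0 else exp(opt$minimum)
  res <- if (boundary) crit0 else reml_profile_crit(phi, design)
  finalize_reml(design, phi, res, boundary)
}

as_lmm_design <- function(object, data, subject) {
  if (inherits(object, "lmm_design")) return(object)
  spec <- if (inherits(object, "formula"))
    as_model_spec(object, subject = subject)
  else if (inherits(object, "model_spec")) object
  else stop("'object' must be a formula, model_spec, or lmm_design")
  if (is.null(data)) stop("'data' is required with a formula or model_spec")
  d <- build_design(data, spec)
  d$data <- data
  d
}

# Profiled REML pieces at a given variance ratio phi = var_subject/var_resid.
reml_profile_crit <- function(phi, design) {
  X <- design$X; y <- design$y; n <- length(y); p <- ncol(X)
  W <- block_cov(phi, 1, design$group)
  Xw <- W$solve(X)
  XtWX <- crossprod(X, Xw)
  beta <- drop(solve(XtWX, crossprod(Xw, y)))
  r <- y - drop(X %*% beta)
  rss <- W$quad(r)
  sigma2 <- rss / (n - p)
  crit <- (n - p) * (log(sigma2) + 1 + log(2 * pi)) + W$logdet() +
    as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  list(crit = crit, beta = beta, sigma2 = sigma2, XtWX = XtWX)
}

finalize_reml <- function(design, phi, res, boundary) {
  p <- ncol(design$X)
  ve <- res$sigma2
  va <- phi * ve
  vcov_beta <- ve * solve(res$XtWX)
  se <- sqrt(diag(vcov_beta))
  fit <- structure(list(
    beta = stats::setNames(res$beta, colnames(design$X)),
    se_beta = stats::setNames(se, colnames(design$X)),
    var_subject = va, var_resid = ve,
    vcov_beta = vcov_beta,
    reml_criterion = res$crit,
    boundary = boundary, converged = is.finite(res$crit),
    n = length(design$y), n_subjects = length(design$group_sizes),
    design = design, spec = design$spec,
    call = sys.call(-1L)), class = "remlmm")
  fit$varcomp_vcov <- tryCatch(varcomp_vcov(fit, design),
                               error = function(e) matrix(NA_real_, 2, 2))
  satterthwaite_tests(fit, design)
}

#' REML criterion (-2 restricted log-likelihood) at given variance components
#'
#' Exposed mainly for diagnostics and tests: the REML deviance as a function
#' of the variance components, with the fixed effects profiled out by GLS.
#'
#' @param var_subject,var_resid Variance components.
#' @param design An `"lmm_design"`.
#' @return The scalar deviance.
#' @export
reml_deviance <- function(var_subject, var_resid, design) {
  X <- design$X; y <- design$y; n <- length(y); p <- ncol(X)
  V <- block_cov(var_subject, var_resid, design$group)
  Xv <- V$solve(X)
  XtVX <- crossprod(X, Xv)
  beta <- drop(solve(XtVX, crossprod(Xv, y)))
  r <- y - drop(X %*% beta)
  V$logdet() + as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) +
    V$quad(r) + (n - p) * log(2 * pi)
}

# Asymptotic covariance of (var_subject, var_resid) from the observed REML
# information (0.5 x Hessian of the deviance), forward differences at the
# var_subject = 0 boundary.
varcomp_vcov <- function(fit, design) {
  f <- function(va, ve) reml_deviance(max(va, 0), ve, design)
  va <- fit$var_subject; ve <- fit$var_resid
  h <- max(va, ve) * 1e-4
  k <- ve * 1e-4
  if (va > 2 * h) {
    H11 <- (f(va + h, ve) - 2 * f(va, ve) + f(va - h, ve)) / h^2
    H12 <- (f(va + h, ve + k) - f(va + h, ve - k) -
            f(va - h, ve + k) + f(va - h, ve - k)) / (4 * h * k)
  } else {
    H11 <- (f(2 * h, ve) - 2 * f(h, ve) + f(0, ve)) / h^2
    H12 <- (f(h, ve + k) - f(h, ve - k) - f(0, ve + k) + f(0, ve - k)) /
      (2 * h * k)
  }
  H22 <- (f(va, ve + k) - 2 * f(va, ve) + f(va, ve - k)) / k^2
  info <- 0.5 * matrix(c(H11, H12, H12, H22), 2, 2)
  A <- solve(info)
  dimnames(A) <- list(c("var_subject", "var_resid"),
                      c("var_subject", "var_resid"))
  A
}

#' Satterthwaite t-tests for the fixed effects of a REML fit
#'
#' For each coefficient (or an arbitrary linear combination `L`), the
#' denominator degrees of freedom are `2 c^2 / Var(c)`, where
#' `c(var_subject, var_resid) = L' (X' V^-1 X)^-1 L` is the coefficient
#' variance and `Var(c)` is obtained by the delta method from the numerical
#' gradient of `c` and the asymptotic covariance of the variance components.
#' Non-positive or non-finite df estimates fall back to `n - p` with a
#' warning.
#'
#' @param fit A `"remlmm"` fit.
#' @param design The realized design (defaults to the one stored in `fit`).
#' @return `fit`, with `satt_df`, `t_values` and `p_values` filled in.
#' @export
satterthwaite_tests <- function(fit, design = fit$design) {
  p <- length(fit$beta)
  if (!isTRUE(design$spec$random_intercept)) {
    # single-level limit: the t-tests are exact with n - p df
    fit$satt_df <- stats::setNames(rep(fit$n - p, p), names(fit$beta))
    fit$t_values <- fit$beta / fit$se_beta
    fit$p_values <- 2 * stats::pt(-abs(fit$t_values), df = fit$satt_df)
    return(fit)
  }
  df <- vapply(seq_len(p), function(j) {
    L <- numeric(p); L[j] <- 1
    satt_df_contrast(fit, design, L)
  }, numeric(1L))
  bad <- !is.finite(df) | df <= 0
  if (any(bad)) {
    warning("non-positive Satterthwaite df for ",
            paste(names(fit$beta)[bad], collapse = ", "),
            "; falling back to n - p")
    df[bad] <- fit$n - p
  }
  fit$satt_df <- stats::setNames(df, names(fit$beta))
  fit$t_values <- fit$beta / fit$se_beta
  fit$p_values <- 2 * stats::pt(-abs(fit$t_values), df = fit$satt_df)
  fit
}

# Satterthwaite df for the variance of L' beta_hat.
satt_df_contrast <- function(fit, design, L) {
  cfun <- function(va, ve) {
    V <- block_cov(max(va, 0), ve, design$group)
    C <- solve(crossprod(design$X, V$solve(design$X)))
    drop(t(L) %*% C %*% L)
  }
  va <- fit$var_subject; ve <- fit$var_resid
  h <- max(va, ve) * 1e-5
  k <- ve * 1e-5
  g1 <- if (va > h) (cfun(va + h, ve) - cfun(va - h, ve)) / (2 * h)
        else (cfun(h, ve) - cfun(0, ve)) / h
  g2 <- (cfun(va, ve + k) - cfun(va, ve - k)) / (2 * k)
  cval <- cfun(va, ve)
  A <- fit$varcomp_vcov
  vc <- drop(t(c(g1, g2)) %*% A %*% c(g1, g2))
  2 * cval^2 / vc
}

#' Partition response variance within and between persons
#'
#' Fits the unconditional (intercept-only) random-intercept model and returns
#' the within-person and between-person variance shares as percentages,
#' together with the component estimates.
#'
#' @param table A long-format data frame.
#' @param response Response column name.
#' @param subject Subject identifier column.
#' @return A list with `within_share`, `between_share` (percent), `sigma2`
#'   (residual variance), `tau00` (between-person variance), and the
#'   underlying `"remlmm"` `fit`.
#' @export
variance_partition <- function(table, response = "sbp_r",
                               subject = "subject_id") {
  counts <- table(table[[subject]][!is.na(table[[response]])])
  if (length(counts) < 2L || !any(counts >= 2L))
    stop("need >= 2 subjects with >= 2 observations")
  fit <- fit_reml(model_spec(response, character(), subject = subject), table)
  tot <- fit$var_subject + fit$var_resid
  if (!is.finite(tot) || tot <= 0) stop("degenerate variance estimates")
  list(within_share = 100 * fit$var_resid / tot,
       between_share = 100 * fit$var_subject / tot,
       sigma2 = fit$var_resid, tau00 = fit$var_subject, fit = fit)
}

#' Probe a cross-level interaction by simple slopes
#'
#' Conditional slopes of a focal (within-person) predictor at moderator
#' values one between-person standard deviation below and above the
#' between-person mean.  The slope is
#' `beta_focal + beta_interaction * (mean(moderator) +/- SD)`; its standard
#' error comes from the coefficient covariance by the delta method, and the
#' p-value uses Satterthwaite degrees of freedom for the same linear
#' combination.  The moderator mean and SD are computed across subjects (one
#' value per subject), since moderators are person-level.
#'
#' @param fit A `"remlmm"` fit whose model contains `focal`, `moderator`,
#'   and their interaction.
#' @param focal Name of the focal predictor (e.g. `"tertile"`).
#' @param moderator Name of the moderating person-level covariate.
#' @return A data frame with one row per conditioning value: `at`,
#'   `moderator_value`, `slope`, `se`, `df`, `t`, `p`.
#' @export
simple_slopes <- function(fit, focal, moderator) {
  stopifnot(inherits(fit, "remlmm"))
  nm <- names(fit$beta)
  int_idx <- which(vapply(nm, function(tm) {
    setequal(term_factors(tm), c(focal, moderator))
  }, logical(1L)))
  if (!focal %in% nm || length(int_idx) != 1L)
    stop("model must contain '", focal, "', '", moderator,
         "', and their interaction")
  data <- fit$design$data
  if (is.null(data)) stop("fit carries no data; refit from a formula")
  sub <- fit$spec$subject
  per_person <- tapply(data[[moderator]], data[[sub]], function(v) v[1L])
  m_mean <- mean(per_person, na.rm = TRUE)
  m_sd <- stats::sd(per_person, na.rm = TRUE)
  p <- length(fit$beta)
  rows <- lapply(c(-1, 1), function(s) {
    at_val <- m_mean + s * m_sd
    L <- numeric(p)
    L[match(focal, nm)] <- 1
    L[int_idx] <- at_val
    slope <- sum(L * fit$beta)
    se <- sqrt(drop(t(L) %*% fit$vcov_beta %*% L))
    df <- satt_df_contrast(fit, fit$design, L)
    if (!is.finite(df) || df <= 0) df <- fit$n - p
    tv <- slope / se
    data.frame(at = sprintf("%+d SD", s), moderator_value = at_val,
               slope = slope, se = se, df = df, t = tv,
               p = 2 * stats::pt(-abs(tv), df), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.remlmm <- function(x, digits = 4, ...) {
  cat("Random-intercept linear mixed model fit by REML\n")
  rhs <- if (length(x$spec$terms)) paste(x$spec$terms, collapse = " + ")
         else "1"
  cat("  ", x$spec$response, " ~ ", rhs, " + (1 | ", x$spec$subject, ")\n",
      sep = "")
  cat("  n =", x$n, "observations,", x$n_subjects, "subjects\n")
  cat("  var_subject (tau00) =", signif(x$var_subject, digits),
      "  var_resid (sigma2) =", signif(x$var_resid, digits), "\n")
  cat("Fixed effects:\n")
  print(signif(x$beta, digits))
  invisible(x)
}

#' @export
summary.remlmm <- function(object, ...) {
  tab <- data.frame(
    parameter = names(object$beta),
    estimate = unname(object$beta),
    se = unname(object$se_beta),
    df = unname(object$satt_df),
    t = unname(object$t_values),
    p = unname(object$p_values),
    sig = p_stars(unname(object$p_values)),
    stringsAsFactors = FALSE)
  vc <- data.frame(
    parameter = c("var_subject", "var_resid"),
    estimate = c(object$var_subject, object$var_resid),
    se = sqrt(pmax(diag(object$varcomp_vcov), 0)),
    stringsAsFactors = FALSE)
  out <- list(coefficients = tab, varcomp = vc,
              reml_criterion = object$reml_criterion, n = object$n,
              n_subjects = object$n_subjects, spec = object$spec)
  class(out) <- "summary.remlmm"
  out
}

#' @export
print.summary.remlmm <- function(x, digits = 4, ...) {
  cat("REML fit: n =", x$n, ", subjects =", x$n_subjects,
      ", -2 restricted logLik =", signif(x$reml_criterion, 6), "\n\n")
  co <- x$coefficients
  co[2:6] <- lapply(co[2:6], signif, digits)
  print(co, row.names = FALSE)
  cat("---\nSignif. codes: * p < 0.05, ** p < 0.01, *** p < 0.001\n")
  cat("\nVariance components:\n")
  vc <- x$varcomp
  vc[2:3] <- lapply(vc[2:3], signif, digits)
  print(vc, row.names = FALSE)
  invisible(x)
}

#' Significance stars for p-values
#'
#' @param p A vector of p-values.
#' @return A character vector: `***` for p < 0.001, `**` for p < 0.01,
#'   `*` for p < 0.05, empty otherwise.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
coef.remlmm <- function(object, ...) object$beta

#' @export
vcov.remlmm <- function(object, ...) object$vcov_beta

#' @export
confint.remlmm <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = object$satt_df)
  ci <- cbind(object$beta - q * object$se_beta,
              object$beta + q * object$se_beta)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.remlmm <- function(object, ...) {
  drop(object$design$X %*% object$beta)
}

#' @export
residuals.remlmm <- function(object, ...) {
  object$design$y - fitted(object)
}

#' @export
logLik.remlmm <- function(object, ...) {
  structure(-0.5 * object$reml_criterion,
            df = length(object$beta) + 2, class = "logLik")
}

#' @export
predict.remlmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  drop(build_X(newdata, object$spec) %*% object$beta)
}

# Fixed-effects design matrix for new data (no response needed).
build_X <- function(data, spec) {
  n <- nrow(data)
  p <- length(spec$terms) + 1L
  X <- matrix(1, n, p)
  colnames(X) <- c("(Intercept)", spec$terms)
  for (j in seq_along(spec$terms)) {
    col <- rep(1, n)
    for (f in term_factors(spec$terms[j])) {
      if (!f %in% names(data)) stop("unknown column '", f, "' in newdata")
      col <- col * as.numeric(data[[f]])
    }
    X[, j + 1L] <- col
  }
  X
}
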