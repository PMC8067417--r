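# Independent reference implementations used as oracles. These deliberately
# use dense linear algebra / closed forms, never the package's block paths.

# Dense marginal covariance of the random-intercept model.
dense_V <- function(var_subject, var_resid, group) {
  n <- length(group)
  var_subject * outer(group, group, "==") + diag(var_resid, n)
}

# Dense multivariate-normal log density.
dense_loglik <- function(theta, y, X, group) {
  V <- dense_V(theta$var_subject, theta$var_resid, group)
  r <- y - drop(X %*% theta$beta)
  n <- length(y)
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            drop(t(r) %*% solve(V, r)))
}

# Dense Jacobian matrix [X, Sa V^-1 r, V^-1 r].
dense_jacobian <- function(theta, y, X, group) {
  V <- dense_V(theta$var_subject, theta$var_resid, group)
  Sa <- outer(group, group, "==") * 1
  r <- y - drop(X %*% theta$beta)
  vr <- solve(V, r)
  cbind(X, Sa %*% vr, vr)
}

# Classical balanced one-way ANOVA variance-component estimators.
anova_varcomp <- function(y, group) {
  m <- unname(table(group))[1]
  means <- tapply(y, group, mean)
  ms_within <- sum((y - means[as.character(group)])^2) /
    (length(y) - length(means))
  ms_between <- m * sum((means - mean(y))^2) / (length(means) - 1)
  list(sigma2 = ms_within,
       tau00 = max((ms_between - ms_within) / m, 0))
}

# JZS two-group Bayes factor as a single 1-D integral in the t statistic
# (the Rouder et al. form), independent of the package's linear-algebra path.
jzs_t_bf <- function(y, x, r_scale) {
  xs <- (x - mean(x)) / stats::sd(x)
  tv <- summary(stats::lm(y ~ xs))$coefficients["xs", "t value"]
  N <- sum(xs^2)
  n <- length(y)
  nu <- n - 2
  f <- function(g) (1 + g * N)^(-0.5) *
    ((1 + tv^2 / ((1 + g * N) * nu)) / (1 + tv^2 / nu))^(-(n - 1) / 2) *
    r_scale / sqrt(2 * pi) * g^(-1.5) * exp(-r_scale^2 / (2 * g))
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# Brute-force marginality-respecting subset enumeration, written differently
# from the package (string keys + per-subset filter over an explicit grid).
brute_force_subsets <- function(terms) {
  k <- length(terms)
  fsets <- strsplit(terms, ":", fixed = TRUE)
  keys <- vapply(fsets, function(f) paste(sort(f), collapse = ":"),
                 character(1))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  keep <- apply(grid, 1, function(inc) {
    present <- keys[as.logical(inc)]
    for (i in which(as.logical(inc))) {
      f <- fsets[[i]]
      if (length(f) < 2) next
      for (m in 1:(2^length(f) - 2)) {
        sub <- f[bitwAnd(m, bitwShiftL(1L, seq_along(f) - 1L)) > 0L]
        if (!paste(sort(sub), collapse = ":") %in% present) return(FALSE)
      }
    }
    TRUE
  })
  sum(keep)
}

# Small random instance generator shared by the dense-oracle tests.
random_instance <- function(n_max = 24, p_terms = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_groups <- sample(2:5, 1)
  sizes <- pmax(1, stats::rmultinom(1, sample(6:n_max, 1), rep(1, n_groups)))
  group <- rep(seq_len(n_groups), times = sizes)
  n <- length(group)
  df <- data.frame(id = group)
  terms <- paste0("x", seq_len(p_terms))
  for (tm in terms) df[[tm]] <- stats::rnorm(n)
  df$y <- stats::rnorm(n, sd = 2)
  spec <- model_spec("y", terms, subject = "id")
  des <- build_design(df, spec)
  theta <- lmm_theta(stats::rnorm(p_terms + 1),
                     stats::rexp(1), stats::rexp(1) + 0.2)
  list(design = des, theta = theta, group = des$group)
}

# The paper-style Model 1 and Model 4 candidate term sets.
model1_terms <- function() {
  c("tertile", "sbp_baseline", "cognition", "physical_w1",
    "tertile:cognition", "tertile:physical_w1")
}
model4_terms <- function() {
  c("tertile", "sbp_baseline", "cognition", "physical_w1", "physical_w2",
    "tertile:cognition", "tertile:physical_w2", "cognition:physical_w2",
    "tertile:cognition:physical_w2")
}
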