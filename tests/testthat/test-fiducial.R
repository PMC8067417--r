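test_that("Jacobian matrix matches the dense construction and its limits", {
  set.seed(11)
  # random instances vs dense oracle
  for (i in 1:20) {
    inst <- random_instance()
    M <- fid_jacobian(inst$theta, inst$design)
    Md <- dense_jacobian(inst$theta, inst$design$y, inst$design$X,
                         inst$design$group)
    expect_equal(unname(M), unname(Md), tolerance = 1e-10)
    lj <- fid_log_jacobian(inst$theta, inst$design)
    expect_equal(lj, 0.5 * as.numeric(determinant(crossprod(Md))$modulus),
                 tolerance = 1e-8)
    expect_equal(fid_log_jacobian(inst$theta, inst$design, root = FALSE),
                 2 * lj, tolerance = 1e-8)
  }

  # var_subject = 0, single group: Sa V^-1 r is the within-group sum of r/ve
  df <- data.frame(id = rep(1L, 6), x = rnorm(6), y = rnorm(6))
  des <- suppressWarnings(build_design(df, model_spec("y", "x", subject = "id",
                                                      random_intercept = FALSE)))
  des$spec$random_intercept <- TRUE   # keep the Sa column, one group
  th <- lmm_theta(c(0, 1), 0, 2)
  M <- fid_jacobian(th, des)
  r <- des$y - drop(des$X %*% th$beta)
  expect_equal(M[, 3], rep(sum(r) / 2, 6))
  expect_equal(M[, 4], r / 2)

  # exact fit: residual columns vanish and the density degenerates
  th_exact <- lmm_theta(c(mean(des$y), 0), 1, 1)
  des2 <- des
  des2$y <- drop(des2$X %*% c(1, 2))
  expect_equal(fid_log_jacobian(lmm_theta(c(1, 2), 1, 1), des2), -Inf)
})

test_that("scaling the residual-derived columns shifts log-Jacobian by a theta-free constant", {
  set.seed(21)
  inst <- random_instance()
  des <- inst$design
  cval <- 3.7
  shift_at <- function(theta) {
    M <- fid_jacobian(theta, des)
    M2 <- M
    M2[, ncol(M) - 1:0] <- cval * M2[, ncol(M) - 1:0]
    0.5 * (as.numeric(determinant(crossprod(M2))$modulus) -
             as.numeric(determinant(crossprod(M))$modulus))
  }
  shifts <- replicate(5, shift_at(lmm_theta(rnorm(3), rexp(1), rexp(1) + 0.1)))
  expect_equal(max(shifts) - min(shifts), 0, tolerance = 1e-8)
  expect_equal(shifts[1], 2 * log(cval), tolerance = 1e-8)
})

test_that("log fiducial density composes likelihood and Jacobian, with -Inf outside the space", {
  set.seed(31)
  inst <- random_instance()
  th <- inst$theta
  expect_equal(fid_log_density(th, inst$design),
               lmm_loglik(th, inst$design) +
                 fid_log_jacobian(th, inst$design))
  expect_identical(fid_log_density(list(beta = th$beta, var_subject = 1,
                                        var_resid = -1), inst$design), -Inf)
  # normalization cancels in differences
  th2 <- lmm_theta(th$beta + 0.1, th$var_subject + 0.5, th$var_resid + 0.5)
  d1 <- fid_log_density(th, inst$design) - fid_log_density(th2, inst$design)
  d2 <- (lmm_loglik(th, inst$design) + fid_log_jacobian(th, inst$design)) -
    (lmm_loglik(th2, inst$design) + fid_log_jacobian(th2, inst$design))
  expect_equal(d1, d2)
})

test_that("a 1-parameter slice of the fiducial density normalizes to 1 under quadrature", {
  set.seed(41)
  df <- data.frame(id = rep(1:4, each = 4), y = rnorm(16, 2, 1))
  des <- build_design(df, model_spec("y", character(), subject = "id"))
  va <- 0.5; ve <- 1.2
  f <- Vectorize(function(b)
    exp(fid_log_density(list(beta = b, var_subject = va, var_resid = ve),
                        des)))
  Z <- integrate(f, -10, 10, rel.tol = 1e-10)$value
  g <- Vectorize(function(b) f(b) / Z)
  expect_equal(integrate(g, -10, 10, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
})

test_that("the Metropolis kernel is invariant to constant shifts of the log target and to the seed contract", {
  set.seed(51)
  target <- function(eta) -0.5 * sum(eta^2)
  target_shifted <- function(eta) target(eta) + 123.4
  ch <- chol(diag(2))
  set.seed(7)
  a <- fidlmm:::run_rwm_chain(target, c(0, 0), ch, 200, 300)
  set.seed(7)
  b <- fidlmm:::run_rwm_chain(target_shifted, c(0, 0), ch, 200, 300)
  expect_identical(a$draws, b$draws)
})

test_that("fiducial fits are reproducible under a fixed seed and mix on the default example", {
  cfg <- synthetic_config(spec = as_model_spec(sbp_r ~ tertile * cognition),
                          beta = c(5.82, -0.33, -11.82, 0.32), seed = 61)
  sim <- simulate_dataset(cfg)
  fit1 <- fidlmm(cfg$spec, sim$table, chains = 2, warmup = 800, keep = 1200,
                 seed = 9)
  fit2 <- fidlmm(cfg$spec, sim$table, chains = 2, warmup = 800, keep = 1200,
                 seed = 9)
  expect_identical(fit1$draws, fit2$draws)
  expect_true(all(fit1$diagnostics$rhat < 1.05))
  expect_true(all(fit1$draws[, "var_resid"] > 0))
  expect_true(all(fit1$draws[, "var_subject"] >= 0))
  expect_equal(nrow(fit1$draws), 2 * 1200)
  # methods behave
  expect_length(coef(fit1), 4L)
  expect_equal(dim(confint(fit1)), c(6L, 2L))
  expect_length(residuals(fit1), length(fit1$design$y))
  expect_equal(predict(fit1, sim$table[1:3, ]),
               fitted(fit1)[1:3], tolerance = 1e-12)
})

test_that("draw summaries use means and equal-tailed quantiles", {
  m <- matrix(5, 100, 1, dimnames = list(NULL, "b"))
  s <- summarize_draws(m)
  expect_equal(s$estimate, 5)
  expect_equal(s$lower, 5)
  expect_equal(s$upper, 5)
  set.seed(71)
  z <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  s2 <- summarize_draws(z, level = 0.95)
  expect_equal(s2$lower, -1.96, tolerance = 0.08)
  expect_equal(s2$upper, 1.96, tolerance = 0.08)
  expect_error(summarize_draws(z, level = 1.2), "level")
})

test_that("null-effect decisions follow the equivalence-test rule", {
  expect_identical(null_effect_decision(c(0.01, 0.64),
                                        equivalence_bound = 1), "nonnull")
  expect_identical(null_effect_decision(c(-0.29, 0.56),
                                        equivalence_bound = 1), "null")
  expect_identical(null_effect_decision(c(-0.2, 5.0),
                                        equivalence_bound = 1),
                   "inconclusive")
  expect_error(null_effect_decision(c(-1, 1), equivalence_bound = -1),
               "positive")
})
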