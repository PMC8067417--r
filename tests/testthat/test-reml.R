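test_that("REML equals the classical ANOVA estimators on balanced one-way layouts", {
  set.seed(13)
  for (i in 1:5) {
    n_g <- sample(5:10, 1); m <- sample(3:6, 1)
    df <- data.frame(id = rep(seq_len(n_g), each = m))
    u <- rnorm(n_g, 0, 2)
    df$y <- 5 + u[df$id] + rnorm(nrow(df), 0, 1.5)
    fit <- fit_reml(y ~ 1, df, subject = "id")
    ref <- anova_varcomp(df$y, df$id)
    expect_equal(fit$var_resid, ref$sigma2, tolerance = 1e-7)
    expect_equal(fit$var_subject, ref$tau00, tolerance = 1e-6)
  }
})

test_that("a zero between-subject variance collapses REML onto OLS", {
  set.seed(23)
  df <- data.frame(id = rep(1:40, each = 6), x = rnorm(240))
  df$y <- 1 + 0.5 * df$x + rnorm(240)   # no subject effect in truth
  fit <- fit_reml(y ~ x, df, subject = "id")
  ols <- lm(y ~ x, df)
  # var_subject is tiny (possibly exactly 0); beta close to OLS
  expect_lt(fit$var_subject, 0.15)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 0.02)
})

test_that("REML estimates and Satterthwaite tests agree with the established mixed-model implementation", {
  skip_if_not_installed("lmerTest")
  cfg <- synthetic_config(
    spec = as_model_spec(sbp_r ~ tertile * cognition + sbp_baseline),
    beta = c(5.8, -0.33, -11.8, 0.22, 0.32), seed = 42)
  sim <- simulate_dataset(cfg)
  fit <- fit_reml(sbp_r ~ tertile * cognition + sbp_baseline, sim$table)
  lf <- lmerTest::lmer(
    sbp_r ~ tertile * cognition + sbp_baseline + (1 | subject_id),
    sim$table, REML = TRUE)
  co <- summary(lf)$coefficients
  ref_beta <- lme4::fixef(lf)[names(fit$beta)]
  expect_equal(unname(fit$beta), unname(ref_beta), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(fit$var_subject, vc[1], tolerance = 1e-4)
  expect_equal(fit$var_resid, vc[2], tolerance = 1e-4)
  expect_equal(unname(fit$se_beta), unname(co[names(fit$beta), "Std. Error"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$satt_df), unname(co[names(fit$beta), "df"]),
               tolerance = 1e-2)
  expect_equal(unname(fit$p_values),
               unname(co[names(fit$beta), "Pr(>|t|)"]), tolerance = 1e-4)
})

test_that("Satterthwaite df collapse to the classical values in balanced designs", {
  set.seed(33)
  # single-group data carry no between-subject information: df ~ n - p
  df1 <- data.frame(id = rep(1L, 30), x = rnorm(30), y = rnorm(30))
  fit1 <- fit_reml(model_spec("y", "x", subject = "id",
                              random_intercept = FALSE), df1)
  expect_equal(unname(fit1$satt_df), rep(28, 2), tolerance = 0.2)
  # balanced design, person-level covariate: df ~ n_subjects - 2
  n_g <- 30; m <- 5
  df2 <- data.frame(id = rep(seq_len(n_g), each = m))
  xs <- rnorm(n_g)
  df2$x <- xs[df2$id]
  u <- rnorm(n_g, 0, 2)
  df2$y <- 1 + 0.5 * df2$x + u[df2$id] + rnorm(nrow(df2))
  fit2 <- fit_reml(y ~ x, df2, subject = "id")
  expect_equal(unname(fit2$satt_df[["x"]]), n_g - 2, tolerance = 0.15)
  # t = 0 gives p = 1
  fitz <- fit2
  fitz$beta[] <- 0
  fitz <- satterthwaite_tests(fitz, fitz$design)
  expect_equal(unname(fitz$p_values), rep(1, 2))
})

test_that("REML is deterministic, permutation-invariant, and optimal at its solution", {
  set.seed(43)
  cfg <- synthetic_config(spec = as_model_spec(sbp_r ~ tertile),
                          beta = c(4, -0.3), seed = 77)
  sim <- simulate_dataset(cfg)
  fit1 <- fit_reml(sbp_r ~ tertile, sim$table)
  fit2 <- fit_reml(sbp_r ~ tertile, sim$table)
  expect_identical(fit1$beta, fit2$beta)
  perm <- sample(nrow(sim$table))
  fit3 <- fit_reml(sbp_r ~ tertile, sim$table[perm, ])
  expect_equal(fit1$beta, fit3$beta, tolerance = 1e-8)
  expect_equal(fit1$var_subject, fit3$var_subject, tolerance = 1e-8)
  # deviance at the solution is no worse than at the generating truth
  expect_lte(fit1$reml_criterion,
             reml_deviance(sim$truth$var_subject, sim$truth$var_resid,
                           fit1$design) + 1e-6)
})

test_that("variance partition returns complementary percentage shares", {
  set.seed(53)
  # one shared mean, iid noise: between share near zero
  df <- data.frame(subject_id = rep(1:25, each = 8))
  df$sbp_r <- rnorm(200)
  vp <- variance_partition(df)
  expect_lt(vp$between_share, 10)
  expect_equal(vp$within_share + vp$between_share, 100)
  # equal components: shares near 50/50 (averaged over replications)
  shares <- replicate(10, {
    cfg <- synthetic_config(n_subjects = 40, var_subject = 50,
                            var_resid = 50, seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    variance_partition(sim$table)$between_share
  })
  expect_equal(mean(shares), 50, tolerance = 6)
  expect_error(variance_partition(data.frame(subject_id = 1:3,
                                             sbp_r = rnorm(3))),
               ">= 2")
})

test_that("simple slopes follow the delta-method arithmetic and sign logic", {
  cfg <- synthetic_config(spec = as_model_spec(sbp_r ~ tertile * cognition),
                          beta = c(5, -0.43, -10, 0.32), seed = 63)
  sim <- simulate_dataset(cfg)
  fit <- fit_reml(sbp_r ~ tertile * cognition, sim$table)
  ss <- simple_slopes(fit, "tertile", "cognition")
  per_person <- tapply(sim$table$cognition, sim$table$subject_id,
                       function(v) v[1])
  mm <- mean(per_person); ms <- sd(per_person)
  b_f <- fit$beta[["tertile"]]; b_i <- fit$beta[["tertile:cognition"]]
  expect_equal(ss$slope, b_f + b_i * (mm + c(-1, 1) * ms), tolerance = 1e-10)
  # SE from the coefficient covariance
  i_f <- match("tertile", names(fit$beta))
  i_i <- match("tertile:cognition", names(fit$beta))
  at <- mm - ms
  se_manual <- sqrt(fit$vcov_beta[i_f, i_f] + at^2 * fit$vcov_beta[i_i, i_i] +
                      2 * at * fit$vcov_beta[i_f, i_i])
  expect_equal(ss$se[1], se_manual, tolerance = 1e-10)
  expect_true(all(ss$p > 0 & ss$p < 1))
  # zero interaction: both conditional slopes equal the focal coefficient
  fit0 <- fit
  fit0$beta[["tertile:cognition"]] <- 0
  ss0 <- simple_slopes(fit0, "tertile", "cognition")
  expect_equal(ss0$slope, rep(fit0$beta[["tertile"]], 2))
  expect_error(simple_slopes(fit, "tertile", "sbp_baseline"), "interaction")
})

test_that("simple-slope sign patterns track a generating cross-level interaction", {
  set.seed(73)
  hits <- replicate(20, {
    cfg <- synthetic_config(
      spec = as_model_spec(sbp_r ~ tertile * cognition),
      beta = c(5, -0.5, -10, 0.45), n_subjects = 150, var_subject = 20,
      var_resid = 40, seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    fit <- fit_reml(cfg$spec, sim$table)
    ss <- simple_slopes(fit, "tertile", "cognition")
    # truth at cognition mean -0.03, sd 0.90: slopes -0.5+0.45*(-0.93|0.87)
    all(sign(ss$slope) == sign(-0.5 + 0.45 * (-0.03 + c(-1, 1) * 0.90)))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("remlmm methods print, summarize, and predict coherently", {
  cfg <- synthetic_config(spec = as_model_spec(sbp_r ~ tertile),
                          beta = c(4, -0.3), seed = 83)
  sim <- simulate_dataset(cfg)
  fit <- fit_reml(sbp_r ~ tertile, sim$table)
  expect_output(print(fit), "REML")
  s <- summary(fit)
  expect_output(print(s), "Signif")
  expect_identical(s$coefficients$parameter, names(fit$beta))
  expect_equal(fitted(fit) + residuals(fit), fit$design$y)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_equal(unname(predict(fit, data.frame(tertile = 0))),
               unname(fit$beta[1]))
  expect_identical(p_stars(c(0.2, 0.04, 0.004, 4e-4)),
                   c("", "*", "**", "***"))
})
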