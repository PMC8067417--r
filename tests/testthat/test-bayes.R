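test_that("subset enumeration respects marginality and always_include", {
  # free main effects: all 2^k subsets
  expect_length(enumerate_models(c("a", "b", "c")), 8L)
  # brute-force cross-check on assorted term sets
  sets <- list(
    c("a", "b", "a:b"),
    c("a", "b", "c", "a:b", "a:c"),
    model1_terms(),
    model4_terms())
  for (tm in sets)
    expect_length(enumerate_models(tm), brute_force_subsets(tm))
  # every returned subset is closed under marginality
  for (mods in enumerate_models(c("a", "b", "c", "a:b", "a:b:c", "b:c",
                                  "a:c"))) {
    for (t1 in mods) {
      f <- strsplit(t1, ":")[[1]]
      if (length(f) < 2) next
      for (m in 1:(2^length(f) - 2)) {
        sub <- f[bitwAnd(m, bitwShiftL(1L, seq_along(f) - 1L)) > 0L]
        expect_true(any(vapply(mods, function(t2)
          setequal(strsplit(t2, ":")[[1]], sub), logical(1))))
      }
    }
  }
  # forced terms
  mods <- enumerate_models(c("a", "b", "a:b"), always_include = "a")
  expect_true(all(vapply(mods, function(m) "a" %in% m, logical(1))))
  expect_length(mods, 3L)   # {a}, {a,b}, {a,b,a:b}
  expect_error(enumerate_models(c("a", "b"), always_include = "z"),
               "not among")
})

test_that("term order inside interactions does not affect enumeration", {
  a <- enumerate_models(c("x", "y", "x:y"))
  b <- enumerate_models(c("x", "y", "y:x"))
  expect_length(a, length(b))
  expect_length(a, 5L)
})

test_that("the mixed-model JZS engine reproduces the closed-form t-test Bayes factor", {
  set.seed(19)
  for (n in c(24, 60)) {
    for (d in c(0, 0.8)) {
      x <- rep(c(0, 1), each = n / 2)
      y <- rnorm(n) + d * x
      df <- data.frame(id = seq_len(n), y = y, x = x)
      eng <- jzs_log_marginal(df, "x", response = "y", subject = "id",
                              random_intercept = FALSE)
      nul <- jzs_log_marginal(df, character(), response = "y",
                              subject = "id", candidate_terms = "x",
                              random_intercept = FALSE)
      bf <- exp(eng$log_marginal - nul$log_marginal)
      expect_equal(bf, jzs_t_bf(y, x, 0.5), tolerance = 1e-3)
    }
  }
})

test_that("Bayes factors are invariant to affine changes of covariate units", {
  set.seed(29)
  cfg <- synthetic_config(spec = as_model_spec(sbp_r ~ tertile * cognition),
                          beta = c(4, -0.3, -8, 0.3), n_subjects = 15,
                          obs_per_subject = 8, missingness = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  terms <- c("tertile", "cognition", "tertile:cognition")
  base <- jzs_log_marginal(sim$table, terms, candidate_terms = terms,
                           budget = 3000, seed = 2)
  tab2 <- sim$table
  tab2$cognition <- 3 * tab2$cognition - 7      # affine rescale
  tab2$tertile <- tab2$tertile / 12
  resc <- jzs_log_marginal(tab2, terms, candidate_terms = terms,
                           budget = 3000, seed = 2)
  expect_equal(base$log_marginal, resc$log_marginal, tolerance = 1e-6)
})

test_that("quadrature and importance-sampling paths agree within their error estimates", {
  cfg <- synthetic_config(spec = as_model_spec(sbp_r ~ tertile),
                          beta = c(4, -0.3), n_subjects = 12,
                          obs_per_subject = 8, missingness = 0, seed = 7)
  sim <- simulate_dataset(cfg)
  pre <- fidlmm:::jzs_prepare(sim$table, "sbp_r", "tertile", "subject_id",
                              jzs_scales(), TRUE)
  mp <- fidlmm:::jzs_model_pre(pre, "tertile")
  q <- fidlmm:::jzs_quad_2d(mp)
  is_res <- fidlmm:::jzs_importance(mp, 20000, 3)
  expect_equal(q$log_marginal, is_res$log_marginal,
               tolerance = 3 * (is_res$error + q$error) + 1e-3)
})

test_that("a huge standardized effect yields overwhelming evidence; a null concentrates below zero", {
  set.seed(39)
  x <- rep(c(0, 1), each = 100)
  y <- rnorm(200) + 2 * x
  df <- data.frame(id = 1:200, y = y, x = x)
  eng <- jzs_log_marginal(df, "x", response = "y", subject = "id",
                          random_intercept = FALSE)
  nul <- jzs_log_marginal(df, character(), response = "y", subject = "id",
                          candidate_terms = "x", random_intercept = FALSE)
  expect_gt(eng$log_marginal - nul$log_marginal, log(100))
  # under a generating null the log Bayes factor is mostly negative
  logk <- replicate(15, {
    y0 <- rnorm(200)
    d0 <- data.frame(id = 1:200, y = y0, x = x)
    a <- jzs_log_marginal(d0, "x", response = "y", subject = "id",
                          random_intercept = FALSE)$log_marginal
    b <- jzs_log_marginal(d0, character(), response = "y", subject = "id",
                          candidate_terms = "x",
                          random_intercept = FALSE)$log_marginal
    a - b
  })
  expect_lt(mean(logk), 0)
  expect_gt(mean(logk < 0), 0.7)
})

test_that("all-subsets comparison reports the null at K = 1 and consistent ratios", {
  cfg <- synthetic_config(spec = as_model_spec(sbp_r ~ tertile * cognition),
                          beta = c(4, -0.4, -10, 0.4), n_subjects = 15,
                          obs_per_subject = 10, missingness = 0, seed = 17)
  sim <- simulate_dataset(cfg)
  cmp <- jzs_compare(sim$table, c("tertile", "cognition",
                                  "tertile:cognition"),
                     budget = 1500, seed = 4)
  expect_equal(nrow(cmp), 5L)
  expect_equal(cmp$log_K[cmp$model == "(intercept only)"], 0)
  best <- attr(cmp, "best_index")
  expect_equal(cmp$ratio_to_best,
               exp(cmp$log_K - cmp$log_K[best]), tolerance = 1e-12)
  expect_equal(max(cmp$ratio_to_best), 1)
  expect_output(print(cmp), "candidate models")
  # determinism under the same seed
  cmp2 <- jzs_compare(sim$table, c("tertile", "cognition",
                                   "tertile:cognition"),
                      budget = 1500, seed = 4)
  expect_identical(cmp$log_K, cmp2$log_K)
})

test_that("K-ratio arithmetic and interpretation heuristics", {
  expect_equal(k_ratio(10, 5), 2)
  expect_equal(k_ratio(10, 10 - log(2), log = TRUE), 2, tolerance = 1e-12)
  expect_identical(interpret_k_ratio(20), "strong")
  expect_identical(interpret_k_ratio(12), "substantial")
  expect_identical(interpret_k_ratio(1), "anecdotal")
  expect_identical(interpret_k_ratio(0.05), "strong (for the other model)")
  expect_error(interpret_k_ratio(-1), "positive")
})
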