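#' Configuration for the synthetic repeated-measures generator
#'
#' The defaults reproduce the structure of the motivating study design: 28
#' subjects, 2 waves of 12 tertiles each (up to 24 rows per subject), rows
#' missing completely at random at rate 0.25 (so about 504 of 672 rows are
#' observed), an unconditional truth with between-person variance 125.97 and
#' residual variance 131.22, and person-level covariates drawn with the
#' published between-person moments (baseline SBP 130.92 / 21.31, cognition
#' -0.03 / 0.90, physical challenges -0.04 / 0.67, mental challenges
#' 0.01 / 0.68, log-cortisol 2.35 / 1.47).  Wave-2 covariates are generated
#' mean-reverting from wave 1 with correlation `wave_cor`.
#'
#' @param n_subjects Number of subjects.
#' @param waves Number of waves (1 or 2).
#' @param tertiles_per_wave Tertiles (time index) per wave.
#' @param missingness MCAR row-drop probability in [0, 1).
#' @param obs_per_subject If non-NULL, exactly this many rows are sampled
#'   per subject instead of applying `missingness`.
#' @param spec A [model_spec()] giving the generating fixed-effect
#'   structure; default is the unconditional (intercept-only) model.
#' @param beta Generating coefficients, intercept first, one per design
#'   column of `spec`; default 4.41 (the mean responsivity) for the
#'   unconditional model.
#' @param var_subject,var_resid Generating variance components.
#' @param covariates Named list of `c(mean, sd)` pairs for the person-level
#'   covariates.
#' @param wave_cor Correlation between wave-1 and wave-2 values of the
#'   wave-varying covariates.
#' @param seed Integer seed (mandatory; the generator is fully
#'   reproducible).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_subjects = 28, waves = 2,
                             tertiles_per_wave = 12, missingness = 0.25,
                             obs_per_subject = NULL, spec = NULL,
                             beta = NULL, var_subject = 125.97,
                             var_resid = 131.22,
                             covariates = list(
                               sbp_baseline = c(130.92, 21.31),
                               cognition = c(-0.03, 0.90),
                               physical = c(-0.04, 0.67),
                               mental = c(0.01, 0.68),
                               log_cortisol = c(2.35, 1.47)),
                             wave_cor = 0.7, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (var_subject < 0 || var_resid < 0) stop("variances must be >= 0")
  if (missingness < 0 || missingness >= 1)
    stop("missingness must be in [0, 1)")
  if (is.null(spec)) spec <- model_spec("sbp_r", character())
  p <- length(spec$terms) + 1L
  if (is.null(beta)) {
    if (p != 1L) stop("'beta' must be supplied for a non-trivial spec")
    beta <- 4.41
  }
  if (length(beta) != p)
    stop("beta has length ", length(beta), " but the spec implies ", p)
  structure(list(n_subjects = n_subjects, waves = waves,
                 tertiles_per_wave = tertiles_per_wave,
                 missingness = missingness,
                 obs_per_subject = obs_per_subject,
                 spec = spec, beta = as.numeric(beta),
                 var_subject = var_subject, var_resid = var_resid,
                 covariates = covariates, wave_cor = wave_cor,
                 seed = as.integer(seed)), class = "synthetic_config")
}

#' Simulate a long-format repeated-measures dataset
#'
#' Draws person-level covariates, per-subject random intercepts
#' `u0 ~ N(0, var_subject)` and residuals `~ N(0, var_resid)`, and
#' assembles the response exactly per the two-level model algebra
#' `y = X beta + u0[subject] + e`, where `X` is realized from the
#' generating spec by [build_design()].  With both variances zero the
#' response is exactly `X beta`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `table` (the analysis table) and `truth`
#'   (generating `beta`, `var_subject`, `var_resid`, and `spec`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cv <- config$covariates
  ns <- config$n_subjects
  draw_cov <- function(nm) stats::rnorm(ns, cv[[nm]][1], cv[[nm]][2])
  persons <- data.frame(
    subject_id = sprintf("S%03d", seq_len(ns)),
    sbp_baseline = draw_cov("sbp_baseline"),
    cognition = draw_cov("cognition"),
    stringsAsFactors = FALSE)
  for (nm in c("physical", "mental", "log_cortisol")) {
    w1 <- draw_cov(nm)
    rho <- config$wave_cor
    w2 <- cv[[nm]][1] + rho * (w1 - cv[[nm]][1]) +
      sqrt(1 - rho^2) * cv[[nm]][2] * stats::rnorm(ns)
    persons[[paste0(nm, "_w1")]] <- w1
    persons[[paste0(nm, "_w2")]] <- w2
  }

  grid <- expand.grid(tertile = seq_len(config$tertiles_per_wave),
                      wave = seq_len(config$waves),
                      subject_id = persons$subject_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject_id", "wave", "tertile")]
  grid$level <- ceiling(grid$tertile / 3)
  tab <- merge(grid, persons, by = "subject_id", sort = FALSE)
  tab <- tab[order(match(tab$subject_id, persons$subject_id),
                   tab$wave, tab$tertile), ]
  rownames(tab) <- NULL

  keep <- rep(TRUE, nrow(tab))
  if (!is.null(config$obs_per_subject)) {
    keep[] <- FALSE
    for (sj in persons$subject_id) {
      idx <- which(tab$subject_id == sj)
      keep[sample(idx, min(config$obs_per_subject, length(idx)))] <- TRUE
    }
  } else if (config$missingness > 0) {
    keep <- stats::runif(nrow(tab)) >= config$missingness
    for (sj in persons$subject_id) {     # every subject keeps >= 1 row
      idx <- which(tab$subject_id == sj)
      if (!any(keep[idx])) keep[idx[1L]] <- TRUE
    }
  }
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL

  tab[[config$spec$response]] <- 0
  des <- build_design(tab, config$spec)
  mu <- drop(des$X %*% config$beta)
  u0 <- stats::rnorm(ns, 0, sqrt(config$var_subject))
  e <- stats::rnorm(nrow(tab), 0, sqrt(config$var_resid))
  tab[[config$spec$response]] <-
    mu + u0[match(tab$subject_id, persons$subject_id)] + e
  list(table = tab,
       truth = list(beta = stats::setNames(config$beta, colnames(des$X)),
                    var_subject = config$var_subject,
                    var_resid = config$var_resid, spec = config$spec))
}

#' Simulate 1 Hz SBP traces with a configurable engagement profile
#'
#' Generates, per subject and wave, a rest window followed by four task
#' levels whose within-level mean SBP follows `baseline + profile[tertile]`
#' (the engagement curve, one value per tertile) plus Gaussian sampling
#' noise.  Exercises the preprocessing pipeline end-to-end: with zero noise
#' and a flat profile the recovered SBP-R values are identically zero.
#'
#' @param n_subjects,waves Design size.
#' @param profile Length-12 engagement curve (mmHg above baseline per
#'   tertile).  The default declines linearly, matching a mild
#'   disengagement trend.
#' @param rest_duration Rest window length in seconds (>= 300 for a proper
#'   baseline).
#' @param level_durations Length-4 vector of level durations in seconds.
#' @param baseline_mean,baseline_sd Person-level baseline SBP distribution.
#' @param noise_sd Per-second sampling noise (mmHg).
#' @param seed Integer seed.
#' @return A list with `traces` (list of [sbp_trace()]) and `truth`
#'   (the profile and per-trace baselines).
#' @export
simulate_trace <- function(n_subjects = 4, waves = 2,
                           profile = 6.2 - 0.33 * (0:11),
                           rest_duration = 600,
                           level_durations = c(120, 140, 160, 180),
                           baseline_mean = 130.92, baseline_sd = 21.31,
                           noise_sd = 5, seed = 1) {
  stopifnot(length(profile) == 12, all(level_durations >= 3))
  set.seed(as.integer(seed))
  traces <- list()
  baselines <- list()
  for (sj in seq_len(n_subjects)) {
    for (wv in seq_len(waves)) {
      bl <- stats::rnorm(1, baseline_mean, baseline_sd)
      t0 <- 0
      segs <- data.frame(segment = c("rest", paste0("level", 1:4)),
                         start_s = NA_real_, end_s = NA_real_)
      times <- numeric(0); vals <- numeric(0)
      durs <- c(rest_duration, level_durations)
      means_by_sec <- function(seg_i, dur) {
        if (seg_i == 1L) return(rep(bl, dur))
        lv <- seg_i - 1L
        n3 <- dur %/% 3L; rem <- dur %% 3L
        lens <- n3 + (seq_len(3L) <= rem)
        rep(bl + profile[(lv - 1L) * 3L + 1:3], times = lens)
      }
      for (i in seq_along(durs)) {
        dur <- durs[i]
        segs$start_s[i] <- t0; segs$end_s[i] <- t0 + dur
        times <- c(times, seq(t0, t0 + dur - 1))
        vals <- c(vals, means_by_sec(i, dur) +
                          stats::rnorm(dur, 0, noise_sd))
        t0 <- t0 + dur
      }
      key <- sprintf("S%03d_w%d", sj, wv)
      traces[[key]] <- sbp_trace(sprintf("S%03d", sj), wv, times, vals, segs)
      baselines[[key]] <- bl
    }
  }
  list(traces = traces,
       truth = list(profile = profile, baselines = unlist(baselines)))
}

#' Empirical interval coverage under the synthetic truth
#'
#' Repeatedly simulates from a [synthetic_config()], fits the requested
#' engine(s), and records whether each fixed effect's interval covers the
#' generating value.  Individual replication failures are logged and
#' excluded; their count is reported.
#'
#' @param config A [synthetic_config()] (its seed anchors the whole study;
#'   replication r uses `seed + r`).
#' @param n_reps Number of replications (>= 2; the formal calibration runs
#'   use hundreds).
#' @param level Nominal interval level.
#' @param engine `"fiducial"` or `"reml"`.
#' @param chains,warmup,keep Sampler settings for the fiducial engine.
#' @return A data frame with one row per fixed effect: `parameter`,
#'   `coverage`, `mc_se` (binomial Monte-Carlo SE), `n_reps_used`; the
#'   failure count is in `attr(, "n_failed")`.
#' @export
coverage_study <- function(config, n_reps = 300, level = 0.95,
                           engine = c("fiducial", "reml"),
                           chains = 2, warmup = 400, keep = 500) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "synthetic_config"), n_reps >= 2)
  p <- length(config$beta)
  hits <- matrix(NA, n_reps, p)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- config$seed + r
      sim <- simulate_dataset(cfg)
      if (engine == "fiducial") {
        fit <- fidlmm(cfg$spec, sim$table, chains = chains, warmup = warmup,
                      keep = keep, seed = cfg$seed, level = level)
        ci <- confint(fit, level = level)[seq_len(p), , drop = FALSE]
      } else {
        fit <- fit_reml(cfg$spec, sim$table)
        ci <- confint(fit, level = level)
      }
      truth <- sim$truth$beta
      as.logical(ci[, 1] <= truth & truth <= ci[, 2])
    }, error = function(e) {
      message("coverage_study: replication ", r, " failed: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else hits[r, ] <- res
  }
  ok <- stats::complete.cases(hits)
  cov <- colMeans(hits[ok, , drop = FALSE])
  n_ok <- sum(ok)
  out <- data.frame(
    parameter = names(config$beta) %||%
      c("(Intercept)", config$spec$terms),
    coverage = cov,
    mc_se = sqrt(cov * (1 - cov) / n_ok),
    n_reps_used = n_ok,
    stringsAsFactors = FALSE)
  attr(out, "n_failed") <- n_failed
  out
}
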