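#' Construct a continuous systolic blood-pressure trace
#'
#' A trace holds the 1 Hz SBP samples of one subject at one wave together
#' with the task markers: the rest window used for the baseline and the
#' start/end of the four task levels.  Timestamps are 0-based seconds and
#' marker intervals are half-open, `[start_s, end_s)`.
#'
#' @param subject_id Subject identifier.
#' @param wave Wave index (1 or 2).
#' @param time Numeric vector of sample times (seconds).
#' @param sbp Numeric vector of SBP values (mmHg), same length as `time`.
#' @param markers Data frame with columns `segment` (one of `"rest"`,
#'   `"level1"` ... `"level4"`), `start_s`, `end_s`.
#' @return A list of class `"sbp_trace"`.
#' @export
sbp_trace <- function(subject_id, wave, time, sbp, markers) {
  stopifnot(length(time) == length(sbp), is.data.frame(markers),
            all(c("segment", "start_s", "end_s") %in% names(markers)))
  mk <- markers[order(markers$start_s), , drop = FALSE]
  if (any(mk$end_s <= mk$start_s))
    stop("marker intervals must have end_s > start_s")
  if (nrow(mk) > 1L && any(mk$start_s[-1L] < mk$end_s[-nrow(mk)]))
    stop("marker intervals overlap")
  structure(list(subject_id = subject_id, wave = wave,
                 time = as.numeric(time), sbp = as.numeric(sbp),
                 markers = mk), class = "sbp_trace")
}

#' @export
print.sbp_trace <- function(x, ...) {
  cat("SBP trace: subject", x$subject_id, "wave", x$wave, "-",
      length(x$time), "samples,", nrow(x$markers), "marked segments\n")
  invisible(x)
}

trace_segment <- function(trace, segment) {
  row <- trace$markers[trace$markers$segment == segment, , drop = FALSE]
  if (nrow(row) != 1L) stop("segment '", segment, "' not marked exactly once")
  sel <- trace$time >= row$start_s & trace$time < row$end_s
  list(time = trace$time[sel], sbp = trace$sbp[sel],
       start = row$start_s, end = row$end_s)
}

#' Baseline SBP from the rest window
#'
#' The mean SBP over the final 5 minutes (300 s) of the marked rest window.
#' A rest window shorter than 300 s is used in full, with a warning.
#'
#' @param trace An [sbp_trace()].
#' @return The baseline SBP in mmHg.
#' @export
baseline_sbp <- function(trace) {
  seg <- trace_segment(trace, "rest")
  dur <- seg$end - seg$start
  if (dur < 300) {
    warning("rest window is ", dur, " s (< 300 s); using the full window")
    return(mean(seg$sbp))
  }
  mean(seg$sbp[seg$time >= seg$end - 300])
}

#' Per-tertile mean SBP across the four task levels
#'
#' Each level's samples are split into three contiguous spans of as near as
#' possible equal length (leftover seconds go to the earlier spans, so span
#' lengths differ by at most one) and averaged, giving 12 values ordered
#' level 1 tertiles 1-3 through level 4 tertiles 10-12.  The spans tile the
#' level exactly: no sample is dropped or double-counted.
#'
#' @param trace An [sbp_trace()] with all four levels marked.
#' @return A numeric vector of 12 tertile means.
#' @export
tertile_means <- function(trace) {
  out <- numeric(12)
  for (lv in 1:4) {
    seg <- trace_segment(trace, paste0("level", lv))
    n <- length(seg$sbp)
    if (n < 3L) stop("level ", lv, " has ", n, " samples (< 3)")
    base <- n %/% 3L; rem <- n %% 3L
    lens <- base + (seq_len(3L) <= rem)     # remainder to earliest spans
    idx_end <- cumsum(lens)
    idx_start <- c(1L, idx_end[-3L] + 1L)
    for (tt in 1:3)
      out[(lv - 1L) * 3L + tt] <- mean(seg$sbp[idx_start[tt]:idx_end[tt]])
  }
  out
}

#' Convert tertile means to responsivity scores
#'
#' SBP responsivity (SBP-R) is task SBP minus the resting baseline:
#' `tertile_means - baseline`, elementwise.
#'
#' @param tertile_means Numeric vector of per-tertile mean SBP.
#' @param baseline Baseline SBP.
#' @return SBP-R values, same length as `tertile_means`.
#' @export
to_sbp_r <- function(tertile_means, baseline) {
  stopifnot(all(is.finite(tertile_means)), is.finite(baseline))
  tertile_means - baseline
}

#' Log-transform hair cortisol concentrations
#'
#' Natural log by default (a `base` switch is provided).  Non-positive
#' concentrations become missing values; their count is reported in a
#' message.
#'
#' @param hcc Numeric vector of concentrations (pg/mg).
#' @param base Logarithm base (default `exp(1)`).
#' @return The transformed vector, with `NA` where `hcc <= 0`.
#' @export
log_cortisol <- function(hcc, base = exp(1)) {
  bad <- !is.na(hcc) & hcc <= 0
  if (any(bad))
    message("log_cortisol: ", sum(bad),
            " non-positive value(s) set to missing")
  out <- rep(NA_real_, length(hcc))
  pos <- !is.na(hcc) & hcc > 0
  out[pos] <- log(hcc[pos], base = base)
  out
}

#' Person-level composite from standardized indicators
#'
#' A transparent substitute for latent factor scoring: each indicator is
#' z-scored across persons, oriented by its declared sign, averaged, and the
#' average re-centered to mean 0.  Zero-variance indicators are excluded
#' with a warning.
#'
#' @param indicators Data frame or matrix, one row per person, one column
#'   per indicator.
#' @param signs Numeric vector of +1/-1 orientations, one per indicator
#'   (default all +1).
#' @return A numeric composite, one value per person (mean 0; SD at most 1).
#' @export
composite_score <- function(indicators, signs = rep(1, ncol(indicators))) {
  indicators <- as.data.frame(indicators)
  if (ncol(indicators) < 2L) stop("need >= 2 indicators")
  stopifnot(length(signs) == ncol(indicators), all(signs %in% c(-1, 1)))
  zs <- list()
  for (j in seq_len(ncol(indicators))) {
    v <- as.numeric(indicators[[j]])
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("indicator '", names(indicators)[j],
              "' has zero variance; excluded")
      next
    }
    zs[[length(zs) + 1L]] <- signs[j] * (v - mean(v, na.rm = TRUE)) / s
  }
  if (length(zs) < 2L) stop("fewer than 2 usable indicators")
  comp <- rowMeans(do.call(cbind, zs), na.rm = TRUE)
  comp - mean(comp, na.rm = TRUE)
}

#' Read SBP traces from delimited text
#'
#' The samples file has columns `subject`, `wave`, `time_s`, `sbp`; the
#' marker file has `subject`, `wave`, `segment`, `start_s`, `end_s`.
#'
#' @param samples_path,markers_path CSV file paths.
#' @return A list of [sbp_trace()] objects, one per subject x wave.
#' @export
read_sbp_traces <- function(samples_path, markers_path) {
  smp <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  mks <- utils::read.csv(markers_path, stringsAsFactors = FALSE)
  for (cl in c("subject", "wave", "time_s", "sbp"))
    if (!cl %in% names(smp)) stop("samples file lacks column '", cl, "'")
  for (cl in c("subject", "wave", "segment", "start_s", "end_s"))
    if (!cl %in% names(mks)) stop("marker file lacks column '", cl, "'")
  keys <- unique(smp[c("subject", "wave")])
  lapply(seq_len(nrow(keys)), function(i) {
    sj <- keys$subject[i]; wv <- keys$wave[i]
    s <- smp[smp$subject == sj & smp$wave == wv, ]
    m <- mks[mks$subject == sj & mks$wave == wv,
             c("segment", "start_s", "end_s")]
    sbp_trace(sj, wv, s$time_s, s$sbp, m)
  })
}

#' Preprocess traces into a long-format analysis table
#'
#' Runs the full preparation pipeline — baseline from the rest window,
#' per-tertile averaging, subtraction into SBP-R — for every trace and
#' stacks the results into the long-format table used by the model fitters,
#' optionally joining person-level covariates.
#'
#' @param traces A list of [sbp_trace()] objects.
#' @param persons Optional data frame of person-level covariates with a
#'   `subject_id` column.
#' @return A data frame with columns `subject_id`, `wave`, `tertile`,
#'   `level`, `sbp_r`, `sbp_baseline`, plus any person covariates.
#' @export
prep_analysis_table <- function(traces, persons = NULL) {
  rows <- lapply(traces, function(tr) {
    bl <- baseline_sbp(tr)
    tm <- tertile_means(tr)
    data.frame(subject_id = tr$subject_id, wave = tr$wave,
               tertile = 1:12, level = rep(1:4, each = 3),
               sbp_r = to_sbp_r(tm, bl), sbp_baseline = bl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(persons)) {
    if (!"subject_id" %in% names(persons))
      stop("persons table needs a 'subject_id' column")
    out <- merge(out, persons, by = "subject_id", all.x = TRUE, sort = FALSE)
    out <- out[order(out$subject_id, out$wave, out$tertile), ]
    rownames(out) <- NULL
  }
  out
}
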