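## Preprocessing: high-pass filtering and detrending, hemodynamic shift,
## voxel selection by t statistic, trial-window extraction, trial averaging,
## and per-run normalization. The fixed pipeline order is
## detrend/high-pass -> shift -> rank voxels -> extract -> average ->
## z-score -> mean-pattern subtraction.

#' Temporal high-pass filter and linear detrend
#'
#' Per voxel: the linear trend (intercept + slope over volume index) is
#' removed by least squares, then discrete-Fourier components at
#' `1 .. cycles_cutoff` cycles per run are projected out. The mean is zero
#' afterwards (removed with the trend).
#'
#' @param ts A `run_timeseries`.
#' @param cycles_cutoff Highest drift frequency removed, in cycles/run
#'   (default 3).
#' @return A `run_timeseries` of the same size.
#' @export
highpass_detrend <- function(ts, cycles_cutoff = 3) {
  stopifnot(inherits(ts, "run_timeseries"))
  abort_if(cycles_cutoff < 1, "cycles_cutoff must be >= 1")
  x <- ts$data
  n <- nrow(x)
  t_idx <- seq_len(n)
  basis <- cbind(1, t_idx)
  for (f in seq_len(cycles_cutoff)) {
    basis <- cbind(basis,
                   sin(2 * pi * f * (t_idx - 1) / n),
                   cos(2 * pi * f * (t_idx - 1) / n))
  }
  # project out the drift basis in one least-squares pass for all voxels
  fit <- stats::lm.fit(basis, x)
  ts$data <- x - basis %*% fit$coefficients
  ts
}

#' Shift a time series to compensate the hemodynamic delay
#'
#' Output volume `t` equals input volume `t + delay_volumes`; trailing
#' volumes are dropped. Event onsets are left untouched, so after the shift
#' a trial's evoked response is aligned with its onset.
#'
#' @param ts A `run_timeseries`.
#' @param delay_volumes Non-negative shift (default 3, i.e. 4.5 s at
#'   tr = 1.5 s).
#' @return A `run_timeseries` with `n - delay_volumes` volumes.
#' @export
shift_timeseries <- function(ts, delay_volumes = 3) {
  stopifnot(inherits(ts, "run_timeseries"))
  n <- nrow(ts$data)
  abort_if(delay_volumes < 0 || delay_volumes >= n,
           "delay_volumes must be in [0, n_volumes)")
  if (delay_volumes > 0)
    ts$data <- ts$data[(delay_volumes + 1):n, , drop = FALSE]
  ts
}

## Volume indices (1-based) covered by each trial window after the shift:
## `response_width` volumes starting at round(onset / tr).
trial_volumes <- function(events, tr, response_width, n_vol) {
  v0 <- round(events$onset / tr) + 1
  v1 <- v0 + response_width - 1
  abort_if(any(v1 > n_vol),
           "trial window exceeds the run (%d volumes); was the series shifted?",
           n_vol)
  cbind(v0, v1)
}

#' Rank voxels by their response to stimulation versus fixation
#'
#' Pools trial-window volumes across runs and computes, per voxel, the
#' two-sample pooled-variance t statistic between stimulus-trial volumes and
#' fixation-trial volumes. Voxels with `t > 0` are retained, ordered by
#' descending t (ties broken by ascending voxel index), truncated to the
#' `k` most active (or all available if fewer). Selection uses the
#' stimulus-vs-fixation contrast only, so it is independent of the near/far
#' classification labels.
#'
#' @param runs List of shifted `run_timeseries`.
#' @param events List of matching `event_table`s.
#' @param k Maximum number of voxels to keep (default 300).
#' @param response_width Volumes per trial window (default 2).
#' @return A `voxel_ranking`: list with `t_values` (all voxels) and
#'   `retained` (ordered indices).
#' @export
rank_voxels <- function(runs, events, k = 300, response_width = 2) {
  stopifnot(length(runs) == length(events), length(runs) >= 1)
  stim <- list(); fix <- list()
  for (r in seq_along(runs)) {
    x <- runs[[r]]$data
    win <- trial_volumes(events[[r]], runs[[r]]$tr, response_width, nrow(x))
    is_fix <- is.na(parse_conditions(events[[r]]$trial_type)$sign)
    for (i in seq_len(nrow(events[[r]]))) {
      rows <- x[win[i, 1]:win[i, 2], , drop = FALSE]
      if (is_fix[i]) fix[[length(fix) + 1]] <- rows
      else stim[[length(stim) + 1]] <- rows
    }
  }
  abort_if(length(fix) == 0, "no fixation trials: cannot form the baseline contrast")
  abort_if(length(stim) == 0, "no stimulus trials")
  A <- do.call(rbind, stim); B <- do.call(rbind, fix)
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  t_vals <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  pos <- which(t_vals > 0)
  ord <- pos[order(-t_vals[pos], pos)]
  structure(list(t_values = t_vals, retained = utils::head(ord, k)),
            class = "voxel_ranking")
}

#' Extract per-trial voxel patterns
#'
#' Averages the `response_width` volumes of each trial window (after the
#' hemodynamic shift) into one pattern per trial. Fixation trials and the
#' dummy are excluded from the labeled patterns.
#'
#' @param ts A shifted `run_timeseries`.
#' @param events The matching `event_table`.
#' @param voxels Optional voxel indices to retain (e.g. from [rank_voxels]).
#' @param response_width Volumes per trial (default 2).
#' @return List with `patterns` (trial x voxel), `level`, `sign` (+1/-1),
#'   `run_id`, `trial_index`.
#' @export
extract_trial_patterns <- function(ts, events, voxels = NULL,
                                   response_width = 2) {
  stopifnot(inherits(ts, "run_timeseries"))
  x <- ts$data
  if (!is.null(voxels)) x <- x[, voxels, drop = FALSE]
  win <- trial_volumes(events, ts$tr, response_width, nrow(x))
  info <- parse_conditions(events$trial_type)
  keep <- which(!is.na(info$sign) & events$dummy == 0)
  pat <- t(vapply(keep,
                  function(i) colMeans(x[win[i, 1]:win[i, 2], , drop = FALSE]),
                  numeric(ncol(x))))
  list(patterns = pat, level = info$level[keep], sign = info$sign[keep],
       run_id = rep(ts$run_id, length(keep)), trial_index = keep)
}

#' Average trials into classifier patterns
#'
#' Within each run x condition (level x sign), trials in presentation order
#' are averaged in consecutive groups — by default sizes (4, 4, 3), turning
#' 11 noisy single-trial patterns into 3 steadier ones per condition per run.
#'
#' @param raw Output of [extract_trial_patterns] (or several `rbind`-style
#'   concatenated via [combine_raw_patterns]).
#' @param grouping Integer group sizes; must sum to the per-condition trial
#'   count in every run.
#' @return A `pattern_set`: list with `patterns` (pattern x voxel), `level`,
#'   `sign`, `run_id`, `voxel_index`.
#' @export
average_trials <- function(raw, grouping = c(4, 4, 3)) {
  key <- interaction(raw$run_id, raw$level, raw$sign, drop = TRUE)
  out <- list(); lev <- c(); sgn <- c(); rid <- c()
  for (g in levels(key)) {
    idx <- which(key == g)
    abort_if(length(idx) != sum(grouping),
             "run %s, level %s, sign %s has %d trials but grouping sums to %d",
             raw$run_id[idx[1]], raw$level[idx[1]], raw$sign[idx[1]],
             length(idx), sum(grouping))
    ends <- cumsum(grouping); starts <- c(1, utils::head(ends, -1) + 1)
    for (j in seq_along(grouping)) {
      rows <- idx[starts[j]:ends[j]]
      out[[length(out) + 1]] <- colMeans(raw$patterns[rows, , drop = FALSE])
      lev <- c(lev, raw$level[idx[1]])
      sgn <- c(sgn, raw$sign[idx[1]])
      rid <- c(rid, raw$run_id[idx[1]])
    }
  }
  structure(list(patterns = do.call(rbind, out), level = lev, sign = sgn,
                 run_id = rid, voxel_index = raw$voxel_index %||%
                   seq_len(ncol(raw$patterns))),
            class = "pattern_set")
}

#' Combine raw per-run pattern lists
#'
#' @param ... Outputs of [extract_trial_patterns].
#' @return A single raw pattern list.
#' @export
combine_raw_patterns <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.null(parts[[1]]$patterns)) parts <- parts[[1]]
  list(patterns = do.call(rbind, lapply(parts, `[[`, "patterns")),
       level = unlist(lapply(parts, `[[`, "level")),
       sign = unlist(lapply(parts, `[[`, "sign")),
       run_id = unlist(lapply(parts, `[[`, "run_id")),
       trial_index = unlist(lapply(parts, `[[`, "trial_index")))
}

#' Normalize a pattern set
#'
#' Per run, per voxel: subtract the mean and divide by the standard
#' deviation across that run's patterns (z-score; zero-variance voxels are
#' set to zero and flagged). Then each pattern has its cross-voxel mean
#' subtracted, removing the univariate signal so that classification rests
#' on the multivariate pattern.
#'
#' @param ps A `pattern_set`.
#' @return A `pattern_set` with attribute `zero_variance_voxels` (per-run
#'   list of flagged voxel positions, possibly empty).
#' @export
normalize_patterns <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  x <- ps$patterns
  flagged <- list()
  for (r in unique(ps$run_id)) {
    rows <- which(ps$run_id == r)
    abort_if(length(rows) < 2, "run %s has < 2 patterns; cannot z-score", r)
    m <- colMeans(x[rows, , drop = FALSE])
    s <- apply(x[rows, , drop = FALSE], 2, stats::sd)
    z <- which(s == 0)
    s[z] <- 1
    x[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, m), 2, s, "/")
    if (length(z)) x[rows, z] <- 0
    flagged[[as.character(r)]] <- z
  }
  x <- x - rowMeans(x)
  ps$patterns <- x
  attr(ps, "zero_variance_voxels") <- flagged
  ps
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d patterns x %d voxels, %d runs, levels: %s\n",
              nrow(x$patterns), ncol(x$patterns), length(unique(x$run_id)),
              paste(sort(unique(x$level)), collapse = ", ")))
  invisible(x)
}

#' Full preprocessing pipeline for a set of runs
#'
#' Applies, in order: high-pass filter + detrend, hemodynamic shift, voxel
#' ranking (pooled across runs, stimulus vs fixation), trial-window
#' extraction, trial averaging, and normalization (z-score then mean-pattern
#' subtraction). The z-scoring stage is applied to averaged patterns by
#' default; `zscore_stage = "timeseries"` instead z-scores the raw shifted
#' series per run before extraction (the two differ only by grouping
#' weights).
#'
#' @param runs List of `run_timeseries`.
#' @param events List of `event_table`s.
#' @param n_voxels_keep Top-t voxel count (default 300).
#' @param delay_volumes Hemodynamic shift (default 3).
#' @param cycles_cutoff High-pass cutoff in cycles/run (default 3).
#' @param grouping Trial-averaging group sizes (default `c(4, 4, 3)`).
#' @param response_width Volumes per trial window (default 2).
#' @param zscore_stage `"patterns"` (default) or `"timeseries"`.
#' @return A normalized `pattern_set` with attribute `ranking`.
#' @export
preprocess_runs <- function(runs, events, n_voxels_keep = 300,
                            delay_volumes = 3, cycles_cutoff = 3,
                            grouping = c(4, 4, 3), response_width = 2,
                            zscore_stage = c("patterns", "timeseries")) {
  zscore_stage <- match.arg(zscore_stage)
  stopifnot(length(runs) == length(events))
  shifted <- lapply(runs, function(ts)
    shift_timeseries(highpass_detrend(ts, cycles_cutoff), delay_volumes))
  ranking <- rank_voxels(shifted, events, k = n_voxels_keep,
                         response_width = response_width)
  if (zscore_stage == "timeseries") {
    shifted <- lapply(shifted, function(ts) {
      s <- apply(ts$data, 2, stats::sd)
      s[s == 0] <- 1
      ts$data <- sweep(sweep(ts$data, 2, colMeans(ts$data)), 2, s, "/")
      ts
    })
  }
  raw <- combine_raw_patterns(lapply(seq_along(shifted), function(r)
    extract_trial_patterns(shifted[[r]], events[[r]], voxels = ranking$retained,
                           response_width = response_width)))
  raw$voxel_index <- ranking$retained
  ps <- average_trials(raw, grouping = grouping)
  if (zscore_stage == "patterns") {
    ps <- normalize_patterns(ps)
  } else {
    ps$patterns <- ps$patterns - rowMeans(ps$patterns)
  }
  attr(ps, "ranking") <- ranking
  ps
}

#' Serialize a pattern set as delimited text
#'
#' One row per pattern: `run`, `level`, `sign`, then voxel values.
#'
#' @param ps A `pattern_set`.
#' @param path Output TSV path.
#' @export
write_pattern_set <- function(ps, path) {
  df <- data.frame(run = ps$run_id, level = ps$level, sign = ps$sign)
  utils::write.table(cbind(df, as.data.frame(ps$patterns)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(patterns = unname(as.matrix(df[, -(1:3)])),
                 level = df$level, sign = df$sign, run_id = df$run,
                 voxel_index = seq_len(ncol(df) - 3)),
            class = "pattern_set")
}
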