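## Synthetic ROI voxel time series and behavioral responses with the
## statistical structure the decoding pipeline assumes: disparity-selective
## voxels whose near/far response difference scales with signal level, a
## fixed hemodynamic delay, slow drift, and i.i.d. Gaussian noise.

#' Configuration for a simulated ROI
#'
#' Voxels carry a selectivity `s_v` between -1 and 1 (preference for near vs
#' far).
#' A non-fixation trial at signal level `L` with depth sign `d` (+1 near,
#' -1 far) adds `amplitude_max * g(L) * d * s_v` to `response_width`
#' consecutive volumes starting `delay_volumes` after `onset / tr`. The
#' coupling `g` maps level to `[0, 1]` (default `level / 100`, i.e. a linear
#' map for a percent-signal task). Hemodynamics are a delayed boxcar on
#' purpose: the pipeline only shifts and averages volumes, so a boxcar keeps
#' index arithmetic exact.
#'
#' @param n_voxels Number of voxels.
#' @param amplitude_max Peak condition response, response units.
#' @param coupling Function mapping signal level to `[0, 1]`, `g(0) = 0`.
#' @param noise_sd SD of i.i.d. Gaussian noise, response units.
#' @param baseline Constant baseline level.
#' @param drift_lin Linear drift over the whole run (units end-to-start).
#' @param drift_sin_amp,drift_sin_cycles Amplitude and cycles/run of a slow
#'   sinusoidal drift (default 1.5 cycles, below a 3 cycles/run high-pass
#'   cutoff).
#' @param delay_volumes Hemodynamic delay in volumes (default 3).
#' @param response_width Volumes per trial carrying signal (default 2).
#' @param selectivity `"uniform"` (s_v drawn uniformly between -1 and 1),
#'   `"bimodal"`
#'   (s_v = +/-1 with jitter), or a numeric vector of length `n_voxels`.
#' @return An `roi_sim_config` list.
#' @export
roi_sim_config <- function(n_voxels = 300, amplitude_max = 1,
                           coupling = function(level) level / 100,
                           noise_sd = 1, baseline = 100,
                           drift_lin = 0, drift_sin_amp = 0,
                           drift_sin_cycles = 1.5,
                           delay_volumes = 3, response_width = 2,
                           selectivity = "uniform") {
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  abort_if(delay_volumes < 0, "delay_volumes must be >= 0")
  abort_if(response_width < 1, "response_width must be >= 1")
  structure(list(n_voxels = as.integer(n_voxels),
                 amplitude_max = amplitude_max, coupling = coupling,
                 noise_sd = noise_sd, baseline = baseline,
                 drift_lin = drift_lin, drift_sin_amp = drift_sin_amp,
                 drift_sin_cycles = drift_sin_cycles,
                 delay_volumes = as.integer(delay_volumes),
                 response_width = as.integer(response_width),
                 selectivity = selectivity),
            class = "roi_sim_config")
}

#' Coupling proportional to a psychometric function
#'
#' Returns `g(level) = (psi(level) - psi(0)) / (psi(L_max) - psi(0))`, a
#' monotone map to `[0, 1]` whose shape matches the observer's psychometric
#' curve — the generative regime under which decoding accuracy is expected
#' to track behavior.
#'
#' @param pf A `psychometric_function`.
#' @param max_level Level at which the coupling reaches 1.
#' @return A function of `level`.
#' @export
coupling_from_psychometric <- function(pf, max_level) {
  p0 <- if (pf$axis == "log") pf$guess else predict(pf, 0)
  p1 <- predict(pf, max_level)
  abort_if(p1 <= p0, "psychometric function must increase over [0, max_level]")
  function(level) {
    p <- ifelse(level <= 0 & pf$axis == "log", p0, predict(pf, pmax(level, 1e-12)))
    pmin(pmax((p - p0) / (p1 - p0), 0), 1)
  }
}

## Draw per-voxel selectivities under a derived seed.
draw_selectivity <- function(cfg, seed) {
  if (is.numeric(cfg$selectivity)) {
    abort_if(length(cfg$selectivity) != cfg$n_voxels,
             "numeric selectivity must have length n_voxels")
    return(cfg$selectivity)
  }
  with_seed(seed, switch(cfg$selectivity,
    uniform = stats::runif(cfg$n_voxels, -1, 1),
    bimodal = sample(c(-1, 1), cfg$n_voxels, replace = TRUE) *
      stats::runif(cfg$n_voxels, 0.7, 1),
    stop("unknown selectivity model: ", cfg$selectivity)
  ))
}

## Parse condition labels of the form "near_40" / "far_40" / "fixation".
## Returns data.frame(sign, level): sign +1 near, -1 far, NA fixation.
parse_conditions <- function(trial_type) {
  sign <- ifelse(startsWith(trial_type, "near"), 1,
                 ifelse(startsWith(trial_type, "far"), -1, NA_real_))
  level <- suppressWarnings(as.numeric(sub("^[a-z]+_", "", trial_type)))
  level[is.na(sign)] <- NA_real_
  data.frame(sign = sign, level = level)
}

#' Condition labels for a graded near/far design
#'
#' @param levels Signal magnitudes.
#' @return Character vector: `"fixation"`, then `near_<level>` and
#'   `far_<level>` per level.
#' @export
condition_labels <- function(levels) {
  c("fixation", as.vector(t(outer(c("near", "far"), levels, paste, sep = "_"))))
}

#' Simulate one ROI run
#'
#' Builds `baseline + drift + trial increments + noise` per the
#' [roi_sim_config] generative model. Fixation trials (and anything labeled
#' `"fixation"`) add nothing. The dummy trial, if present, still evokes a
#' response (it is a real stimulus in the scanner); downstream code excludes
#' it by label.
#'
#' @param cfg An `roi_sim_config`.
#' @param events An `event_table` whose `trial_type` labels parse as
#'   `near_<level>` / `far_<level>` / `fixation`.
#' @param tr Repetition time in seconds.
#' @param seed Integer seed; selectivity and noise use derived sub-streams.
#' @param run_duration Run length in seconds; defaults to the event table's
#'   `total_duration` attribute.
#' @param roi_name Label stored with the run.
#' @return A `run_timeseries`: list with `data` (volumes x voxels), `tr`,
#'   `run_id`, `roi_name`, `selectivity`.
#' @export
simulate_roi_run <- function(cfg, events, tr, seed,
                             run_duration = attr(events, "total_duration"),
                             roi_name = "ROI") {
  stopifnot(inherits(cfg, "roi_sim_config"))
  abort_if(tr <= 0, "tr must be positive")
  abort_if(is.null(run_duration), "run_duration must be supplied")
  n_vol <- round(run_duration / tr)
  abort_if(abs(n_vol * tr - run_duration) > 1e-8,
           "run_duration (%s s) is not an integer number of volumes at tr = %s",
           run_duration, tr)

  sel <- draw_selectivity(cfg, derive_seed(seed, 1))
  v_idx <- seq_len(n_vol)
  drift <- cfg$drift_lin * (v_idx - 1) / max(n_vol - 1, 1) +
    cfg$drift_sin_amp * sin(2 * pi * cfg$drift_sin_cycles * (v_idx - 1) / n_vol)
  x <- matrix(cfg$baseline + drift, n_vol, cfg$n_voxels)

  info <- parse_conditions(events$trial_type)
  for (i in seq_len(nrow(events))) {
    if (is.na(info$sign[i])) next # fixation: no increment
    v0 <- round(events$onset[i] / tr) + cfg$delay_volumes + 1 # 1-based
    v1 <- v0 + cfg$response_width - 1
    abort_if(v1 > n_vol,
             "trial %d (onset %.1f s) extends past the run end after the hemodynamic delay",
             i, events$onset[i])
    amp <- cfg$amplitude_max * cfg$coupling(info$level[i]) * info$sign[i]
    x[v0:v1, ] <- x[v0:v1, ] + rep(amp * sel, each = v1 - v0 + 1)
  }
  if (cfg$noise_sd > 0) {
    x <- x + with_seed(derive_seed(seed, 2),
                       matrix(stats::rnorm(n_vol * cfg$n_voxels, 0, cfg$noise_sd),
                              n_vol, cfg$n_voxels))
  }
  structure(list(data = x, tr = tr, run_id = attr(events, "run_id") %||% 1L,
                 roi_name = roi_name, selectivity = sel),
            class = "run_timeseries")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_timeseries <- function(x, ...) {
  cat(sprintf("run_timeseries: %d volumes x %d voxels, tr = %g s, run %d (%s)\n",
              nrow(x$data), ncol(x$data), x$tr, x$run_id, x$roi_name))
  invisible(x)
}

#' Simulate a whole session: runs, events, and behavioral responses
#'
#' Generates `n_runs` history-balanced runs (fresh order per run from derived
#' seeds), simulates the ROI time series for each, and draws per-trial
#' correctness from the observer's psychometric function. The design has
#' `2 * length(levels) + 1` conditions (near/far at each level plus
#' fixation); `reps` defaults to the condition count so the one-back
#' transition matrix is exactly uniform.
#'
#' @param cfg An `roi_sim_config` (or named list of configs for several ROIs).
#' @param pf A `psychometric_function` driving simulated responses.
#' @param levels Signal magnitudes.
#' @param n_runs Number of runs (>= 2 for leave-one-run-out).
#' @param reps Repetitions per condition per run.
#' @param tr Repetition time (s).
#' @param seed Master seed.
#' @return List with `runs` (list of `run_timeseries`, or list of lists when
#'   several ROI configs are given), `events` (list of `event_table`s with
#'   added `response` (+1/-1 sign report) and `correct` columns), `levels`,
#'   `pf`.
#' @export
simulate_experiment <- function(cfg, pf, levels = c(0, 20, 40, 60, 100),
                                n_runs = 9, reps = NULL, tr = 1.5, seed = 1L) {
  abort_if(n_runs < 2, "leave-one-run-out needs n_runs >= 2")
  multi <- !inherits(cfg, "roi_sim_config")
  cfgs <- if (multi) cfg else list(ROI = cfg)
  # voxel selectivities are a property of the ROI, not of a run: freeze them
  # once per ROI so every run sees the same voxels
  for (j in seq_along(cfgs)) {
    cfgs[[j]]$selectivity <-
      draw_selectivity(cfgs[[j]], derive_seed(seed, 0, j))
  }
  labs <- condition_labels(levels)
  n_cond <- length(labs)
  if (is.null(reps)) reps <- n_cond

  events <- vector("list", n_runs)
  runs <- lapply(cfgs, function(.) vector("list", n_runs))
  for (r in seq_len(n_runs)) {
    sq <- generate_balanced_sequence(n_cond, reps, seed = derive_seed(seed, r, 1),
                                     labels = labs, run_id = r)
    ev <- assign_timing(sq, seed = derive_seed(seed, r, 2))
    info <- parse_conditions(ev$trial_type)
    p <- ifelse(is.na(info$level), NA_real_,
                predict(pf, pmax(info$level,
                                 if (pf$axis == "log") 1e-12 else -Inf)))
    correct <- with_seed(derive_seed(seed, r, 3),
                         ifelse(is.na(p), NA_integer_,
                                stats::rbinom(nrow(ev), 1, ifelse(is.na(p), 0.5, p))))
    ev$correct <- correct
    ev$response <- ifelse(is.na(correct), NA_real_,
                          ifelse(correct == 1, info$sign, -info$sign))
    events[[r]] <- ev
    for (j in seq_along(cfgs)) {
      runs[[j]][[r]] <- simulate_roi_run(cfgs[[j]], ev, tr,
                                         seed = derive_seed(seed, r, 10 + j),
                                         roi_name = names(cfgs)[j] %||% "ROI")
    }
  }
  list(runs = if (multi) runs else runs[[1]], events = events,
       levels = levels, pf = pf)
}

#' Tabulate behavioral performance from simulated events
#'
#' @param events List of `event_table`s carrying a `correct` column.
#' @return A `behavioral_data` with one row per level (dummy and fixation
#'   trials excluded).
#' @export
behavior_from_events <- function(events) {
  ev <- do.call(rbind, lapply(events, as.data.frame))
  info <- parse_conditions(ev$trial_type)
  keep <- !is.na(info$level) & ev$dummy == 0
  agg <- stats::aggregate(ev$correct[keep],
                          list(level = info$level[keep]),
                          function(z) c(sum(z), length(z)))
  behavioral_data(agg$level, agg$x[, 1], agg$x[, 2])
}

#' Write / read a run time series as delimited text plus JSON sidecar
#'
#' The matrix goes to `<path>` as TSV (volumes x voxels, no headers); the
#' sidecar `<path>.json` records `tr`, `run_id`, `roi_name`.
#'
#' @param run A `run_timeseries`.
#' @param path Output TSV path.
#' @export
write_run_timeseries <- function(run, path) {
  utils::write.table(run$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(tr = run$tr, run_id = run$run_id, roi_name = run$roi_name)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_run_timeseries
#' @export
read_run_timeseries <- function(path) {
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(data = x, tr = meta$tr, run_id = as.integer(meta$run_id),
                 roi_name = meta$roi_name, selectivity = NULL),
            class = "run_timeseries")
}
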