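## Orchestration: analysis configuration, the simulate -> preprocess ->
## decode -> null -> fit pipeline, per-ROI report tables, and a small CLI
## dispatcher.

#' Analysis configuration
#'
#' Bundles the knobs of the full pipeline. Serializes losslessly to JSON
#' (and YAML if the `yaml` package is available); ROI simulation configs are
#' supplied separately to [run_pipeline] because they contain functions.
#'
#' @param task `"signal_in_noise"` (levels in % signal, linear axis) or
#'   `"feature_difference"` (levels in arcsec).
#' @param levels Stimulus magnitudes, ascending.
#' @param n_runs Number of runs (>= 2).
#' @param n_voxels_keep Voxel-selection cap (default 300).
#' @param delay_volumes Hemodynamic shift in volumes (default 3).
#' @param grouping Trial-averaging group sizes (default `c(4, 4, 3)`).
#' @param n_perm Permutation count for the null (default 999).
#' @param alpha One-tailed per-ROI significance level before Bonferroni
#'   (default 0.005).
#' @param n_rois_bonferroni Number of ROIs the criterion is corrected over
#'   (default 12; with `alpha = 0.005` this is folded into the centile via
#'   `criterion_centile`).
#' @param criterion_centile Centile used as the significance criterion
#'   (default 99.5).
#' @param tr Repetition time in seconds (default 1.5).
#' @param seed Master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(task = c("signal_in_noise", "feature_difference"),
                            levels = NULL, n_runs = 9, n_voxels_keep = 300,
                            delay_volumes = 3, grouping = c(4, 4, 3),
                            n_perm = 999, alpha = 0.005,
                            n_rois_bonferroni = 12, criterion_centile = 99.5,
                            tr = 1.5, seed = 1L) {
  task <- match.arg(task)
  if (is.null(levels))
    levels <- if (task == "signal_in_noise") c(0, 20, 40, 60, 100)
              else c(6, 18, 30, 60, 240)
  abort_if(is.unsorted(levels, strictly = TRUE), "levels must be ascending")
  abort_if(n_runs < 2 || n_voxels_keep < 1 || n_perm < 1 || tr <= 0 ||
             any(grouping < 1), "all counts must be positive")
  structure(list(task = task, levels = levels, n_runs = as.integer(n_runs),
                 n_voxels_keep = as.integer(n_voxels_keep),
                 delay_volumes = as.integer(delay_volumes),
                 grouping = as.integer(grouping),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 n_rois_bonferroni = as.integer(n_rois_bonferroni),
                 criterion_centile = criterion_centile,
                 tr = tr, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read / write an analysis config (JSON or YAML)
#'
#' @param cfg An `analysis_config`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @export
write_analysis_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) {
    abort_if(!requireNamespace("yaml", quietly = TRUE),
             "yaml package not available")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    abort_if(!requireNamespace("yaml", quietly = TRUE),
             "yaml package not available")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(analysis_config, x)
}

#' Run the full analysis pipeline on simulated data
#'
#' For each ROI simulation config: simulate a session, preprocess, decode
#' with leave-one-run-out cross-validation trained at the highest level,
#' build the permutation null, apply the significance criterion, fit the
#' free fMR-metric function and the psychophysically scaled model, and
#' compute goodness of fit. Behavioral responses are shared across ROIs
#' (one observer per session) and fitted once.
#'
#' @param cfg An `analysis_config`.
#' @param roi_cfgs Named list of [roi_sim_config] objects.
#' @param pf_observer `psychometric_function` generating behavior (and, via
#'   [coupling_from_psychometric], typically the coupled ROI's signal).
#' @param out_dir Optional directory; when given, all intermediate artifacts
#'   (events TSVs, pattern sets, decoding tables, null distributions, the
#'   report) are written there, each stamped with the config hash.
#' @return A `pipeline_report`: list with `behavior` (fit + data), `rois`
#'   (per-ROI list: decoding result, null summary, significance verdict,
#'   free and scaled fits, gof), `table` (per-ROI summary data.frame),
#'   `config`, `config_hash`, `log`.
#' @export
run_pipeline <- function(cfg, roi_cfgs, pf_observer, out_dir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  abort_if(length(roi_cfgs) < 1 || is.null(names(roi_cfgs)),
           "roi_cfgs must be a named list")
  hash <- config_hash(unclass(cfg))
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log <<- c(log, msg)
  }
  note("pipeline start: task=%s, %d runs, %d ROIs, seed=%d, config=%s",
       cfg$task, cfg$n_runs, length(roi_cfgs), cfg$seed, hash)

  sim <- simulate_experiment(roi_cfgs, pf_observer, levels = cfg$levels,
                             n_runs = cfg$n_runs, tr = cfg$tr, seed = cfg$seed)
  note("simulated %d runs x %d trials", cfg$n_runs, nrow(sim$events[[1]]))

  bd <- behavior_from_events(sim$events)
  # the feature task spans levels multiplicatively (6..240 arcsec) and its
  # threshold recovery is unbiased on a log axis; the signal task includes a
  # 0% level and stays linear
  axis <- if (cfg$task == "feature_difference") "log" else "linear"
  pf_fit <- fit_psychometric(bd, axis = axis)
  note("behavioral fit: mu=%.2f sigma=%.2f, 75%% threshold=%.2f",
       pf_fit$mu, pf_fit$sigma, threshold(pf_fit, 0.75))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_along(sim$events))
      write_events_tsv(sim$events[[r]],
                       file.path(out_dir, sprintf("events_run%02d_%s.tsv", r, hash)))
    jsonlite::write_json(
      list(mu = pf_fit$mu, sigma = pf_fit$sigma, guess = pf_fit$guess,
           lapse = pf_fit$lapse, threshold75 = threshold(pf_fit, 0.75),
           config = hash),
      file.path(out_dir, sprintf("behavior_fit_%s.json", hash)),
      auto_unbox = TRUE, digits = NA)
  }

  rois <- list()
  rows <- list()
  for (nm in names(roi_cfgs)) {
    ps <- preprocess_runs(sim$runs[[nm]], sim$events,
                          n_voxels_keep = cfg$n_voxels_keep,
                          delay_volumes = cfg$delay_volumes,
                          grouping = cfg$grouping)
    res <- run_locv(ps)
    nd <- permutation_null(ps, n_iter = cfg$n_perm,
                           seed = derive_seed(cfg$seed, 777, match(nm, names(roi_cfgs))))
    crit <- significance_criterion(nd, cfg$criterion_centile)
    top_acc <- unname(res$accuracy_by_level[as.character(res$train_level)])
    signif <- top_acc > crit$criterion
    band <- if (cfg$n_perm >= 2) chance_band(nd)
            else rep(nd$accuracies, 2) # degenerate band for smoke runs
    acc <- unname(res$accuracy_by_level)
    free_fit <- fit_fmrmetric(res$levels, acc, band, axis = axis)
    scaled <- scaled_behavioral_fit(pf_fit, res$levels, acc, band,
                                    lower_hint = stats::median(nd$accuracies))
    # a scaled fit driven to its floor predicts a constant: gof undefined
    scaled$gof <- tryCatch(goodness_of_fit(acc, scaled$fitted),
                           error = function(e) list(r = NA_real_, p = NA_real_,
                                                    r_squared = NA_real_,
                                                    df = length(acc) - 2L,
                                                    warning_low_n = length(acc) < 5))
    note("ROI %s: top accuracy %.3f (criterion %.3f, %s), gof r=%.3f p=%.4g",
         nm, top_acc, crit$criterion,
         if (signif) "significant" else "n.s.", scaled$gof$r, scaled$gof$p)
    rois[[nm]] <- list(pattern_set = ps, decoding = res, null = nd,
                       criterion = crit, significant = signif,
                       band = band, free_fit = free_fit, scaled = scaled)
    rows[[nm]] <- data.frame(roi = nm, top_accuracy = top_acc,
                             criterion = crit$criterion, significant = signif,
                             pearson_r = scaled$gof$r, p_value = scaled$gof$p,
                             r_squared = scaled$gof$r_squared)
    if (!is.null(out_dir)) {
      write_decoding_result(res, file.path(out_dir, sprintf("decoding_%s_%s.tsv", nm, hash)))
      write_null_distribution(nd, file.path(out_dir, sprintf("null_%s_%s.tsv", nm, hash)))
      write_pattern_set(ps, file.path(out_dir, sprintf("patterns_%s_%s.tsv", nm, hash)))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    utils::write.table(tab, file.path(out_dir, sprintf("report_%s.tsv", hash)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log, file.path(out_dir, sprintf("log_%s.txt", hash)))
  }
  structure(list(behavior = list(fit = pf_fit, data = bd), rois = rois,
                 table = tab, config = cfg, config_hash = hash, log = log),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (%s, config %s)\n", x$config$task, x$config_hash))
  cat(sprintf("behavioral 75%% threshold: %.2f\n", threshold(x$behavior$fit, 0.75)))
  print(x$table, digits = 3)
  invisible(x)
}

#' Minimal command-line dispatcher
#'
#' Subcommands: `design` (write a balanced events TSV), `simulate` (write a
#' simulated session), `report` (run the full pipeline from a config file).
#' Used by the `inst/cli/fmrmetric` wrapper script.
#'
#' @param args Character vector, e.g.
#'   `c("design", "--conditions", "11", "--reps", "11", "--seed", "1",
#'     "--out", "events.tsv")`.
#' @return Invisibly, the subcommand's main artifact.
#' @export
fmrmetric_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  abort_if(length(args) < 1, "usage: fmrmetric <design|simulate|report> ...")
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  get_opt <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  switch(cmd,
    design = {
      n <- as.integer(get_opt("conditions", 11))
      reps <- as.integer(get_opt("reps", n))
      seed <- as.integer(get_opt("seed", 1))
      out <- get_opt("out", "events.tsv")
      sq <- generate_balanced_sequence(n, reps, seed)
      ev <- assign_timing(sq, seed = derive_seed(seed, 2))
      write_events_tsv(ev, out)
      message(sprintf("wrote %d trials (%g s run) to %s", nrow(ev),
                      attr(ev, "total_duration"), out))
      invisible(out)
    },
    simulate = ,
    report = {
      cfg_path <- get_opt("config")
      abort_if(is.null(cfg_path), "--config is required")
      cfg <- read_analysis_config(cfg_path)
      out <- get_opt("out", "fmrmetric_out")
      pf <- psychometric_function(
        mu = if (cfg$task == "signal_in_noise") 42 else 21,
        sigma = diff(range(cfg$levels)) / 3, guess = 0.5)
      roi_cfgs <- list(
        coupled = roi_sim_config(
          n_voxels = cfg$n_voxels_keep,
          coupling = coupling_from_psychometric(pf, max(cfg$levels)),
          amplitude_max = 0.12, noise_sd = 1,
          delay_volumes = cfg$delay_volumes),
        null = roi_sim_config(n_voxels = cfg$n_voxels_keep,
                              amplitude_max = 0, noise_sd = 1,
                              delay_volumes = cfg$delay_volumes))
      rep <- run_pipeline(cfg, roi_cfgs, pf, out_dir = out)
      print(rep)
      invisible(rep)
    },
    stop("unknown subcommand: ", cmd)
  )
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    abort_if(!startsWith(args[i], "--"), "unexpected argument: %s", args[i])
    key <- sub("^--", "", args[i])
    abort_if(i + 1 > length(args), "missing value for --%s", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
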