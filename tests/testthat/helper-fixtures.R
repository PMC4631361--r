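# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays well inside its budget.

# Standard observer used throughout: 75% threshold at 42 (% signal),
# two-alternative judgment.
fx_observer <- function() psychometric_function(42, 20, guess = 0.5)

# Small simulated session: few voxels/runs, graded coupling, quick.
fx_session <- function(seed = 7, n_runs = 4, n_voxels = 60,
                       amplitude_max = 3, noise_sd = 1,
                       coupling = NULL, pf = fx_observer()) {
  if (is.null(coupling)) coupling <- function(level) level / 100
  cfg <- roi_sim_config(n_voxels = n_voxels, amplitude_max = amplitude_max,
                        noise_sd = noise_sd, coupling = coupling)
  simulate_experiment(cfg, pf, n_runs = n_runs, seed = seed)
}

# A pattern_set of pure-noise Gaussian patterns at a single level: used for
# null-calibration checks where no signal exists by construction.
fx_null_patterns <- function(seed, n_runs = 4, per_class = 3, n_voxels = 20,
                             level = 100) {
  n_pat <- n_runs * per_class * 2
  pats <- withr::with_seed(seed,
    matrix(stats::rnorm(n_pat * n_voxels), n_pat, n_voxels))
  structure(list(
    patterns = pats,
    level = rep(level, n_pat),
    sign = rep(rep(c(-1, 1), each = per_class), n_runs),
    run_id = rep(seq_len(n_runs), each = per_class * 2),
    voxel_index = seq_len(n_voxels)),
    class = "pattern_set")
}

# Hand-rolled pooled-variance two-sample t (textbook formula) for oracles.
oracle_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  (mean(a) - mean(b)) / (sp * sqrt(1 / n1 + 1 / n2))
}

# Primal objective of the linear soft-margin SVM (L1 hinge), for grid oracles.
svm_primal_objective <- function(w, b, x, y, C) {
  margins <- 1 - y * (drop(x %*% w) + b)
  sum(w^2) / 2 + C * sum(pmax(margins, 0))
}
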