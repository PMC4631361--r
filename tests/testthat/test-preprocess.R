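# Preprocessing: filtering, shifting, voxel ranking, extraction, averaging,
# normalization.

make_ts <- function(data, tr = 1.5, run_id = 1L) {
  structure(list(data = as.matrix(data), tr = tr, run_id = run_id,
                 roi_name = "toy", selectivity = NULL),
            class = "run_timeseries")
}

test_that("high-pass filter removes constants, ramps, and slow sinusoids", {
  n <- 64
  ts_const <- make_ts(matrix(5, n, 2))
  expect_true(all(abs(highpass_detrend(ts_const)$data) < 1e-10))

  ts_ramp <- make_ts(cbind(seq_len(n), 3 * seq_len(n) + 2))
  expect_true(all(abs(highpass_detrend(ts_ramp)$data) < 1e-8))

  # sum of 2 and 20 cycles/run: cutoff 3 removes the slow one, keeps the fast
  t0 <- (seq_len(n) - 1) / n
  slow <- sin(2 * pi * 2 * t0); fast <- sin(2 * pi * 20 * t0)
  ts_mix <- make_ts(matrix(slow + fast, ncol = 1))
  out <- highpass_detrend(ts_mix, cycles_cutoff = 3)$data[, 1]
  # Fourier-coefficient oracle: project output onto each component
  pow <- function(x, f) {
    (2 * mean(x * sin(2 * pi * f * t0)))^2 + (2 * mean(x * cos(2 * pi * f * t0)))^2
  }
  expect_lt(pow(out, 2) / pow(slow + fast, 2), 0.01)
  expect_gt(pow(out, 20) / pow(slow + fast, 20), 0.99)
})

test_that("shift drops leading volumes and preserves alignment", {
  x <- matrix(seq_len(256 * 2), 256, 2)
  ts <- make_ts(x)
  expect_equal(shift_timeseries(ts, 0)$data, x)
  sh <- shift_timeseries(ts, 3)
  expect_equal(nrow(sh$data), 253)
  expect_equal(sh$data[1, ], x[4, ]) # row 0 equals former row 3 (0-based)
  expect_error(shift_timeseries(ts, 256), "delay_volumes")
})

test_that("shift + extraction recovers the generator's injected increments", {
  sim <- fx_session(seed = 9, n_runs = 2, n_voxels = 6, amplitude_max = 2,
                    noise_sd = 0)
  sel <- sim$runs[[1]]$selectivity
  sh <- shift_timeseries(sim$runs[[1]], 3)
  raw <- extract_trial_patterns(sh, sim$events[[1]])
  base <- sim$runs[[1]]$data[1, ] # baseline row (constant, no drift)
  for (i in seq_along(raw$level)) {
    inj <- 2 * (raw$level[i] / 100) * raw$sign[i] * sel
    expect_equal(raw$patterns[i, ], base + inj, tolerance = 1e-10)
  }
  # 3 s trials at tr = 1.5 average exactly 2 volumes
  expect_equal(ncol(raw$patterns), 6)
  expect_equal(length(raw$level), 110) # 121 analyzed - 11 fixation
})

test_that("voxel ranking orders by pooled two-sample t and respects k", {
  # toy: 6 volumes, 2 voxels, hand-checkable
  ev <- data.frame(onset = c(0, 3), duration = 3,
                   trial_type = c("near_100", "fixation"),
                   stimulus_duration = 0.3, delay = 1.2,
                   cue_onset = c(1.5, 4.5), cue_offset = c(2.7, 5.7),
                   dummy = 0L, run_id = 1L)
  class(ev) <- c("event_table", "data.frame")
  x <- cbind(c(5, 6, 1, 2, 0, 0), c(1, 1.5, 1.2, 1.1, 0, 0))
  ts <- make_ts(x)
  rk <- rank_voxels(list(ts), list(ev), k = 2)
  for (v in 1:2) {
    expect_equal(unname(rk$t_values[v]),
                 oracle_t(x[1:2, v], x[3:4, v]), tolerance = 1e-12)
  }
  expect_equal(rk$retained[1], 1L) # strongly responsive voxel ranked first

  # k exceeding the positive-t count returns only positive-t voxels
  x2 <- cbind(c(5, 6, 1, 2, 0, 0), c(1, 1.1, 3, 3.2, 0, 0))
  rk2 <- rank_voxels(list(make_ts(x2)), list(ev), k = 10)
  expect_equal(rk2$retained, 1L) # voxel 2 has t < 0
  expect_error(rank_voxels(list(make_ts(x)),
                           list(transform(ev, trial_type = "near_100"))),
               "fixation")
})

test_that("trial averaging groups (4,4,3) in presentation order", {
  # 11 trials valued 1..11 in one voxel
  raw <- list(patterns = matrix(1:11, ncol = 1), level = rep(100, 11),
              sign = rep(1, 11), run_id = rep(1L, 11), trial_index = 1:11)
  ps <- average_trials(raw)
  expect_equal(ps$patterns[, 1], c(2.5, 6.5, 10)) # group means
  expect_equal(ps$level, rep(100, 3))

  # identical patterns average to themselves
  raw2 <- list(patterns = matrix(3, 11, 2), level = rep(20, 11),
               sign = rep(-1, 11), run_id = rep(1L, 11), trial_index = 1:11)
  expect_true(all(average_trials(raw2)$patterns == 3))

  # count mismatch names the offender
  raw3 <- list(patterns = matrix(1:10, ncol = 1), level = rep(100, 10),
               sign = rep(1, 10), run_id = rep(2L, 10), trial_index = 1:10)
  expect_error(average_trials(raw3), "run 2")
})

test_that("an 11-rep run yields 3 patterns per condition per run", {
  sim <- fx_session(seed = 2, n_runs = 2, n_voxels = 5)
  ps <- preprocess_runs(sim$runs, sim$events, n_voxels_keep = 5)
  tab <- table(ps$run_id, ps$level, ps$sign)
  expect_true(all(tab == 3))
  expect_equal(nrow(ps$patterns), 2 * 5 * 2 * 3) # runs x levels x signs x 3
})

test_that("normalization satisfies its defining identities", {
  set.seed(20)
  ps <- fx_null_patterns(seed = 20, n_runs = 3, per_class = 4, n_voxels = 7)
  out <- normalize_patterns(ps)
  for (r in 1:3) {
    rows <- out$patterns[out$run_id == r, ]
    # per-run per-voxel z-scoring happened before mean-pattern subtraction,
    # so column means are zero and rows are mean-centered
    expect_true(all(abs(colMeans(rows)) < 1e-10))
  }
  expect_true(all(abs(rowMeans(out$patterns)) < 1e-10))

  # zero-variance voxel flagged and zeroed
  ps2 <- fx_null_patterns(seed = 21, n_runs = 2)
  ps2$patterns[, 3] <- 5
  out2 <- normalize_patterns(ps2)
  flags <- attr(out2, "zero_variance_voxels")
  expect_true(all(vapply(flags, function(f) 3 %in% f, logical(1))))

  # per-run shift invariance: adding a constant to one run changes nothing
  ps3 <- fx_null_patterns(seed = 22, n_runs = 2)
  ps3b <- ps3
  ps3b$patterns[ps3b$run_id == 1, ] <- ps3b$patterns[ps3b$run_id == 1, ] + 42
  expect_equal(normalize_patterns(ps3)$patterns,
               normalize_patterns(ps3b)$patterns, tolerance = 1e-10)
})

test_that("z-score and mean-subtraction order matters (canary)", {
  ps <- fx_null_patterns(seed = 30, n_runs = 2, per_class = 4, n_voxels = 6)
  out <- normalize_patterns(ps)$patterns
  # reversed order: mean-pattern subtraction first, then z-score
  x <- ps$patterns - rowMeans(ps$patterns)
  for (r in 1:2) {
    rows <- which(ps$run_id == r)
    m <- colMeans(x[rows, ]); s <- apply(x[rows, ], 2, sd)
    x[rows, ] <- sweep(sweep(x[rows, ], 2, m), 2, s, "/")
  }
  expect_gt(max(abs(out - x)), 1e-3)
})

test_that("preprocessing is label-blind", {
  sim <- fx_session(seed = 6, n_runs = 2, n_voxels = 10)
  ps1 <- preprocess_runs(sim$runs, sim$events, n_voxels_keep = 10)
  # shuffle near/far *within* each level: stimulus-vs-fixation ranking and
  # all matrices must be identical; only labels move
  ev2 <- lapply(sim$events, function(ev) {
    swap <- ev$trial_type
    swap <- sub("^near_", "tmp_", swap)
    swap <- sub("^far_", "near_", swap)
    swap <- sub("^tmp_", "far_", swap)
    ev$trial_type <- swap
    ev
  })
  ps2 <- preprocess_runs(sim$runs, ev2, n_voxels_keep = 10)
  # same matrices up to the row permutation induced by the relabeling
  o1 <- order(ps1$run_id, ps1$level, ps1$sign)
  o2 <- order(ps2$run_id, ps2$level, -ps2$sign)
  expect_equal(ps1$patterns[o1, ], ps2$patterns[o2, ], tolerance = 1e-12)
  expect_equal(attr(ps1, "ranking")$retained, attr(ps2, "ranking")$retained)
})

test_that("pattern sets round-trip through TSV", {
  ps <- fx_null_patterns(seed = 40, n_runs = 2, n_voxels = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_set(ps, path)
  back <- read_pattern_set(path)
  expect_equal(back$patterns, ps$patterns, tolerance = 1e-10)
  expect_equal(back$sign, ps$sign)
  expect_equal(back$run_id, ps$run_id)
})
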