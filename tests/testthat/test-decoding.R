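# Linear SVM and leave-one-run-out decoding.

test_that("svm_cost follows its closed form", {
  # N unit-norm patterns, n_folds folds -> C = n_folds / N
  x <- diag(8) # 8 unit-norm rows
  expect_equal(svm_cost(x, 5), 5 / 8)
  # homogeneity: doubling every value divides C by 4
  expect_equal(svm_cost(2 * x, 5), 5 / 32)
  # one pattern (3,4), 1 fold -> 1/25
  expect_equal(svm_cost(matrix(c(3, 4), 1), 1), 1 / 25)
  # alternative reading divides by n_folds instead
  expect_equal(svm_cost(x, 5, divide = TRUE), 1 / 40)
  expect_error(svm_cost(matrix(0, 2, 2), 1), "all-zero")
})

test_that("SVM separates a trivial pair and is symmetric under class swap", {
  x <- matrix(c(-1, 1), 2, 1)
  m <- train_linear_svm(x, c("a", "b"), C = 10)
  expect_equal(predict(m, x), c("a", "b"))
  expect_lt(abs(m$bias), 1e-6) # boundary between the points

  set.seed(1)
  x2 <- rbind(matrix(rnorm(20, -1), 10, 2), matrix(rnorm(20, 1), 10, 2))
  y2 <- rep(c(-1, 1), each = 10)
  m1 <- train_linear_svm(x2, y2, C = 1)
  m2 <- train_linear_svm(x2, -y2, C = 1)
  expect_equal(m1$weights, -m2$weights, tolerance = 1e-6)
  expect_error(train_linear_svm(x2, rep(1, 20), C = 1), "two classes")
})

test_that("4-point 2-D SVM matches a brute-force primal grid oracle", {
  x <- rbind(c(1, 0), c(2, 1), c(-1, 0), c(-2, -1))
  y <- c(1, 1, -1, -1)
  C <- 10
  m <- train_linear_svm(x, y, C)
  # coarse-to-fine grid over (w1, w2, b)
  ctr <- c(0, 0, 0); hw <- 3
  for (stage in 1:5) {
    g1 <- seq(ctr[1] - hw, ctr[1] + hw, length.out = 13)
    g2 <- seq(ctr[2] - hw, ctr[2] + hw, length.out = 13)
    g3 <- seq(ctr[3] - hw, ctr[3] + hw, length.out = 13)
    best <- c(Inf, ctr)
    for (w1 in g1) for (w2 in g2) for (b in g3) {
      obj <- svm_primal_objective(c(w1, w2), b, x, y, C)
      if (obj < best[1]) best <- c(obj, w1, w2, b)
    }
    ctr <- best[2:4]; hw <- hw / 4
  }
  expect_equal(m$weights, ctr[1:2], tolerance = 1e-3)
  expect_equal(m$bias, ctr[3], tolerance = 1e-3)
  # same margin and the same support set (points with positive alpha)
  expect_equal(sort(which(m$alpha > 1e-6)), c(1, 3))
})

test_that("held-out structure of an 11-rep design gives 6 test patterns/level", {
  sim <- fx_session(seed = 3, n_runs = 3, n_voxels = 8)
  ps <- preprocess_runs(sim$runs, sim$events, n_voxels_keep = 8)
  res <- run_locv(ps)
  expect_equal(res$n_test_per_level, 6L) # 3 near + 3 far
  expect_equal(res$n_train, (3 - 1) * 6L)
  expect_equal(res$n_folds, 3L)
  expect_equal(dim(res$per_fold), c(3L, 5L))
  expect_true(all(res$accuracy_by_level >= 0 & res$accuracy_by_level <= 1))
})

test_that("constant test patterns with balanced labels score exactly 0.5", {
  ps <- fx_null_patterns(seed = 1, n_runs = 3, per_class = 3, n_voxels = 5)
  # make run 1's patterns all identical: prediction is constant there
  ps$patterns[ps$run_id == 1, ] <- 1
  res <- run_locv(ps)
  expect_equal(unname(res$per_fold[1, 1]), 0.5)
})

test_that("noiseless separable data decode perfectly at all coupled levels", {
  # The noiseless world is rank-1 (every voxel is a multiple of one time
  # course), so two preprocessing steps are kept out of its path: the t-based
  # ranking would retain only same-sign voxels (whose z-scored patterns are
  # then annihilated by mean-pattern subtraction) and the high-pass filter
  # distorts the common course. Shift -> extract -> average -> normalize
  # preserves exact separability; assert accuracy 1.0 wherever g > 0.
  cfg <- roi_sim_config(n_voxels = 8, amplitude_max = 2, noise_sd = 0,
                        selectivity = c(1, -1, 0.6, -0.6, 0.3, -0.3, 0.9, -0.9))
  sim <- simulate_experiment(cfg, fx_observer(), n_runs = 3, seed = 8)
  sh <- lapply(sim$runs, shift_timeseries, 3)
  raw <- combine_raw_patterns(lapply(1:3, function(r)
    extract_trial_patterns(sh[[r]], sim$events[[r]])))
  ps <- normalize_patterns(average_trials(raw))
  res <- run_locv(ps)
  expect_true(all(res$accuracy_by_level[c("20", "40", "60", "100")] == 1))
})

test_that("fold accuracies depend only on their own data", {
  ps <- fx_null_patterns(seed = 2, n_runs = 3, per_class = 3, n_voxels = 6,
                         level = 100)
  # add a second (test-only) level so we can mutate it
  extra <- fx_null_patterns(seed = 3, n_runs = 3, per_class = 3, n_voxels = 6,
                            level = 20)
  ps$patterns <- rbind(ps$patterns, extra$patterns)
  ps$level <- c(ps$level, extra$level)
  ps$sign <- c(ps$sign, extra$sign)
  ps$run_id <- c(ps$run_id, extra$run_id)
  r1 <- run_locv(ps, train_level = 100)
  # mutate run 3's level-20 (test-only) patterns: folds 1 and 2 at level 100
  # and every other run's rows are untouched
  ps2 <- ps
  ps2$patterns[ps2$run_id == 3 & ps2$level == 20, ] <- 99
  r2 <- run_locv(ps2, train_level = 100)
  expect_equal(r1$per_fold[1:2, ], r2$per_fold[1:2, ])
  expect_equal(r1$per_fold[, "100"], r2$per_fold[, "100"])
})

test_that("consistent near/far relabeling leaves accuracies unchanged", {
  sim <- fx_session(seed = 12, n_runs = 3, n_voxels = 10)
  ps <- preprocess_runs(sim$runs, sim$events, n_voxels_keep = 10)
  ps_flip <- ps
  ps_flip$sign <- -ps$sign
  expect_equal(run_locv(ps)$accuracy_by_level,
               run_locv(ps_flip)$accuracy_by_level)
})

test_that("mean accuracy is non-decreasing in level on coupled data", {
  # trend over a seed battery; Monte-Carlo error tolerated via the mean
  accs <- sapply(1:10, function(seed) {
    sim <- fx_session(seed = seed, n_runs = 3, n_voxels = 20,
                      amplitude_max = 1.2, noise_sd = 1)
    ps <- preprocess_runs(sim$runs, sim$events, n_voxels_keep = 20)
    unname(run_locv(ps)$accuracy_by_level)
  })
  m <- rowMeans(accs)
  expect_true(all(diff(m) > -0.05))
  expect_gt(m[5], m[1] + 0.2)
})

test_that("missing training level in a run is rejected", {
  ps <- fx_null_patterns(seed = 4, n_runs = 2)
  ps$level[ps$run_id == 2] <- 60
  expect_error(run_locv(ps, train_level = 100), "no patterns at the training level")
})

test_that("decoding results serialize with metadata", {
  sim <- fx_session(seed = 3, n_runs = 2, n_voxels = 5)
  ps <- preprocess_runs(sim$runs, sim$events, n_voxels_keep = 5)
  res <- run_locv(ps)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decoding_result(res, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$mean_accuracy, unname(res$accuracy_by_level))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$n_folds, 2)
  expect_equal(meta$cost_rule, "n_folds/sum_sq")
})
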