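test_that("all writers round-trip exactly", {
  dir <- withr::local_tempdir()
  ras <- spike_raster(c(1.2, 3.4, 3.4), c("A", "B1", "B2"), c(3L, 1L, 2L),
                      duration = 10)
  p1 <- file.path(dir, "r.tsv")
  write_raster(ras, p1)
  expect_equal(read_raster(p1), ras, ignore_attr = "row.names")
  expect_equal(attr(read_raster(p1), "duration"), 10)

  pat <- synth_formant_patterns(n_classes = 2, n_channels = 12,
                                n_bins = 6, seed = 2)[[1]]
  p2 <- file.path(dir, "p.txt")
  write_pattern(pat, p2)
  expect_equal(read_pattern(p2), pat)

  m <- matrix(rnorm(20), 4)
  p3 <- file.path(dir, "m.tsv")
  write_matrix(m, p3)
  expect_equal(read_matrix(p3), m, tolerance = 1e-12)

  tab <- data.frame(class = c("a", "b"), rep = 1:2, count = c(3L, 9L),
                    sigma = 0.15, rate_percent = 100)
  p4 <- file.path(dir, "t.tsv")
  write_response_table(tab, p4)
  expect_equal(read_response_table(p4), tab)
})

test_that("fixtures have their documented structure", {
  td <- make_fixture("two-dot")
  expect_equal(sum(td$grid), 2)
  expect_equal(sort(which(td$grid == 1, arr.ind = TRUE)[, 1]), c(5, 9))

  ds <- make_fixture("double-sweep")
  # two rising trajectories: channel-of-activity range grows over time
  ridge_hi <- apply(ds$grid, 2, function(col) max(which(col == 1)))
  expect_true(all(diff(ridge_hi) >= 0))

  ct <- make_fixture("chirp-train")
  per <- attr(ct, "period")
  len <- attr(ct, "chirp_len")
  for (ci in 0:4) {
    cols <- ci * per + seq_len(len)
    chans <- apply(ct$grid[, cols], 2, which.max)
    expect_true(all(diff(chans) < 0))   # strictly descending chirps
  }

  fs <- make_fixture("formant-set", seed = 9)
  expect_length(fs, 21)
  expect_identical(make_fixture("formant-set", seed = 9), fs)
  expect_error(make_fixture("bogus"))

  dir <- withr::local_tempdir()
  paths <- write_fixture("two-dot", dir)
  expect_true(file.exists(paths))
  expect_equal(read_pattern(paths)$grid, td$grid)
})

test_that("experiment configuration round-trips through YAML", {
  cfg <- experiment_config(master_seed = 7,
                           network = list(n_channels = 12, fan_out = 4),
                           stimulus = list(n_classes = 3, jitter = 0.5),
                           trial = list(sigma_grid = c(0, 0.45),
                                        n_probe_reps = 2))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  cfg2 <- read_experiment_config(path)
  expect_equal(cfg2, cfg)
  expect_error(experiment_config(stimulus = list(family = "x")), "family")
})

test_that("a minimal experiment runs end to end and reproduces bit-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- experiment_config(
    master_seed = 3,
    network = list(n_channels = 16, fan_out = 5),
    stimulus = list(n_classes = 2, exposure_class = "class1"),
    trial = list(n_exposure_reps = 3, n_probe_reps = 2,
                 sigma_grid = c(0, 0.45), rate_grid = 100))
  res1 <- run_experiment(cfg, out_dir = dir1)
  expect_length(res1$tables, 2)
  expect_equal(nrow(res1$auc), 2)
  expect_equal(sort(unique(res1$ssi$class)), c("class1", "class2"))
  expect_true(file.exists(file.path(dir1, "manifest.yaml")))
  # every artifact reproduces bit-identically from the same configuration
  res2 <- run_experiment(cfg, out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)), label = f)
  }
  # sigma-grid emits one response table per level
  expect_named(res1$tables, c("sigma0.00_rate100", "sigma0.45_rate100"))
})

test_that("rate-grid configurations emit one table per rate", {
  cfg <- experiment_config(
    master_seed = 5,
    network = list(n_channels = 16, fan_out = 5),
    stimulus = list(n_classes = 2),
    trial = list(n_exposure_reps = 2, n_probe_reps = 1, sigma_grid = 0,
                 rate_grid = c(60, 100, 150, 200)))
  res <- run_experiment(cfg)
  expect_named(res$tables, paste0("sigma0.00_rate", c(60, 100, 150, 200)))
})
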