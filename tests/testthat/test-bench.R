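test_that("benchmark tallies are exact ratios of per-realization decisions", {
  cfg <- bench_config(measure = "pcmi", n_realizations = 3, n_surrogates = 8,
                      cmi_params = cmi_params(tau = 5, m = 3, eta = 5),
                      rossler = rossler_config(n_transient = 500,
                                               n_samples = 400),
                      seed = 5)
  res <- run_benchmark(cfg)
  expect_equal(nrow(res$results), 1L)
  d <- res$decisions
  expect_equal(res$results$tpr, mean(d$x1_to_x2))
  expect_equal(res$results$fpr, mean(d$x2_to_x1))
  expect_equal(res$results$n_ok, 3L)
  expect_true(all(c("sim_seed", "proto_seed") %in% names(d)))
})

test_that("identical configurations reproduce identical result tables", {
  cfg <- bench_config(measure = "cmi1", n_realizations = 2, n_surrogates = 5,
                      cmi_params = cmi_params(tau = 5, Q = 4),
                      rossler = rossler_config(n_transient = 500,
                                               n_samples = 300),
                      seed = 9)
  r1 <- run_benchmark(cfg)
  r2 <- run_benchmark(cfg)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$decisions, r2$decisions)
})

test_that("a failing condition is recorded, not dropped", {
  # series far too short for the window geometry -> every realization fails
  cfg <- bench_config(measure = "pccc", n_realizations = 2, n_surrogates = 5,
                      ccc_params = ccc_params(L = 200, w = 100, delta = 20),
                      m = 3, eta_x = 5, eta_y = 5,
                      rossler = rossler_config(n_transient = 100,
                                               n_samples = 120),
                      seed = 3)
  res <- run_benchmark(cfg)
  expect_equal(res$results$n_failed, 2L)
  expect_true(all(!is.na(res$decisions$error)))
  expect_equal(res$results$tpr, 0)
})

test_that("benchmark artifacts round-trip through the output directory", {
  out <- file.path(tempdir(), "bench-out")
  cfg <- bench_config(measure = "cmi1", n_realizations = 2, n_surrogates = 5,
                      cmi_params = cmi_params(tau = 3, Q = 4),
                      rossler = rossler_config(n_transient = 200,
                                               n_samples = 300),
                      seed = 21)
  res <- run_benchmark(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "decisions.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  back <- read.csv(file.path(out, "results.csv"))
  expect_equal(back$tpr, res$results$tpr)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$config$seed, 21)
  unlink(out, recursive = TRUE)
})

test_that("CSV series reading handles headers, time columns and missing cells", {
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("value", "1.5", "2.5", "NA", "4.0"), p1)
  expect_warning(v <- read_series_csv(p1), "missing")
  expect_equal(v, c(1.5, 2.5, 4.0))

  p2 <- tempfile(fileext = ".csv")
  writeLines(c("t,x", "0,1.0", "1,2.0", "2,3.0"), p2)
  expect_equal(read_series_csv(p2), c(1, 2, 3))

  p3 <- tempfile(fileext = ".csv")
  writeLines(c("0.1", "0.2", "0.3"), p3)
  expect_equal(read_series_csv(p3), c(0.1, 0.2, 0.3))

  p4 <- tempfile(fileext = ".csv")
  writeLines(c("x", "a", "b"), p4)
  expect_error(read_series_csv(p4), "non-numeric")
  expect_error(read_series_csv("/nonexistent/file.csv"), "cannot read")
  file.remove(p1, p2, p3, p4)
})

test_that("pair analysis reproduces the in-memory pipeline from CSV files", {
  sim <- simulate_coupled_rossler(
    rossler_config(n_transient = 500, n_samples = 600, seed = 33))
  fx <- tempfile(fileext = ".csv"); fy <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = sim$x1), fx, row.names = FALSE)
  write.csv(data.frame(x = sim$x2), fy, row.names = FALSE)

  p <- ccc_params(L = 25, w = 15, delta = 20)
  rep1 <- run_pair_analysis(fx, fy, measure = "pccc", n_surr = 6,
                            surrogate_method = "aaft",
                            ccc_params = p, m = 3, eta_x = 5, eta_y = 5,
                            seed = 17)
  direct <- causality_significance(sim$x1, sim$x2, measure = "pccc",
                                   n_surr = 6, surrogate_method = "aaft",
                                   ccc_params = p, m = 3, eta_x = 5,
                                   eta_y = 5, seed = 17)
  expect_equal(rep1$value[1], direct$x_to_y$signed_original)
  expect_equal(rep1$z_score[2], direct$y_to_x$z_score)
  expect_identical(rep1$significant[1], direct$x_to_y$significant)

  # two copies of the same file with scalar CCC: statistic 0 both ways
  rep0 <- run_pair_analysis(fx, fx, measure = "ccc", n_surr = 6,
                            surrogate_method = "aaft",
                            ccc_params = ccc_params(25, 15, 20, B = 8),
                            seed = 19)
  expect_equal(rep0$value, c(0, 0))
  file.remove(fx, fy)
})

test_that("shipped presets cover the benchmark and real-data protocols", {
  pr <- benchmark_presets()
  expect_true("rossler" %in% names(pr))
  expect_equal(pr$rossler$ccc$L, 300L)
  expect_equal(pr$rossler$pccc$L, 25L)
  expect_equal(pr$rossler$pccc$delta, 20L)
  expect_equal(pr$rossler$cmi$tau, 20L)
  expect_equal(pr$rossler$eta_x, 5)
  expect_equal(pr$`monthly-nino-monsoon`$cmi$tau, 1:30)
  for (p in pr) expect_s3_class(p$pccc, "ccc_params")
})
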