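test_that("seed schedule is deterministic, valid, and counter-based", {
  s1 <- derive_seed(1, 1, 1)
  expect_identical(s1, derive_seed(1, 1, 1))
  expect_false(derive_seed(1, 1, 2) == s1)
  expect_false(derive_seed(1, 2, 1) == s1)
  expect_false(derive_seed(2, 1, 1) == s1)
  ss <- vapply(1:200, function(k) derive_seed(7, k, 3), integer(1))
  expect_true(all(ss >= 1 & ss <= 2147483646))
  expect_false(any(duplicated(ss)))
})

test_that("paired ensembles are reproducible and correctly shaped", {
  cfg <- experiment_config(
    landscape_params(5, "rmf", c = 1, lambda = 1),
    dynamics_params(150, 0.02, 1),
    t_max = 60, n_runs = 8, master_seed = 42)
  pe1 <- paired_ensemble(cfg)
  pe2 <- paired_ensemble(cfg)
  expect_identical(pe1$delta, pe2$delta)
  expect_identical(pe1$seeds, pe2$seeds)
  expect_identical(nrow(pe1$delta), 61L)
  expect_true(all(pe1$delta$n_pairs == 8))
  expect_s3_class(pe1, "paired_ensemble")
  expect_named(pe1$summary, c("t_max", "delta_max", "t_zero"))
})

test_that("null pairing (r = 0 vs r = 0) fluctuates around zero", {
  cfg <- experiment_config(
    landscape_params(6, "rmf", c = 1, lambda = 1),
    dynamics_params(300, 0.02, 0),   # both arms non-recombining
    t_max = 120, n_runs = 40, master_seed = 7)
  pe <- paired_ensemble(cfg)
  d <- pe$delta
  late <- d$t >= 20
  # exchangeable arms: delta_F consistent with zero at 3 SE, P_plus near 1/2
  expect_true(all(abs(d$delta_F[late]) <= 3 * d$se_delta_F[late] + 1e-12))
  expect_lt(abs(mean(d$P_plus[late]) - 0.5), 0.15)
})

test_that("sweeps share the landscape seed schedule across values", {
  cfg <- experiment_config(
    landscape_params(5, "rmf", c = 1, lambda = 1),
    dynamics_params(100, 0.02, 1),
    t_max = 30, n_runs = 5, master_seed = 11,
    sweep = list(param = "r", values = c(0.2, 1)))
  res <- sweep_ensemble(cfg)
  expect_named(res, c("0.2", "1"))
  expect_identical(res[["0.2"]]$seeds[, "landscape"],
                   res[["1"]]$seeds[, "landscape"])
  expect_identical(res[["0.2"]]$config$dynamics$r, 0.2)
  # swept lambda propagates to the landscape
  cfg2 <- experiment_config(
    landscape_params(5, "rmf", c = 1, lambda = 1),
    dynamics_params(100, 0.02, 1),
    t_max = 10, n_runs = 2, master_seed = 11,
    sweep = list(param = "lambda", values = c(0.5, 2)))
  res2 <- sweep_ensemble(cfg2)
  expect_equal(res2[["2"]]$config$landscape$lambda, 2)
  expect_error(experiment_config(
    landscape_params(5, "rmf"), dynamics_params(100, 0.02, 1),
    10, 2, 1, sweep = list(param = "banana", values = 1)),
    "unrecognized sweep parameter")
})

test_that("fixtures carry correct hand-computed properties", {
  fx <- make_fixture("two_locus_valley")
  expect_identical(local_maxima(fx$landscape), fx$expected$local_maxima)
  expect_equal(entropy(fx$expected$p_example), fx$expected$entropy)
  expect_equal(as.numeric(additive_variance(fx$expected$p_example,
                                            fx$landscape)),
               fx$expected$additive_variance)
  fa <- make_fixture("additive_L3")
  expect_identical(local_maxima(fa$landscape), fa$expected$local_maxima)
  expect_equal(fa$landscape$F[8], 3)
  expect_equal(entropy(fa$expected$p_example), 3 * log(2))
  f2 <- make_fixture("two_peak_L3")
  expect_identical(local_maxima(f2$landscape), f2$expected$local_maxima)
  # fixtures survive serialization
  path <- tempfile(fileext = ".tsv")
  write_landscape(f2$landscape, path)
  expect_identical(read_landscape(path)$F, f2$landscape$F)
  expect_error(make_fixture("unknown"))
})

test_that("trajectory and ensemble TSV outputs carry config headers", {
  land <- generate_landscape(landscape_params(4, "rmf", c = 1, lambda = 1,
                                              seed = 81))
  tr <- run_finite(land, dynamics_params(100, 0.02, 0.5, seed = 82), 10)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "# "))
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  expect_equal(hdr$dynamics$N, 100)
  expect_equal(hdr$engine, "finite")
  body <- read.table(path, sep = "\t", header = FALSE, skip = 2)
  expect_identical(nrow(body), 11L)

  cfg <- experiment_config(landscape_params(4, "rmf", c = 1, lambda = 1),
                           dynamics_params(80, 0.02, 1),
                           t_max = 15, n_runs = 3, master_seed = 5)
  pe <- paired_ensemble(cfg)
  path2 <- tempfile(fileext = ".tsv")
  write_ensemble(pe, path2)
  l2 <- readLines(path2)
  expect_true(startsWith(l2[1], "# "))
  expect_identical(length(l2), 2L + 16L)

  ev <- data.frame(run = 1L, genotype = 3L, t_start = 5L, t_end = 9L,
                   distance_from_start = 2L)
  path3 <- tempfile(fileext = ".tsv")
  write_events(ev, 4, path3)
  got <- read.table(path3, header = TRUE, sep = "\t",
                    colClasses = c(genotype_bits = "character"))
  expect_identical(got$genotype_bits, "1100")
})

test_that("command-line interface: subcommands, outputs, validation", {
  out <- tempfile()
  capture.output(status <- cli_main(c("paired", "--model", "rmf", "--L", "5", "--c", "1",
                       "--lambda", "1", "--N", "100", "--mu", "0.02",
                       "--r", "1", "--t-max", "20", "--runs", "3",
                       "--seed", "7", "--out", out)))
  expect_identical(status, 0L)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".json")))
  # missing required flag
  expect_identical(suppressMessages(cli_main(c("landscape", "--model", "rmf"))),
                   1L)
  # unknown subcommand
  expect_identical(suppressMessages(cli_main("frobnicate")), 1L)
  # landscape generation writes a readable file
  lout <- tempfile(fileext = ".tsv")
  capture.output(st_l <- cli_main(c("landscape", "--L", "4", "--model", "hoc",
                                    "--lambda", "2", "--seed", "3",
                                    "--out", lout)))
  expect_identical(st_l, 0L)
  expect_identical(length(read_landscape(lout)$F), 16L)
  # infinite engine with high precision honors the L cap
  expect_identical(suppressMessages(
    cli_main(c("run", "--engine", "infinite", "--L", "13",
               "--precision-digits", "35", "--t-max", "2"))), 1L)
  capture.output(st <- cli_main(c("run", "--engine", "infinite", "--L", "4",
                                  "--precision-digits", "35", "--mu", "0.05",
                                  "--r", "0.5", "--t-max", "3",
                                  "--seed", "2")))
  expect_identical(st, 0L)
  # config file overrides flags
  cfgfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(L = 3, runs = 2), cfgfile, auto_unbox = TRUE)
  out2 <- tempfile()
  capture.output(st_c <- cli_main(c("paired", "--L", "9", "--t-max", "5",
                                    "--N", "50", "--config", cfgfile,
                                    "--out", out2)))
  expect_identical(st_c, 0L)
  hdr <- jsonlite::fromJSON(sub("^# ", "", readLines(out2)[1]))
  expect_equal(hdr$landscape$L, 3)
})
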