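test_that("missing configuration keys take the documented defaults", {
  cfg <- growthssd:::resolve_config(list(m = 5, seed = 1))
  expect_equal(cfg$eta, 0.8)
  expect_equal(cfg$BFthres, 3)
  expect_equal(cfg$eff.size, 0.8)
  expect_equal(cfg$t.points, c(0, 1, 2, 3, 4))
  expect_equal(cfg$var.u0, 0.03)
  expect_equal(cfg$var.u1, 0.1)
  expect_equal(cfg$var.e, 0.02)
  expect_equal(cfg$cov, 0)
  expect_equal(cfg$fraction, 1)
  expect_false(cfg$sensitivity)
  expect_identical(cfg$hyp, "both")
  expect_identical(cfg$test, "alt")
  expect_equal(cfg$m, 5)
})

test_that("hypothesis and test tokens accept both spellings and reject others", {
  expect_identical(growthssd:::normalize_hyp("b"), "both")
  expect_identical(growthssd:::normalize_hyp("h1"), "H1")
  expect_identical(growthssd:::normalize_hyp("H0"), "H0")
  expect_identical(growthssd:::normalize_test("hc"), "Hc")
  expect_identical(growthssd:::normalize_test("Hu"), "Hu")
  expect_error(growthssd:::normalize_hyp("hboth"), "valid values",
               class = "growthssd_config")
  expect_error(growthssd:::normalize_test("null"), "valid values",
               class = "growthssd_config")
  expect_error(growthssd:::resolve_config(list(bfthresh = 3)),
               "unknown configuration", class = "growthssd_config")
})

test_that("a YAML config round-trips through a run and its JSON report", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("eff.size: 1.5", "var.u1: 0.0030", "var.e: 0.0262",
               "var.u0: 0.0333", "m: 30", "eta: 0.5", "seed: 7",
               "Nmin: 8", "Nmax: 64"), path)
  rep1 <- suppressWarnings(run_ssd(path))
  expect_s3_class(rep1, "run_report")
  out <- tempfile(fileext = ".json")
  write_report(rep1, out)
  parsed <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_identical(parsed$mode, "ssd")
  expect_equal(parsed$config$m, 30)
  expect_true(all(c("per_fraction", "trace") %in% names(parsed$result)))
  # the echoed configuration reproduces the identical run
  rep2 <- suppressWarnings(run_ssd(parsed$config[
    setdiff(names(parsed$config), c("Nmin", "Nmax"))],
    n_min = parsed$config$Nmin, n_max = parsed$config$Nmax))
  expect_identical(rep1$result$per_b, rep2$result$per_b)
  unlink(c(path, out))
})

test_that("warnings raised during a run are carried into the report", {
  rep <- suppressWarnings(run_ssd(list(
    eff.size = 1.5, var.u1 = 0.003, var.e = 0.0262, var.u0 = 0.0333,
    m = 20, eta = 0.05, seed = 1, Nmin = 8, Nmax = 40)))
  expect_true(any(grepl("already met", rep$warnings)))
})

test_that("the log-linear example config enforces the log-shift policy", {
  path <- system.file("extdata", "example2.yaml", package = "growthssd")
  cfg <- read_config(path)
  expect_true(cfg$log)
  bad <- cfg; bad$log.shift <- 0; bad$m <- 4
  expect_error(suppressWarnings(run_ssd(bad, direction = "negative")),
               "time 0")
  cfg$m <- 10; cfg$eta <- 0.1; cfg$BFthres <- 2
  rep <- suppressWarnings(run_ssd(cfg, direction = "negative",
                                  n_min = 6, n_max = 60))
  expect_true(all(is.na(rep$result$per_b$eta0)))
  expect_false(any(is.na(rep$result$per_b$eta1)))
})

test_that("power mode reports at a fixed sample size", {
  rep <- run_power(list(eff.size = 0.8, var.u1 = 0.003, var.e = 0.0262,
                        var.u0 = 0.0333, m = 15, seed = 2), n_subjects = 24)
  expect_s3_class(rep$result, "bayes_power")
  payload <- growthssd:::report_payload(rep)
  expect_equal(payload$result$n_subjects, 24)
})

test_that("the command-line wrapper runs and signals config errors", {
  script <- system.file("cli", "growthssd.R", package = "growthssd")
  skip_if(script == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- tempfile(fileext = ".json")
  res <- suppressWarnings(system2(
    rscript, c(script, "--mode", "power", "--n", "16", "--m", "10",
               "--eff-size", "0.8", "--var-u1", "0.003",
               "--var-e", "0.0262", "--var-u0", "0.0333",
               "--seed", "3", "--out", out),
    stdout = TRUE, stderr = TRUE))
  expect_identical(attr(res, "status"), NULL)
  expect_true(file.exists(out))
  parsed <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_identical(parsed$mode, "power")
  unlink(out)

  bad <- suppressWarnings(system2(
    rscript, c(script, "--mode", "power", "--n", "16", "--hyp", "nope"),
    stdout = TRUE, stderr = TRUE))
  expect_identical(attr(bad, "status"), 2L)
})
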