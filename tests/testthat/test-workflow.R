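# cli_report: analysis configs, end-to-end workflows, CLI dispatch.

write_toy_psa <- function(n = 3000, seed = 19, sds = c(1, 0.5),
                          means = rep(0, length(sds))) {
  psa <- linear_gaussian_toy(means, sds, n_draws = n, seed = seed)
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write_psa_csv(psa, f)
  f
}

test_that("analysis_config demands exactly one PSA source", {
  expect_error(analysis_config(), "exactly one")
  expect_error(analysis_config(psa_path = "x.csv", simulator = TRUE),
               "exactly one")
  expect_error(analysis_config(psa_path = "x.csv"), "k is required")
  cfg <- analysis_config(simulator = TRUE, n_draws = 5, seed = 3)
  expect_s3_class(cfg, "analysis_config")
  expect_identical(cfg$seed, 3L)
})

test_that("analysis config round-trips through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(psa_path = "psa.csv", k = 13000,
                            incident_population = 24799, seed = 7,
                            tol = "auto"),
                       f, auto_unbox = TRUE)
  cfg <- read_analysis_config(f)
  expect_equal(cfg$k, 13000)
  expect_identical(cfg$seed, 7L)
  jsonlite::write_json(list(psa_path = "x", k = 1, bogus = 2), f,
                       auto_unbox = TRUE)
  expect_error(read_analysis_config(f), "bogus")
})

test_that("update workflow runs end to end and is deterministic", {
  f <- write_toy_psa()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- function(d) analysis_config(psa_path = f, k = 13000, seed = 5,
                                     out_dir = d)
  r1 <- run_update_workflow(cfg(d1))
  r2 <- run_update_workflow(cfg(d2))
  expect_identical(readLines(file.path(d1, "update_ranking.csv")),
                   readLines(file.path(d2, "update_ranking.csv")))
  expect_identical(readLines(file.path(d1, "update_report.md")),
                   readLines(file.path(d2, "update_report.md")))
  expect_s3_class(r1$ranking, "ranking_table")
  expect_equal(r1$ranking$parameter[1], "theta1")
  got <- utils::read.csv(file.path(d1, "update_ranking.csv"))
  expect_equal(got$cumulative_evppi, r1$ranking$cumulative_evppi)
})

test_that("single-parameter toy gives a one-row table near 100%", {
  f <- write_toy_psa(n = 4000, sds = 1)
  res <- run_update_workflow(analysis_config(psa_path = f, k = 13000,
                                             seed = 2))
  expect_equal(nrow(res$ranking), 1L)
  expect_lt(abs(res$ranking$update_metric - 100), 10)
})

test_that("adapt workflow produces the full ordered table", {
  f <- write_toy_psa(n = 2000, sds = c(0.3, 0.2), means = c(2, 1))
  d <- withr::local_tempdir()
  res <- suppressWarnings(
    run_adapt_workflow(analysis_config(psa_path = f, k = 13000, seed = 5,
                                       out_dir = d)))
  expect_s3_class(res$table, "semielasticity_table")
  expect_equal(utils::tail(res$table$adaptation_metric, 1), 100,
               tolerance = 1e-9)
  expect_true(file.exists(file.path(d, "adapt_ranking.csv")))
  expect_true(file.exists(file.path(d, "adapt_report.md")))
})

test_that("simulator route flows seed and population into the results", {
  cfg <- analysis_config(simulator = list(horizon = 15), n_draws = 120,
                         seed = 9, incident_population = 1000)
  psa <- load_psa(cfg)
  expect_equal(nrow(psa$draws), 120)
  expect_equal(psa$incident_population, 1000)
  expect_identical(psa$draws, load_psa(cfg)$draws)
})

test_that("CLI subcommands dispatch and write outputs", {
  d <- withr::local_tempdir()
  psa_file <- file.path(d, "psa.csv")
  sim <- voi_cli(c("simulate", "--n-draws", "120", "--seed", "4",
                   "--out", psa_file))
  expect_true(file.exists(psa_file))
  expect_equal(nrow(sim$draws), 120)
  out <- capture.output(
    est <- voi_cli(c("evpi", "--psa", psa_file, "--k", "13000",
                     "--population", "24799")))
  expect_s3_class(est, "voi_estimate")
  expect_match(paste(out, collapse = ""), "\"per_person\"")
  f <- write_toy_psa(n = 1500, sds = c(1, 0.5))
  res <- capture.output(
    rk <- voi_cli(c("update-rank", "--psa", f, "--k", "13000",
                    "--seed", "3", "--out-dir", file.path(d, "rep"))))
  expect_true(file.exists(file.path(d, "rep", "update_report.md")))
  expect_s3_class(rk$ranking, "ranking_table")
  expect_error(voi_cli(c("frobnicate")), "unknown subcommand")
})
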