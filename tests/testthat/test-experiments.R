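write_config <- function(lines) {
  f <- tempfile(fileext = ".cfg")
  writeLines(lines, f)
  f
}

test_that("config parsing and schema validation", {
  f <- write_config(c(
    "# tiny experiment",
    "network: er",
    "n: 500",
    "mean_degree: 8",
    "beta_grid: 0.1, 0.2, 0.3",
    "beta_f_values: 0, 1",
    "gamma_values: 0.1"
  ))
  cfg <- read_config(f)
  expect_equal(cfg$beta_grid, c(0.1, 0.2, 0.3))
  expect_equal(cfg$beta_f_values, c(0, 1))
  expect_match(attr(cfg, "hash"), "^[0-9a-f]{8}$")

  bad <- write_config(c("network: er", "betagrid: 0.1", "bogus_key: 2"))
  expect_error(read_config(bad), "betagrid.*bogus_key|bogus_key")
  expect_error(ssfir:::as_config(list(network = "er")), "beta_grid")
})

test_that("theory subcommand reproduces threshold orderings", {
  f <- write_config(c(
    "network: er", "n: 10000", "mean_degree: 10",
    "beta_grid: 0.05, 0.15, 0.3",
    "beta_f_values: 0, 1, 4",
    "gamma_values: 0.1"
  ))
  out <- file.path(tempfile(), "theory")
  res <- cmd_theory(f, out, quiet = TRUE)
  thr <- res$threshold_values
  bc <- vapply(thr, `[[`, numeric(1), "beta_c")
  bf <- vapply(thr, `[[`, numeric(1), "beta_f")
  expect_equal(bc[bf == 0], 1 / 9, tolerance = 1e-8)
  expect_true(all(diff(bc[order(bf)]) > 0))  # threshold grows with beta_f

  sweep <- read.csv(file.path(out, "theory_sweep.csv"))
  expect_setequal(names(sweep),
                  c("beta", "beta_f", "gamma", "mu", "theta", "prevalence", "margin"))
  # gamma sweep at fixed beta_f: threshold nonincreasing in gamma
  f2 <- write_config(c(
    "network: er", "n: 10000", "mean_degree: 10",
    "beta_grid: 0.1", "beta_f_values: 1",
    "gamma_values: 0.05, 0.2, 0.5, 0.9"
  ))
  res2 <- cmd_theory(f2, out, quiet = TRUE)
  bc2 <- vapply(res2$threshold_values, `[[`, numeric(1), "beta_c")
  gm2 <- vapply(res2$threshold_values, `[[`, numeric(1), "gamma")
  expect_true(all(diff(bc2[order(gm2)]) <= 1e-12))
})

test_that("simulate subcommand writes byte-stable seeded outputs", {
  f <- write_config(c(
    "network: er", "n: 300", "mean_degree: 8",
    "beta_grid: 0.1, 0.25, 0.5",
    "beta_f_values: 0", "gamma_values: 0.1",
    "n_realizations: 40"
  ))
  out1 <- file.path(tempfile(), "a")
  out2 <- file.path(tempfile(), "b")
  suppressWarnings(cmd_simulate(f, seed = 77, out_dir = out1, quiet = TRUE))
  suppressWarnings(cmd_simulate(f, seed = 77, out_dir = out2, quiet = TRUE))
  for (fn in c("sim_sweep.csv", "realizations.csv")) {
    expect_identical(readLines(file.path(out1, fn)),
                     readLines(file.path(out2, fn)))
  }
  sweep <- read.csv(file.path(out1, "sim_sweep.csv"))
  expect_equal(nrow(sweep), 3)
  reals <- read.csv(file.path(out1, "realizations.csv"))
  expect_equal(nrow(reals), 120)
})

test_that("compare subcommand joins the three engines coherently", {
  f <- write_config(c(
    "network: er", "n: 1000", "mean_degree: 10",
    "beta_grid: 0.05, 0.3",
    "beta_f_values: 0", "gamma_values: 0.5",
    "n_realizations: 150"
  ))
  out <- file.path(tempfile(), "cmp")
  # the 2-point beta grid triggers the (expected) no-interior-peak warning
  res <- suppressWarnings(cmd_compare(f, seed = 5, out_dir = out, quiet = TRUE))
  cmp <- read.csv(file.path(out, "compare.csv"))
  # beta_f = 0 at strongly supercritical beta: simulation tracks the
  # percolation theory; the mean-field engine overestimates by a small but
  # systematic margin (it ignores dynamic correlations), about 0.05 here
  sup <- cmp[cmp$beta == 0.3, ]
  expect_lt(abs(sup$sim_mean_rho_outbreak - sup$theory_prevalence), 0.03)
  expect_gt(sup$mf_prevalence, sup$theory_prevalence)
  expect_lt(sup$mf_prevalence - sup$theory_prevalence, 0.08)
  thr <- res$threshold_values[[1]]
  expect_lt(abs(thr$beta_c_percolation - 1 / 9), 0.01)
  expect_lt(abs(thr$beta_c_meanfield - 1 / 11), 0.01)
})

test_that("net subcommand and CLI dispatcher produce files", {
  f <- write_config(c("network: ucm", "n: 400", "exponent: 3", "k_min: 3",
                      "beta_grid: 0.1"))
  out <- file.path(tempfile(), "net")
  status <- ssfir_cli(c("net", "--config", f, "--out", out, "--seed", "3", "--quiet"))
  expect_identical(status, 0L)
  net <- read_edge_list(file.path(out, "edges.tsv"))
  expect_true(all(net$degree[net$degree > 0] >= 3))
  expect_true(file.exists(file.path(out, "degree_dist.tsv")))

  expect_identical(suppressMessages(ssfir_cli(character(0))), 1L)
  expect_identical(suppressMessages(
    ssfir_cli(c("bogus", "--config", f, "--out", out))), 1L)
})
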