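test_that("run_config validates, defaults, and hashes deterministically", {
  cfg <- run_config()
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$g, 2000)
  expect_equal(cfg$zc, 1e6)
  expect_match(cfg$hash, "^[0-9a-f]{32}$")
  expect_identical(cfg$hash, run_config()$hash)
  expect_false(identical(cfg$hash, run_config(list(mu = 2e-10))$hash))

  expect_error(run_config(list(nonsense = 1)), "unknown config keys")
  expect_error(run_config(list(model = "bogus")), "model must be")
  expect_error(run_config(list(bracket = c(5, 1))), "bracket")
  expect_error(run_config(list(mu = "x")), "numeric")

  # model-aware defaults activate the right mutation types
  exp_cfg <- run_config(list(model = "expanded"))
  expect_equal(exp_cfg$lambda_indel_plus, 1)
  expect_equal(exp_cfg$lambda_pm, 1)
  ind_cfg <- run_config(list(model = "indel_only"))
  expect_equal(ind_cfg$lambda_indel_minus, 1)

  # JSON round trip
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(mu = 1e-9, N = 1e6, model = "expanded"), tmp,
                       auto_unbox = TRUE)
  cfg2 <- run_config(tmp)
  expect_equal(cfg2$mu, 1e-9)
  expect_equal(cfg2$model, "expanded")
})

test_that("result tables round-trip through TSV with their config hash", {
  df <- data.frame(N = 1e8, mu = 1e-10, value = pi / 7, converged = TRUE)
  tmp <- tempfile(fileext = ".tsv")
  write_result_table(df, tmp, config_hash = "abc123")
  back <- read_result_table(tmp)
  expect_identical(attr(back, "config_hash"), "abc123")
  expect_identical(back$value, df$value)   # full-precision serialization
  expect_equal(back$N, df$N)               # integer-valued doubles may narrow
})

test_that("species tables are validated row by row with line numbers", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("species\tNe\tmu\tnoncoding_fraction",
               "sp1\t1e6\t1e-9\t0.5",
               "sp2\t-3\t1e-9\t0.4",
               "sp3\t1e7\t1e-9\t1.7"), tmp)
  expect_error(read_species_table(tmp), "line 3.*Ne")
  expect_error(read_species_table(tmp), "line 4.*noncoding_fraction")

  writeLines(c("species\tNe", "sp1\t1e6"), tmp)
  expect_error(read_species_table(tmp), "missing required columns")

  writeLines(c("species\tNe\tmu\tnoncoding_fraction",
               "sp1\t1e6\t1e-9\t0.5"), tmp)
  ok <- read_species_table(tmp)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$Ne, 1e6)
})

test_that("fixture species tables are reproducible and noise-free at noise = 0", {
  f1 <- generate_fixture_table(4, seed = 11, noise = 0)
  f2 <- generate_fixture_table(4, seed = 11, noise = 0)
  expect_identical(f1, f2)
  expect_equal(f1$noncoding_fraction, attr(f1, "predicted_fraction"))

  tmp1 <- tempfile(); tmp2 <- tempfile()
  write_species_table(f1, tmp1); write_species_table(f2, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))  # byte-identical output

  back <- read_species_table(tmp1)
  expect_identical(back$Ne, f1$Ne)
  expect_identical(back$noncoding_fraction, f1$noncoding_fraction)
})

test_that("observed-vs-predicted agreement degrades with fixture noise", {
  f0 <- generate_fixture_table(6, seed = 3, noise = 0)
  ov0 <- predict_overlay(f0)
  expect_equal(ov0$observed_fraction, ov0$predicted_fraction)
  expect_equal(stats::cor(ov0$observed_fraction, ov0$predicted_fraction,
                          method = "spearman"), 1)
  fn <- generate_fixture_table(6, seed = 3, noise = 0.4)
  expect_false(all(fn$noncoding_fraction == f0$noncoding_fraction))
})

test_that("predictions decrease with the compound parameter Ne x mu", {
  recs <- data.frame(species = c("low", "high"),
                     Ne = c(1e6, 1e8), mu = c(1e-10, 1e-9),
                     noncoding_fraction = c(0.9, 0.1))
  ov <- predict_overlay(recs)
  expect_true(all(ov$converged))
  expect_gt(ov$predicted_fraction[ov$species == "low"],
            ov$predicted_fraction[ov$species == "high"])
})

test_that("cli dispatch produces hashed tables and distinct no-equilibrium status", {
  out <- tempfile(fileext = ".tsv")
  expect_equal(cli_main(c("equilibrium", "--mu", "1e-10", "--N", "1e8",
                          "--out", out)), 0L)
  tab <- read_result_table(out)
  expect_true(tab$converged)
  expect_equal(tab$status, "converged")
  expect_match(attr(tab, "config_hash"), "^[0-9a-f]{32}$")
  expect_lt(abs(tab$bias_residual), 1e-5)

  expect_equal(suppressMessages(
    cli_main(c("equilibrium", "--model", "indel_only", "--out", out))), 0L)
  tab2 <- read_result_table(out)
  expect_false(tab2$converged)
  expect_match(tab2$status, "no_equilibrium")

  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(cli_main(c("equilibrium", "--model", "bogus"))), 2L)

  # neutrality over a toy architecture
  expect_equal(cli_main(c("neutrality", "--g", "2", "--zc", "6", "--znc", "4",
                          "--out", out)), 0L)
  nt <- read_result_table(out)
  expect_equal(nt$neutral_prob[nt$type == "deletion"], 0.06)
  expect_equal(nt$neutral_prob[nt$type == "duplication"], 0.12)
})

test_that("cli curve runs a small grid with monotone fractions per kappa", {
  out <- tempfile(fileext = ".tsv")
  st <- cli_main(c("curve", "--n-mu", "1e-3,1e-2,1e-1", "--kappa-grid", "1,2",
                   "--mu", "1e-9", "--out", out))
  expect_equal(st, 0L)
  tab <- read_result_table(out)
  expect_equal(nrow(tab), 6)
  for (km in unique(tab$kappa)) {
    fr <- tab$fraction_star[tab$kappa == km][order(tab$N_mu[tab$kappa == km])]
    expect_true(all(diff(fr) < 0))
  }
})

test_that("cli validate reports machine-readable oracle outcomes", {
  out <- tempfile(fileext = ".tsv")
  expect_equal(cli_main(c("validate", "--seed", "3", "--out", out)), 0L)
  v <- read_result_table(out)
  expect_true(all(v$pass))
  expect_true(all(c("enumeration", "wright_fisher") %in% v$suite))
  # empty suite selection is a no-op success
  empty <- run_validate(run_config(), suites = character(0))
  expect_equal(nrow(empty), 0)
})

test_that("the installed command-line script runs end to end", {
  script <- system.file("cli", "noncodeq", package = "noncodeq")
  skip_if(script == "", "package not installed with inst/cli")
  out <- tempfile(fileext = ".tsv")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(script, "equilibrium", "--mu", "1e-10", "--N", "1e8",
                   "--out", out),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(out))
  tab <- read_result_table(out)
  expect_true(tab$converged)
})
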