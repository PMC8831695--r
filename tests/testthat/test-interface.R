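test_that("unknown config keys abort with status 2 and no outputs", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("K1: 0.3", "K2: 2", "bogus_key: 1"), cfg)
  out <- file.path(tempdir(), "cli_bad")
  status <- suppressMessages(
    crispri_cli(c("sweep", "--config", cfg, "--out", out)))
  expect_equal(status, 2L)
  expect_false(file.exists(file.path(out, "sweep.csv")))
  expect_equal(suppressMessages(crispri_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(crispri_cli(character())), 2L)
})

test_that("sweep writes the documented CSV and a manifest, deterministically", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("K1: 0.3", "K2: 2", "Ctot: 100", "Dtot: 10",
               "sweep:", "  field: gtot", "  min: 0.01", "  max: 10000",
               "  points: 12"), cfg)
  out1 <- file.path(tempdir(), "cli_s1"); out2 <- file.path(tempdir(), "cli_s2")
  expect_equal(crispri_cli(c("sweep", "--config", cfg, "--out", out1)), 0L)
  expect_equal(crispri_cli(c("sweep", "--config", cfg, "--out", out2)), 0L)
  sw <- read.csv(file.path(out1, "sweep.csv"))
  expect_named(sw, c("input_value", "C", "g", "D", "Cg", "CgD",
                     "D_over_Dtot", "R"))
  expect_equal(nrow(sw), 12)
  expect_identical(readLines(file.path(out1, "sweep.csv")),
                   readLines(file.path(out2, "sweep.csv")))
  mf <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(mf$subcommand, "sweep")
  expect_true(nzchar(mf$config_md5))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("the synth / process-plate / fit / predict pipeline runs end to end", {
  base <- file.path(tempdir(), "cli_e2e")
  synth_dir <- file.path(base, "synth")
  expect_equal(crispri_cli(c("synth", "plate", "--seed", "11",
                             "--out", synth_dir)), 0L)
  expect_true(all(file.exists(file.path(synth_dir,
    c("plate.csv", "wellmap.csv", "truth.json", "manifest.json")))))
  kin_dir <- file.path(base, "kin")
  expect_equal(crispri_cli(c("process-plate",
                             "--plate", file.path(synth_dir, "plate.csv"),
                             "--map", file.path(synth_dir, "wellmap.csv"),
                             "--out", kin_dir)), 0L)
  kin <- read.csv(file.path(kin_dir, "kinetics.csv"))
  expect_true(all(c("mu_per_h", "S_cell_RFP", "S_cell_GFP") %in% names(kin)))

  curve_dir <- file.path(base, "curve")
  expect_equal(crispri_cli(c("synth", "curve", "--Km", "5", "--n", "2",
                             "--seed", "3", "--out", curve_dir)), 0L)
  fit_dir <- file.path(base, "fit")
  expect_equal(crispri_cli(c("fit",
                             "--data", file.path(curve_dir, "curve.csv"),
                             "--kind", "repression", "--out", fit_dir)), 0L)
  fj <- jsonlite::read_json(file.path(fit_dir, "fit.json"))
  expect_lt(abs(fj$estimates$Km - 5) / 5, 0.25)

  model <- circuit_model(list(hill_stage("repression", 1, 50, 5, 2)),
                         "cascade")
  model_path <- file.path(base, "model.json")
  write_circuit_model(model, model_path)
  pred_dir <- file.path(base, "pred")
  expect_equal(crispri_cli(c("predict", "--model", model_path,
                             "--grid-min", "0.1", "--grid-max", "100",
                             "--points", "10", "--out", pred_dir)), 0L)
  pr <- read.csv(file.path(pred_dir, "prediction.csv"))
  expect_equal(pr$output_value, hill_eval(model$stages[[1]], pr$input_value))
  unlink(base, recursive = TRUE)
})

test_that("simulate prints a JSON equilibrium state", {
  out <- capture.output(
    status <- crispri_cli(c("simulate", "--Ctot", "100", "--gtot", "1000",
                            "--Dtot", "10")))
  expect_equal(status, 0L)
  st <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_true(st$converged)
  eq <- solve_equilibrium(binding_params(), species_totals(100, 1000, 10))
  expect_equal(st$D, eq$D, tolerance = 1e-9)
})
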