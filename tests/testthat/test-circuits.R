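test_that("a single-stage cascade is just hill_eval", {
  st <- hill_stage("repression", 2, 20, 5, 2)
  m <- circuit_model(list(st), "cascade")
  x <- c(0, 1, 5, 50)
  expect_equal(cascade_predict(m, x), hill_eval(st, x))
  expect_equal(predict(m, x), hill_eval(st, x))
})

test_that("an even chain of ideal repressions is increasing, odd decreasing", {
  s1 <- hill_stage("repression", 0, 100, 10, 2)
  s2 <- hill_stage("repression", 0, 50, 20, 1.5)
  s3 <- hill_stage("repression", 0, 80, 5, 1)
  x <- 10^seq(-2, 3, length.out = 30)
  even <- cascade_predict(circuit_model(list(s1, s2), "cascade"), x)
  odd <- cascade_predict(circuit_model(list(s1, s2, s3), "cascade"), x)
  expect_true(all(diff(even) > 0))
  expect_true(all(diff(odd) < 0))
  expect_error(circuit_model(list(), "cascade"), "at least one stage")
})

test_that("the mechanistic CRISPRi inverter hits its limits and the oracle", {
  act <- hill_stage("activation", basal = 0, range = 2000, Km = 10, n = 1.5)
  params <- binding_params(K1 = 0.3, K2 = 2, theta = 5)
  totals <- species_totals(Ctot = 500, gtot = 0, Dtot = 10)
  m <- circuit_model(list(), "cascade",
                     crispri_stage = list(activation = act, params = params,
                                          totals = totals))
  # zero inducer, zero basal: no sgRNA, promoter fully free
  expect_equal(crispri_not_predict(m, 0), 5 * 10)
  # saturating inducer: gtot >> K1 and Ctot >> K2*Dtot, near-full repression
  expect_lt(crispri_not_predict(m, 1e6), 0.05 * 5 * 10)
  # mid-curve agrees with the independent bisection solver
  gtot_mid <- hill_eval(act, 10)
  oracle <- solve_equilibrium_oracle(params,
                                     species_totals(500, gtot_mid, 10))
  expect_equal(crispri_not_predict(m, 10), oracle$R, tolerance = 1e-6)
  expect_error(crispri_not_predict(circuit_model(list(
    hill_stage("repression", 0, 1, 1, 1)), "cascade"), 1), "crispri_stage")
})

test_that("NOR output is high only when both inputs are low", {
  s1 <- hill_stage("repression", 1, 99, 5, 2)
  s2 <- hill_stage("repression", 3, 101, 50, 1.5)
  m <- circuit_model(list(s1, s2), "nor")
  expect_equal(m$basal, 2)                  # shared promoter floor: mean
  expect_equal(m$range, 100)
  expect_equal(nor_predict(m, 0, 0), 102)
  big <- 1e9
  expect_equal(nor_predict(m, big, 0), 2, tolerance = 1e-3)
  expect_equal(nor_predict(m, 0, big), 2, tolerance = 1e-3)
  expect_equal(nor_predict(m, big, big), 2, tolerance = 1e-3)
  # symmetry: swapping stage parameters mirrors swapping the inputs
  msw <- circuit_model(list(s2, s1), "nor")
  a <- nor_predict(m, 2, 30); b <- nor_predict(msw, 30, 2)
  expect_equal(a, b)
  expect_error(nor_predict(circuit_model(list(s1), "cascade"), 1, 1), "NOR")
  expect_error(circuit_model(list(s1), "nor"), "exactly 2")
})

test_that("stage-wise cascade fitting composes to the end-to-end truth", {
  act <- hill_stage("activation", 1, 200, 10, 1.5)
  rep1 <- hill_stage("repression", 2, 80, 40, 2)
  x <- 10^seq(-1, 3, length.out = 10)
  d_act <- data.frame(input_value = x, output_value = hill_eval(act, x))
  mid <- sort(unique(hill_eval(act, x)))
  d_rep <- data.frame(input_value = mid, output_value = hill_eval(rep1, mid))
  m <- fit_cascade(list(d_act, d_rep), c("activation", "repression"))
  truth <- hill_eval(rep1, hill_eval(act, x))
  expect_equal(cascade_predict(m, x), truth, tolerance = 1e-3)
  expect_length(attr(m, "fits"), 2)
  # NOR topology from two stage data sets
  d2 <- data.frame(input_value = x, output_value = hill_eval(rep1, x))
  mn <- fit_cascade(list(d2, d2), "nor")
  expect_equal(mn$topology, "nor")
  expect_error(fit_cascade(list(d2), "nor"), "2 stage data sets")
})

test_that("circuit models survive a JSON round trip", {
  m <- circuit_model(list(hill_stage("repression", 1, 99, 5, 2),
                          hill_stage("repression", 3, 101, 50, 1.5)), "nor")
  path <- tempfile(fileext = ".json")
  write_circuit_model(m, path)
  m2 <- read_circuit_model(path)
  expect_equal(nor_predict(m2, 2, 30), nor_predict(m, 2, 30))
  cs <- list(activation = hill_stage("activation", 0, 100, 10, 1),
             params = binding_params(), totals = species_totals(100, 0, 10))
  mc <- circuit_model(list(hill_stage("repression", 1, 9, 2, 1)), "cascade",
                      crispri_stage = cs)
  write_circuit_model(mc, path)
  mc2 <- read_circuit_model(path)
  expect_equal(cascade_predict(mc2, c(0, 5, 50)),
               cascade_predict(mc, c(0, 5, 50)))
})
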