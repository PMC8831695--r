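test_that("degenerate totals give the analytic no-complex state", {
  p <- default_params()
  # no sgRNA: no complex can form, promoter fully free
  eq <- solve_equilibrium(p, species_totals(Ctot = 100, gtot = 0, Dtot = 10))
  expect_equal(eq$D, 10)
  expect_equal(eq$Cg, 0)
  expect_equal(eq$CgD, 0)
  expect_equal(eq$C, 100)
  # no dCas9
  eq <- solve_equilibrium(p, species_totals(Ctot = 0, gtot = 100, Dtot = 10))
  expect_equal(eq$D, 10)
  expect_equal(eq$g, 100)
  expect_true(eq$converged)
})

test_that("without target DNA the complex matches the single-binding quadratic", {
  # with Dtot = 0 the system collapses to one binding step whose complex is
  # the smaller root of x^2 - (Ctot + gtot + K1) x + Ctot*gtot = 0
  p <- default_params()
  for (tot in list(c(1, 1), c(10, 0.5), c(100, 100))) {
    eq <- solve_equilibrium(p, species_totals(tot[1], tot[2], 0))
    s <- tot[1] + tot[2] + p$K1
    root <- (s - sqrt(s^2 - 4 * tot[1] * tot[2])) / 2
    expect_equal(eq$Cg, root, tolerance = 1e-8)
    expect_equal(eq$CgD, 0)
    expect_equal(eq$D, 0)
  }
})

test_that("fixed-point and nested-bisection solvers agree across the box", {
  set.seed(7)
  p <- default_params()
  for (tt in random_totals(200)) {
    a <- solve_equilibrium(p, tt)
    b <- solve_equilibrium_oracle(p, tt)
    expect_true(a$converged)
    expect_lt(abs(a$D - b$D) / max(b$D, 1e-300), 1e-6)
  }
})

test_that("returned states satisfy conservation and mass action", {
  set.seed(11)
  p <- default_params()
  for (tt in random_totals(150)) {
    for (eq in list(solve_equilibrium(p, tt),
                    solve_equilibrium_oracle(p, tt))) {
      expect_lt(conservation_residual(eq), 1e-8)
      expect_lt(mass_action_residual(eq), 1e-8)
      expect_true(all(unlist(eq[c("C", "g", "D", "Cg", "CgD")]) >= 0))
      expect_equal(eq$R, eq$params$theta * eq$D)
    }
  }
})

test_that("free DNA is symmetric under exchanging dCas9 and sgRNA totals", {
  set.seed(13)
  p <- default_params()
  pairs <- 10^matrix(runif(80, -2, 4), ncol = 2)
  for (i in seq_len(nrow(pairs))) {
    a <- solve_equilibrium(p, species_totals(pairs[i, 1], pairs[i, 2], 10))
    b <- solve_equilibrium(p, species_totals(pairs[i, 2], pairs[i, 1], 10))
    expect_equal(a$D, b$D, tolerance = 1e-7)
  }
})

test_that("free DNA responds monotonically to each total", {
  p <- default_params()
  grid <- 10^seq(-1, 4, length.out = 12)
  d_g <- sapply(grid, function(g)
    solve_equilibrium(p, species_totals(100, g, 10))$D)
  d_c <- sapply(grid, function(cc)
    solve_equilibrium(p, species_totals(cc, 100, 10))$D)
  d_d <- sapply(grid, function(dd)
    solve_equilibrium(p, species_totals(100, 100, dd))$D)
  expect_true(all(diff(d_g) <= 1e-12))
  expect_true(all(diff(d_c) <= 1e-12))
  expect_true(all(diff(d_d) >= -1e-12))
})

test_that("explicit limit expression matches its closed-form anchors", {
  p <- binding_params(K1 = 0.3, K2 = 2, theta = 3)
  # no sgRNA: repression term vanishes
  expect_equal(explicit_output(p, species_totals(100, 0, 10)), 3 * 10)
  # saturating sgRNA with Ctot = K2: denominator tends to 2
  r <- explicit_output(p, species_totals(Ctot = 2, gtot = 1e12, Dtot = 10))
  expect_equal(r, 3 * 10 / 2, tolerance = 1e-9)
})

test_that("explicit output approximates the full solve in its regime", {
  p <- default_params()
  tt <- species_totals(Ctot = 100, gtot = 1e4, Dtot = 0.1)
  r_imp <- solve_equilibrium(p, tt)$R
  r_exp <- explicit_output(p, tt)
  expect_lt(abs(r_exp - r_imp) / r_imp, 0.02)
})

test_that("invalid inputs are rejected", {
  expect_error(binding_params(K1 = -1), "K1")
  expect_error(binding_params(K1 = NA), "finite")
  expect_error(species_totals(-1, 1, 1), ">= 0")
  expect_error(species_totals(Inf, 1, 1), "finite")
  expect_error(solve_equilibrium(default_params(),
                                 species_totals(1, 1, 1), tol = -1), "tol")
})
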