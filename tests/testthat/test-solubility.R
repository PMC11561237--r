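curcumin_solute <- function(dH = 120)
  solute_params(molar_volume = 3.961e-4,
                reference_vapor_pressure = 3.08e-12 * 133.322,
                reference_temperature = 298.15,
                sublimation_enthalpy = dH)

test_that("sublimation pressure reproduces its reference point exactly", {
  sol <- curcumin_solute()
  expect_identical(sublimation_pressure(298.15, sol),
                   3.08e-12 * 133.322)
  # frozen from an independent evaluation of the integrated form:
  # P = 1 * exp((1e5/8.314462618) * (1/298.15 - 1/350)) = 393.868 Pa
  sol2 <- solute_params(1e-4, 1, 298.15, sublimation_enthalpy = 100)
  expect_equal(sublimation_pressure(350, sol2), 393.868, tolerance = 1e-5)
})

test_that("sublimation pressure requires the enthalpy input", {
  sol <- solute_params(3.961e-4, 4.106e-10, 298.15)
  expect_error(sublimation_pressure(363.15, sol), "sublimation enthalpy")
})

test_that("number density converts g/cm^3 to molecules per m^3", {
  # hand calculation: 962 kg/m^3 / 0.018015 kg/mol * N_A = 3.2158e28
  expect_equal(number_density(0.962, 18.015), 3.21582e28, tolerance = 1e-5)
  expect_equal(number_density(2 * 0.962, 18.015),
               2 * number_density(0.962, 18.015))
  expect_lt(number_density(0.962, 1e30), 1)      # M -> Inf limit
  expect_error(number_density(-1, 18), "positive")
})

test_that("Poynting factor is exactly 1 at the sublimation pressure", {
  sol <- curcumin_solute()
  psat <- sublimation_pressure(363.15, sol)
  y2 <- mole_fraction_solubility(363.15, psat, -35.848, 0.962, sol)
  expect_identical(attr(y2, "poynting"), 1)
})

test_that("zero solvation free energy reduces to the bare ratio", {
  sol <- curcumin_solute()
  y2 <- mole_fraction_solubility(400, 2e6, 0, 0.95, sol)
  psat <- attr(y2, "psat")
  expect_equal(as.numeric(y2),
               psat * attr(y2, "poynting") /
                 (attr(y2, "number_density") * mdsolv_constants()["k_B"] * 400),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("worked curcumin example lands at the expected magnitude", {
  # independent step-by-step oracle, frozen from a hand calculation:
  #   rho_n = 3.2158e28 m^-3; RT = 3019.3 J/mol
  #   Poynting = exp(3.961e-4 * (2e6 - 2.86e-3) / RT)   = 1.2999
  #   denom   = rho_n * k_B * T * exp(-35848/RT)        = 1125.4 Pa
  #   y2      = 2.86e-3 * 1.2999 / 1125.4               = 3.304e-6
  y2 <- mole_fraction_solubility(363.15, 2e6, -35.848, 0.962,
                                 curcumin_solute(),
                                 sublimation_pressure_Pa = 2.86e-3)
  expect_equal(as.numeric(y2), 3.304e-6, tolerance = 1e-3)
})

test_that("out-of-range mole fractions warn but do not abort", {
  sol <- solute_params(3.961e-4, 1e6, 298.15, sublimation_enthalpy = 100)
  expect_warning(mole_fraction_solubility(400, 2e6, 50, 0.9, sol),
                 "outside \\(0, 1\\)")
})

test_that("AARD matches hand-computed cases and validates input", {
  expect_equal(aard(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(aard(1.1, 1.0), 10, tolerance = 1e-12)
  # the four complete density pairs of the subcritical-water data set:
  # mean(0.062370, 0.052854, 0.065241, 0.079655) * 100 = 6.503
  expect_equal(aard(c(0.902, 0.896, 0.874, 0.855),
                    c(0.962, 0.946, 0.935, 0.929)), 6.503, tolerance = 1e-3)
  expect_error(aard(1:3, 1:2), "equal")
  expect_error(aard(1, 0), "nonzero")
})

test_that("solubility_table flags trends and degenerate tables", {
  sol <- curcumin_solute()
  tab <- thermo_table(363.15, -35.848, 0.962)
  res1 <- solubility_table(tab, sol, 2e6)
  expect_equal(nrow(res1), 1L)
  expect_equal(attr(res1, "monotonicity"), "undefined")

  tt <- gen_thermo_truth(seq(363.15, 453.15, length.out = 5),
                         c(-20, -0.045), c(1.35, -0.00125), sol, 2e6)
  res <- solubility_table(tt$table, sol, 2e6)
  expect_equal(attr(res, "monotonicity"), "increasing")
  expect_equal(res$mole_fraction, tt$true_solubility, tolerance = 1e-15)
})

test_that("thermodynamic properties hold over random parameter sweeps", {
  set.seed(77)
  n <- 1000
  for (i in seq_len(n)) {
    Tref <- runif(1, 250, 400)
    Pref <- 10^runif(1, -12, 2)
    dH <- runif(1, 20, 200)
    sol <- solute_params(10^runif(1, -5, -3), Pref, Tref,
                         sublimation_enthalpy = dH)
    # reference point is exact
    if (abs(sublimation_pressure(Tref, sol) - Pref) > 1e-15 * Pref)
      fail(sprintf("psat(Tref) != Pref at i=%d", i))
    # strictly increasing in T for positive enthalpy
    Ts <- sort(runif(2, 260, 500))
    ps <- sublimation_pressure(Ts, sol)
    if (ps[2] <= ps[1]) fail(sprintf("psat not increasing at i=%d", i))
  }
  succeed()
})

test_that("solubility falls strictly with less favourable solvation", {
  set.seed(78)
  sol <- curcumin_solute()
  for (i in 1:1000) {
    temp <- runif(1, 300, 500)
    dg <- sort(runif(2, -60, 20))
    y <- suppressWarnings(vapply(dg, function(g)
      as.numeric(mole_fraction_solubility(temp, 2e6, g, 0.9, sol)), 0))
    if (y[2] >= y[1]) fail(sprintf("y2 not decreasing in dG at i=%d", i))
  }
  succeed()
})

test_that("AARD is scale invariant", {
  set.seed(79)
  for (i in 1:1000) {
    m <- sample(2:8, 1)
    ref <- runif(m, 0.5, 2)
    sim <- ref * (1 + runif(m, -0.3, 0.3))
    k <- 10^runif(1, -3, 3)
    if (abs(aard(sim, ref) - aard(k * sim, k * ref)) > 1e-9)
      fail(sprintf("scale invariance broken at i=%d", i))
    if (aard(sim, ref) < 0) fail("negative AARD")
  }
  expect_equal(aard(c(1, 2), c(1, 2)), 0)
})
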