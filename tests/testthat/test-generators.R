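test_that("generators are seed-deterministic", {
  b <- periodic_box(20)
  expect_equal(gen_brownian(5, 1e-9, 1000, 10, b, seed = 11),
               gen_brownian(5, 1e-9, 1000, 10, b, seed = 11))
  expect_equal(gen_ideal_gas(10, b, 3, seed = 11),
               gen_ideal_gas(10, b, 3, seed = 11))
  expect_equal(gen_pair_gas(8, 2.0, b, seed = 11),
               gen_pair_gas(8, 2.0, b, seed = 11))
  # different seeds differ
  expect_false(isTRUE(all.equal(gen_ideal_gas(10, b, 1, seed = 1)$coords,
                                gen_ideal_gas(10, b, 1, seed = 2)$coords)))
})

test_that("generators do not disturb the session RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(gen_brownian(3, 1e-9, 1000, 5, periodic_box(10), seed = 5))
  expect_identical(runif(1), a)
})

test_that("zero diffusion gives a frozen trajectory", {
  tr <- gen_brownian(4, 0, 1000, 6, periodic_box(15), seed = 3)
  for (k in 2:6) expect_equal(tr$coords[, , k], tr$coords[, , 1])
})

test_that("Brownian per-step variance matches 2*D*dt", {
  D <- 4.4e-9; dt_fs <- 1000
  tr <- gen_brownian(500, D, dt_fs, 5000, periodic_box(21.2), seed = 8)
  steps <- tr$coords[, , -1] - tr$coords[, , -5000]     # angstrom
  target <- 2 * D * dt_fs * 1e-15 / 1e-20               # angstrom^2
  # ~7.5M samples: the sample variance is within far less than 2 percent
  expect_lt(abs(stats::var(as.numeric(steps)) / target - 1), 0.02)
  expect_false(tr$wrapped)
})

test_that("ideal gas frames stay inside the box and are wrapped", {
  b <- periodic_box(c(12, 18, 24))
  tr <- gen_ideal_gas(50, b, n_frames = 4, seed = 5)
  expect_true(tr$wrapped)
  for (ax in 1:3) {
    expect_true(all(tr$coords[, ax, ] >= 0))
    expect_true(all(tr$coords[, ax, ] < as.numeric(b)[ax]))
  }
})

test_that("pair gas fixes the intra-dimer separation", {
  b <- periodic_box(40)
  tr <- gen_pair_gas(30, 2.5, b, seed = 6)
  a <- tr$coords[tr$species == "A", , 1]
  p <- tr$coords[tr$species == "B", , 1]
  d <- minimum_image(a - p, b)
  expect_equal(sqrt(rowSums(d^2)), rep(2.5, 30), tolerance = 1e-10)
  expect_error(gen_pair_gas(10, 40, periodic_box(60)), "half the shortest")
})

test_that("a single dimer yields exactly one nonzero cross count", {
  tr <- gen_pair_gas(1, 3.0, periodic_box(60), seed = 9)
  # bin width chosen so 3.0 sits inside a bin, not on an edge
  prof <- compute_rdf(tr, "A", "B", r_max = 10, bin_width = 0.07)
  nz <- which(prof$raw_counts > 0)
  expect_length(nz, 1L)
  expect_equal(prof$raw_counts[nz], 1)
  expect_true(prof$bin_edges[nz] <= 3.0 && 3.0 < prof$bin_edges[nz + 1])
})

test_that("thermo truth round trip is exact and guards its range", {
  sol <- solute_params(3.961e-4, 4.106e-10, 298.15,
                       sublimation_enthalpy = 120)
  tt <- gen_thermo_truth(c(363.15, 453.15), c(-35, 0), c(0.9, 0), sol, 2e6)
  res <- solubility_table(tt$table, sol, 2e6)
  expect_equal(res$mole_fraction, tt$true_solubility, tolerance = 1e-15)

  # a huge reference pressure drives y2 past 1: refuse to emit the fixture
  bad <- solute_params(3.961e-4, 1e8, 298.15, sublimation_enthalpy = 120)
  expect_error(gen_thermo_truth(c(363.15, 453.15), c(-35, 0), c(0.9, 0),
                                bad, 2e6), "outside \\(0, 1\\)")

  # construction with favourable high-T solvation is strictly increasing
  tt2 <- gen_thermo_truth(seq(363.15, 453.15, length.out = 5),
                          c(-20, -0.045), c(1.35, -0.00125), sol, 2e6)
  expect_true(all(diff(tt2$true_solubility) > 0))
})

test_that("LJ fluid produces liquid-like structure", {
  lj <- gen_lj_fluid(108, 0.8, 0.9, n_sweeps = 400, seed = 7)
  acc <- attr(lj, "acceptance_rate")
  expect_gt(acc, 0)
  expect_lt(acc, 1)
  expect_equal(dim(lj$coords)[3], 10L)
  prof <- compute_rdf(lj, "LJ", "LJ", r_max = min(lj$box) / 2 * 0.99,
                      bin_width = 0.05)
  pk <- first_peak(prof, min_position = 0.8)
  expect_gte(pk$position, 1.0)
  expect_lte(pk$position, 1.2)
  expect_gt(pk$intensity, 1.5)   # a liquid's first shell is well above 1
})

test_that("dilute LJ gas approaches the Boltzmann pair limit", {
  lj <- gen_lj_fluid(400, 0.05, 1.0, n_sweeps = 300, seed = 13)
  prof <- compute_rdf(lj, "LJ", "LJ", r_max = 3.0, bin_width = 0.1)
  ref <- mdsolv:::lj_boltzmann_g(prof$r_centers, 1.0)
  sel <- prof$r_centers > 0.85 & prof$r_centers < 2.5
  # sparse counting: compare at a generous noise tolerance
  expect_lt(mean(abs(prof$g[sel] - ref[sel])), 0.25)
  # the hard core is essentially empty
  expect_lt(max(prof$g[prof$r_centers < 0.8]), 0.2)
})
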