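test_that("binned raw counts equal the brute-force pair scan", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(10:60, 1)
    box <- periodic_box(runif(3, 8, 16))
    nf <- sample(1:3, 1)
    coords <- array(runif(n * 3 * nf, -5, 25), c(n, 3, nf))  # deliberately unwrapped
    species <- sample(c("A", "B"), n, replace = TRUE)
    if (sum(species == "A") < 2) species[1:2] <- "A"
    if (sum(species == "B") < 2) species[3:4] <- "B"
    tr <- trajectory(box, species, coords, timestep = 1, wrapped = FALSE)
    bw <- runif(1, 0.05, 0.4)
    rmax <- min(box) / 2 * runif(1, 0.6, 0.99)
    for (pair in list(c("A", "B"), c("A", "A"))) {
      prof <- compute_rdf(tr, pair[1], pair[2], r_max = rmax, bin_width = bw)
      expect_equal(prof$raw_counts,
                   brute_rdf_counts(tr, pair[1], pair[2], prof$bin_edges))
    }
  }
})

test_that("ideal-gas normalisation gives unit pair correlation", {
  gas <- gen_ideal_gas(400, periodic_box(30), n_frames = 30, seed = 22)
  prof <- compute_rdf(gas, "gas", "gas", r_max = 14, bin_width = 0.25)
  sel <- prof$r_centers > 2
  m <- mean(prof$g[sel])
  se <- stats::sd(prof$g[sel]) / sqrt(sum(sel))
  expect_lt(abs(m - 1), 3 * se + 1e-3)
})

test_that("number conservation holds exactly", {
  tr <- gen_ideal_gas(60, periodic_box(12), n_frames = 2, seed = 23)
  prof <- compute_rdf(tr, "gas", "gas", r_max = 5, bin_width = 0.3)
  vshell <- 4 / 3 * pi * diff(prof$bin_edges^3)
  lhs <- prof$target_density * sum(prof$g * vshell)
  # mean neighbour count within r_max per particle (pairs count for both ends)
  mean_neighbours <- 2 * sum(prof$raw_counts) / prof$n_frames_averaged / 60
  expect_equal(lhs, mean_neighbours, tolerance = 1e-12)
})

test_that("cross-species profiles are symmetric in the pair", {
  tr <- gen_pair_gas(40, 2.0, periodic_box(30), seed = 24)
  p1 <- compute_rdf(tr, "A", "B", r_max = 8, bin_width = 0.2)
  p2 <- compute_rdf(tr, "B", "A", r_max = 8, bin_width = 0.2)
  expect_equal(p1$g, p2$g, tolerance = 1e-12)
})

test_that("compute_rdf validates its inputs", {
  tr <- gen_ideal_gas(10, periodic_box(10), seed = 1)
  expect_error(compute_rdf(tr, "gas", "gas", r_max = 8), "half the shortest")
  expect_error(compute_rdf(tr, "gas", "nope", r_max = 4), "not present")
  one <- trajectory(periodic_box(10), c("A", "B"),
                    array(runif(6), c(2, 3, 1)))
  expect_error(compute_rdf(one, "A", "A", r_max = 4), "at least two")
})

test_that("first_peak finds the paper-style first maximum", {
  # profile climbing to 1.10 at bin centre 1.75 then decaying
  bw <- 0.5
  vals <- c(0.00, 0.40, 0.90, 1.10, 0.95, 0.90, 1.00, 1.02, 1.00)
  prof <- make_profile(vals, bin_width = bw)   # centres 0.25, 0.75, ...
  pk <- first_peak(prof)
  expect_equal(pk$position, 1.75)
  expect_equal(pk$intensity, 1.10)
})

test_that("first_peak rejects profiles without a qualifying peak", {
  expect_error(first_peak(make_profile(seq(0, 1, length.out = 10))),
               class = "mdsolv_no_peak")
  expect_error(first_peak(make_profile(rep(1, 10))),
               class = "mdsolv_no_peak")
  # sub-prominence ripple is ignored
  expect_error(first_peak(make_profile(c(1, 1.02, 1, 1.01, 1))),
               class = "mdsolv_no_peak")
  expect_error(first_peak(make_profile(numeric(0))),
               class = "mdsolv_empty_profile")
})

test_that("first_peak honours min_position", {
  vals <- c(0.1, 2.0, 0.1, 0.1, 1.5, 0.1)
  prof <- make_profile(vals, bin_width = 1)   # centres 0.5, 1.5, ...
  expect_equal(first_peak(prof)$position, 1.5)
  expect_equal(first_peak(prof, min_position = 3)$position, 4.5)
})

test_that("peak_trend classifies temperature trends", {
  mk <- function(intensity) {
    vals <- c(0.1, 0.3, intensity, 0.4, 0.9, 1.0, 1.0)
    make_profile(vals, bin_width = 0.5)
  }
  temps <- c(363.15, 393.15, 413.15, 423.15, 453.15)

  up <- setNames(lapply(c(1.03, 1.34, 1.42, 1.45, 1.56), mk), temps)
  tr_up <- peak_trend(up)
  expect_equal(attr(tr_up, "verdict"), "increasing")
  expect_equal(tr_up$peak_intensity, c(1.03, 1.34, 1.42, 1.45, 1.56))

  down <- setNames(lapply(c(1.10, 1.08, 1.07, 1.01, 0.90), mk), temps)
  expect_equal(attr(peak_trend(down), "verdict"), "decreasing")

  flat <- setNames(lapply(c(1.2, 1.2), mk), c(363.15, 393.15))
  expect_equal(attr(peak_trend(flat), "verdict"), "neither")

  bad <- list(`363.15` = mk(1.1), `393.15` = make_profile(rep(1.2, 7), 0.7))
  expect_error(peak_trend(bad), "inconsistent binning")
})
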