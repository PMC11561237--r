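# Independent brute-force oracles.  These deliberately share no code with
# the package internals: the minimum image is found by scanning all image
# shifts, pair counts by an O(N^2) double loop, and the MSD by the literal
# double loop over origins.

# Minimum-image displacement by exhaustive scan over image shifts in
# {-2..2} per axis (the orthorhombic minimum image is componentwise);
# exact ties at L/2 resolve to the positive representative.
brute_min_image <- function(d, box) {
  vapply(1:3, function(ax) {
    cands <- d[ax] + (-2:2) * box[ax]
    m <- min(abs(cands))
    max(cands[abs(cands) <= m + 1e-12])
  }, numeric(1))
}

# Per-bin raw pair counts by a double loop with the minimum-image rule.
brute_pair_counts <- function(xyz, idx_a, idx_b, box, edges) {
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  same <- identical(sort(idx_a), sort(idx_b))
  for (i in idx_a) {
    for (j in idx_b) {
      if (same && j <= i) next
      if (!same && j == i) next
      d <- xyz[i, ] - xyz[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r < edges[nb + 1L]) {
        b <- findInterval(r, edges)
        if (b >= 1L && b <= nb) counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# Sum of compute_rdf-style raw counts over all frames, brute force.
brute_rdf_counts <- function(traj, species_a, species_b, edges) {
  box <- as.numeric(traj$box)
  idx_a <- which(traj$species == species_a)
  idx_b <- which(traj$species == species_b)
  total <- 0
  for (k in seq_len(dim(traj$coords)[3])) {
    xyz <- traj$coords[, , k]
    xyz <- xyz - rep(box, each = nrow(xyz)) * floor(xyz / rep(box, each = nrow(xyz)))
    total <- total + brute_pair_counts(xyz, idx_a, idx_b, box, edges)
  }
  total
}

# All-origin (or strided) MSD by the literal double loop, in m^2 vs s.
brute_msd <- function(traj, species, max_lag, stride = 1L) {
  idx <- which(traj$species == species)
  X <- traj$coords[idx, , , drop = FALSE] * 1e-10
  nf <- dim(X)[3]
  vapply(seq_len(max_lag), function(k) {
    t0 <- seq.int(1L, nf - k, by = stride)
    acc <- 0
    for (t in t0) {
      d <- X[, , t + k] - X[, , t]
      acc <- acc + sum(d^2)
    }
    acc / (length(t0) * length(idx))
  }, numeric(1))
}

# Hand-built RDF profile for peak-finding tests.
make_profile <- function(values, bin_width = 0.05, pair = c("A", "B")) {
  edges <- seq(0, by = bin_width, length.out = length(values) + 1L)
  structure(list(bin_edges = edges,
                 r_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 g = values, raw_counts = rep(NA_real_, length(values)),
                 pair = pair, n_frames_averaged = 1L,
                 target_density = 1, box = mdsolv::periodic_box(100)),
            class = "rdf_profile")
}

# Small random trajectory for I/O round trips.
random_trajectory <- function(n = 5L, nf = 3L, seed = 1L) {
  set.seed(seed)
  box <- mdsolv::periodic_box(round(runif(3, 8, 20), 3))
  coords <- array(round(runif(n * 3 * nf, 0, min(box)), 6), c(n, 3L, nf))
  mdsolv::trajectory(box, sample(c("O_water", "H_water", "O_OHcurcumin"),
                                 n, replace = TRUE),
                     coords, timestep = 500, wrapped = sample(c(TRUE, FALSE), 1))
}
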