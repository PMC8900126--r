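test_that("single-charge potential matches the closed-form hand value", {
  ch <- data.frame(x = 0, y = 0, z = 0, q = -1)
  # oracle by hand: 1000 * 1.439964/(80*1) * exp(-1/lambda), lambda = 0.304/sqrt(0.1)
  lambda <- 0.304 / sqrt(0.1)
  hand <- -1000 * 1.439964 / 80 * exp(-1 / lambda)
  phi <- screened_potential(ch, matrix(c(1, 0, 0), 1), eps_r = 80,
                            ionic_strength = 0.1)
  expect_equal(phi, hand, tolerance = 1e-12)
  expect_equal(phi, -6.3, tolerance = 0.02)
  # unscreened unit charge at 1 nm in eps_r 80 is ~18 mV
  phi0 <- screened_potential(data.frame(x = 0, y = 0, z = 0, q = 1),
                             matrix(c(1, 0, 0), 1), ionic_strength = 1e-12)
  expect_equal(phi0, 18.0, tolerance = 0.01)
})

test_that("engine agrees with the unvectorized oracle at random probes", {
  set.seed(101)
  charges <- data.frame(x = runif(15, -2, 2), y = runif(15, -2, 2),
                        z = runif(15, -2, 2), q = sample(c(-1, -1, -1, 1), 15, TRUE))
  probes <- matrix(runif(60, -4, 4), ncol = 3)
  got <- screened_potential(charges, probes, eps_r = 80, ionic_strength = 0.15)
  want <- oracle_screened_potential(charges, probes, 80, 0.15)
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), 1e-9)
})

test_that("grid is a superposition and equals the engine at voxel centers", {
  a <- data.frame(x = 0, y = 0, z = 0, q = -1)
  b <- data.frame(x = 1, y = 0.4, z = -0.2, q = -2)
  spec <- list(origin = c(-1, -1, -1), spacing = 0.25, dim = c(9L, 9L, 9L))
  ga <- compute_potential_grid(a, grid = spec)
  gb <- compute_potential_grid(b, grid = spec)
  gab <- compute_potential_grid(rbind(a, b), grid = spec)
  expect_equal(gab$values, ga$values + gb$values, tolerance = 1e-12)
  # voxel values = engine evaluated at voxel coordinates with the cap
  ijk <- as.matrix(expand.grid(1:9, 1:9, 1:9))[c(1, 100, 500), ]
  pts <- cmcnano:::voxel_coords(gab, ijk)
  expect_equal(gab$values[ijk], screened_potential(rbind(a, b), pts, cap = 0.25),
               tolerance = 1e-12)
  expect_equal(gab$lambda_d, 0.304 / sqrt(0.1), tolerance = 1e-12)
})

test_that("infinite screening kills the potential beyond the cap radius", {
  ch <- data.frame(x = 0, y = 0, z = 0, q = -1)
  spec <- list(origin = c(-1, -1, -1), spacing = 0.2, dim = c(11L, 11L, 11L))
  g <- compute_potential_grid(ch, grid = spec, ionic_strength = 1e8)
  ijk <- as.matrix(expand.grid(1:11, 1:11, 1:11))
  far <- sqrt(rowSums(cmcnano:::voxel_coords(g, ijk)^2)) > 0.2
  expect_lt(max(abs(g$values[ijk[far, ]])), 1e-12)
})

test_that("weaker screening weakly deepens every off-cap voxel", {
  set.seed(7)
  charges <- data.frame(x = runif(5), y = runif(5), z = runif(5), q = -1)
  spec <- list(origin = c(-1, -1, -1), spacing = 0.25, dim = c(10L, 10L, 10L))
  g_hi <- compute_potential_grid(charges, grid = spec, ionic_strength = 0.5)
  g_lo <- compute_potential_grid(charges, grid = spec, ionic_strength = 0.05)
  expect_true(all(g_lo$values <= g_hi$values + 1e-12))  # all-negative field
  expect_true(all(abs(g_lo$values) >= abs(g_hi$values) - 1e-12))
})

test_that("zero-charge input warns and yields a zero grid with no hotspots", {
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      q = numeric(0))
  expect_warning(g <- compute_potential_grid(empty), "no charges")
  expect_true(all(g$values == 0))
  expect_length(find_hotspots(g, -1, 1), 0)
  expect_error(compute_potential_grid(empty, spacing = 0), "spacing")
})

test_that("hotspots: tri-charged sites are deeper and larger than mono sites", {
  tri <- data.frame(x = c(0, 0.1, -0.1), y = c(0.1, -0.1, 0), z = 0, q = -1)
  mono <- data.frame(x = 4, y = 0, z = 0, q = -1)
  g <- compute_potential_grid(rbind(tri, mono), spacing = 0.2, padding = 1.2)
  hs <- find_hotspots(g, threshold_mV = -10, min_voxels = 1)
  expect_equal(length(hs), 2)
  # sorted deepest first; the -3e site must be deeper and at least as large
  expect_lt(hs[[1]]$min_mV, hs[[2]]$min_mV)
  expect_gte(hs[[1]]$n_voxels, hs[[2]]$n_voxels)
  # oracle: direct analytic comparison at the two centers
  phi_tri <- screened_potential(rbind(tri, mono), matrix(c(0, 0, 0), 1))
  phi_mono <- screened_potential(rbind(tri, mono), matrix(c(4.1, 0, 0), 1))
  expect_lt(phi_tri, phi_mono)
  expect_error(find_hotspots(g, threshold_mV = 5), "negative")
})

test_that("hotspot detection is translation invariant", {
  set.seed(12)
  charges <- data.frame(x = runif(6), y = runif(6), z = runif(6), q = -1)
  spec <- list(origin = c(-1, -1, -1), spacing = 0.2, dim = c(12L, 12L, 12L))
  g1 <- compute_potential_grid(charges, grid = spec)
  shift <- c(3.7, -1.1, 0.9)
  charges2 <- charges
  charges2[, 1:3] <- sweep(as.matrix(charges[, 1:3]), 2, shift, "+")
  spec2 <- spec; spec2$origin <- spec$origin + shift
  g2 <- compute_potential_grid(charges2, grid = spec2)
  h1 <- find_hotspots(g1, -15, 2); h2 <- find_hotspots(g2, -15, 2)
  expect_gt(length(h1), 0)
  expect_equal(length(h1), length(h2))
  expect_equal(vapply(h1, `[[`, numeric(1), "n_voxels"),
               vapply(h2, `[[`, numeric(1), "n_voxels"))
  expect_equal(vapply(h1, `[[`, numeric(1), "min_mV"),
               vapply(h2, `[[`, numeric(1), "min_mV"), tolerance = 1e-9)
})

test_that("Zn placement: empty, additive over disjoint hotspots, bounded by max packing", {
  empty <- place_zn_ions(structure(list(values = array(0, c(2, 2, 2))),
                                   class = "potential_grid"), list())
  expect_equal(nrow(empty$placements), 0)

  two <- data.frame(x = c(0, 0, 5, 5), y = c(0, 0.1, 0, 0.1), z = 0,
                    q = c(-2, -2, -2, -2))
  g <- compute_potential_grid(two, spacing = 0.2, padding = 1)
  hs <- find_hotspots(g, -20, 1)
  expect_equal(length(hs), 2)
  zn_all <- place_zn_ions(g, hs, min_separation = 0.4)
  zn_1 <- place_zn_ions(g, hs[1], min_separation = 0.4)
  zn_2 <- place_zn_ions(g, hs[2], min_separation = 0.4)
  expect_equal(nrow(zn_all$placements),
               nrow(zn_1$placements) + nrow(zn_2$placements))
  expect_equal(sum(zn_all$occupancy), nrow(zn_all$placements))
  # greedy occupancy cannot exceed the exhaustive max packing of the voxel set
  vox <- hs[[1]]$coords
  if (nrow(vox) > 12) vox <- vox[1:12, , drop = FALSE]
  hs_small <- hs[1]
  hs_small[[1]]$coords <- vox
  hs_small[[1]]$voxels <- hs[[1]]$voxels[seq_len(nrow(vox)), , drop = FALSE]
  zn_small <- place_zn_ions(g, hs_small, min_separation = 0.4)
  expect_lte(nrow(zn_small$placements), oracle_max_packing(vox, 0.4))
  # min-separation respected
  if (nrow(zn_all$placements) > 1) {
    dmin <- min(dist(zn_all$placements[, c("x", "y", "z")]))
    expect_gte(dmin, 0.4)
  }
})
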