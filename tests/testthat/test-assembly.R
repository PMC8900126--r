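make_pool <- function(amide_fraction, n = 5, N = 20, seed0 = 40) {
  d <- default_dist()
  lapply(seq_len(n), function(i)
    embed_chain(generate_chain(d, N, amide_fraction = amide_fraction,
                               seed = seed0 + i),
                lp = 3, seed = seed0 + 100 + i))
}

test_that("packing density follows from composition arithmetic", {
  pool <- make_pool(200 / 900)
  empty <- pack_chains(pool, 0, box_edge = 100, seed = 1)
  expect_equal(empty$density, 0)

  one <- pack_chains(pool[1], 1, box_edge = 100, seed = 1)
  m <- chain_statistics(pool[[1]]$chain)$mean_monomer_mass * 20
  expect_equal(one$density, m / (6.02214076e23 * (100e-8)^3), tolerance = 1e-12)
  # both conventions, hand arithmetic
  m_acid <- chain_statistics(pool[[1]]$chain, "free_acid")$mean_monomer_mass * 20
  rep_ <- packed_density_report(one)
  expect_equal(unname(rep_["free_acid"]), m_acid / (6.02214076e23 * (100e-8)^3),
               tolerance = 1e-12)
  expect_gt(rep_["sodium_salt"], rep_["free_acid"])
})

test_that("the published packing geometry gives ~0.5 g/cm^3, not 0.6, by mass arithmetic", {
  # 2700 100-mers in a 600 A box: recompute under both conventions and record
  # the discrepancy with the printed ~0.6 rather than forcing it
  na <- bulk_density(2700, 100, 600, mass_convention = "sodium_salt")
  ha <- bulk_density(2700, 100, 600, mass_convention = "free_acid")
  expect_equal(na, 0.523, tolerance = 0.01)
  expect_equal(ha, 0.491, tolerance = 0.01)
  expect_lt(abs(na - 0.6) / 0.6, 0.2)  # order-of-magnitude agreement only
  # oracle: hand mass/volume arithmetic from the monomer mass table
  lib <- build_monomer_library()
  m_mono <- lib$mass[lib$code == "OH.OH.OH"] +
    0.9 * (700 / 900) * (lib$mass[lib$code == "CM.OH.OH"] -
                           lib$mass[lib$code == "OH.OH.OH"]) +
    0.9 * (200 / 900) * (lib$mass[lib$code == "CM8.OH.OH"] -
                           lib$mass[lib$code == "OH.OH.OH"])
  expect_equal(na, 2700 * 100 * m_mono / (6.02214076e23 * (600e-8)^3),
               tolerance = 1e-12)
})

test_that("overlap rejection keeps inter-chain contacts above the cutoff", {
  pool <- make_pool(200 / 900)
  sys <- pack_chains(pool, 12, box_edge = 80, contact_distance = 0.3, seed = 2)
  expect_equal(sys$n_chains, 12)
  xyz <- as.matrix(sys$beads[, c("x", "y", "z")])
  d <- cmcnano:::pairwise_min_image_dist(xyz, box = sys$box_nm)
  inter <- outer(sys$beads$chain, sys$beads$chain, "!=")
  expect_gte(min(d[inter]), 0.3)
  # beads inside the box
  expect_true(all(xyz >= 0 & xyz < sys$box_nm))
  # determinism
  sys2 <- pack_chains(pool, 12, box_edge = 80, contact_distance = 0.3, seed = 2)
  expect_identical(sys$beads, sys2$beads)
  # impossible box errors with the achieved count
  expect_error(pack_chains(pool, 500, box_edge = 30, contact_distance = 0.5,
                           max_attempts = 5, seed = 1),
               "packing failed")
})

test_that("cluster detection equals the brute-force union-find oracle (periodic)", {
  pool <- make_pool(200 / 900)
  for (seed in 1:4) {
    sys <- pack_chains(pool, 10, box_edge = 60, contact_distance = 0.2,
                       seed = seed)
    for (type in c("alkyl", "charge")) {
      cutoff <- if (type == "alkyl") 0.6 else 0.8
      rep_ <- cmcnano:::.detect_bead_clusters(sys, type, cutoff)
      rows <- which(sys$beads$type == type)
      xyz <- as.matrix(sys$beads[rows, c("x", "y", "z")])
      want <- oracle_clusters(xyz, cutoff, box = sys$box_nm)
      got <- lapply(rep_$clusters, function(cl) match(cl$members, rows))
      expect_equal(canon_clusters(got), canon_clusters(want))
    }
  }
})

test_that("clustering is exact across periodic boundaries (planted wrap case)", {
  # two beads 0.2 nm apart through the boundary, plus a far-away singleton
  beads <- data.frame(x = c(0.05, 5.95, 3), y = c(1, 1, 4), z = c(1, 1, 4),
                      type = "alkyl", chain = 1:3)
  sys <- list(beads = beads, box_nm = 6, periodic = TRUE)
  rep_ <- detect_hydrophobic_clusters(sys, cutoff = 0.6)
  expect_equal(length(rep_$clusters), 1)
  expect_equal(sort(rep_$clusters[[1]]$members), c(1L, 2L))
  # non-periodic reading of the same coordinates: no cluster
  sys$periodic <- FALSE
  expect_length(detect_hydrophobic_clusters(sys, cutoff = 0.6)$clusters, 0)
})

test_that("pure CMC systems have no alkyl beads, hence no hydrophobic clusters and no flagged sites", {
  pool <- make_pool(0)
  sys <- pack_chains(pool, 10, box_edge = 60, contact_distance = 0.2, seed = 3)
  expect_equal(sum(sys$beads$type == "alkyl"), 0)
  hc <- detect_hydrophobic_clusters(sys)
  expect_length(hc$clusters, 0)
  ac <- detect_acidic_clusters_near(sys, hc)
  expect_false(any(vapply(ac$clusters, `[[`, logical(1), "flagged")))
})

test_that("planted 5-alkyl/3-chain + 9-acid at 12 A fixture is detected exactly and flagged", {
  sys <- gen_planted_system(planted_alkyl_cluster_sizes = 5,
                            planted_acid_cluster_sizes = 9,
                            alkyl_acid_distance = 12,
                            chains_per_cluster = 3, seed = 99)
  truth <- attr(sys, "truth")
  hc <- detect_hydrophobic_clusters(sys, cutoff = 0.6)
  expect_equal(length(hc$clusters), 1)
  expect_equal(hc$clusters[[1]]$size, truth$alkyl_sizes)
  expect_equal(hc$clusters[[1]]$n_chains, truth$chains_per_cluster)
  ac <- detect_acidic_clusters_near(sys, hc, acid_cutoff = 0.8)
  expect_equal(length(ac$clusters), 1)
  expect_equal(ac$clusters[[1]]$size, truth$acid_sizes)
  expect_true(ac$clusters[[1]]$flagged)
  expect_equal(ac$clusters[[1]]$alkyl_distance_A, truth$alkyl_acid_distance_A,
               tolerance = 1e-6)
  # oracle: brute-force pairwise distances confirm the memberships
  rows <- which(sys$beads$type == "alkyl")
  want <- oracle_clusters(as.matrix(sys$beads[rows, c("x", "y", "z")]), 0.6,
                          sys$box_nm)
  expect_equal(length(want), 1)
  expect_equal(length(want[[1]]), 5)
})

test_that("acid clusters outside the 10-15 A window are detected but not flagged", {
  far <- gen_planted_system(planted_acid_cluster_sizes = 9,
                            alkyl_acid_distance = 30, box_edge = 200, seed = 5)
  hc <- detect_hydrophobic_clusters(far, cutoff = 0.6)
  ac <- detect_acidic_clusters_near(far, hc)
  expect_equal(length(ac$clusters), 1)
  expect_false(ac$clusters[[1]]$flagged)
  expect_equal(ac$clusters[[1]]$alkyl_distance_A, 30, tolerance = 1e-6)
  # a cutoff below the minimum pairwise distance finds nothing
  expect_length(detect_hydrophobic_clusters(far, cutoff = 0.005)$clusters, 0)
  # no hydrophobic clusters at all -> nothing can be flagged
  none <- detect_acidic_clusters_near(far, list(clusters = list()))
  expect_false(any(vapply(none$clusters, `[[`, logical(1), "flagged")))
  expect_equal(none$clusters[[1]]$alkyl_distance_A, Inf)
})
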