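# DPD engine: configuration arithmetic, determinism, thermostat sanity at
# small scale, bond kinetics, and the block-level structural analysis.

test_that("particle counts follow density x volume and the block layout", {
  # published-scale configuration
  pub <- sim_params(box = c(50, 50, 50), density = 3, n_blocks = 64L,
                    inactive_per_block = 500L, active_per_block = 50L)
  expect_equal(total_particles(pub), 375000)

  # desk-scale configuration: chain length checks
  desk <- sim_params(box = c(16, 16, 16), n_blocks = 8L,
                     inactive_per_block = 55L, active_per_block = 5L)
  cb <- laminatad:::chain_blocks(desk)
  expect_equal(nrow(cb), 480)
  expect_equal(sum(cb$inactive), 440)
  expect_equal(length(unique(cb$block)), 8)
})

test_that("zero-solvent configurations hold only chain and wall particles", {
  p <- sim_params(box = c(8, 8, 8), n_blocks = 2L, inactive_per_block = 10L,
                  active_per_block = 2L, no_solvent = TRUE, n_steps = 10L,
                  n_runs = 1L, snapshot_interval = 10L, seed = 1L)
  r <- run_simulation(p)
  # wall lattice on an 8x8 face at unit spacing: 8 columns x 9 rows
  n_wall_expected <- 8 * floor(8 / (sqrt(3) / 2))
  expect_equal(r[[1]]$n_particles, 24 + n_wall_expected)
})

test_that("identical seeds reproduce trajectories bit for bit", {
  p <- sim_params(box = c(8, 8, 8), n_blocks = 2L, inactive_per_block = 10L,
                  active_per_block = 2L, n_steps = 600L, n_runs = 1L,
                  snapshot_interval = 200L, seed = 42L)
  r1 <- run_simulation(p)
  r2 <- run_simulation(p)
  expect_identical(r1[[1]]$snapshots, r2[[1]]$snapshots)
  p2 <- p; p2$seed <- 43L
  r3 <- run_simulation(p2)
  expect_false(identical(r1[[1]]$snapshots, r3[[1]]$snapshots))
})

test_that("n_steps = 0 returns the initial configuration only", {
  p <- sim_params(box = c(8, 8, 8), n_blocks = 2L, inactive_per_block = 10L,
                  active_per_block = 2L, n_steps = 0L, n_runs = 1L,
                  snapshot_interval = 100L, seed = 3L)
  r <- run_simulation(p)
  expect_equal(length(r[[1]]$snapshots), 1)
  expect_equal(r[[1]]$snap_steps, 0)
  # chain confined to the box, off the walls
  z <- r[[1]]$snapshots[[1]][, 3]
  expect_true(all(z >= 0 & z <= 8))
})

test_that("wall-free periodic solvent conserves momentum and holds kT", {
  p <- sim_params(box = c(6, 6, 6), n_blocks = 0L, inactive_per_block = 0L,
                  active_per_block = 0L, wall = FALSE, check_interval = 0L,
                  n_steps = 2000L, n_runs = 1L, snapshot_interval = 500L,
                  seed = 7L)
  r <- run_simulation(p, track_momentum = TRUE)
  expect_lt(r[[1]]$max_momentum, 1e-9)      # machine precision, 648 particles
  expect_equal(mean(r[[1]]$temps), 1, tolerance = 0.05)
})

test_that("bond kinetics follow the two-state Markov closed form", {
  b <- bond_toy(0.001, 0.01, 4e4, seed = 3L)
  frac <- mean(b[-(1:5000)])
  # stationary mean 1/11 within 3 SE; the chain decorrelates over
  # ~1/(p_on + p_off) = 91 checks, so ~385 independent samples
  se <- sqrt((1 / 11) * (10 / 11) / (35000 / 91))
  expect_lt(abs(frac - 1 / 11), 3 * se)
  # symmetric rates give 1/2
  b2 <- bond_toy(0.05, 0.05, 2e4, seed = 4L)
  expect_equal(mean(b2[-(1:2000)]), 0.5, tolerance = 0.1)
})

test_that("gyration analysis is exact on a regular tetrahedron", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) + 5
  p <- sim_params(n_blocks = 1L, inactive_per_block = 4L,
                  active_per_block = 0L)
  bs <- block_summary(tet, p)
  expect_equal(bs$lambda1, bs$lambda3, tolerance = 1e-12)  # isotropic
  expect_equal(bs$oblateness, 1, tolerance = 1e-12)
  # eigenvalues of the tetrahedron gyration tensor are all 1 here
  expect_equal(bs$lambda1, 1, tolerance = 1e-12)
  expect_equal(bs$volume_proxy, 4 * pi / 3 * 3^1.5, tolerance = 1e-9)
})

test_that("surface contacts and the LAD flag follow the r_cut rule", {
  p <- sim_params(n_blocks = 2L, inactive_per_block = 4L,
                  active_per_block = 0L, r_cut = 1)
  pos <- rbind(
    matrix(c(1, 1, 5, 2, 1, 5, 3, 1, 5, 4, 1, 5), 4, 3, byrow = TRUE),  # far
    matrix(c(1, 1, 0.5, 2, 1, 5, 3, 1, 5, 4, 1, 5), 4, 3, byrow = TRUE))
  bs <- block_summary(pos, p)
  expect_equal(bs$n_surface_contacts, c(0, 1))
  expect_equal(bs$is_lad, c(FALSE, TRUE))
})

test_that("intra-block contacts exclude backbone neighbours", {
  p <- sim_params(n_blocks = 1L, inactive_per_block = 4L,
                  active_per_block = 0L, r_cut = 1)
  # beads on a straight line, spacing 0.5: neighbours |i-j|=1 excluded,
  # |i-j|=2 pairs are at distance 1.0 (not < r_cut), so zero contacts
  line <- cbind(seq(1, 2.5, 0.5), 1, 5)
  expect_equal(block_summary(line, p)$n_intra_contacts, 0)
  # tighter spacing 0.4: |i-j|=2 pairs at 0.8 count (two of them)
  line2 <- cbind(seq(1, 2.2, 0.4), 1, 5)
  expect_equal(block_summary(line2, p)$n_intra_contacts, 2)
})

test_that("ensemble distance maps average snapshots of coarse-grained segments", {
  # single straight-line conformation: distances proportional to |i-j|
  line <- cbind(seq_len(40), 1, 1)
  m <- ensemble_distance_map(list(line), coarse_grain = 10L)
  expect_equal(dim(m), c(4, 4))
  expect_equal(m[1, 2], 10)
  expect_equal(m[1, 4], 30)
  # two snapshots: elementwise mean
  line2 <- cbind(seq_len(40) * 2, 1, 1)
  m2 <- ensemble_distance_map(list(line, line2), coarse_grain = 10L)
  expect_equal(m2[1, 2], 15)
})
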