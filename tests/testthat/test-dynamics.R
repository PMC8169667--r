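test_that("Maxwell-Boltzmann velocities satisfy equipartition and zero momentum", {
  n <- 10000
  topo <- bead_topology(rep("W", n), mass = 72, group = "solvent",
                        residue_id = seq_len(n))
  v <- init_velocities(topo, T = 300, seed = 7)
  ke <- 0.5 * sum(72 * v^2) * 1e4
  t_kin <- 2 * ke / (3 * n * 0.0083144621)
  expect_lt(abs(t_kin - 300) / 300, 0.02)
  expect_lt(max(abs(colSums(72 * v))), 1e-8)
  expect_identical(v, init_velocities(topo, T = 300, seed = 7))
  expect_error(init_velocities(topo, T = -1), "positive")
})

test_that("zero forces and zero velocities leave coordinates unchanged", {
  s <- lj_dimer(60) # beyond cutoff: no interaction
  tr <- run_nvt(s$conf, s$topo, s$ff, T = 300, dt = 10, n_steps = 50,
                tau = Inf, velocities = matrix(0, 2, 3))
  expect_identical(tr$final$coords, s$conf$coords)
})

test_that("the NVE limit conserves energy, improving ~4x when dt halves", {
  s <- lj_dimer(5.5)
  drift <- sapply(c(1, 0.5), function(dt) {
    tr <- run_nvt(s$conf, s$topo, s$ff, T = 300, dt = dt,
                  n_steps = round(1000 / dt), tau = Inf, seed = 3,
                  sample_every = 10)
    et <- tr$thermo$epot + tr$thermo$ekin
    max(abs(et - et[1]))
  })
  expect_lt(drift[1], 1e-3)
  expect_gt(drift[1] / drift[2], 3)
})

test_that("the Berendsen thermostat holds the target temperature", {
  s <- make_lj_cluster(13, seed = 1)
  centre <- colMeans(s$conf$coords)
  tr <- run_nvt(s$conf, s$topo, s$ff, T = 600, dt = 10, n_steps = 1000,
                tau = 100, seed = 4, sample_every = 10,
                container = list(center = centre, radius = 30, k = 10))
  t_mean <- mean(utils::tail(tr$thermo$temp, 50))
  expect_lt(abs(t_mean - 600) / 600, 0.10)
})

test_that("trajectories are reproducible for a fixed seed", {
  s <- make_lj_cluster(7, seed = 2)
  tr1 <- run_nvt(s$conf, s$topo, s$ff, T = 600, dt = 10, n_steps = 100,
                 tau = 100, seed = 9)
  tr2 <- run_nvt(s$conf, s$topo, s$ff, T = 600, dt = 10, n_steps = 100,
                 tau = 100, seed = 9)
  expect_identical(tr1$final$coords, tr2$final$coords)
  expect_identical(tr1$thermo, tr2$thermo)
})

test_that("overlapping beads abort with a diagnostic naming the pair", {
  topo <- bead_topology(c("A", "A"), mass = 72, group = "ligand")
  ff <- ff_params("A", sigma = 4.7, epsilon = 5)
  conf <- conformation(rbind(c(0, 0, 0), c(1e-4, 0, 0)))
  expect_error(
    run_nvt(conf, topo, ff, T = 300, dt = 10, n_steps = 10, tau = 100,
            velocities = matrix(0, 2, 3)),
    "beads 1 and 2")
})

test_that("trajectory constructor validates times and frame counts", {
  fr <- list(matrix(0, 2, 3), matrix(1, 2, 3))
  expect_error(trajectory(fr, times = c(2, 1)), "increasing")
  tr <- trajectory(fr, times = c(0, 10))
  expect_equal(n_frames(tr), 2)
})
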