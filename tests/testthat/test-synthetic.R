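test_that("small LJ clusters minimize to their analytic global minima", {
  s2 <- make_lj_cluster(2, epsilon = 1, seed = 1)
  m2 <- local_minimize(s2$conf, s2$topo, s2$ff, force_tol = 1e-6,
                       max_iter = 20000)
  expect_lt(abs(m2$energy - (-1)), 1e-6)
  s3 <- make_lj_cluster(3, epsilon = 1, seed = 1)
  m3 <- local_minimize(s3$conf, s3$topo, s3$ff, force_tol = 1e-6,
                       max_iter = 20000)
  expect_lt(abs(m3$energy - (-3)), 1e-4)
})

test_that("cluster generation is reproducible and non-overlapping", {
  s <- make_lj_cluster(10, seed = 5)
  s2 <- make_lj_cluster(10, seed = 5)
  expect_identical(s$conf$coords, s2$conf$coords)
  expect_gt(min(dist(s$conf$coords)), 0.8 * 4.7)
  expect_true(all(sqrt(rowSums(s$conf$coords^2)) <= 2 * 10^(1 / 3) * 4.7))
  expect_error(make_lj_cluster(1), ">= 2")
})

test_that("the designed groove pose beats the flat-face pose", {
  pg <- make_pocket_system(n_ligand = 4, seed = 1, pose = "groove")
  pf <- make_pocket_system(n_ligand = 4, seed = 1, pose = "flat")
  eg <- group_interaction_energy(pg$conf, pg$topo, pg$ff)
  ef <- group_interaction_energy(pf$conf, pf$topo, pf$ff)
  expect_lt(eg, ef)
  expect_lt(eg, 0)
})

test_that("the pocket system is built to its own specification", {
  p <- make_pocket_system(n_ligand = 5, seed = 2,
                          charge_pattern = "zwitterion")
  topo <- p$topo
  # ligand bonds at rest length
  lig <- group_indices(topo, "ligand")
  lb <- topo$bonds[topo$bonds$i %in% lig & topo$bonds$j %in% lig, ]
  r <- sqrt(rowSums((p$conf$coords[lb$i, ] - p$conf$coords[lb$j, ])^2))
  expect_lt(max(abs(r - lb$r0)), 1e-6)
  # designed net charge is zero before ions
  expect_lt(abs(sum(topo$charge)), 1e-9)
  # group bookkeeping
  expect_equal(sum(topo$group == "ligand"), 10)
  expect_equal(sum(topo$group == "receptor"), 132)
  expect_equal(sort(unique(topo$residue_id[lig])), 1:5)
  expect_true(all(topo$backbone[lig] == rep(c(TRUE, FALSE), 5)))
  # finite energy, no hard-core overlap
  expect_true(is.finite(total_energy(p$conf, topo, p$ff)))
  expect_gt(min(dist(p$conf$coords)), 3)
})

test_that("solvation reaches the target density while keeping distances", {
  base <- make_pocket_system(n_ligand = 3, seed = 3)
  conf <- conformation(sweep(base$conf$coords, 2, c(-10, -10, -20)),
                       box = c(56, 56, 56))
  sol <- solvate(conf, base$topo, density = 0.3, min_dist = 5,
                 water_min_dist = 3, seed = 4)
  wat <- group_indices(sol$topo, "solvent")
  solute <- setdiff(seq_len(n_beads(sol$topo)), wat)
  for (w in sample(wat, 25)) {
    d <- sweep(sol$conf$coords[solute, , drop = FALSE], 2,
               sol$conf$coords[w, ])
    d <- d - 56 * round(d / 56)
    expect_gte(sqrt(min(rowSums(d^2))), 5)
  }
  dens <- sum(sol$topo$mass) / prod(conf$box) * 1.66053906660
  expect_lt(abs(dens - 0.3) / 0.3, 0.03)
  # reproducible
  sol2 <- solvate(conf, base$topo, density = 0.3, min_dist = 5,
                  water_min_dist = 3, seed = 4)
  expect_identical(sol$conf$coords, sol2$conf$coords)
  expect_error(solvate(base$conf, base$topo), "periodic")
})

test_that("counterions neutralize by replacing solvent beads", {
  n <- 30
  topo <- bead_topology(
    c(rep("L", 4), rep("W", n - 4)), mass = 72,
    charge = c(rep(-1, 4), rep(0, n - 4)),
    group = c(rep("ligand", 4), rep("solvent", n - 4)),
    residue_id = seq_len(n))
  conf <- conformation(matrix(runif(3 * n, 0, 30), n, 3))
  out <- add_counterions(topo, conf, ion_charge = 1, seed = 5)
  expect_equal(sum(out$topo$charge), 0)
  expect_equal(sum(out$topo$group == "ion"), 4)
  expect_equal(n_beads(out$topo), n) # replacement conserves bead count
  expect_identical(out$conf$coords, conf$coords)
  # already neutral: unchanged
  out2 <- add_counterions(out$topo, out$conf, ion_charge = 1)
  expect_identical(out2$topo, out$topo)
  # non-neutralizable charge
  topo$charge[1] <- -0.5
  expect_error(add_counterions(topo, conf, ion_charge = 1), "neutralized")
})
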