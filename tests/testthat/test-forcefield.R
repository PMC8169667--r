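test_that("nonbonded pairs beyond the cutoff contribute exactly zero", {
  s <- lj_dimer(13, r_cut = 12)
  expect_identical(total_energy(s$conf, s$topo, s$ff), 0)
  expect_identical(max(abs(forces(s$conf, s$topo, s$ff))), 0)
})

test_that("LJ dimer at 2^(1/6) sigma gives -epsilon and zero force", {
  r_min <- 2^(1 / 6) * 4.7
  s <- lj_dimer(r_min)
  expect_equal(total_energy(s$conf, s$topo, s$ff), -1, tolerance = 1e-12)
  expect_lt(max(abs(forces(s$conf, s$topo, s$ff))), 1e-10)
})

test_that("a bonded pair at its rest length has zero energy", {
  topo <- bead_topology(c("A", "A"), mass = 72, group = "ligand",
                        bonds = data.frame(i = 1, j = 2, r0 = 4, k = 50))
  ff <- ff_params("A", sigma = 4.7, epsilon = 1)
  conf <- conformation(rbind(c(0, 0, 0), c(4, 0, 0)))
  # the bonded pair is excluded from nonbonded terms, so the total is zero
  expect_equal(total_energy(conf, topo, ff), 0, tolerance = 1e-12)
  e <- total_energy(conf, topo, ff, components = TRUE)
  expect_equal(e$e_bond, 0)
  expect_equal(e$e_lj, 0)
})

test_that("an isolated bead feels no force", {
  topo <- bead_topology("A", mass = 72, group = "ligand")
  ff <- ff_params("A")
  conf <- conformation(matrix(c(1, 2, 3), 1, 3))
  expect_identical(forces(conf, topo, ff), matrix(0, 1, 3))
})

test_that("analytic forces match central differences on a random system", {
  set.seed(11)
  n <- 20
  coords <- as.matrix(expand.grid(1:3, 1:3, 1:3))[1:n, ] * 6 +
    matrix(runif(3 * n, -1, 1), n, 3)
  topo <- bead_topology(
    sample(c("A", "B"), n, replace = TRUE), mass = runif(n, 40, 100),
    charge = sample(c(-0.4, 0, 0.6), n, replace = TRUE), group = "ligand",
    bonds = data.frame(i = c(1, 3, 5), j = c(2, 4, 6), r0 = 4, k = 60),
    angles = data.frame(i = 1, j = 2, k = 3, theta0 = 110, ka = 12))
  ff <- ff_params(c("A", "B"), sigma = c(A = 4.7, B = 4.1),
                  epsilon = c(A = 2, B = 3.5))
  conf <- conformation(coords)
  f_ana <- forces(conf, topo, ff)
  h <- 1e-5
  f_num <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      cp <- coords; cp[i, k] <- cp[i, k] + h
      cm <- coords; cm[i, k] <- cm[i, k] - h
      f_num[i, k] <- -(total_energy(conformation(cp), topo, ff) -
                         total_energy(conformation(cm), topo, ff)) / (2 * h)
    }
  }
  expect_lt(max(abs(f_ana - f_num)), 1e-4)
})

test_that("energy is invariant under rigid motions (non-periodic)", {
  s <- random_toy(21)
  conf <- conformation(s$conf$coords) # drop the box
  e0 <- total_energy(conf, s$topo, s$ff)
  set.seed(3)
  for (rep in 1:5) {
    R <- stunbh:::.random_rotation()
    t_vec <- runif(3, -20, 20)
    moved <- conformation(conf$coords %*% t(R) +
                            matrix(t_vec, nrow(conf$coords), 3, byrow = TRUE))
    expect_lt(abs(total_energy(moved, s$topo, s$ff) - e0), 1e-8)
  }
})

test_that("the switched potential is continuous and vanishes at the cutoff", {
  for (r in c(9, 12)) { # switch start and cutoff
    below <- lj_dimer(r - 1e-7, shift = TRUE, r_cut = 12)
    above <- lj_dimer(r + 1e-7, shift = TRUE, r_cut = 12)
    below$ff$lj_shift_start <- 9; above$ff$lj_shift_start <- 9
    e1 <- total_energy(below$conf, below$topo, below$ff)
    e2 <- total_energy(above$conf, above$topo, above$ff)
    expect_lt(abs(e1 - e2), 1e-5)
    f1 <- forces(below$conf, below$topo, below$ff)
    f2 <- forces(above$conf, above$topo, above$ff)
    expect_lt(max(abs(f1 - f2)), 1e-4)
  }
  at_cut <- lj_dimer(12, shift = TRUE, r_cut = 12)
  at_cut$ff$lj_shift_start <- 9
  expect_identical(total_energy(at_cut$conf, at_cut$topo, at_cut$ff), 0)
})

test_that("nonbonded energy is linear in the scale factor", {
  s <- random_toy(31)
  e1 <- total_energy(s$conf, s$topo, s$ff, components = TRUE)
  for (sc in c(0.01, 0.3, 0.77)) {
    ffs <- s$ff; ffs$nonbonded_scale <- sc
    e2 <- total_energy(s$conf, s$topo, ffs, components = TRUE)
    expect_equal(e2$e_lj, sc * e1$e_lj, tolerance = 1e-12)
    expect_equal(e2$e_coul, sc * e1$e_coul, tolerance = 1e-12)
    expect_equal(e2$e_bond, e1$e_bond)
  }
})

test_that("cross-group energy requires disjoint selections and obeys closed forms", {
  s <- lj_dimer(2^(1 / 6) * 4.7)
  topo <- s$topo
  topo$group <- c("ligand", "receptor")
  expect_equal(group_interaction_energy(s$conf, topo, s$ff), -1,
               tolerance = 1e-12)
  expect_error(group_interaction_energy(s$conf, topo, s$ff, 1:2, 2),
               "disjoint")
  far <- lj_dimer(60)
  far$topo$group <- c("ligand", "receptor")
  expect_identical(group_interaction_energy(far$conf, far$topo, far$ff), 0)
})

test_that("fixed-geometry binding energy equals the cross-pair sum", {
  for (seed in c(41, 42, 43)) {
    s <- random_toy(seed)
    g <- group_interaction_energy(s$conf, s$topo, s$ff)
    b <- binding_energy(s$conf, s$topo, s$ff)
    expect_lt(abs(g - b), 1e-8)
  }
  # single cross pair at the LJ minimum, no environment
  s <- lj_dimer(2^(1 / 6) * 4.7)
  s$topo$group <- c("ligand", "receptor")
  expect_equal(binding_energy(s$conf, s$topo, s$ff), -1, tolerance = 1e-10)
  expect_error(binding_energy(s$conf, lj_dimer(5)$topo, s$ff), "receptor")
})

test_that("DMD scaling weakens nonbonded terms by exactly 1/100", {
  s <- random_toy(51)
  ffd <- dmd_scaled_params(s$ff)
  e_md <- total_energy(s$conf, s$topo, s$ff, components = TRUE)
  e_dmd <- total_energy(s$conf, s$topo, ffd, components = TRUE)
  nb_md <- e_md$e_lj + e_md$e_coul
  nb_dmd <- e_dmd$e_lj + e_dmd$e_coul
  expect_equal(nb_dmd / nb_md, 0.01, tolerance = 1e-12)
  expect_equal(e_dmd$e_bond, e_md$e_bond)
  expect_equal(e_dmd$e_angle, e_md$e_angle)
  # idempotent with a warning
  expect_warning(ffd2 <- dmd_scaled_params(ffd), "already")
  expect_identical(ffd2, ffd)
})

test_that("invalid inputs are rejected with structural errors", {
  s <- lj_dimer(5)
  expect_error(conformation(matrix(c(0, 0, 0, Inf, 0, 0), 2, 3,
                                   byrow = TRUE)), "finite")
  bad_conf <- conformation(matrix(0, 3, 3))
  expect_error(total_energy(bad_conf, s$topo, s$ff), "beads")
  expect_error(bead_topology("A", mass = -1, group = "ligand"), "positive")
  small_box <- conformation(s$conf$coords, box = c(20, 20, 20))
  expect_error(total_energy(small_box, s$topo, s$ff), "r_cut")
})
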