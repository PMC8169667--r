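test_that("the tunnelling transform matches its closed form and sign law", {
  expect_identical(stun_transform(5, 5), 0)
  expect_lt(abs(stun_transform(1, 0) - log(1 + sqrt(2))), 1e-9)
  expect_lt(abs(stun_transform(-3, 0) - log(-3 + sqrt(10))), 1e-9)
  expect_lt(abs(stun_transform(1, 0) - 0.881374), 1e-6)
  expect_lt(abs(stun_transform(-3, 0) - (-1.818446)), 1e-6)
  # strictly increasing in f, negative exactly when f < f0
  f <- seq(-40, 40, by = 0.25)
  e <- stun_transform(f, 3)
  expect_true(all(diff(e) > 0))
  expect_identical(e < 0, f < 3)
})

test_that("the three Metropolis cases follow the printed rules", {
  # equal or lower effective energy: accepted for any u
  expect_true(boltzmann_accept(1.0, 1.0, kT = 0.5, u = 0.999999))
  expect_true(boltzmann_accept(0.2, 1.0, kT = 1e-6, u = 0.999999))
  # uphill by kT ln 2: factor is exactly 0.5
  kT <- 0.7
  expect_true(boltzmann_accept(kT * log(2), 0, kT, u = 0.4))
  expect_false(boltzmann_accept(kT * log(2), 0, kT, u = 0.6))
  expect_error(boltzmann_accept(1, 0, kT = 0, u = 0.5), "positive")
})

test_that("kT adaptation follows the 50% controller rule with clamping", {
  st <- new_search_state(conformation(matrix(0, 1, 3)), f0 = 0, kT0 = 1)
  st$accept_history <- rep(c(TRUE, FALSE), 10) # exactly 50%
  expect_equal(adapt_kT(st)$kT, 1)
  st$accept_history <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 4) # 80%
  expect_equal(adapt_kT(st)$kT, 1 / 1.2)
  st$accept_history <- rep(c(TRUE, FALSE, FALSE, FALSE), 5) # 25%
  expect_equal(adapt_kT(st)$kT, 1.2)
  st$kT <- 2e6
  st$accept_history <- rep(FALSE, 20)
  expect_equal(adapt_kT(st)$kT, 1e6)
})

test_that("receptor re-orientation is a rigid rotation about its COM", {
  p <- make_pocket_system(n_ligand = 3, seed = 2)
  idx <- group_indices(p$topo, "receptor")
  rot <- random_orientation(p$conf, p$topo, seed = 8)
  d0 <- dist(p$conf$coords[idx, ])
  d1 <- dist(rot$coords[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-10)
  com0 <- stunbh:::.com(p$conf$coords, p$topo$mass, idx)
  com1 <- stunbh:::.com(rot$coords, p$topo$mass, idx)
  expect_lt(max(abs(com0 - com1)), 1e-10)
  # ligand untouched
  lig <- group_indices(p$topo, "ligand")
  expect_identical(rot$coords[lig, ], p$conf$coords[lig, ])
})

test_that("random rotations are uniform on the sphere", {
  set.seed(17)
  n <- 10000
  v <- t(vapply(seq_len(n),
                function(i) as.numeric(stunbh:::.random_rotation() %*%
                                         c(0, 0, 1)),
                numeric(3)))
  # each component has mean 0 (sd of the mean ~ 1/sqrt(3n))
  expect_lt(max(abs(colMeans(v))), 3 / sqrt(3 * n))
  expect_lt(max(abs(rowSums(v^2) - 1)), 1e-10)
})

test_that("a seeded run keeps f0 non-increasing and restores rejected moves", {
  set.seed(23)
  s <- make_lj_cluster(7, seed = 3)
  settings <- stun_settings(objective = "total")
  m <- local_minimize(s$conf, s$topo, s$ff)
  f0 <- total_energy(m$conformation, s$topo, s$ff)
  st <- new_search_state(m$conformation, f0, settings$kT0)
  f0_trace <- numeric(0)
  n_rejected <- 0
  for (i in 1:60) {
    x_before <- st$x_last
    st <- stun_step(st, s$topo, s$ff, settings)
    f0_trace <- c(f0_trace, st$f0)
    if (!st$last$accepted) {
      n_rejected <- n_rejected + 1
      expect_identical(st$x_last, x_before) # bit-for-bit restore
    } else {
      expect_equal(st$stun_last, stun_transform(st$last$f, st$f0))
    }
  }
  expect_true(all(diff(f0_trace) <= 0))
  expect_identical(st$iteration, 60L)
  # both proposal modes were exercised
  expect_gt(n_rejected, 0)
})

test_that("a search with zero iterations returns the minimized input", {
  s <- make_lj_cluster(4, seed = 4)
  r <- run_search(s$conf, s$topo, s$ff, n_starts = 1, iters_per_start = 0,
                  seed = 1, settings = stun_settings(objective = "total"))
  m <- local_minimize(s$conf, s$topo, s$ff)
  expect_lt(abs(r$best_f - total_energy(m$conformation, s$topo, s$ff)), 1e-6)
  expect_lt(rmsd(r$best_conformation, m$conformation), 1e-3)
})

test_that("the search recovers the LJ4 tetrahedron at -6 eps", {
  s <- make_lj_cluster(4, seed = 2)
  r <- run_search(s$conf, s$topo, s$ff, n_starts = 1, iters_per_start = 80,
                  seed = 1, settings = stun_settings(objective = "total"))
  expect_lt(abs(r$best_f - (-30)), 1e-4 * 5) # epsilon = 5 kJ/mol
  d <- as.numeric(dist(r$best_conformation$coords))
  expect_lt(max(abs(d - 2^(1 / 6) * 4.7)), 0.01)
})
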