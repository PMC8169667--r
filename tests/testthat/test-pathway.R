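test_that("NEB on the quartic double well recovers the barrier and symmetry", {
  images <- linear_images(-1, 1, 16)
  res <- neb_path(images, dw_fn, dw_gr, spring_k = 1, force_tol = 1e-6,
                  max_iter = 5000)
  expect_true(res$converged)
  # endpoints frozen
  expect_identical(res$images[[1]], images[[1]])
  expect_identical(res$images[[16]], images[[16]])
  barrier <- max(res$energies) - res$energies[1]
  expect_lt(abs(barrier - 1) / 1, 0.02)
  # symmetric potential: symmetric profile
  expect_lt(max(abs(res$energies - rev(res$energies))), 1e-3)
})

test_that("refining the image count converges the barrier monotonically", {
  b <- sapply(c(8, 16, 32), function(ni) {
    res <- neb_path(linear_images(-1, 1, ni), dw_fn, dw_gr, spring_k = 1,
                    force_tol = 1e-6, max_iter = 8000)
    max(res$energies) - res$energies[1]
  })
  expect_true(all(diff(b) > 0))
  expect_true(all(b <= 1 + 1e-6))
  expect_lt(abs(b[3] - 1), 0.005)
})

test_that("NEB resolves the saddle of a 2-D channel within 2%", {
  # V = (x^2-1)^2 + 2 y^2: minima at (+-1, 0), saddle at the origin, height 1
  set.seed(5)
  images <- linear_images(c(-1, 0), c(1, 0), 16)
  images[2:15] <- lapply(images[2:15], function(p) p + c(0, runif(1, 0.05, 0.3)))
  res <- neb_path(images, dw2_fn, dw2_gr, spring_k = 2, force_tol = 1e-5,
                  max_iter = 8000)
  barrier <- max(res$energies) - res$energies[1]
  expect_lt(abs(barrier - 1), 0.02)
})

test_that("a climbing image lands exactly on the saddle", {
  res <- neb_path(linear_images(-1, 1, 10), dw_fn, dw_gr, spring_k = 1,
                  force_tol = 1e-8, max_iter = 10000, climbing = TRUE)
  expect_lt(abs(max(res$energies) - 1), 1e-6)
})

test_that("steered pulling yields monotone COM distances ending unbound", {
  p <- make_pocket_system(n_ligand = 3, seed = 9, pose = "groove")
  path <- pull_path(p$conf, p$topo, p$ff, n_images = 6, pull_distance = 35,
                    velocity = 0.5, minimize_iters = 150)
  d <- attr(path, "com_distance")
  expect_equal(length(path), 6)
  expect_true(all(diff(d) > 0))
  # first image: the minimized input complex
  m0 <- local_minimize(p$conf, p$topo, p$ff)
  expect_lt(rmsd(path[[1]], m0$conformation, fit = FALSE), 0.1)
  # final image: pulled beyond interaction range
  be_end <- group_interaction_energy(path[[6]], p$topo, p$ff)
  expect_gte(be_end, -1e-6)
})

test_that("system NEB keeps endpoints fixed and reports a full profile", {
  p <- make_pocket_system(n_ligand = 3, seed = 9, pose = "groove")
  path <- pull_path(p$conf, p$topo, p$ff, n_images = 6, pull_distance = 35,
                    velocity = 0.5, minimize_iters = 150)
  images <- rev(path) # reactant (unbound) first
  mep <- neb_relax(images, p$topo, p$ff, spring_k = 10, force_tol = 0.5,
                   max_iter = 300)
  expect_identical(mep$images[[1]]$coords, images[[1]]$coords)
  expect_identical(mep$images[[6]]$coords, images[[6]]$coords)
  expect_gte(mep$barrier, 0)
  rep <- barrier_report(mep)
  expect_equal(nrow(rep$profile), 6)
  expect_equal(rep$barrier, mep$barrier)
  # binding switches on somewhere along the adsorption path
  expect_true(is.na(rep$onset_index) ||
                mep$binding_energy[rep$onset_index] < 0)
})

test_that("a monotone downhill profile reports a zero barrier at the reactant", {
  rep <- barrier_report(c(5, 4, 2.5, 1, 0))
  expect_equal(rep$barrier, 0)
  expect_equal(rep$ts_index, 1)
  expect_equal(nrow(rep$profile), 5)
})
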