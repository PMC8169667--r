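test_that("RMSD obeys closed forms with and without fitting", {
  co <- matrix(rnorm(30), 10, 3)
  expect_lt(rmsd(co, co), 1e-12)
  shifted <- co + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  expect_lt(rmsd(shifted, co, fit = TRUE), 1e-10)
  expect_gt(rmsd(shifted, co, fit = FALSE), 1)
  # two beads displaced by (3,4,0) and (0,0,0): sqrt(25/2)
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  b <- rbind(c(3, 4, 0), c(10, 0, 0))
  expect_equal(rmsd(b, a, fit = FALSE), sqrt(25 / 2), tolerance = 1e-12)
  expect_error(rmsd(matrix(0, 2, 3), matrix(0, 3, 3), fit = FALSE), "differ")
})

test_that("the radius of gyration matches hand-computed geometries", {
  topo1 <- bead_topology("A", mass = 72, group = "ligand")
  expect_equal(radius_of_gyration(matrix(c(5, 5, 5), 1, 3), topo1), 0)
  topo2 <- bead_topology(c("A", "A"), mass = 1, group = "ligand")
  d <- 6.4
  expect_equal(
    radius_of_gyration(rbind(c(0, 0, 0), c(d, 0, 0)), topo2), d / 2,
    tolerance = 1e-12)
  topo4 <- bead_topology(rep("A", 4), mass = 1, group = "ligand")
  a <- 3.1
  sq <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0))
  expect_equal(radius_of_gyration(sq, topo4), a / sqrt(2), tolerance = 1e-12)
  # mass-weighting and the unnormalized compatibility form
  topo_w <- bead_topology(c("A", "A"), mass = c(1, 3), group = "ligand")
  co <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(co, topo_w), sqrt((1 * 9 + 3 * 1) / 4),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(co, topo_w, normalize = FALSE),
               sqrt(1 * 9 + 3 * 1), tolerance = 1e-12)
  expect_error(radius_of_gyration(co, topo_w, selection = integer(0)),
               "empty")
})

test_that("Rg is invariant under rigid motions", {
  s <- random_toy(61)
  topo <- s$topo
  r0 <- radius_of_gyration(s$conf$coords, topo)
  set.seed(2)
  R <- stunbh:::.random_rotation()
  moved <- s$conf$coords %*% t(R) + matrix(c(5, 6, 7), 27, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(moved, topo), r0, tolerance = 1e-10)
})

test_that("RMSF separates static and fluctuating beads", {
  p <- make_pocket_system(n_ligand = 3, seed = 1)
  co <- p$conf$coords
  static_tr <- trajectory(list(co, co, co, co))
  r <- rmsf(static_tr, p$topo, fit = FALSE)
  expect_lt(max(r), 1e-12)
  # one nucleobase bead alternating between two points d apart, no fit
  lig_nb <- which(p$topo$group == "ligand" & !p$topo$backbone)
  co2 <- co
  co2[lig_nb[1], ] <- co[lig_nb[1], ] + c(2, 0, 0)
  tr <- trajectory(list(co, co2, co, co2))
  per_bead <- rmsf(tr, p$topo, fit = FALSE, group_by = "none")
  expect_equal(per_bead[lig_nb[1]], 1, tolerance = 1e-12) # d/2 with d = 2
  expect_lt(max(per_bead[-lig_nb[1]]), 1e-12)
  # per-nucleobase values are means of member-bead values
  grouped <- rmsf(tr, p$topo, fit = FALSE)
  pb <- attr(grouped, "per_bead")
  lig1 <- which(p$topo$group == "ligand" & !p$topo$backbone &
                  p$topo$residue_id == 1)
  expect_equal(unname(grouped["1"]), mean(pb[lig1]), tolerance = 1e-12)
  expect_error(rmsf(trajectory(list(co, co)), p$topo, window = 1), "2 frames")
})

test_that("COM distance traces respect mass centers and minimum image", {
  topo <- bead_topology(c("L", "R"), mass = 72,
                        group = c("ligand", "receptor"))
  # 95 A apart along x in a 100 A box: minimum image gives 5 A
  fr <- rbind(c(1, 0, 0), c(96, 0, 0))
  tr <- trajectory(list(fr), box = c(100, 100, 100))
  expect_equal(com_distance_trace(tr, topo), 5, tolerance = 1e-12)
  # rigid translation of both groups leaves the trace unchanged
  tr2 <- trajectory(list(fr, fr + 2), box = c(100, 100, 100))
  d <- com_distance_trace(tr2, topo)
  expect_equal(d[1], d[2], tolerance = 1e-12)
  # coincident groups
  tr3 <- trajectory(list(rbind(c(4, 4, 4), c(4, 4, 4))))
  expect_equal(com_distance_trace(tr3, topo), 0)
})

test_that("per-nucleobase distance traces have one column per nucleobase", {
  p <- make_pocket_system(n_ligand = 4, seed = 3)
  tr <- trajectory(list(p$conf$coords, p$conf$coords + 0.1))
  m <- com_distance_trace(tr, p$topo, per_nucleobase = TRUE)
  expect_equal(dim(m), c(2, 4))
})

test_that("the interaction map reproduces the pairwise-additive totals", {
  p <- make_pocket_system(n_ligand = 4, seed = 5, pose = "groove")
  co2 <- p$conf$coords
  lig <- group_indices(p$topo, "ligand")
  co2[lig, ] <- co2[lig, ] + c(0.3, -0.2, 0.4)
  tr <- trajectory(list(p$conf$coords, co2))
  im <- interaction_map(tr, p$topo, p$ff)
  expect_equal(dim(im$matrix), c(132, 4))
  # column sums are the per-nucleobase histogram, exactly
  expect_equal(colSums(im$matrix), im$histogram, tolerance = 1e-12)
  # matrix total equals the time-mean nucleobase-receptor interaction energy
  nb <- lig[!p$topo$backbone[lig]]
  ref <- mean(c(
    group_interaction_energy(p$conf, p$topo, p$ff, nb, "receptor"),
    group_interaction_energy(conformation(co2), p$topo, p$ff, nb,
                             "receptor")))
  expect_lt(abs(sum(im$matrix) - ref), 1e-8)
  # single-frame window equals the instantaneous decomposition
  im1 <- interaction_map(tr, p$topo, p$ff, window = 1)
  e1 <- group_interaction_energy(p$conf, p$topo, p$ff, nb, "receptor")
  expect_lt(abs(sum(im1$matrix) - e1), 1e-8)
  expect_equal(im$mask, im$matrix < -8.4)
})

test_that("separated groups give an all-zero interaction map", {
  topo <- bead_topology(c("R", "L"), mass = 72,
                        group = c("receptor", "ligand"))
  ff <- ff_params(c("R", "L"), sigma = 4.7, epsilon = 2)
  tr <- trajectory(list(rbind(c(0, 0, 0), c(100, 0, 0))))
  im <- interaction_map(tr, topo, ff)
  expect_identical(sum(abs(im$matrix)), 0)
})

test_that("shell counts use a strict threshold and match a brute-force scan", {
  topo <- bead_topology(c("L", "W", "W"), mass = 72,
                        group = c("ligand", "solvent", "solvent"))
  conf <- conformation(rbind(c(0, 0, 0), c(6.9, 0, 0), c(7.1, 0, 0)))
  r <- count_within(conf, topo, around = "ligand", cutoff = 7)
  expect_equal(r$count, 1L)
  expect_equal(r$ids, 2L)
  # empty target
  topo2 <- bead_topology(c("L", "L"), mass = 72, group = "ligand")
  expect_equal(count_within(conformation(matrix(0, 2, 3)), topo2,
                            "ligand")$count, 0L)
  # random periodic system vs an independent O(N^2) loop
  set.seed(71)
  n <- 300
  co <- matrix(runif(3 * n, 0, 40), n, 3)
  grp <- c(rep("ligand", 10), rep("solvent", n - 10))
  topo3 <- bead_topology(rep("W", n), mass = 72, group = grp,
                         residue_id = seq_len(n))
  conf3 <- conformation(co, box = c(40, 40, 40))
  got <- count_within(conf3, topo3, "ligand", "solvent", cutoff = 7)
  expected <- 0L
  for (i in 11:n) {
    hit <- FALSE
    for (j in 1:10) {
      d <- co[i, ] - co[j, ]
      d <- d - 40 * round(d / 40)
      if (sqrt(sum(d^2)) < 7) hit <- TRUE
    }
    expected <- expected + hit
  }
  expect_equal(got$count, expected)
})

test_that("analyses are pure: repeated calls are identical", {
  p <- make_pocket_system(n_ligand = 3, seed = 6)
  tr <- trajectory(list(p$conf$coords, p$conf$coords + 0.2))
  expect_identical(interaction_map(tr, p$topo, p$ff),
                   interaction_map(tr, p$topo, p$ff))
  expect_identical(rmsf(tr, p$topo), rmsf(tr, p$topo))
})
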