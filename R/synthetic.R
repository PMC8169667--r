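#' Lennard-Jones cluster fixture
#'
#' `n` identical neutral beads at random non-overlapping positions inside a
#' sphere of radius `2 n^(1/3) sigma`; no bonded terms. A standard benchmark
#' surface for the global search (the n = 3 and n = 4 global minima are the
#' equilateral triangle at -3 eps and the regular tetrahedron at -6 eps).
#'
#' @param n number of beads (>= 2).
#' @param sigma LJ sigma (A).
#' @param epsilon LJ epsilon (kJ/mol).
#' @param seed optional integer seed.
#' @param mass bead mass (amu).
#' @return list with `topo`, `conf` and a matching `ff` (shift disabled so
#'   small clusters sit on the plain LJ surface; pass your own `ff` to
#'   study switched interactions).
#' @export
make_lj_cluster <- function(n, sigma = 4.7, epsilon = 5.0, seed = NULL,
                            mass = 72) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  R <- 2 * n^(1 / 3) * sigma
  min_d <- 0.85 * sigma
  coords <- matrix(NA_real_, n, 3)
  placed <- 0
  attempts <- 0
  while (placed < n) {
    attempts <- attempts + 1
    if (attempts > 1e6) stop("could not place beads", call. = FALSE)
    p <- runif(3, -R, R)
    if (sum(p^2) > R^2) next
    if (placed > 0) {
      d2 <- rowSums(sweep(coords[seq_len(placed), , drop = FALSE], 2, p)^2)
      if (any(d2 < min_d^2)) next
    }
    placed <- placed + 1
    coords[placed, ] <- p
  }
  topo <- bead_topology(rep("LJ", n), mass = mass, charge = 0,
                        group = "ligand", residue_id = seq_len(n))
  ff <- ff_params("LJ", sigma = sigma, epsilon = epsilon,
                  r_cut = 6 * sigma, lj_shift_start = 6 * sigma)
  list(topo = topo, conf = conformation(coords), ff = ff)
}

#' Pocket-bearing receptor + flexible ligand fixture
#'
#' A synthetic stand-in for a pocket-binding complex: the receptor is a
#' near-rigid U-shaped groove — a slot carved into the top face of a
#' compact 4 A lattice block (two walls and a floor, the block held
#' together by stiff harmonic bonds) — with attractive
#' "sticky" bead types lining the groove floor so the groove-bound pose is
#' the designed optimum. The ligand is a chain of backbone beads, each
#' carrying one pendant nucleobase bead, braced into a near-rigid ladder
#' (harmonic bonds and angles only) so that its straight designed
#' conformation is also its rest shape. Group and residue labels are
#' populated for the binding-energy decomposition and the analysis module.
#'
#' @param n_ligand number of backbone/nucleobase pairs (>= 3).
#' @param pocket_depth wall height (A); walls carry beads every 5 A up to
#'   this height.
#' @param seed optional seed (used by `pose = "random"`).
#' @param charge_pattern `"neutral"` (all charges zero) or `"zwitterion"`
#'   (+0.2 e per nucleobase, balanced by the sticky floor beads so the
#'   designed total charge is zero).
#' @param pose starting ligand placement: `"groove"` (the designed optimum),
#'   `"flat"` (same ligand geometry against the flat underside, a weaker
#'   pose), or `"random"` (unbound, displaced in a random direction).
#' @param box optional periodic box; default non-periodic.
#' @return list with `topo`, `conf`, `ff`, and `poses` (the designed groove
#'   and flat-face ligand coordinates for direct comparison).
#' @export
make_pocket_system <- function(n_ligand = 4, pocket_depth = 10, seed = NULL,
                               charge_pattern = c("neutral", "zwitterion"),
                               pose = c("groove", "flat", "random"),
                               box = NULL) {
  charge_pattern <- match.arg(charge_pattern)
  pose <- match.arg(pose)
  if (n_ligand < 3) stop("n_ligand must be >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # The receptor is a compact 3-D lattice block with a slot (the groove)
  # carved out of its top face. Two design constraints keep the designed
  # groove pose the true optimum: the lattice constant (4 A) is smaller
  # than the bead diameter (sigma = 4.7 A), so ligand beads cannot
  # intercalate, and the block is several layers thick everywhere, so it
  # has no soft plate-bending modes the ligand could exploit by wrapping
  # the receptor around itself.
  a <- 4
  a_lig <- 5
  n_slot_layers <- max(1, round(pocket_depth / a))
  xs <- seq(0, 5) * a
  ys <- seq(0, 6) * a
  zs <- seq(0, n_slot_layers + 1) * a
  block <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  slot_y <- ys[3:5]
  slot_z <- zs[zs > a]
  in_slot <- block[, 2] %in% slot_y & block[, 3] %in% slot_z
  rec <- block[!in_slot, , drop = FALSE]
  nrec <- nrow(rec)
  # sticky lining: the slot floor (top remaining layer under the slot)
  sticky <- which(rec[, 3] == a & rec[, 2] %in% slot_y)
  rtype <- rep("RW", nrec)
  rtype[sticky] <- "RS"

  # ligand: backbone row and nucleobase row along x inside the slot,
  # nucleobases over the sticky centre line
  xc <- mean(xs)
  bx <- xc + (seq_len(n_ligand) - (n_ligand + 1) / 2) * a_lig
  zlig <- a + 2^(1 / 6) * 4.7
  groove_bb <- cbind(bx, slot_y[1] + 1, zlig)
  groove_nb <- cbind(bx, slot_y[1] + 1 + a_lig, zlig)
  flat_bb <- cbind(bx, slot_y[1] + 1, -2^(1 / 6) * 4.7)
  flat_nb <- cbind(bx, slot_y[1] + 1 + a_lig, -2^(1 / 6) * 4.7)
  interleave <- function(bb, nb) {
    out <- matrix(0, 2 * n_ligand, 3)
    out[seq(1, 2 * n_ligand, 2), ] <- bb
    out[seq(2, 2 * n_ligand, 2), ] <- nb
    out
  }
  groove_pose <- interleave(groove_bb, groove_nb)
  flat_pose <- interleave(flat_bb, flat_nb)
  lig <- switch(pose,
    groove = groove_pose,
    flat = flat_pose,
    random = {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      centre <- c(mean(xs), mean(ys), mean(zs))
      shift <- centre + u * (max(ys) + 12) - colMeans(groove_pose)
      sweep(groove_pose, 2, -shift)
    })

  coords <- rbind(rec, lig)
  n <- nrow(coords)
  lig_idx <- nrec + seq_len(2 * n_ligand)
  bb_idx <- lig_idx[seq(1, 2 * n_ligand, 2)]
  nb_idx <- lig_idx[seq(2, 2 * n_ligand, 2)]

  # near-rigid receptor: k = 100 bonds to first neighbors and diagonals
  # (thermal distortion ~0.2 A at 600 K) plus softer second-neighbor bonds
  # for additional shear/bending rigidity of the block
  rb <- NULL
  first2 <- (1.45 * a)^2
  second2 <- (2.05 * a)^2
  for (i in seq_len(nrec - 1)) {
    d2 <- rowSums(sweep(rec[(i + 1):nrec, , drop = FALSE], 2, rec[i, ])^2)
    j1 <- which(d2 < first2) + i
    j2 <- which(d2 >= first2 & d2 < second2) + i
    if (length(j1)) rb <- rbind(rb, cbind(i, j1, sqrt(d2[j1 - i]), 100))
    if (length(j2)) rb <- rbind(rb, cbind(i, j2, sqrt(d2[j2 - i]), 25))
  }
  bonds <- data.frame(i = rb[, 1], j = rb[, 2], r0 = rb[, 3], k = rb[, 4])
  # ligand bonds: backbone chain, pendant nucleobases, and ladder bracing
  # (nucleobase-nucleobase rungs plus diagonals). The bracing keeps the
  # designed straight conformation as the chain's rest shape, so the
  # groove-bound pose remains the designed optimum instead of being beaten
  # by collapsed conformations; the harmonic terms still allow thermal
  # bending.
  lb <- rbind(
    if (n_ligand > 1) cbind(bb_idx[-n_ligand], bb_idx[-1]),
    cbind(bb_idx, nb_idx),
    if (n_ligand > 1) cbind(nb_idx[-n_ligand], nb_idx[-1]))
  bonds <- rbind(bonds, data.frame(i = lb[, 1], j = lb[, 2], r0 = a_lig,
                                   k = 20))
  if (n_ligand > 1) {
    diag_b <- rbind(cbind(bb_idx[-n_ligand], nb_idx[-1]),
                    cbind(nb_idx[-n_ligand], bb_idx[-1]))
    bonds <- rbind(bonds, data.frame(i = diag_b[, 1], j = diag_b[, 2],
                                     r0 = a_lig * sqrt(2), k = 20))
  }
  angles <- NULL
  if (n_ligand >= 3) {
    tri <- cbind(bb_idx[1:(n_ligand - 2)], bb_idx[2:(n_ligand - 1)],
                 bb_idx[3:n_ligand])
    angles <- data.frame(i = tri[, 1], j = tri[, 2], k = tri[, 3],
                         theta0 = 180, ka = 5)
  }

  type <- c(rtype, rep(c("LB", "LN"), n_ligand))
  charge <- numeric(n)
  if (charge_pattern == "zwitterion") {
    charge[nb_idx] <- 0.2
    charge[sticky] <- -0.2 * n_ligand / length(sticky)
  }
  group <- c(rep("receptor", nrec), rep("ligand", 2 * n_ligand))
  residue_id <- c(seq_len(nrec), rep(seq_len(n_ligand), each = 2))
  backbone <- c(rep(FALSE, nrec), rep(c(TRUE, FALSE), n_ligand))

  topo <- bead_topology(type, mass = 72, charge = charge, group = group,
                        residue_id = residue_id, backbone = backbone,
                        bonds = bonds, angles = angles)
  ff <- ff_params(c("RW", "RS", "LB", "LN", "W", "QD"),
                  sigma = 4.7,
                  epsilon = c(RW = 2, RS = 2, LB = 2, LN = 2, W = 5, QD = 2),
                  pair_eps = c("LN:RS" = 8))
  list(topo = topo, conf = conformation(coords, box = box), ff = ff,
       poses = list(groove = groove_pose, flat = flat_pose))
}

#' Solvate a system with water beads
#'
#' Random insertion of coarse-grained water beads (72 amu, one bead per four
#' waters, neutral) into the periodic box until the mass density reaches the
#' target. Inserted beads keep at least `min_dist` to every pre-existing
#' (solute) bead and at least `water_min_dist` to each other.
#'
#' @param conf a periodic [conformation()].
#' @param topo a [bead_topology()].
#' @param density target mass density (g/cm^3).
#' @param min_dist minimum inserted-water to solute distance (A).
#' @param water_min_dist minimum water-water distance (A).
#' @param seed optional seed.
#' @param water_type bead type label for the inserted beads.
#' @param max_attempts insertion attempt budget before giving up.
#' @return list with the extended `topo` and `conf`.
#' @export
solvate <- function(conf, topo, density = 1.0, min_dist = 5,
                    water_min_dist = 3, seed = NULL, water_type = "W",
                    max_attempts = 1e6) {
  if (is.null(conf$box)) stop("solvation needs a periodic box", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vol <- prod(conf$box)
  amu_per_A3 <- density / 1.66053906660 # 1 amu/A^3 = 1.66054 g/cm^3
  n_w <- round((amu_per_A3 * vol - sum(topo$mass)) / 72)
  if (n_w <= 0) stop("target density already reached", call. = FALSE)
  solute <- conf$coords
  placed <- matrix(NA_real_, n_w, 3)
  np <- 0
  attempts <- 0
  while (np < n_w) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("could not reach the target density after ", max_attempts,
           " attempts; lower the density or min_dist", call. = FALSE)
    }
    p <- runif(3) * conf$box
    ds <- .min_image(sweep(solute, 2, p), conf$box)
    if (any(rowSums(ds^2) < min_dist^2)) next
    if (np > 0) {
      dw <- .min_image(sweep(placed[seq_len(np), , drop = FALSE], 2, p),
                       conf$box)
      if (any(rowSums(dw^2) < water_min_dist^2)) next
    }
    np <- np + 1
    placed[np, ] <- p
  }
  new_topo <- .topo_append(topo, rep(water_type, n_w), 72, 0, "solvent",
                           max(topo$residue_id) + seq_len(n_w))
  new_conf <- conformation(rbind(conf$coords, placed), box = conf$box)
  list(topo = new_topo, conf = new_conf)
}

#' Neutralize a system with counterions
#'
#' Replaces randomly chosen solvent beads with monatomic ions until the
#' total charge is zero; the bead count is conserved. A system that is
#' already neutral is returned unchanged.
#'
#' @param topo a [bead_topology()].
#' @param conf a [conformation()].
#' @param ion_charge charge per ion (e); its sign must oppose the net
#'   system charge, and the net charge must be an integer multiple of it.
#' @param seed optional seed.
#' @param ion_type bead type label for the ions.
#' @return list with updated `topo` and `conf`.
#' @export
add_counterions <- function(topo, conf, ion_charge = 1, seed = NULL,
                            ion_type = "QD") {
  net <- sum(topo$charge)
  if (abs(net) < 1e-9) return(list(topo = topo, conf = conf))
  n_ions <- -net / ion_charge
  if (n_ions < 0 || abs(n_ions - round(n_ions)) > 1e-6) {
    stop(sprintf(
      "net charge %+g cannot be neutralized with ions of charge %+g",
      net, ion_charge), call. = FALSE)
  }
  n_ions <- round(n_ions)
  wat <- which(topo$group == "solvent")
  if (length(wat) < n_ions) {
    stop("not enough solvent beads to replace with ions", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pick <- sample(wat, n_ions)
  topo$bead_type[pick] <- ion_type
  topo$charge[pick] <- ion_charge
  topo$group[pick] <- "ion"
  list(topo = topo, conf = conf)
}
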