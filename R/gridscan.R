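#' Brute-force rigid pose scan
#'
#' Exhaustive rigid-body docking of the ligand on the receptor over a
#' translation grid times an orientation grid, by direct evaluation of the
#' cross-group LJ + switched-Coulomb energy at every pose (poses with a
#' bead-bead overlap below 0.6 sigma are discarded). A coarse pass over the
#' full grids is followed by a local refinement (1 A / 15 degrees around the
#' best coarse poses). Intended as an orientation-grid oracle against which
#' the stochastic search is validated; for anything beyond toy systems it is
#' deliberately expensive.
#'
#' @param conf a [conformation()] holding the current ligand/receptor pose
#'   (the ligand's internal geometry is taken from here and kept rigid).
#' @param topo a [bead_topology()] with ligand and receptor groups.
#' @param ff a [ff_params()].
#' @param spacing coarse translation-grid spacing (A).
#' @param angle coarse orientation-grid spacing (degrees).
#' @param refine_spacing,refine_angle fine local grid (A, degrees).
#' @param margin how far (A) the translation grid extends beyond the
#'   receptor's bounding box.
#' @param topk number of coarse poses carried into refinement.
#' @return list with `best_energy` (kJ/mol, rigid cross energy),
#'   `best_conformation` (full system at the best pose), `top`
#'   (data frame of the refined candidate energies), and `candidates`
#'   (the full-system conformation of each refined candidate, e.g. for
#'   subsequent flexible minimization).
#' @export
scan_rigid_poses <- function(conf, topo, ff, spacing = 2, angle = 30,
                             refine_spacing = 1, refine_angle = 15,
                             margin = 8, topk = 20) {
  il <- group_indices(topo, "ligand")
  ir <- group_indices(topo, "receptor")
  if (!length(il) || !length(ir)) {
    stop("scan needs ligand and receptor groups", call. = FALSE)
  }
  rec <- conf$coords[ir, , drop = FALSE]
  lig0 <- conf$coords[il, , drop = FALSE]
  mlig <- topo$mass[il]
  com <- colSums(lig0 * mlig) / sum(mlig)
  lig <- sweep(lig0, 2, com)

  ti <- match(topo$bead_type, ff$types)
  sigp <- ff$sig_mat[ti[il], ti[ir], drop = FALSE]
  epsp <- ff$eps_mat[ti[il], ti[ir], drop = FALSE] * ff$nonbonded_scale
  qqp <- outer(topo$charge[il], topo$charge[ir]) *
    ff$coulomb_prefactor / ff$dielectric * ff$nonbonded_scale

  lo <- apply(rec, 2, min) - margin
  hi <- apply(rec, 2, max) + margin
  grid_axes <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
  trans <- as.matrix(expand.grid(grid_axes))
  rots <- .euler_grid(angle)

  coarse <- cpp_grid_scan(rec, lig, sigp, epsp, qqp, ff$r_cut,
                          ff$lj_shift_start, ff$coulomb_shift_start,
                          trans, rots, as.integer(topk))
  keep <- which(is.finite(coarse$energy))
  if (!length(keep)) stop("no clash-free pose found on the grid", call. = FALSE)

  # local refinement around each retained coarse pose
  doff <- as.matrix(expand.grid(d1 = c(-1, 0, 1), d2 = c(-1, 0, 1),
                                d3 = c(-1, 0, 1))) * refine_spacing
  small <- .small_rotations(refine_angle)
  best_e <- Inf; best_trans <- NULL; best_rot <- NULL
  top_rows <- list()
  cand_confs <- list()
  pose_conf <- function(tr, Ro) {
    coords <- conf$coords
    coords[il, ] <- lig %*% t(Ro) + matrix(tr, length(il), 3, byrow = TRUE)
    conformation(coords, box = conf$box)
  }
  for (m in keep) {
    t0 <- trans[coarse$trans_idx[m], ]
    R0 <- matrix(rots[coarse$rot_idx[m], ], 3, 3, byrow = TRUE)
    tfine <- sweep(doff, 2, t0, `+`)
    rfine <- t(vapply(seq_len(nrow(small)),
                      function(i) as.numeric(t(matrix(small[i, ], 3, 3,
                                                      byrow = TRUE) %*% R0)),
                      numeric(9)))
    fine <- cpp_grid_scan(rec, lig, sigp, epsp, qqp, ff$r_cut,
                          ff$lj_shift_start, ff$coulomb_shift_start,
                          tfine, rfine, 1L)
    if (is.finite(fine$energy[1])) {
      top_rows[[length(top_rows) + 1]] <- data.frame(
        coarse_rank = m, energy = fine$energy[1])
      tr1 <- tfine[fine$trans_idx[1], ]
      Ro1 <- matrix(rfine[fine$rot_idx[1], ], 3, 3, byrow = TRUE)
      cand_confs[[length(cand_confs) + 1]] <- pose_conf(tr1, Ro1)
      if (fine$energy[1] < best_e) {
        best_e <- fine$energy[1]
        best_trans <- tr1
        best_rot <- Ro1
      }
    }
  }
  list(best_energy = best_e,
       best_conformation = pose_conf(best_trans, best_rot),
       top = do.call(rbind, top_rows),
       candidates = cand_confs)
}

# ZYZ Euler grid at the given angular resolution, rows = row-major matrices
.euler_grid <- function(step) {
  al <- seq(0, 360 - step, by = step) * pi / 180
  be <- seq(step / 2, 180, by = step) * pi / 180
  ga <- seq(0, 360 - step, by = step) * pi / 180
  g <- expand.grid(al = al, be = be, ga = ga)
  t(mapply(function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    as.numeric(t(Rz1 %*% Ry %*% Rz2))
  }, g$al, g$be, g$ga))
}

# identity plus +/- step rotations about each axis
.small_rotations <- function(step) {
  s <- step * pi / 180
  axis_rot <- function(axis, th) {
    c1 <- cos(th); s1 <- sin(th)
    switch(axis,
      x = matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, 3, byrow = TRUE),
      y = matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, 3, byrow = TRUE),
      z = matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  }
  mats <- list(diag(3))
  for (ax in c("x", "y", "z")) {
    for (th in c(-s, s)) mats[[length(mats) + 1]] <- axis_rot(ax, th)
  }
  t(vapply(mats, function(m) as.numeric(t(m)), numeric(9)))
}
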