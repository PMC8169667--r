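#' Nudged-elastic-band relaxation on an arbitrary surface
#'
#' Chain-of-states relaxation of a discretized path: each interior image
#' feels the true force projected perpendicular to the (energy-weighted,
#' improved-tangent) path direction plus a spring force along it; the
#' endpoints are frozen. Relaxation uses a FIRE integrator on the whole band.
#'
#' This generic engine works on flat numeric coordinate vectors with a
#' user-supplied energy/gradient; [neb_relax()] wraps it for bead systems.
#'
#' @param images list of numeric vectors (>= 3), the initial path; first and
#'   last images are the fixed endpoints.
#' @param fn energy function of a coordinate vector.
#' @param gr gradient function of a coordinate vector.
#' @param spring_k spring constant between adjacent images
#'   (energy / distance^2 in the coordinates' units).
#' @param force_tol convergence threshold on the largest band-force
#'   component norm.
#' @param max_iter relaxation budget.
#' @param climbing if `TRUE`, the highest interior image climbs along the
#'   tangent (its spring force is dropped and the parallel true-force
#'   component inverted), converging onto the saddle point.
#' @param mask optional integer vector of coordinate positions that define
#'   the band metric (tangents, spring lengths) and receive the NEB
#'   projection; positions outside the mask relax on the plain true force.
#'   Default: all coordinates.
#' @return list with `images`, `energies`, `converged`, `iterations`.
#' @export
neb_path <- function(images, fn, gr, spring_k = 10, force_tol = 1e-3,
                     max_iter = 2000, climbing = FALSE, mask = NULL) {
  ni <- length(images)
  if (ni < 3) stop("need at least 3 images", call. = FALSE)
  d <- length(images[[1]])
  if (is.null(mask)) mask <- seq_len(d)
  X <- do.call(rbind, lapply(images, as.numeric)) # ni x d

  band_force <- function(X, E) {
    G <- do.call(rbind, lapply(seq_len(ni), function(i) as.numeric(gr(X[i, ]))))
    FF <- matrix(0, ni, d)
    imax <- which.max(E[2:(ni - 1)]) + 1L
    for (i in 2:(ni - 1)) {
      dp <- X[i + 1, mask] - X[i, mask]
      dm <- X[i, mask] - X[i - 1, mask]
      # improved tangent (energy-weighted switch at extrema)
      if (E[i + 1] > E[i] && E[i] > E[i - 1]) {
        tau <- dp
      } else if (E[i + 1] < E[i] && E[i] < E[i - 1]) {
        tau <- dm
      } else {
        dEmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        dEmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        tau <- if (E[i + 1] > E[i - 1]) dp * dEmax + dm * dEmin
               else dp * dEmin + dm * dEmax
      }
      nt <- sqrt(sum(tau^2))
      if (nt < 1e-14) tau <- dp / max(sqrt(sum(dp^2)), 1e-14) else tau <- tau / nt
      g <- G[i, ]
      gpar <- sum(g[mask] * tau)
      f <- -g
      if (climbing && i == imax) {
        f[mask] <- -g[mask] + 2 * gpar * tau
      } else {
        f[mask] <- -(g[mask] - gpar * tau) +
          spring_k * (sqrt(sum(dp^2)) - sqrt(sum(dm^2))) * tau
      }
      FF[i, ] <- f
    }
    FF
  }

  energies <- function(X) vapply(seq_len(ni), function(i) fn(X[i, ]), 0)

  # FIRE on the band (interior images only)
  V <- matrix(0, ni, d)
  dt <- 0.05; dtmax <- 0.5; alpha <- 0.1; npos <- 0; dmax <- 0.3
  E <- energies(X)
  FF <- band_force(X, E)
  converged <- FALSE
  it <- 0
  repeat {
    fmax <- max(abs(FF[2:(ni - 1), , drop = FALSE]))
    if (fmax <= force_tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    it <- it + 1
    P <- sum(FF[2:(ni - 1), ] * V[2:(ni - 1), ])
    if (P > 0) {
      npos <- npos + 1
      if (npos > 5) { dt <- min(dt * 1.1, dtmax); alpha <- alpha * 0.99 }
    } else {
      V[] <- 0; dt <- dt * 0.5; alpha <- 0.1; npos <- 0
    }
    V <- V + dt * FF
    vn <- sqrt(sum(V[2:(ni - 1), ]^2)); fnorm <- sqrt(sum(FF[2:(ni - 1), ]^2))
    if (fnorm > 1e-300) {
      V[2:(ni - 1), ] <- (1 - alpha) * V[2:(ni - 1), ] +
        alpha * vn * FF[2:(ni - 1), ] / fnorm
    }
    step <- dt * V
    smax <- max(abs(step[2:(ni - 1), ]))
    if (smax > dmax) step <- step * dmax / smax
    X[2:(ni - 1), ] <- X[2:(ni - 1), ] + step[2:(ni - 1), ]
    E <- energies(X)
    FF <- band_force(X, E)
  }
  list(images = lapply(seq_len(ni), function(i) X[i, ]),
       energies = E, converged = converged, iterations = it)
}

#' NEB minimum-energy pathway for a bead system
#'
#' Relaxes a chain of conformations (e.g. from [pull_path()]) to the
#' minimum-energy pathway with frozen endpoints, and reports the per-image
#' total energies, ligand-receptor binding energies, and center-of-mass
#' distances. Only ligand and receptor beads define the band metric by
#' default; solvent beads relax on the plain physical force (this avoids the
#' solvent-permutation degeneracy of the path distance while letting water
#' redistribute along the pathway).
#'
#' @param images list of [conformation()]s (>= 3); the first and last are
#'   the fixed endpoint minima.
#' @param topo a [bead_topology()].
#' @param ff a [ff_params()].
#' @param spring_k inter-image spring constant (kJ/mol/A^2).
#' @param force_tol convergence threshold (kJ/mol/A).
#' @param max_iter relaxation budget.
#' @param climbing use a climbing image (off by default).
#' @param band_selection beads defining the band metric; default ligand +
#'   receptor when those groups exist, else all beads.
#' @return An object of class `"mep_result"`: list with `images`,
#'   `total_energy`, `binding_energy`, `com_distance`, `barrier`
#'   (max total energy minus the first image's), `converged`, `iterations`.
#' @export
neb_relax <- function(images, topo, ff, spring_k = 10, force_tol = 1e-2,
                      max_iter = 2000, climbing = FALSE,
                      band_selection = NULL) {
  if (length(images) < 3) stop("need at least 3 images", call. = FALSE)
  box <- images[[1]]$box
  n <- n_beads(topo)
  sys <- .compile_sys(topo, ff, images[[1]])
  if (is.null(band_selection)) {
    lr <- c(group_indices(topo, "ligand"), group_indices(topo, "receptor"))
    band_selection <- if (length(lr)) lr else seq_len(n)
  } else {
    band_selection <- group_indices(topo, band_selection)
  }
  mask <- as.integer(outer(band_selection, c(0L, n, 2L * n), `+`))
  fn <- function(x) {
    cpp_eval(sys, matrix(x, n, 3), ff$nonbonded_scale, integer(0), integer(0),
             FALSE, FALSE)$energy
  }
  gr <- function(x) {
    -as.numeric(cpp_eval(sys, matrix(x, n, 3), ff$nonbonded_scale,
                         integer(0), integer(0), FALSE, TRUE)$forces)
  }
  res <- neb_path(lapply(images, function(im) as.numeric(im$coords)),
                  fn, gr, spring_k = spring_k, force_tol = force_tol,
                  max_iter = max_iter, climbing = climbing, mask = mask)
  confs <- lapply(res$images, function(x) conformation(matrix(x, n, 3), box = box))
  has_groups <- length(group_indices(topo, "ligand")) > 0 &&
    length(group_indices(topo, "receptor")) > 0
  be <- com <- rep(NA_real_, length(confs))
  if (has_groups) {
    be <- vapply(confs, group_interaction_energy, 0, topo = topo, ff = ff)
    com <- vapply(confs, function(cf) {
      .com_distance(cf$coords, topo, group_indices(topo, "ligand"),
                    group_indices(topo, "receptor"), box)
    }, 0)
  }
  structure(
    list(images = confs, total_energy = res$energies, binding_energy = be,
         com_distance = com,
         barrier = max(res$energies) - res$energies[1],
         converged = res$converged, iterations = res$iterations),
    class = "mep_result")
}

#' @export
print.mep_result <- function(x, ...) {
  cat("mep_result:", length(x$images), "images, barrier",
      sprintf("%.4g kJ/mol", x$barrier),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

.com_distance <- function(coords, topo, ia, ib, box) {
  d <- .com(coords, topo$mass, ia) - .com(coords, topo$mass, ib)
  d <- .min_image(d, box)
  sqrt(sum(d^2))
}

#' Steered pulling: initial path for NEB
#'
#' Starting from the bound complex (the NEB product), a harmonic restraint on
#' the ligand-receptor center-of-mass distance is moved outward at constant
#' velocity in the overdamped (quasi-static) limit, and the system is
#' snapshot at `n_images` evenly spaced COM distances, each snapshot
#' restrained-minimized at its target distance. Solvent beads stay mobile
#' throughout. The first image is the minimized input complex.
#'
#' @param conf bound-complex [conformation()].
#' @param topo a [bead_topology()] with ligand and receptor groups.
#' @param ff a [ff_params()].
#' @param n_images number of snapshots (>= 2).
#' @param pull_distance total outward COM-distance increase (A).
#' @param k_pull restraint stiffness (kJ/mol/A^2).
#' @param velocity restraint-target increment per relaxation segment (A);
#'   smaller values track the quasi-static limit more closely.
#' @param minimize_iters optimizer iterations per snapshot.
#' @return list of conformations ordered from the bound complex outward,
#'   with attribute `"com_distance"`.
#' @export
pull_path <- function(conf, topo, ff, n_images = 16, pull_distance = 20,
                      k_pull = 50, velocity = 0.25, minimize_iters = 300) {
  il <- group_indices(topo, "ligand")
  ir <- group_indices(topo, "receptor")
  if (!length(il) || !length(ir)) {
    stop("pull_path needs ligand and receptor groups", call. = FALSE)
  }
  n <- n_beads(topo)
  sys <- .compile_sys(topo, ff, conf)
  box <- conf$box
  ml <- topo$mass[il]; mr <- topo$mass[ir]
  Ml <- sum(ml); Mr <- sum(mr)

  restr <- function(x, d0) {
    co <- matrix(x, n, 3)
    dvec <- .com(co, topo$mass, il) - .com(co, topo$mass, ir)
    dvec <- .min_image(dvec, box)
    d <- sqrt(sum(dvec^2))
    list(e = 0.5 * k_pull * (d - d0)^2, d = d, u = dvec / d)
  }
  fn <- function(x, d0) {
    e <- cpp_eval(sys, matrix(x, n, 3), ff$nonbonded_scale, integer(0),
                  integer(0), FALSE, FALSE)$energy
    e + restr(x, d0)$e
  }
  gr <- function(x, d0) {
    g <- -as.numeric(cpp_eval(sys, matrix(x, n, 3), ff$nonbonded_scale,
                              integer(0), integer(0), FALSE, TRUE)$forces)
    r <- restr(x, d0)
    pref <- k_pull * (r$d - d0)
    G <- matrix(0, n, 3)
    G[il, ] <- outer(ml / Ml, pref * r$u)
    G[ir, ] <- -outer(mr / Mr, pref * r$u)
    g + as.numeric(G)
  }
  rmin <- function(x, d0, maxit) {
    stats::optim(x, fn, gr, d0 = d0, method = "CG",
                 control = list(maxit = maxit, reltol = 1e-12))$par
  }

  m0 <- local_minimize(conf, topo, ff, max_iter = 3000)
  x <- as.numeric(m0$conformation$coords)
  d_start <- restr(x, 0)$d
  targets <- seq(d_start, d_start + pull_distance, length.out = n_images)

  out <- vector("list", n_images)
  out[[1]] <- m0$conformation
  dists <- numeric(n_images)
  dists[1] <- d_start
  d0 <- d_start
  for (im in 2:n_images) {
    while (d0 < targets[im] - 1e-9) {
      d0 <- min(d0 + velocity, targets[im])
      x <- rmin(x, d0, 20)
    }
    x <- rmin(x, targets[im], minimize_iters)
    co <- matrix(x, n, 3)
    if (!is.null(box) && any(abs(co[il, ]) > 1.5 * max(box))) {
      stop("ligand escaped the simulation box during pulling; ",
           "use a larger box or a shorter pull_distance", call. = FALSE)
    }
    out[[im]] <- conformation(co, box = box)
    dists[im] <- restr(x, 0)$d
  }
  attr(out, "com_distance") <- dists
  out
}

#' Barrier and profile report for a relaxed pathway
#'
#' @param mep an `"mep_result"` from [neb_relax()], or a plain numeric
#'   vector of per-image energies.
#' @param reactant index of the reactant image (default 1; use the last
#'   image if the path was built bound-first and not reversed).
#' @return list with `barrier` (kJ/mol, max energy minus the reactant's,
#'   >= 0), `ts_index` (transition-state image), `onset_index` (first image,
#'   scanning from the reactant, whose binding energy drops below zero;
#'   `NA` if binding energies are unavailable), and `profile` (a data frame
#'   with one row per image).
#' @export
barrier_report <- function(mep, reactant = 1) {
  if (is.numeric(mep)) {
    mep <- list(total_energy = mep,
                binding_energy = rep(NA_real_, length(mep)),
                com_distance = rep(NA_real_, length(mep)))
  }
  e <- mep$total_energy
  ni <- length(e)
  ts <- which.max(e)
  barrier <- max(e) - e[reactant]
  if (barrier <= 0) { barrier <- 0; ts <- reactant }
  scan <- if (reactant <= ni / 2) seq_len(ni) else rev(seq_len(ni))
  onset <- NA_integer_
  for (i in scan) {
    if (!is.na(mep$binding_energy[i]) && mep$binding_energy[i] < 0) {
      onset <- i
      break
    }
  }
  list(barrier = barrier, ts_index = ts, onset_index = onset,
       profile = data.frame(image = seq_len(ni),
                            com_distance = mep$com_distance,
                            total_energy = e,
                            binding_energy = mep$binding_energy))
}
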