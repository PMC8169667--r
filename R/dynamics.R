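#' Maxwell-Boltzmann velocities
#'
#' Draws bead velocities at temperature `T` and removes the center-of-mass
#' momentum. No rescaling is applied afterwards, so the instantaneous kinetic
#' temperature fluctuates about `T` with the usual O(1/sqrt(N)) spread.
#'
#' @param topo a [bead_topology()].
#' @param T target temperature (K).
#' @param seed optional integer seed for reproducibility.
#' @return n x 3 matrix of velocities (A/fs).
#' @export
init_velocities <- function(topo, T, seed = NULL) {
  if (T <= 0) stop("T must be positive", call. = FALSE)
  n <- n_beads(topo)
  if (n == 0) stop("topology has no beads", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # <v^2> = kB T / m in kJ/mol-amu units; 1e-4 converts to (A/fs)^2
  sd <- sqrt(.KB * T / topo$mass * 1e-4)
  v <- matrix(rnorm(3 * n), n, 3) * sd
  p <- colSums(v * topo$mass)
  v - matrix(p / sum(topo$mass), n, 3, byrow = TRUE)
}

#' NVT molecular dynamics
#'
#' Velocity-Verlet integration with Berendsen velocity rescaling
#' (`lambda = sqrt(1 + (dt/tau) (T_target/T_inst - 1))`). With `tau = Inf`
#' the thermostat is off and the run samples the NVE ensemble. Passing
#' DMD-scaled parameters (see [dmd_scaled_params()]) turns the same
#' integrator into the weakened-interaction proposal move.
#'
#' @param conf starting [conformation()]; velocities are taken from
#'   `velocities`, then `conf$velocities`, else drawn at `T`.
#' @param topo a [bead_topology()].
#' @param ff a [ff_params()].
#' @param T target temperature (K).
#' @param dt time step (fs).
#' @param n_steps number of integration steps.
#' @param tau Berendsen coupling time (fs); `Inf` disables the thermostat.
#' @param seed optional seed (used only if velocities are drawn here).
#' @param velocities optional n x 3 starting velocities (A/fs).
#' @param sample_every store a frame every this many steps (the initial and
#'   final frames are always stored).
#' @param container optional harmonic spherical restraint,
#'   `list(center =, radius =, k =)`, applied to every bead beyond `radius`
#'   from `center`; used by the search moves to keep clusters from
#'   evaporating. `NULL` for none.
#' @return A `"cg_trajectory"`: list with `frames` (coordinate matrices),
#'   `times` (fs), `thermo` (data frame: epot, ekin, temp), `box`, and
#'   `final` (a conformation carrying the final velocities).
#' @export
run_nvt <- function(conf, topo, ff, T, dt = 10, n_steps = 300, tau = 100,
                    seed = NULL, velocities = NULL, sample_every = n_steps,
                    container = NULL) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  sys <- .compile_sys(topo, ff, conf)
  if (is.null(velocities)) velocities <- conf$velocities
  if (is.null(velocities)) velocities <- init_velocities(topo, T, seed)
  cc <- numeric(0); crad <- -1; ckk <- 0
  if (!is.null(container)) {
    cc <- as.numeric(container$center); crad <- container$radius
    ckk <- if (is.null(container$k)) 10 else container$k
  }
  out <- cpp_run_nvt(sys, conf$coords, velocities, dt, as.integer(n_steps),
                     T, tau, ff$nonbonded_scale, as.integer(sample_every),
                     cc, crad, ckk)
  if (out$status != 0) {
    stop(sprintf(
      "energy overflow during MD: beads %d and %d at r = %.3g A (overlapping pair)",
      out$bad_pair[1], out$bad_pair[2], out$bad_r), call. = FALSE)
  }
  structure(
    list(frames = out$frames, times = out$times,
         thermo = data.frame(epot = out$epot, ekin = out$ekin, temp = out$temp),
         box = conf$box,
         final = conformation(out$coords, box = conf$box,
                              velocities = out$vel)),
    class = "cg_trajectory")
}

#' Assemble a trajectory from frames
#'
#' Convenience constructor mainly for the analysis functions: wraps a list of
#' coordinate matrices (or conformations) into the same `"cg_trajectory"`
#' shape that [run_nvt()] returns.
#'
#' @param frames list of n x 3 coordinate matrices or [conformation()]s.
#' @param times frame times (fs); default `0, 1, 2, ...`.
#' @param box periodic box or `NULL`.
#' @param thermo optional data frame with per-frame `epot`, `ekin`, `temp`.
#' @return a `"cg_trajectory"`.
#' @export
trajectory <- function(frames, times = NULL, box = NULL, thermo = NULL) {
  frames <- lapply(frames, function(fr) {
    if (inherits(fr, "conformation")) fr$coords else as.matrix(fr)
  })
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) {
    stop("times must match frame count", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (is.null(thermo)) {
    thermo <- data.frame(epot = rep(NA_real_, length(frames)),
                         ekin = NA_real_, temp = NA_real_)
  }
  if (nrow(thermo) != length(frames)) {
    stop("thermo rows must match frame count", call. = FALSE)
  }
  structure(list(frames = frames, times = times, thermo = thermo, box = box,
                 final = conformation(frames[[length(frames)]], box = box)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", length(x$frames), "frames,",
      nrow(x$frames[[1]]), "beads, t =", x$times[1], "...",
      x$times[length(x$times)], "fs\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `"cg_trajectory"`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)
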