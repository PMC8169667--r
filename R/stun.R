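#' Stochastic-tunnelling effective potential
#'
#' Monotone transform of the objective about the best value found so far,
#' `ln((f - f0) + sqrt((f - f0)^2 + 1))` (the inverse hyperbolic sine of
#' `f - f0`). It compresses the landscape above `f0` onto a gently growing
#' scale so the Metropolis walk can tunnel through high barriers, is zero at
#' `f = f0`, strictly increasing in `f`, and negative exactly when `f < f0`.
#'
#' @param f objective value(s), kJ/mol.
#' @param f0 lowest objective value found so far, kJ/mol.
#' @return dimensionless effective energy (vectorized over `f`).
#' @export
stun_transform <- function(f, f0) {
  d <- f - f0
  asinh(d)
}

#' Metropolis acceptance on the transformed surface
#'
#' A step is accepted outright when the new effective energy does not exceed
#' the stored one; otherwise it is accepted when the Boltzmann factor
#' `exp((stun_last - e_stun_new)/kT)` exceeds the supplied uniform variate.
#'
#' @param e_stun_new proposed effective energy.
#' @param stun_last stored effective energy of the current state.
#' @param kT Metropolis temperature parameter on the transformed surface
#'   (dimensionless effective-energy units), positive.
#' @param u uniform random number in `[0, 1]`.
#' @return logical: accept?
#' @export
boltzmann_accept <- function(e_stun_new, stun_last, kT, u) {
  if (kT <= 0) stop("kT must be positive", call. = FALSE)
  if (e_stun_new <= stun_last) return(TRUE)
  exp((stun_last - e_stun_new) / kT) > u
}

#' Search-state constructor
#'
#' @param conf minimized starting [conformation()].
#' @param f0 objective value of `conf` (the initial best).
#' @param kT0 initial Metropolis temperature on the transformed surface.
#' @param container_radius radius (A) of the harmonic container applied
#'   during proposal moves; by default sized once from the extent of the
#'   starting structure (its maximal center-of-geometry distance plus 5 A)
#'   and then held fixed, so proposal moves cannot progressively evaporate
#'   the system. `NA` disables the container.
#' @return an object of class `"stun_state"`.
#' @export
new_search_state <- function(conf, f0, kT0 = 1.0, container_radius = NULL) {
  if (is.null(container_radius)) {
    centre <- colMeans(conf$coords)
    container_radius <-
      max(sqrt(rowSums(sweep(conf$coords, 2, centre)^2))) + 5
  }
  structure(
    list(f0 = f0, stun_last = 0.0, x_last = conf$coords, box = conf$box,
         kT = kT0, accept_history = logical(0), iteration = 0L,
         mode_next = "MD", best = list(coords = conf$coords, f = f0),
         container_radius = container_radius),
    class = "stun_state")
}

#' Adaptive Metropolis temperature
#'
#' Every `period` steps the acceptance fraction over the last `period` steps
#' is compared to the target (50%): too many acceptances cool the walk
#' (`kT / factor`), too few heat it (`kT * factor`); at exactly the target
#' `kT` is unchanged. `kT` is clamped to `[1e-6, 1e6]`.
#'
#' @param state a `"stun_state"`.
#' @param period adaptation period (steps).
#' @param target target acceptance fraction.
#' @param factor multiplicative adjustment factor.
#' @return the state with updated `kT`.
#' @export
adapt_kT <- function(state, period = 20L, target = 0.5, factor = 1.2) {
  h <- utils::tail(state$accept_history, period)
  frac <- mean(h)
  if (frac > target) {
    state$kT <- state$kT / factor
  } else if (frac < target) {
    state$kT <- state$kT * factor
  }
  state$kT <- min(max(state$kT, 1e-6), 1e6)
  state
}

#' Move and control settings for the search
#'
#' Defaults follow the published protocol: proposal moves are 300 NVT steps
#' of 10 fs at 600 K, nonbonded interactions weakened to 1/100 on every
#' second (DMD) move, `kT` re-adapted every 20 steps toward 50% acceptance.
#'
#' @param T_move proposal-move temperature (K).
#' @param dt time step (fs).
#' @param n_steps MD steps per proposal move.
#' @param tau Berendsen coupling constant (fs).
#' @param dmd_scale nonbonded scale of the DMD proposal surface.
#' @param objective `"binding"` (ligand-receptor interaction energy, the
#'   default) or `"total"` (total potential energy, for ligand-free
#'   clusters).
#' @param force_tol,max_iter_min local-minimization controls.
#' @param kT0 initial Metropolis temperature (transformed-surface units).
#' @param adapt_period,adapt_target,adapt_factor acceptance-controller knobs.
#' @param container_k,container_radius harmonic container applied during the
#'   proposal MD (not during minimization and not part of the objective);
#'   `container_radius = NULL` auto-sizes from the system extent, `NA`
#'   disables the container.
#' @return a settings list of class `"stun_settings"`.
#' @export
stun_settings <- function(T_move = 600, dt = 10, n_steps = 300, tau = 100,
                          dmd_scale = 0.01,
                          objective = c("binding", "total"),
                          force_tol = 1e-2, max_iter_min = 2000,
                          kT0 = 1.0, adapt_period = 20L, adapt_target = 0.5,
                          adapt_factor = 1.2, container_k = 10,
                          container_radius = NULL) {
  structure(list(T_move = T_move, dt = dt, n_steps = n_steps, tau = tau,
                 dmd_scale = dmd_scale, objective = match.arg(objective),
                 force_tol = force_tol, max_iter_min = max_iter_min,
                 kT0 = kT0, adapt_period = as.integer(adapt_period),
                 adapt_target = adapt_target, adapt_factor = adapt_factor,
                 container_k = container_k,
                 container_radius = container_radius),
            class = "stun_settings")
}

.objective_value <- function(conf, topo, ff, settings) {
  if (settings$objective == "binding") {
    group_interaction_energy(conf, topo, ff, "ligand", "receptor")
  } else {
    total_energy(conf, topo, ff)
  }
}

.auto_container <- function(coords, settings, state_radius = NULL) {
  r <- settings$container_radius
  if (is.null(r)) r <- state_radius
  if (is.null(r) || is.na(r)) return(NULL)
  list(center = colMeans(coords), radius = r, k = settings$container_k)
}

#' One STUN-BH-DMD iteration
#'
#' Runs one proposal move (NVT MD on the physical surface or on the
#' DMD-weakened surface, alternating), minimizes the result on the physical
#' surface, evaluates the objective, and applies the three-case Metropolis
#' rule on the transformed surface: a new minimum (`f < f0`) is always
#' accepted and becomes the new `f0`; a non-improving move is accepted by
#' [boltzmann_accept()]; a rejected move restores the stored coordinates.
#' Every `adapt_period` iterations the Metropolis temperature is re-adapted.
#' An MD blow-up counts as a rejection (with a warning).
#'
#' Randomness (proposal velocities, the acceptance variate) is drawn from the
#' R random number stream; seed the session or [run_search()] for
#' reproducibility.
#'
#' @param state a `"stun_state"`.
#' @param topo a [bead_topology()].
#' @param ff physical (unscaled) [ff_params()].
#' @param settings a [stun_settings()].
#' @return the updated state.
#' @export
stun_step <- function(state, topo, ff, settings = stun_settings()) {
  conf <- conformation(state$x_last, box = state$box)
  ff_move <- if (state$mode_next == "DMD") {
    dmd_scaled_params(ff, settings$dmd_scale)
  } else {
    ff
  }
  cont <- .auto_container(state$x_last, settings, state$container_radius)
  vel <- init_velocities(topo, settings$T_move)
  u <- runif(1)

  proposal <- tryCatch({
    traj <- run_nvt(conf, topo, ff_move, T = settings$T_move,
                    dt = settings$dt, n_steps = settings$n_steps,
                    tau = settings$tau, velocities = vel,
                    sample_every = settings$n_steps, container = cont)
    # the PES of record is the physical one: minimize with unscaled params
    local_minimize(traj$final, topo, ff, force_tol = settings$force_tol,
                   max_iter = settings$max_iter_min)
  }, error = function(e) e)

  accepted <- FALSE
  f <- NA_real_; e_stun <- NA_real_
  if (inherits(proposal, "error")) {
    warning("proposal move failed (", conditionMessage(proposal),
            "); step rejected", call. = FALSE)
  } else {
    f <- .objective_value(proposal$conformation, topo, ff, settings)
    if (f < state$f0) {
      state$f0 <- f
      state$best <- list(coords = proposal$conformation$coords, f = f)
      e_stun <- 0.0
      accepted <- TRUE
    } else {
      e_stun <- stun_transform(f, state$f0)
      accepted <- boltzmann_accept(e_stun, state$stun_last, state$kT, u)
    }
    if (accepted) {
      state$stun_last <- e_stun
      state$x_last <- proposal$conformation$coords
    }
  }
  state$iteration <- state$iteration + 1L
  state$accept_history <- c(state$accept_history, accepted)
  state$mode_next <- if (state$mode_next == "MD") "DMD" else "MD"
  state$last <- list(f = f, e_stun = e_stun, accepted = accepted)
  if (state$iteration %% settings$adapt_period == 0) {
    state <- adapt_kT(state, settings$adapt_period, settings$adapt_target,
                      settings$adapt_factor)
  }
  state
}

#' Random rigid re-orientation of the receptor
#'
#' Rotates the receptor beads by a rotation drawn uniformly from SO(3)
#' (random unit quaternion) about the receptor's center of mass; all other
#' beads are untouched and the receptor's internal geometry is preserved.
#'
#' @param conf a [conformation()].
#' @param topo a [bead_topology()] with a non-empty receptor group.
#' @param seed optional integer seed.
#' @return the rotated conformation.
#' @export
random_orientation <- function(conf, topo, seed = NULL) {
  idx <- group_indices(topo, "receptor")
  if (!length(idx)) stop("receptor group is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  R <- .random_rotation()
  coords <- conf$coords
  com <- .com(coords, topo$mass, idx)
  centered <- sweep(coords[idx, , drop = FALSE], 2, com)
  coords[idx, ] <- centered %*% t(R) + matrix(com, length(idx), 3, byrow = TRUE)
  conformation(coords, box = conf$box, velocities = conf$velocities)
}

# uniform rotation matrix from a random unit quaternion
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Multi-start STUN-BH-DMD global search
#'
#' For each start the receptor is randomly re-oriented about its center of
#' mass (start 1 keeps the supplied pose), the system is minimized, and
#' `iters_per_start` STUN-BH-DMD iterations are run. The global best over all
#' starts (lowest objective) is returned together with the per-iteration log.
#' A start that fails entirely is skipped with a warning; at least one start
#' must complete.
#'
#' @param conf starting [conformation()].
#' @param topo a [bead_topology()].
#' @param ff physical [ff_params()].
#' @param n_starts number of independent starts.
#' @param iters_per_start STUN-BH-DMD iterations per start.
#' @param seed master seed; per-start seeds are derived from it and logged.
#' @param settings a [stun_settings()].
#' @return An object of class `"stun_search"`: list with
#'   `best_conformation`, `best_f` (kJ/mol), `log` (data frame with columns
#'   start, iteration, mode, f, f0, e_stun, kT, accepted), `start_seeds` and
#'   `settings`.
#' @export
run_search <- function(conf, topo, ff, n_starts = 1, iters_per_start = 100,
                       seed = NULL, settings = stun_settings()) {
  if (!is.null(seed)) set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  has_receptor <- length(group_indices(topo, "receptor")) > 0
  best <- NULL
  logs <- vector("list", n_starts)
  completed <- 0L
  for (s in seq_len(n_starts)) {
    res <- tryCatch({
      set.seed(start_seeds[s])
      conf_s <- if (has_receptor && s > 1) {
        random_orientation(conf, topo)
      } else {
        conf
      }
      m <- local_minimize(conf_s, topo, ff, force_tol = settings$force_tol,
                          max_iter = settings$max_iter_min)
      f0 <- .objective_value(m$conformation, topo, ff, settings)
      state <- new_search_state(m$conformation, f0, settings$kT0)
      rows <- vector("list", iters_per_start)
      for (it in seq_len(iters_per_start)) {
        mode <- state$mode_next
        state <- stun_step(state, topo, ff, settings)
        rows[[it]] <- data.frame(
          start = s, iteration = it, mode = mode,
          f = state$last$f, f0 = state$f0, e_stun = state$last$e_stun,
          kT = state$kT, accepted = state$last$accepted)
      }
      list(state = state,
           log = if (iters_per_start > 0) do.call(rbind, rows) else NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("start ", s, " failed: ", conditionMessage(res), call. = FALSE)
      next
    }
    completed <- completed + 1L
    logs[[s]] <- res$log
    if (is.null(best) || res$state$best$f < best$f) best <- res$state$best
  }
  if (completed == 0L) stop("all starts failed", call. = FALSE)
  # polish: re-minimize the global best with a generous budget so the
  # reported structure and objective are tightly converged
  polish <- local_minimize(conformation(best$coords, box = conf$box), topo, ff,
                           force_tol = settings$force_tol,
                           max_iter = 4L * settings$max_iter_min)
  f_pol <- .objective_value(polish$conformation, topo, ff, settings)
  if (f_pol < best$f) {
    best <- list(coords = polish$conformation$coords, f = f_pol)
  }
  structure(
    list(best_conformation = conformation(best$coords, box = conf$box),
         best_f = best$f,
         log = do.call(rbind, logs[!vapply(logs, is.null, logical(1))]),
         start_seeds = start_seeds, settings = settings,
         n_starts = n_starts, iters_per_start = iters_per_start),
    class = "stun_search")
}

#' @export
print.stun_search <- function(x, ...) {
  cat("stun_search:", x$n_starts, "starts x", x$iters_per_start,
      "iterations\n")
  cat(sprintf("  best objective: %.6g kJ/mol\n", x$best_f))
  if (!is.null(x$log) && nrow(x$log)) {
    cat(sprintf("  overall acceptance: %.1f%%\n",
                100 * mean(x$log$accepted)))
  }
  invisible(x)
}
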