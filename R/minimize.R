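#' Local geometry optimization
#'
#' Maps a conformation to its nearest local minimum on the (unscaled or
#' scaled) potential-energy surface. The default optimizer is FIRE (fast
#' inertial relaxation engine) with an adaptive time step and a per-bead
#' displacement cap; `method = "cg"` uses Polak-Ribiere conjugate gradients
#' via [stats::optim()].
#'
#' @param conf starting [conformation()].
#' @param topo a [bead_topology()].
#' @param ff a [ff_params()].
#' @param method `"fire"` (default) or `"cg"`.
#' @param force_tol convergence threshold on the largest per-bead force norm
#'   (kJ/mol/A).
#' @param max_iter iteration budget; on non-convergence the best structure
#'   seen is returned with `converged = FALSE`.
#' @param container optional spherical restraint as in [run_nvt()].
#' @return list with `conformation`, `energy` (kJ/mol), `converged`,
#'   `fmax` and `iterations`.
#' @export
local_minimize <- function(conf, topo, ff, method = c("fire", "cg"),
                           force_tol = 1e-2, max_iter = 5000,
                           container = NULL) {
  method <- match.arg(method)
  sys <- .compile_sys(topo, ff, conf)
  cc <- numeric(0); crad <- -1; ckk <- 0
  if (!is.null(container)) {
    cc <- as.numeric(container$center); crad <- container$radius
    ckk <- if (is.null(container$k)) 10 else container$k
  }
  if (method == "fire") {
    out <- cpp_fire(sys, conf$coords, ff$nonbonded_scale, force_tol,
                    as.integer(max_iter), 0.05, 0.5, 0.3, cc, crad, ckk)
    coords <- out$coords
    res <- list(energy = out$energy, converged = out$converged,
                fmax = out$fmax, iterations = out$iterations)
  } else {
    n <- n_beads(topo)
    fn <- function(x) {
      cpp_eval(sys, matrix(x, n, 3), ff$nonbonded_scale,
               integer(0), integer(0), FALSE, FALSE)$energy
    }
    gr <- function(x) {
      -as.numeric(cpp_eval(sys, matrix(x, n, 3), ff$nonbonded_scale,
                           integer(0), integer(0), FALSE, TRUE)$forces)
    }
    opt <- stats::optim(as.numeric(conf$coords), fn, gr, method = "CG",
                        control = list(maxit = max_iter, reltol = 1e-14))
    coords <- matrix(opt$par, n, 3)
    f <- cpp_eval(sys, coords, ff$nonbonded_scale, integer(0), integer(0),
                  FALSE, TRUE)$forces
    fmax <- max(sqrt(rowSums(f^2)))
    res <- list(energy = opt$value, converged = fmax <= force_tol,
                fmax = fmax, iterations = opt$counts[["function"]])
  }
  res$conformation <- conformation(coords, box = conf$box)
  res[c("conformation", "energy", "converged", "fmax", "iterations")]
}
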