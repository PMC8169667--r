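#' Force-field parameters for the coarse-grained bead model
#'
#' Typed Lennard-Jones plus screened Coulomb nonbonded interactions, both
#' multiplied by a quintic switching polynomial that takes each pair potential
#' smoothly to zero at the cutoff (value and first two derivatives vanish at
#' both ends of the switching window). Cross terms default to
#' Lorentz-Berthelot combination; explicit pair overrides may be given.
#'
#' @param types character vector of known bead type labels.
#' @param sigma per-type LJ sigma (A); single value recycled, or named by type.
#' @param epsilon per-type LJ epsilon (kJ/mol); recycled or named by type.
#' @param pair_sigma,pair_eps optional named numeric vectors overriding
#'   specific pairs; names are `"A:B"` type pairs (order-insensitive).
#' @param dielectric relative dielectric screening of the Coulomb term
#'   (default 15, the standard value for non-polarizable MARTINI water).
#' @param coulomb_prefactor Coulomb constant, kJ/mol * A / e^2.
#' @param r_cut nonbonded cutoff (A); pairs at `r >= r_cut` contribute 0.
#' @param lj_shift_start switching-window start for the LJ term (A);
#'   `>= r_cut` disables switching (plain truncation).
#' @param coulomb_shift_start switching-window start for the Coulomb term (A).
#' @param nonbonded_scale uniform scale factor in (0, 1] applied to all
#'   nonbonded terms; 1 is the physical (MD) surface, 0.01 the weakened
#'   DMD proposal surface.
#' @param kB Boltzmann constant (kJ/mol/K).
#' @param dmd_hardcore if `TRUE`, pairs closer than `r_hardcore` keep the
#'   unscaled LJ term even in DMD mode (an optional repulsive floor; off by
#'   default).
#' @param r_hardcore hard-core radius (A) used when `dmd_hardcore` is `TRUE`.
#' @return An object of class `"ff_params"`.
#' @export
ff_params <- function(types, sigma = 4.7, epsilon = 5.0,
                      pair_sigma = NULL, pair_eps = NULL,
                      dielectric = 15, coulomb_prefactor = 1389.35,
                      r_cut = 12, lj_shift_start = 9,
                      coulomb_shift_start = 0.5,
                      nonbonded_scale = 1.0, kB = .KB,
                      dmd_hardcore = FALSE, r_hardcore = 3.0) {
  types <- as.character(types)
  sigma <- .per_type(sigma, types, "sigma")
  epsilon <- .per_type(epsilon, types, "epsilon")
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  if (r_cut <= 0) stop("r_cut must be positive", call. = FALSE)
  if (lj_shift_start <= 0 || coulomb_shift_start <= 0) {
    stop("shift starts must be positive", call. = FALSE)
  }
  if (nonbonded_scale <= 0 || nonbonded_scale > 1) {
    stop("nonbonded_scale must lie in (0, 1]", call. = FALSE)
  }
  nt <- length(types)
  sig <- outer(sigma, sigma, function(a, b) (a + b) / 2)
  eps <- outer(epsilon, epsilon, function(a, b) sqrt(a * b))
  dimnames(sig) <- dimnames(eps) <- list(types, types)
  .apply_pairs <- function(mat, overrides, what) {
    if (is.null(overrides)) return(mat)
    for (nm in names(overrides)) {
      ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(ab) != 2 || !all(ab %in% types)) {
        stop("unknown type pair in ", what, ": ", nm, call. = FALSE)
      }
      mat[ab[1], ab[2]] <- mat[ab[2], ab[1]] <- overrides[[nm]]
    }
    mat
  }
  sig <- .apply_pairs(sig, pair_sigma, "pair_sigma")
  eps <- .apply_pairs(eps, pair_eps, "pair_eps")
  structure(
    list(types = types, sigma = sigma, epsilon = epsilon,
         sig_mat = sig, eps_mat = eps,
         dielectric = dielectric, coulomb_prefactor = coulomb_prefactor,
         r_cut = r_cut, lj_shift_start = lj_shift_start,
         coulomb_shift_start = coulomb_shift_start,
         nonbonded_scale = nonbonded_scale, kB = kB,
         dmd_hardcore = dmd_hardcore, r_hardcore = r_hardcore),
    class = "ff_params")
}

.per_type <- function(x, types, what) {
  if (!is.null(names(x))) {
    if (!all(types %in% names(x))) {
      stop(what, " is named but misses types: ",
           paste(setdiff(types, names(x)), collapse = ", "), call. = FALSE)
    }
    return(as.numeric(x[types]))
  }
  rep_len(as.numeric(x), length(types))
}

#' @export
print.ff_params <- function(x, ...) {
  cat("ff_params:", length(x$types), "types (",
      paste(x$types, collapse = ", "), ")\n")
  cat(sprintf("  r_cut %.4g A, LJ switch from %.4g A, Coulomb switch from %.4g A\n",
              x$r_cut, x$lj_shift_start, x$coulomb_shift_start))
  cat(sprintf("  dielectric %.4g, nonbonded scale %.4g%s\n", x$dielectric,
              x$nonbonded_scale,
              if (x$nonbonded_scale < 1) " (DMD mode)" else ""))
  invisible(x)
}

#' DMD-mode parameters: uniformly weakened nonbonded interactions
#'
#' Returns a copy of the parameters with all nonbonded interaction strengths
#' (LJ and Coulomb) uniformly reduced, by default to 1/100 of their physical
#' values; bonded terms are untouched. Applying it to an already scaled
#' parameter set warns and returns the input unchanged (idempotent).
#'
#' @param ff a [ff_params()] with `nonbonded_scale = 1`.
#' @param scale target scale factor (default 0.01).
#' @return scaled `ff_params`.
#' @export
dmd_scaled_params <- function(ff, scale = 0.01) {
  stopifnot(inherits(ff, "ff_params"))
  if (ff$nonbonded_scale < 1) {
    warning("parameters are already DMD-scaled; returning them unchanged",
            call. = FALSE)
    return(ff)
  }
  ff$nonbonded_scale <- scale
  ff
}

#' Compile a system for the C++ kernels (internal)
#' @noRd
.compile_sys <- function(topo, ff, conf) {
  stopifnot(inherits(topo, "bead_topology"), inherits(ff, "ff_params"))
  n <- n_beads(topo)
  if (nrow(conf$coords) != n) {
    stop("conformation has ", nrow(conf$coords), " beads but topology has ", n,
         call. = FALSE)
  }
  ti <- match(topo$bead_type, ff$types)
  if (anyNA(ti)) {
    stop("bead types unknown to the force field: ",
         paste(unique(topo$bead_type[is.na(ti)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(conf$box) && any(conf$box <= 2 * ff$r_cut)) {
    stop("periodic box lengths must exceed 2 * r_cut", call. = FALSE)
  }
  bonds <- topo$bonds
  angles <- topo$angles
  excl <- rbind(
    if (nrow(bonds)) cbind(bonds$i, bonds$j),
    if (nrow(angles)) cbind(angles$i, angles$k))
  if (is.null(excl)) excl <- matrix(integer(0), 0, 2)
  list(
    n = n, ntype = length(ff$types),
    box = if (is.null(conf$box)) numeric(0) else conf$box,
    type = ti - 1L,
    sig = as.numeric(ff$sig_mat), eps = as.numeric(ff$eps_mat),
    q = topo$charge, mass = topo$mass,
    coulk = ff$coulomb_prefactor / ff$dielectric,
    rcut = ff$r_cut, ljs = ff$lj_shift_start, couls = ff$coulomb_shift_start,
    kB = ff$kB, hardcore = isTRUE(ff$dmd_hardcore), r_hc = ff$r_hardcore,
    bonds = matrix(as.integer(c(bonds$i, bonds$j)) - 1L, ncol = 2),
    bond_r0 = as.numeric(bonds$r0), bond_k = as.numeric(bonds$k),
    angles = matrix(as.integer(c(angles$i, angles$j, angles$k)) - 1L, ncol = 3),
    angle_th0 = as.numeric(angles$theta0) * pi / 180,
    angle_k = as.numeric(angles$ka),
    excl = matrix(as.integer(excl) - 1L, ncol = 2))
}

#' Total potential energy
#'
#' Bond + angle + switched, scaled LJ + Coulomb energy of a conformation.
#' Nonbonded pairs use minimum-image distances when the box is periodic and
#' contribute exactly zero at or beyond the cutoff.
#'
#' @param conf a [conformation()].
#' @param topo a [bead_topology()].
#' @param ff a [ff_params()].
#' @param components if `TRUE` return the bond/angle/LJ/Coulomb split.
#' @return energy in kJ/mol (or a named list of components).
#' @export
total_energy <- function(conf, topo, ff, components = FALSE) {
  sys <- .compile_sys(topo, ff, conf)
  out <- cpp_eval(sys, conf$coords, ff$nonbonded_scale,
                  integer(0), integer(0), FALSE, FALSE)
  if (components) out else out$energy
}

#' Per-bead forces
#'
#' Analytic negative gradient of [total_energy()]; continuous across the
#' switching window and exactly zero at the cutoff.
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces, kJ/mol/A.
#' @export
forces <- function(conf, topo, ff) {
  sys <- .compile_sys(topo, ff, conf)
  cpp_eval(sys, conf$coords, ff$nonbonded_scale,
           integer(0), integer(0), FALSE, TRUE)$forces
}

#' Cross-group interaction energy
#'
#' Sum of the scaled, switched LJ + Coulomb terms over pairs with one bead in
#' each selection. This is the search objective f(x): the interaction energy
#' between the ligand beads and the receptor beads.
#'
#' @inheritParams total_energy
#' @param group_a,group_b disjoint bead selections (group name, index vector
#'   or logical mask; see [group_indices()]).
#' @return energy in kJ/mol.
#' @export
group_interaction_energy <- function(conf, topo, ff, group_a = "ligand",
                                     group_b = "receptor") {
  ia <- group_indices(topo, group_a)
  ib <- group_indices(topo, group_b)
  if (length(intersect(ia, ib))) {
    stop("group_a and group_b must be disjoint", call. = FALSE)
  }
  sys <- .compile_sys(topo, ff, conf)
  cpp_eval(sys, conf$coords, ff$nonbonded_scale, ia, ib, TRUE, FALSE)$energy
}

#' Fixed-geometry binding energy
#'
#' Binding energy of the ligand on the receptor from single-point energies at
#' identical coordinates: the full system, the system with the ligand
#' removed, the system with the receptor removed, and the environment
#' (solvent + ions) alone, combined by inclusion-exclusion,
#' \deqn{G_{BE} = G_{complex} - G_{-ligand} - G_{-receptor} + G_{env}.}
#' Solvent and ions are retained in every term; for a pairwise-additive
#' potential this equals the ligand-receptor cross-pair sum exactly, and when
#' no environment beads are present it reduces to the plain three-term
#' difference of complex, isolated ligand and isolated receptor.
#'
#' @inheritParams total_energy
#' @param mode decomposition mode; only `"fixed_geometry"` is defined.
#' @param ligand,receptor bead selections (default the group labels).
#' @return binding energy in kJ/mol.
#' @export
binding_energy <- function(conf, topo, ff, mode = "fixed_geometry",
                           ligand = "ligand", receptor = "receptor") {
  mode <- match.arg(mode, "fixed_geometry")
  il <- group_indices(topo, ligand)
  ir <- group_indices(topo, receptor)
  if (!length(il)) stop("no ligand beads in topology", call. = FALSE)
  if (!length(ir)) stop("no receptor beads in topology", call. = FALSE)
  if (length(intersect(il, ir))) {
    stop("ligand and receptor selections must be disjoint", call. = FALSE)
  }
  all_idx <- seq_len(n_beads(topo))
  env <- setdiff(all_idx, c(il, ir))
  e_of <- function(keep) {
    if (!length(keep)) return(0)
    s <- subset_system(topo, conf, keep)
    total_energy(s$conf, s$topo, ff)
  }
  e_of(all_idx) - e_of(c(ir, env)) - e_of(c(il, env)) + e_of(env)
}
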