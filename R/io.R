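#' Write a structure as PDB
#'
#' One ATOM record per bead: atom name = bead type, residue number =
#' residue id, chain = group (L/R/W/I for ligand/receptor/solvent/ion),
#' occupancy = numeric group code (1-4), B-factor = residue id. Coordinates
#' are written at PDB's native 3-decimal precision; the in-memory
#' representation is never rounded.
#'
#' @param conf a [conformation()].
#' @param topo a [bead_topology()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(conf, topo, path) {
  chain_of <- c(ligand = "L", receptor = "R", solvent = "W", ion = "I")
  gcode <- c(ligand = 1, receptor = 2, solvent = 3, ion = 4)
  resid3 <- c(ligand = "LIG", receptor = "REC", solvent = "SOL", ion = "ION")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(conf$coords)),
    type = rep("ATOM", n_beads(topo)),
    resno = topo$residue_id,
    resid = resid3[topo$group],
    eleno = seq_len(n_beads(topo)),
    elety = topo$bead_type,
    chain = chain_of[topo$group],
    o = gcode[topo$group],
    b = topo$residue_id)
  invisible(path)
}

#' Read a structure from PDB
#'
#' Rebuilds a topology + conformation from a PDB file and a mapping
#' configuration that declares the bead library (name to mass/charge) and
#' the chain-to-group assignment. Bonded terms, if any, are carried by the
#' mapping as well.
#'
#' @param path PDB file.
#' @param mapping list with elements:
#'   \describe{
#'     \item{beads}{named list: for each bead name, a list with `mass`
#'       (amu), and optionally `charge` (e) and `backbone` (logical).}
#'     \item{chains}{named character vector mapping chain id to group label
#'       (default `c(L = "ligand", R = "receptor", W = "solvent",
#'       I = "ion")`).}
#'     \item{bonds, angles}{optional bonded-term data frames as in
#'       [bead_topology()].}
#'   }
#' @param box optional periodic box lengths.
#' @return list with `topo` and `conf`.
#' @export
read_structure <- function(path, mapping, box = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  names_seen <- trimws(at$elety)
  known <- names(mapping$beads)
  unknown <- setdiff(unique(names_seen), known)
  if (length(unknown)) {
    stop("bead names missing from the mapping: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  chains <- mapping$chains
  if (is.null(chains)) {
    chains <- c(L = "ligand", R = "receptor", W = "solvent", I = "ion")
  }
  ch <- as.character(at$chain)
  if (any(!ch %in% names(chains))) {
    stop("chains missing from the mapping: ",
         paste(setdiff(unique(ch), names(chains)), collapse = ", "),
         call. = FALSE)
  }
  get_field <- function(nm, field, default) {
    v <- mapping$beads[[nm]][[field]]
    if (is.null(v)) default else v
  }
  topo <- bead_topology(
    bead_type = names_seen,
    mass = vapply(names_seen, get_field, 0, field = "mass", default = 72),
    charge = vapply(names_seen, get_field, 0, field = "charge", default = 0),
    group = unname(chains[ch]),
    residue_id = at$resno,
    backbone = vapply(names_seen, get_field, FALSE, field = "backbone",
                      default = FALSE),
    bonds = mapping$bonds, angles = mapping$angles)
  conf <- conformation(cbind(at$x, at$y, at$z), box = box)
  list(topo = topo, conf = conf)
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying
#' `time=<fs> epot=<kJ/mol> ekin=<kJ/mol> temp=<K>` (and `box="lx ly lz"`
#' when periodic), then one `type x y z` line per bead.
#'
#' @param traj a `"cg_trajectory"`.
#' @param topo a [bead_topology()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, topo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(traj$frames[[1]])
  for (i in seq_along(traj$frames)) {
    th <- traj$thermo[i, ]
    comment <- sprintf("time=%.10g epot=%.10g ekin=%.10g temp=%.10g",
                       traj$times[i], th$epot, th$ekin, th$temp)
    if (!is.null(traj$box)) {
      comment <- paste0(comment, sprintf(' box="%.10g %.10g %.10g"',
                                         traj$box[1], traj$box[2], traj$box[3]))
    }
    writeLines(c(as.character(n), comment), con)
    fr <- traj$frames[[i]]
    writeLines(sprintf("%s %.10g %.10g %.10g", topo$bead_type,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path file written by [write_trajectory()].
#' @return a `"cg_trajectory"` (bead types of the first frame attached as
#'   attribute `"bead_type"`).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  pos <- 1
  frames <- list()
  times <- epot <- ekin <- temp <- numeric(0)
  box <- NULL
  types <- NULL
  parse_kv <- function(comment, key) {
    m <- regmatches(comment, regexec(paste0(key, '="?([^" ]+)'), comment))[[1]]
    if (length(m) < 2) NA_real_ else as.numeric(m[2])
  }
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1; next }
    n <- as.integer(lines[pos])
    comment <- lines[pos + 1]
    times <- c(times, parse_kv(comment, "time"))
    epot <- c(epot, parse_kv(comment, "epot"))
    ekin <- c(ekin, parse_kv(comment, "ekin"))
    temp <- c(temp, parse_kv(comment, "temp"))
    bm <- regmatches(comment, regexec('box="([^"]+)"', comment))[[1]]
    if (length(bm) == 2) box <- as.numeric(strsplit(bm[2], " +")[[1]])
    block <- lines[pos + 1 + seq_len(n)]
    parts <- strsplit(trimws(block), "[ \t]+")
    if (is.null(types)) types <- vapply(parts, `[`, "", 1)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- co
    pos <- pos + 2 + n
  }
  tr <- trajectory(frames, times = times, box = box,
                   thermo = data.frame(epot = epot, ekin = ekin, temp = temp))
  attr(tr, "bead_type") <- types
  tr
}

#' Load run configuration
#'
#' Shipped defaults follow the published coarse-grained protocol: 10 fs time
#' step, 600 K proposal moves of 300 steps, acceptance-controller period 20
#' with a 50% target, 12 A cutoff with LJ switching from 9 A and Coulomb
#' switching from 0.5 A, dielectric 15, 16 NEB images. A YAML file and/or an
#' override list replace individual keys; unknown keys are an error in
#' strict mode and a warning otherwise.
#'
#' @param path optional YAML config file.
#' @param overrides optional named list applied after the file.
#' @param strict unknown keys are an error (`TRUE`, default) or a warning.
#' @return named list of validated settings, class `"stun_config"`.
#' @export
load_config <- function(path = NULL, overrides = list(), strict = TRUE) {
  defaults <- list(
    dt = 10, temperature_move = 600, steps_per_move = 300, tau = 100,
    adapt_period = 20L, acceptance_target = 0.5, adapt_factor = 1.2,
    kT0 = 1.0, dmd_scale = 0.01,
    r_cut = 12, lj_shift_start = 9, coulomb_shift_start = 0.5,
    dielectric = 15, neb_images = 16L, spring_k = 10, force_tol = 1e-2,
    density = 1.0, min_dist = 5, seed = NULL)
  cfg <- defaults
  apply_keys <- function(cfg, vals, src) {
    unknown <- setdiff(names(vals), names(defaults))
    if (length(unknown)) {
      msg <- paste0("unknown configuration key(s) in ", src, ": ",
                    paste(unknown, collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      vals <- vals[setdiff(names(vals), unknown)]
    }
    modifyList(cfg, vals)
  }
  if (!is.null(path)) cfg <- apply_keys(cfg, yaml::read_yaml(path), path)
  if (length(overrides)) cfg <- apply_keys(cfg, overrides, "overrides")
  for (key in c("dt", "temperature_move", "steps_per_move", "r_cut",
                "dielectric", "neb_images", "adapt_period")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("configuration key '", key, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (cfg$acceptance_target <= 0 || cfg$acceptance_target >= 1) {
    stop("configuration key 'acceptance_target' must lie in (0, 1)",
         call. = FALSE)
  }
  class(cfg) <- "stun_config"
  cfg
}

#' Literature reference binding energies
#'
#' Published binding energies (kJ/mol) for the MARTINI coarse-grained
#' EpCAM/aptamer complex that motivates the defaults of this package: the
#' pocket-bound pose found by searching directly in water, the secondary
#' pose outside the pocket, and the vacuum-derived pose re-relaxed in water.
#' Used for worked examples of relative-stability arithmetic.
#'
#' @return data frame with columns `complex` and `binding_energy`.
#' @export
reference_binding_energies <- function() {
  data.frame(
    complex = c("pocket_bound", "outside_pocket", "vacuum_refined"),
    binding_energy = c(-1837.8, -1675.1, -1780.0))
}

#' Relative binding-energy difference
#'
#' Percentage by which `e_other` is weaker (higher, i.e. less negative) than
#' the reference binding energy `e_ref`:
#' `100 * (e_other - e_ref) / |e_ref|`.
#'
#' @param e_ref reference (strongest) binding energy, kJ/mol.
#' @param e_other binding energy to compare, kJ/mol.
#' @return percentage difference.
#' @export
relative_binding_difference <- function(e_ref, e_other) {
  100 * (e_other - e_ref) / abs(e_ref)
}
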