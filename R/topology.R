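#' Bead topology
#'
#' Container for the per-bead identities of a coarse-grained system: bead
#' types, masses, charges, bonded terms, and the group partition
#' (ligand / receptor / solvent / ion) with residue labels used by the
#' binding-energy decomposition and the analysis module.
#'
#' @param bead_type character vector, one type label per bead.
#' @param mass numeric vector of bead masses (amu), positive.
#' @param charge numeric vector of bead charges (elementary charge units).
#' @param group character vector; each bead is exactly one of
#'   `"ligand"`, `"receptor"`, `"solvent"`, `"ion"`.
#' @param residue_id integer vector: receptor residue index or ligand
#'   nucleobase index of each bead.
#' @param backbone logical vector: `TRUE` for ligand backbone beads,
#'   `FALSE` for nucleobase (or non-ligand) beads.
#' @param bonds data frame with columns `i`, `j`, `r0` (A) and
#'   `k` (kJ/mol/A^2), or `NULL`. Energies are `0.5 * k * (r - r0)^2`.
#' @param angles data frame with columns `i`, `j`, `k`, `theta0` (degrees)
#'   and `ka` (kJ/mol/rad^2), or `NULL`; `j` is the vertex. Energies are
#'   `0.5 * ka * (theta - theta0)^2`.
#'
#' @return An object of class `"bead_topology"`.
#' @details Directly bonded (1-2) pairs and angle-end (1-3) pairs are
#'   excluded from nonbonded interactions.
#' @export
bead_topology <- function(bead_type, mass, charge = 0, group = "ligand",
                          residue_id = 1L, backbone = FALSE,
                          bonds = NULL, angles = NULL) {
  n <- length(bead_type)
  mass <- rep_len(as.numeric(mass), n)
  charge <- rep_len(as.numeric(charge), n)
  group <- rep_len(as.character(group), n)
  residue_id <- rep_len(as.integer(residue_id), n)
  backbone <- rep_len(as.logical(backbone), n)
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("all bead masses must be positive and finite", call. = FALSE)
  }
  ok_groups <- c("ligand", "receptor", "solvent", "ion")
  if (!all(group %in% ok_groups)) {
    stop("group labels must be one of: ", paste(ok_groups, collapse = ", "),
         call. = FALSE)
  }
  bonds <- .check_bonded(bonds, c("i", "j", "r0", "k"), n, "bonds")
  angles <- .check_bonded(angles, c("i", "j", "k", "theta0", "ka"), n, "angles")
  structure(
    list(bead_type = as.character(bead_type), mass = mass, charge = charge,
         group = group, residue_id = residue_id, backbone = backbone,
         bonds = bonds, angles = angles),
    class = "bead_topology")
}

.check_bonded <- function(df, cols, n, what) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(df)
  }
  df <- as.data.frame(df)
  if (!all(cols %in% names(df))) {
    stop(what, " must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[cols]
  idx_cols <- setdiff(cols, c("r0", "k", "theta0", "ka"))
  if (what == "bonds") idx_cols <- c("i", "j")
  if (what == "angles") idx_cols <- c("i", "j", "k")
  for (cc in idx_cols) {
    v <- df[[cc]]
    if (any(v < 1 | v > n | v != round(v))) {
      stop(what, " indices out of range", call. = FALSE)
    }
    df[[cc]] <- as.integer(v)
  }
  df
}

#' @export
print.bead_topology <- function(x, ...) {
  cat("bead_topology:", length(x$bead_type), "beads (",
      paste(sprintf("%s: %d", names(table(x$group)), table(x$group)),
            collapse = ", "),
      ")\n", sep = " ")
  cat("  types:", paste(unique(x$bead_type), collapse = ", "), "\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " net charge:", sum(x$charge), "\n")
  invisible(x)
}

#' Number of beads in a topology
#' @param topo a [bead_topology()].
#' @return integer bead count.
#' @export
n_beads <- function(topo) length(topo$bead_type)

#' Bead indices of a group or selection
#'
#' @param topo a [bead_topology()].
#' @param selection either a group name (`"ligand"`, `"receptor"`,
#'   `"solvent"`, `"ion"`), an integer index vector, or a logical mask.
#' @return sorted integer vector of bead indices.
#' @export
group_indices <- function(topo, selection) {
  n <- n_beads(topo)
  if (is.character(selection) && length(selection) >= 1 &&
      all(selection %in% c("ligand", "receptor", "solvent", "ion"))) {
    return(which(topo$group %in% selection))
  }
  if (is.logical(selection)) {
    if (length(selection) != n) stop("logical selection has wrong length", call. = FALSE)
    return(which(selection))
  }
  sel <- as.integer(selection)
  if (any(sel < 1 | sel > n)) stop("selection indices out of range", call. = FALSE)
  sort(unique(sel))
}

#' Extract a subsystem
#'
#' Keeps the selected beads and remaps the bonded terms; bonds and angles with
#' any deleted member are dropped.
#'
#' @param topo a [bead_topology()].
#' @param conf a [conformation()].
#' @param keep selection of beads to keep (see [group_indices()]).
#' @return list with elements `topo` and `conf`.
#' @export
subset_system <- function(topo, conf, keep) {
  keep <- group_indices(topo, keep)
  map <- integer(n_beads(topo))
  map[keep] <- seq_along(keep)
  bonds <- topo$bonds
  if (nrow(bonds)) {
    ok <- bonds$i %in% keep & bonds$j %in% keep
    bonds <- bonds[ok, , drop = FALSE]
    bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  }
  angles <- topo$angles
  if (nrow(angles)) {
    ok <- angles$i %in% keep & angles$j %in% keep & angles$k %in% keep
    angles <- angles[ok, , drop = FALSE]
    angles$i <- map[angles$i]; angles$j <- map[angles$j]; angles$k <- map[angles$k]
  }
  new_topo <- bead_topology(
    topo$bead_type[keep], topo$mass[keep], topo$charge[keep], topo$group[keep],
    topo$residue_id[keep], topo$backbone[keep], bonds, angles)
  vel <- if (!is.null(conf$velocities)) conf$velocities[keep, , drop = FALSE]
  new_conf <- conformation(conf$coords[keep, , drop = FALSE], box = conf$box,
                           velocities = vel)
  list(topo = new_topo, conf = new_conf)
}

#' Append beads to a topology (internal)
#' @noRd
.topo_append <- function(topo, bead_type, mass, charge, group, residue_id,
                         backbone = FALSE) {
  m <- length(bead_type)
  bead_topology(
    c(topo$bead_type, bead_type), c(topo$mass, rep_len(mass, m)),
    c(topo$charge, rep_len(charge, m)), c(topo$group, rep_len(group, m)),
    c(topo$residue_id, rep_len(as.integer(residue_id), m)),
    c(topo$backbone, rep_len(backbone, m)), topo$bonds, topo$angles)
}

#' Conformation: coordinates in an optional periodic box
#'
#' @param coords numeric n x 3 matrix of bead positions (A).
#' @param box numeric length-3 vector of orthorhombic box lengths (A), or
#'   `NULL` for a non-periodic system.
#' @param velocities optional n x 3 matrix (A/fs).
#' @return An object of class `"conformation"`.
#' @export
conformation <- function(coords, box = NULL, velocities = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix", call. = FALSE)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive lengths", call. = FALSE)
    }
  }
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(coords))) {
      stop("velocities must match coords in shape", call. = FALSE)
    }
  }
  structure(list(coords = unname(coords), box = box, velocities = velocities),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("conformation:", nrow(x$coords), "beads,",
      if (is.null(x$box)) "non-periodic" else
        paste0("box ", paste(signif(x$box, 6), collapse = " x "), " A"),
      if (is.null(x$velocities)) "" else "(with velocities)", "\n")
  invisible(x)
}

#' Mass-weighted center of a selection (internal)
#' @noRd
.com <- function(coords, mass, idx = seq_len(nrow(coords))) {
  m <- mass[idx]
  colSums(coords[idx, , drop = FALSE] * m) / sum(m)
}

#' Minimum-image displacement (internal)
#' @noRd
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    sweep_box <- matrix(box, nrow(d), 3, byrow = TRUE)
    d - sweep_box * round(d / sweep_box)
  } else {
    d - box * round(d / box)
  }
}
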