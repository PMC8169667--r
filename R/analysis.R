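#' Optimal rigid superposition (Kabsch)
#'
#' @param P,Q n x 3 coordinate matrices; `P` is rotated/translated onto `Q`.
#' @param w optional per-point weights.
#' @return list with the transform (`R`, `t`) and `P_fit`, the transformed
#'   coordinates.
#' @export
kabsch <- function(P, Q, w = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (is.null(w)) w <- rep(1, nrow(P))
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  list(R = R, t = t_vec,
       P_fit = P %*% t(R) + matrix(t_vec, nrow(P), 3, byrow = TRUE))
}

.coords_of <- function(x) {
  if (inherits(x, "conformation")) x$coords else as.matrix(x)
}

#' Root-mean-square deviation
#'
#' Mass-unweighted RMSD between two structures over a selection, optionally
#' after optimal rigid superposition (Kabsch) of the selected beads.
#'
#' @param conf structure to compare ([conformation()] or coordinate matrix).
#' @param ref reference structure.
#' @param selection bead indices (default: all).
#' @param fit superpose before measuring (default `TRUE`).
#' @return RMSD in A.
#' @export
rmsd <- function(conf, ref, selection = NULL, fit = TRUE) {
  P <- .coords_of(conf); Q <- .coords_of(ref)
  if (!is.null(selection)) {
    P <- P[selection, , drop = FALSE]
    Q <- Q[selection, , drop = FALSE]
  }
  if (nrow(P) != nrow(Q)) stop("selection sizes differ", call. = FALSE)
  if (fit) P <- kabsch(P, Q)$P_fit
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of the selected beads from their center of
#' mass: `Rg = sqrt( sum m_i |r_i - r_COM|^2 / sum m_i )`. A larger value
#' indicates a more expansive structure. With `normalize = FALSE` the
#' division by the total mass is omitted (a compatibility form, units
#' amu^1/2 A, useful only as a relative stability monitor).
#'
#' @param conf a [conformation()] or coordinate matrix.
#' @param topo a [bead_topology()] (provides masses).
#' @param selection bead selection (default: all).
#' @param normalize divide by total mass (default `TRUE`).
#' @return Rg in A.
#' @export
radius_of_gyration <- function(conf, topo, selection = NULL,
                               normalize = TRUE) {
  co <- .coords_of(conf)
  idx <- if (is.null(selection)) seq_len(nrow(co)) else group_indices(topo, selection)
  if (!length(idx)) stop("empty selection", call. = FALSE)
  m <- topo$mass[idx]
  if (any(m <= 0)) stop("masses must be positive", call. = FALSE)
  r <- co[idx, , drop = FALSE]
  com <- colSums(r * m) / sum(m)
  s <- sum(m * rowSums(sweep(r, 2, com)^2))
  if (normalize) sqrt(s / sum(m)) else sqrt(s)
}

#' Root-mean-square fluctuation per bead and per nucleobase
#'
#' Each frame in the window is superposed (Kabsch, receptor beads by
#' default) onto the window-mean structure; the per-bead RMSF is
#' `sqrt(<|r_i - <r_i>|^2>)` over the window, and the per-nucleobase value
#' is the mean over that nucleobase's beads (ligand beads grouped by
#' `residue_id`, backbone beads excluded by default).
#'
#' @param traj a `"cg_trajectory"`.
#' @param topo a [bead_topology()].
#' @param window integer frame range to analyse (default: all frames);
#'   must contain at least 2 frames.
#' @param fit superpose frames before measuring (default `TRUE`; disable
#'   for trajectories that are already aligned).
#' @param fit_selection beads used for the superposition (default: the
#'   receptor group when present, else all beads).
#' @param group_by `"nucleobase"` groups ligand non-backbone beads by
#'   residue id; `"none"` returns only the per-bead profile.
#' @return named numeric vector of per-group RMSF values (A) with the
#'   per-bead profile in attribute `"per_bead"`; for `group_by = "none"`,
#'   the per-bead vector itself.
#' @export
rmsf <- function(traj, topo, window = NULL, fit = TRUE,
                 fit_selection = NULL, group_by = c("nucleobase", "none")) {
  group_by <- match.arg(group_by)
  nf <- n_frames(traj)
  if (is.null(window)) window <- seq_len(nf)
  if (any(window < 1 | window > nf)) stop("window outside trajectory", call. = FALSE)
  if (length(window) < 2) stop("window must span at least 2 frames", call. = FALSE)
  frames <- traj$frames[window]
  if (fit) {
    if (is.null(fit_selection)) {
      rec <- group_indices(topo, "receptor")
      fit_selection <- if (length(rec)) rec else seq_len(nrow(frames[[1]]))
    } else {
      fit_selection <- group_indices(topo, fit_selection)
    }
    align_to <- function(frames, ref) {
      lapply(frames, function(fr) {
        k <- kabsch(fr[fit_selection, , drop = FALSE],
                    ref[fit_selection, , drop = FALSE])
        fr %*% t(k$R) + matrix(k$t, nrow(fr), 3, byrow = TRUE)
      })
    }
    frames <- align_to(frames, frames[[1]])
    mean_str <- Reduce(`+`, frames) / length(frames)
    frames <- align_to(frames, mean_str)
  }
  mean_str <- Reduce(`+`, frames) / length(frames)
  msf <- Reduce(`+`, lapply(frames, function(fr) rowSums((fr - mean_str)^2))) /
    length(frames)
  per_bead <- sqrt(msf)
  if (group_by == "none") return(per_bead)
  lig <- which(topo$group == "ligand" & !topo$backbone)
  if (!length(lig)) lig <- which(topo$group == "ligand")
  groups <- split(lig, topo$residue_id[lig])
  out <- vapply(groups, function(idx) mean(per_bead[idx]), 0)
  attr(out, "per_bead") <- per_bead
  out
}

#' Center-of-mass distance trace
#'
#' Per-frame distance between the mass centers of two selections
#' (minimum-image when the box is periodic), or — with
#' `per_nucleobase = TRUE` — between each ligand nucleobase and the
#' receptor mass center.
#'
#' @param traj a `"cg_trajectory"`.
#' @param topo a [bead_topology()].
#' @param group_a,group_b bead selections (default ligand vs receptor).
#' @param per_nucleobase trace each ligand nucleobase separately.
#' @return numeric vector (one distance per frame), or a frames x
#'   nucleobases matrix.
#' @export
com_distance_trace <- function(traj, topo, group_a = "ligand",
                               group_b = "receptor",
                               per_nucleobase = FALSE) {
  ib <- group_indices(topo, group_b)
  if (!length(ib)) stop("group_b is empty", call. = FALSE)
  box <- traj$box
  one <- function(fr, ia) .com_distance(fr, topo, ia, ib, box)
  if (!per_nucleobase) {
    ia <- group_indices(topo, group_a)
    if (!length(ia)) stop("group_a is empty", call. = FALSE)
    return(vapply(traj$frames, one, 0, ia = ia))
  }
  lig <- which(topo$group == "ligand" & !topo$backbone)
  groups <- split(lig, topo$residue_id[lig])
  out <- sapply(groups, function(ia) vapply(traj$frames, one, 0, ia = ia))
  matrix(out, nrow = n_frames(traj),
         dimnames = list(NULL, names(groups)))
}

#' Residue-by-nucleobase interaction-energy map
#'
#' Time-averaged (over the analysis window) interaction energy between each
#' receptor residue and each ligand nucleobase, with the per-nucleobase
#' histogram (column sums) and a highlight mask at the threshold (default
#' -8.4 kJ/mol, the level below which contacts are considered strongly
#' bound). For a pairwise potential the matrix total equals the time-mean
#' nucleobase-receptor interaction energy exactly.
#'
#' @param traj a `"cg_trajectory"`.
#' @param topo a [bead_topology()].
#' @param ff a [ff_params()].
#' @param window frame range to average (default: all frames).
#' @param threshold highlight level, kJ/mol.
#' @param include_backbone include ligand backbone beads in the nucleobase
#'   columns (default `FALSE`).
#' @return An object of class `"interaction_map"`: list with `matrix`
#'   (residues x nucleobases, kJ/mol), `histogram` (column sums),
#'   `threshold`, `mask` (`matrix < threshold`), and `window`.
#' @export
interaction_map <- function(traj, topo, ff, window = NULL, threshold = -8.4,
                            include_backbone = FALSE) {
  nf <- n_frames(traj)
  if (is.null(window)) window <- seq_len(nf)
  if (!length(window) || any(window < 1 | window > nf)) {
    stop("invalid window", call. = FALSE)
  }
  rec <- group_indices(topo, "receptor")
  lig <- group_indices(topo, "ligand")
  if (!include_backbone) lig <- lig[!topo$backbone[lig]]
  if (!length(rec) || !length(lig)) {
    stop("need receptor and ligand beads", call. = FALSE)
  }
  res_ids <- sort(unique(topo$residue_id[rec]))
  base_ids <- sort(unique(topo$residue_id[lig]))
  rowbin <- integer(n_beads(topo))
  rowbin[rec] <- match(topo$residue_id[rec], res_ids)
  colbin <- integer(n_beads(topo))
  colbin[lig] <- match(topo$residue_id[lig], base_ids)
  conf0 <- conformation(traj$frames[[window[1]]], box = traj$box)
  sys <- .compile_sys(topo, ff, conf0)
  acc <- matrix(0, length(res_ids), length(base_ids))
  for (w in window) {
    acc <- acc + cpp_cross_matrix(sys, traj$frames[[w]], ff$nonbonded_scale,
                                  rowbin, colbin, length(res_ids),
                                  length(base_ids))
  }
  m <- acc / length(window)
  dimnames(m) <- list(residue = res_ids, nucleobase = base_ids)
  structure(
    list(matrix = m, histogram = colSums(m), threshold = threshold,
         mask = m < threshold, window = window),
    class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("interaction_map:", nrow(x$matrix), "residues x", ncol(x$matrix),
      "nucleobases, averaged over", length(x$window), "frames\n")
  cat(sprintf("  total interaction energy: %.4g kJ/mol; %d cells below %.3g\n",
              sum(x$matrix), sum(x$mask), x$threshold))
  invisible(x)
}

#' Beads within a distance shell of a selection
#'
#' Beads of `target_group` having any bead-bead distance strictly below
#' `cutoff` to the `around` selection (minimum-image when periodic); e.g.
#' the water beads within 7 A of the ligand.
#'
#' @param conf a [conformation()].
#' @param topo a [bead_topology()].
#' @param around central selection (group name or indices).
#' @param target_group selection to count (default `"solvent"`).
#' @param cutoff shell radius (A), positive; strict `<` comparison.
#' @return list with `count` and `ids` (bead indices).
#' @export
count_within <- function(conf, topo, around, target_group = "solvent",
                         cutoff = 7) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  ia <- group_indices(topo, around)
  it <- setdiff(group_indices(topo, target_group), ia)
  if (!length(it) || !length(ia)) return(list(count = 0L, ids = integer(0)))
  co <- .coords_of(conf)
  A <- co[ia, , drop = FALSE]
  hit <- vapply(it, function(i) {
    d <- sweep(A, 2, co[i, ], `-`)
    d <- .min_image(d, conf$box)
    any(rowSums(d^2) < cutoff^2)
  }, logical(1))
  list(count = sum(hit), ids = it[hit])
}
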