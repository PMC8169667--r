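# Shared fixtures, all built in code.

# two neutral LJ beads at separation r, switching disabled unless asked
lj_dimer <- function(r, sigma = 4.7, epsilon = 1, shift = FALSE,
                     r_cut = 50) {
  topo <- bead_topology(c("A", "A"), mass = 72, group = "ligand",
                        residue_id = 1:2)
  ff <- ff_params("A", sigma = sigma, epsilon = epsilon, r_cut = r_cut,
                  lj_shift_start = if (shift) 0.75 * r_cut else r_cut)
  conf <- conformation(rbind(c(0, 0, 0), c(r, 0, 0)))
  list(topo = topo, conf = conf, ff = ff)
}

# small solvated toy on a jittered grid (guaranteed separations), with
# ligand/receptor/solvent/ion groups, mixed types and charges
random_toy <- function(seed, n_side = 3, box = c(30, 30, 30), spacing = 7,
                       charged = TRUE) {
  set.seed(seed)
  g <- as.matrix(expand.grid(seq_len(n_side), seq_len(n_side),
                             seq_len(n_side))) * spacing
  n <- nrow(g) # 27
  coords <- g + matrix(runif(3 * n, -1.5, 1.5), n, 3)
  group <- rep("solvent", n)
  group[1:4] <- "ligand"
  group[5:10] <- "receptor"
  group[11] <- "ion"
  type <- ifelse(group == "ligand", "L", ifelse(group == "receptor", "R",
                 ifelse(group == "ion", "Q", "W")))
  charge <- if (charged) {
    ifelse(type == "Q", 1, sample(c(-0.5, 0, 0.5), n, replace = TRUE))
  } else 0
  topo <- bead_topology(type, mass = runif(n, 40, 100), charge = charge,
                        group = group,
                        residue_id = c(1:4, 1:6, seq_len(n - 10)),
                        backbone = c(TRUE, FALSE, TRUE, FALSE,
                                     rep(FALSE, n - 4)))
  ff <- ff_params(c("L", "R", "W", "Q"), sigma = 4.7,
                  epsilon = c(L = 2, R = 3, W = 5, Q = 1))
  list(topo = topo, conf = conformation(coords, box = box), ff = ff)
}

# quartic double well and a 2-D channel with a saddle at the origin
dw_fn <- function(x) (x[1]^2 - 1)^2
dw_gr <- function(x) 4 * x[1] * (x[1]^2 - 1)
dw2_fn <- function(x) (x[1]^2 - 1)^2 + 2 * x[2]^2
dw2_gr <- function(x) c(4 * x[1] * (x[1]^2 - 1), 4 * x[2])

linear_images <- function(from, to, n) {
  lapply(seq_len(n), function(i) from + (to - from) * (i - 1) / (n - 1))
}
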