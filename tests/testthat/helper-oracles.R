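# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own computational paths.

# Numerical cosine-transform of the three-Gaussian electron density profile,
# the quadrature oracle for the closed-form form factor.
quadrature_form_factor <- function(q, Z_H, sigma_H, sigma_C, rho_r) {
  rho <- function(z) {
    exp(-(z - Z_H)^2 / (2 * sigma_H^2)) +
      exp(-(z + Z_H)^2 / (2 * sigma_H^2)) +
      rho_r * exp(-z^2 / (2 * sigma_C^2))
  }
  vapply(q, function(qi) {
    stats::integrate(function(z) rho(z) * cos(qi * z), -120, 120,
                     rel.tol = 1e-11, abs.tol = 1e-12,
                     subdivisions = 500L)$value
  }, numeric(1))
}

# Plain minimum-image displacement, written independently.
oracle_mi <- function(d, box) d - box * round(d / box)

# O(N^2) brute-force geometric hydrogen-bond count: explicit loops over
# donor / same-molecule hydrogen / acceptor, acos angle test.
oracle_hbond_count <- function(conf, r_max = 0.35, theta_max = 30) {
  pos <- conf$positions; box <- conf$box
  donors <- which(conf$role == "donor")
  acceptors <- which(conf$role == "acceptor")
  hydrogens <- which(conf$role == "hydrogen")
  count <- 0L
  for (d in donors) {
    hs <- hydrogens[conf$mol_id[hydrogens] == conf$mol_id[d]]
    for (a in acceptors) {
      if (conf$mol_id[a] == conf$mol_id[d]) next
      da <- oracle_mi(pos[a, ] - pos[d, ], box)
      r <- sqrt(sum(da^2))
      if (r > r_max) next
      for (h in hs) {
        dh <- oracle_mi(pos[h, ] - pos[d, ], box)
        ang <- acos(max(-1, min(1, sum(da * dh) /
                                  (r * sqrt(sum(dh^2)))))) * 180 / pi
        if (ang <= theta_max + 1e-9) count <- count + 1L
      }
    }
  }
  count
}

# Exhaustive single-linkage components of solute molecules by recursive
# depth-first search on the pairwise contact matrix.
oracle_cluster_sizes <- function(conf, cutoff = 0.25) {
  ids <- unique(conf$mol_id[conf$mol_kind == "solute"])
  n <- length(ids)
  atoms <- lapply(ids, function(id) {
    which(conf$mol_id == id & conf$mol_kind == "solute")
  })
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      dmin <- Inf
      for (ai in atoms[[i]]) {
        for (aj in atoms[[j]]) {
          dv <- oracle_mi(conf$positions[aj, ] - conf$positions[ai, ], conf$box)
          dmin <- min(dmin, sqrt(sum(dv^2)))
        }
      }
      adj[i, j] <- adj[j, i] <- dmin <= cutoff
    }
  }
  comp <- rep(0L, n)
  visit <- function(i, label) {
    comp[i] <<- label
    for (j in which(adj[i, ])) if (comp[j] == 0L) visit(j, label)
  }
  label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { label <- label + 1L; visit(i, label) }
  }
  sort(as.integer(table(comp)), decreasing = TRUE)
}

# Random periodic configuration with donor/hydrogen/acceptor triplets and
# multi-atom solute molecules, for oracle cross-checks.
random_hbond_config <- function(seed, n_donor = 15, n_acceptor = 15,
                                box = c(3, 3, 3)) {
  set.seed(seed)
  pos <- NULL; mol <- integer(0); role <- character(0)
  m <- 0L
  for (i in seq_len(n_donor)) {
    m <- m + 1L
    d <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    pos <- rbind(pos, d, d + 0.1 * u)
    mol <- c(mol, m, m)
    role <- c(role, "donor", "hydrogen")
  }
  for (i in seq_len(n_acceptor)) {
    m <- m + 1L
    pos <- rbind(pos, runif(3, 0, box))
    mol <- c(mol, m)
    role <- c(role, "acceptor")
  }
  membranr::md_config(positions = pos, box = box, mol_id = mol,
                      mol_kind = rep("water", length(mol)),
                      role = role, mass = rep(10, length(mol)))
}

random_solute_config <- function(seed, n_mol = 12, atoms_per_mol = 2,
                                 box = c(2.5, 2.5, 2.5)) {
  set.seed(seed)
  pos <- NULL; mol <- integer(0)
  for (m in seq_len(n_mol)) {
    center <- runif(3, 0, box)
    for (a in seq_len(atoms_per_mol)) {
      pos <- rbind(pos, center + rnorm(3, 0, 0.08))
    }
    mol <- c(mol, rep(m, atoms_per_mol))
  }
  n <- length(mol)
  membranr::md_config(positions = pos, box = box, mol_id = mol,
                      mol_kind = rep("solute", n),
                      role = rep("other", n), mass = rep(100, n))
}

# Gaussian-mixture spectrum builder used by the infrared tests.
two_band_spectrum <- function(w_low, centers = c(1742, 1728),
                              widths = c(8, 8),
                              x = seq(1670, 1780, by = 0.5)) {
  y <- (1 - w_low) * dnorm(x, max(centers), widths[1]) +
    w_low * dnorm(x, min(centers), widths[2])
  membranr::xy_curve(x, y, meta = list(x_unit = "1/cm"))
}
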