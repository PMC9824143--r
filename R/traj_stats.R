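#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triplet is counted as a hydrogen bond when the
#' donor-acceptor distance is at most `r_max` and the angle at the donor
#' between the donor-to-hydrogen and donor-to-acceptor directions is at most
#' `theta_max` (both inclusive).
#'
#' @param r_max Donor-acceptor distance cutoff in nm, default 0.35.
#' @param theta_max Angle cutoff in degrees, default 30.
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(r_max = 0.35, theta_max = 30) {
  if (r_max <= 0) stop("r_max must be > 0", call. = FALSE)
  if (theta_max <= 0 || theta_max >= 90) {
    stop("theta_max must be in (0, 90) degrees", call. = FALSE)
  }
  structure(list(r_max = r_max, theta_max = theta_max),
            class = "hbond_criterion")
}

# Minimum-image displacement(s) r2 - r1 in an orthorhombic box.
min_image <- function(d, box) {
  d - rep(box, each = NROW(d)) * round(d / rep(box, each = NROW(d)))
}

min_image_vec <- function(d, box) d - box * round(d / box)

#' Select particle indices by kind and role
#'
#' @param conf An [md_config].
#' @param kind Optional molecule kind filter (`lipid`, `solute`, `water`).
#' @param role Optional site role filter.
#' @return Integer particle indices.
#' @export
select_particles <- function(conf, kind = NULL, role = NULL) {
  keep <- rep(TRUE, nrow(conf$positions))
  if (!is.null(kind)) keep <- keep & conf$mol_kind %in% kind
  if (!is.null(role)) keep <- keep & conf$role %in% role
  which(keep)
}

#' Area per lipid
#'
#' The lateral box area divided by the number of lipids per leaflet,
#' evaluated per frame and summarized over the trajectory.
#'
#' @param traj An [md_traj] (an [md_config] is treated as one frame).
#' @param n_lipids Total lipid count over both leaflets (even); defaults to
#'   the number of distinct lipid molecules in the labeling.
#' @return List with `mean`, `sd` (nm^2) and `per_frame`.
#' @export
area_per_lipid <- function(traj, n_lipids = NULL) {
  frames <- if (inherits(traj, "md_traj")) traj$frames else list(traj)
  if (is.null(n_lipids)) {
    n_lipids <- length(unique(frames[[1]]$mol_id[frames[[1]]$mol_kind == "lipid"]))
  }
  if (n_lipids <= 0) stop("no lipids", call. = FALSE)
  if (n_lipids %% 2L != 0L) {
    stop("n_lipids must be even (two equally populated leaflets)", call. = FALSE)
  }
  apl <- vapply(frames, function(f) f$box[1] * f$box[2] / (n_lipids / 2),
                numeric(1))
  list(mean = mean(apl), sd = if (length(apl) > 1L) stats::sd(apl) else 0,
       per_frame = apl)
}

#' Assign lipids to leaflets by phosphorus position
#'
#' Each lipid is assigned to the upper or lower leaflet by the z coordinate
#' of its phosphorus site relative to the mass-weighted center of all lipid
#' particles. Phosphorus sites within 0.1 nm of the center plane are flagged
#' ambiguous (and still assigned by sign).
#'
#' @param conf An [md_config]; every lipid must carry exactly one
#'   `phosphorus` site.
#' @return Data frame with `mol_id`, `z_P` (nm, relative to the bilayer
#'   center), `leaflet` (`"upper"`/`"lower"`), `ambiguous`.
#' @export
assign_leaflets <- function(conf) {
  stopifnot(inherits(conf, "md_config"))
  lip <- select_particles(conf, kind = "lipid")
  if (!length(lip)) stop("no lipid particles", call. = FALSE)
  z_center <- stats::weighted.mean(conf$positions[lip, 3], conf$mass[lip])
  p_idx <- select_particles(conf, kind = "lipid", role = "phosphorus")
  ids <- unique(conf$mol_id[lip])
  has_p <- table(factor(conf$mol_id[p_idx], levels = ids))
  if (any(has_p != 1L)) {
    stop("every lipid must have exactly one phosphorus site", call. = FALSE)
  }
  zp <- conf$positions[p_idx, 3] - z_center
  out <- data.frame(mol_id = conf$mol_id[p_idx], z_P = zp,
                    leaflet = ifelse(zp >= 0, "upper", "lower"),
                    ambiguous = abs(zp) < 0.1,
                    stringsAsFactors = FALSE)
  n_up <- sum(out$leaflet == "upper")
  if (n_up == 0L || n_up == nrow(out)) {
    warning(sprintf("degenerate leaflet split %d/%d: all phosphorus on one side",
                    n_up, nrow(out) - n_up))
  }
  out
}

#' Phosphorus-to-phosphorus bilayer thickness
#'
#' Per frame, the difference between the mean phosphorus z of the upper
#' leaflet and that of the lower leaflet; summarized over frames.
#'
#' @param traj An [md_traj] (or single [md_config]).
#' @return List with `mean`, `sd` (nm) and `per_frame`.
#' @export
pp_thickness <- function(traj) {
  frames <- if (inherits(traj, "md_traj")) traj$frames else list(traj)
  th <- vapply(frames, function(f) {
    lf <- assign_leaflets(f)
    up <- lf$z_P[lf$leaflet == "upper"]
    lo <- lf$z_P[lf$leaflet == "lower"]
    if (!length(up) || !length(lo)) {
      stop("a leaflet has no phosphorus sites", call. = FALSE)
    }
    mean(up) - mean(lo)
  }, numeric(1))
  list(mean = mean(th), sd = if (length(th) > 1L) stats::sd(th) else 0,
       per_frame = th)
}

# Cell-list neighbor candidates: for each probe point, indices of target
# points in the same or adjacent periodic cells (cell edge >= cutoff).
cell_pairs <- function(pos_a, pos_b, box, cutoff) {
  ncell <- pmax(1L, floor(box / cutoff))
  # with fewer than 3 cells along an axis adjacency wraps onto itself;
  # collapse to 1 cell (-> all pairs) to avoid double counting
  ncell[ncell < 3L] <- 1L
  cell_of <- function(p) {
    ix <- pmin(floor((p %% rep(box, each = nrow(p))) /
                       rep(box / ncell, each = nrow(p))),
               rep(ncell - 1L, each = nrow(p)))
    ix[, 1] + ncell[1] * (ix[, 2] + ncell[2] * ix[, 3])
  }
  ca <- cell_of(pos_a)
  cb <- cell_of(pos_b)
  # target indices by cell
  by_cell <- split(seq_len(nrow(pos_b)), cb)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  key <- function(ix) ix[, 1] + ncell[1] * (ix[, 2] + ncell[2] * ix[, 3])
  lapply(seq_len(nrow(pos_a)), function(i) {
    ci <- c(ca[i] %% ncell[1],
            (ca[i] %/% ncell[1]) %% ncell[2],
            ca[i] %/% (ncell[1] * ncell[2]))
    neigh <- sweep(offs, 2, ci, `+`)
    neigh <- sweep(neigh, 2, ncell, `%%`)
    ks <- unique(key(neigh))
    unlist(by_cell[as.character(ks)], use.names = FALSE)
  })
}

#' Count geometric hydrogen bonds in a configuration
#'
#' Donors are paired with the hydrogen atoms of the same molecule (topology
#' pairing); a triplet is a bond when the minimum-image donor-acceptor
#' distance and the hydrogen-donor-acceptor angle satisfy the
#' [hbond_criterion()]. Intra-molecular donor-acceptor pairs are excluded.
#' The default cell-list search is exact: it is guaranteed to agree with the
#' all-pairs scan, which is also available as `method = "brute"`.
#'
#' @param conf An [md_config].
#' @param donors,hydrogens,acceptors Particle index vectors; default to the
#'   particles with roles `donor`, `hydrogen`, `acceptor`.
#' @param crit An [hbond_criterion()].
#' @param method `"grid"` (cell list) or `"brute"` (all pairs).
#' @return List with `count` and `bonds` (data frame of donor, hydrogen,
#'   acceptor particle indices).
#' @export
hydrogen_bonds <- function(conf, donors = NULL, hydrogens = NULL,
                           acceptors = NULL, crit = hbond_criterion(),
                           method = c("grid", "brute")) {
  stopifnot(inherits(conf, "md_config"), inherits(crit, "hbond_criterion"))
  method <- match.arg(method)
  if (is.null(donors)) donors <- select_particles(conf, role = "donor")
  if (is.null(hydrogens)) hydrogens <- select_particles(conf, role = "hydrogen")
  if (is.null(acceptors)) acceptors <- select_particles(conf, role = "acceptor")
  box <- conf$box
  pos <- conf$positions
  # topology pairing: hydrogens of the donor's molecule
  h_by_mol <- split(hydrogens, conf$mol_id[hydrogens])
  d_hyd <- lapply(donors, function(d) {
    h <- h_by_mol[[as.character(conf$mol_id[d])]]
    if (is.null(h)) {
      stop(sprintf("donor without attached hydrogen in molecule %d",
                   conf$mol_id[d]), call. = FALSE)
    }
    h
  })
  if (!length(donors) || !length(acceptors)) {
    return(list(count = 0L,
                bonds = data.frame(donor = integer(0), hydrogen = integer(0),
                                   acceptor = integer(0))))
  }
  cand <- if (method == "grid") {
    cell_pairs(pos[donors, , drop = FALSE], pos[acceptors, , drop = FALSE],
               box, crit$r_max)
  } else {
    rep(list(seq_along(acceptors)), length(donors))
  }
  cos_min <- cos(crit$theta_max * pi / 180)
  bonds <- list()
  for (di in seq_along(donors)) {
    d <- donors[di]
    aj <- cand[[di]]
    if (!length(aj)) next
    a <- acceptors[aj]
    a <- a[conf$mol_id[a] != conf$mol_id[d]]
    if (!length(a)) next
    dv <- min_image(sweep(pos[a, , drop = FALSE], 2, pos[d, ]), box)
    r <- sqrt(rowSums(dv^2))
    a <- a[r <= crit$r_max]; dv <- dv[r <= crit$r_max, , drop = FALSE]
    if (!length(a)) next
    for (h in d_hyd[[di]]) {
      hv <- min_image_vec(pos[h, ] - pos[d, ], box)
      nh <- sqrt(sum(hv^2))
      cosang <- (dv %*% hv) / (sqrt(rowSums(dv^2)) * nh)
      hit <- which(cosang >= cos_min - 1e-12)
      for (k in hit) {
        bonds[[length(bonds) + 1L]] <- c(d, h, a[k])
      }
    }
  }
  bonds <- if (length(bonds)) {
    as.data.frame(do.call(rbind, bonds)) |>
      stats::setNames(c("donor", "hydrogen", "acceptor"))
  } else {
    data.frame(donor = integer(0), hydrogen = integer(0), acceptor = integer(0))
  }
  list(count = nrow(bonds), bonds = bonds)
}

#' Non-symmetrized mass density profile along the bilayer normal
#'
#' Each frame is recentered so the mass-weighted z centroid of the lipid
#' particles sits at z = 0, the selected particles' masses are binned along
#' z (bin volume = box_x * box_y * bin width) and the per-frame profiles are
#' averaged. No leaflet symmetrization is applied, so an asymmetric solute
#' distribution stays asymmetric in the profile.
#'
#' @param traj An [md_traj] (or single [md_config]).
#' @param kind,role Selection filters passed to [select_particles()];
#'   both `NULL` selects everything.
#' @param bin_width Requested z bin width in nm (> 0); the actual width is
#'   box_z divided by the nearest integer bin count.
#' @return An object of class `density_profile`: `z` (bin centers, nm),
#'   `density` (amu/nm^3), `bin_width`, `selection`, `total_mass`.
#' @export
mass_density_profile <- function(traj, kind = NULL, role = NULL,
                                 bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  frames <- if (inherits(traj, "md_traj")) traj$frames else list(traj)
  sel <- select_particles(frames[[1]], kind = kind, role = role)
  if (!length(sel)) stop("empty selection", call. = FALSE)
  Lz <- frames[[1]]$box[3]
  n_bins <- max(1L, round(Lz / bin_width))
  width <- Lz / n_bins
  edges <- seq(-Lz / 2, Lz / 2, length.out = n_bins + 1L)
  acc <- numeric(n_bins)
  for (f in frames) {
    lip <- select_particles(f, kind = "lipid")
    ref <- if (length(lip)) lip else seq_len(nrow(f$positions))
    z0 <- stats::weighted.mean(f$positions[ref, 3], f$mass[ref])
    z <- f$positions[sel, 3] - z0
    z <- z - f$box[3] * round(z / f$box[3])  # wrap into [-Lz/2, Lz/2)
    bin <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L), n_bins)
    vol <- f$box[1] * f$box[2] * width
    acc <- acc + vapply(seq_len(n_bins),
                        function(b) sum(f$mass[sel][bin == b]), numeric(1)) / vol
  }
  structure(list(z = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 density = acc / length(frames), bin_width = width,
                 selection = list(kind = kind, role = role),
                 total_mass = sum(frames[[1]]$mass[sel]),
                 box = frames[[1]]$box),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d bins of %.3f nm, total mass %.1f amu\n",
              length(x$z), x$bin_width, x$total_mass))
  invisible(x)
}

# Minimum-image minimum distance between two atom sets (all-pairs).
min_set_distance <- function(pa, pb, box) {
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    dv <- min_image(sweep(pb, 2, pa[i, ]), box)
    best <- min(best, sqrt(min(rowSums(dv^2))))
  }
  best
}

#' Solute cluster size distribution
#'
#' Per frame, two solute molecules are linked when the minimum-image minimum
#' distance between any atom of one and any atom of the other is at most
#' `cutoff` (single linkage: clusters are the connected components of the
#' link graph). The histogram counts molecules per cluster size, accumulated
#' over frames; `monomer_fraction` is the time-averaged fraction of solute
#' molecules found as monomers.
#'
#' @param traj An [md_traj] (or single [md_config]).
#' @param cutoff Contact cutoff in nm (> 0), default 0.25.
#' @param metric `"min"` (default, minimum over all atom pairs) or
#'   `"centroid"` (distance between molecular centroids).
#' @return An object of class `cluster_distribution`: `histogram` (named
#'   vector, cluster size to mean molecule count per frame),
#'   `monomer_fraction`, `per_frame` (list of per-frame histograms),
#'   `n_solute`.
#' @export
cluster_size_distribution <- function(traj, cutoff = 0.25,
                                      metric = c("min", "centroid")) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  metric <- match.arg(metric)
  frames <- if (inherits(traj, "md_traj")) traj$frames else list(traj)
  f1 <- frames[[1]]
  sol_ids <- unique(f1$mol_id[f1$mol_kind == "solute"])
  if (!length(sol_ids)) stop("no solute molecules", call. = FALSE)
  n_sol <- length(sol_ids)
  atoms_by_mol <- lapply(sol_ids, function(id) which(f1$mol_id == id &
                                                       f1$mol_kind == "solute"))
  per_frame <- lapply(frames, function(f) {
    linked <- matrix(FALSE, n_sol, n_sol)
    if (metric == "centroid") {
      cen <- t(vapply(atoms_by_mol, function(ix) {
        colMeans(f$positions[ix, , drop = FALSE])
      }, numeric(3)))
    }
    for (i in seq_len(n_sol - 1L)) {
      for (j in (i + 1L):n_sol) {
        d <- if (metric == "min") {
          min_set_distance(f$positions[atoms_by_mol[[i]], , drop = FALSE],
                           f$positions[atoms_by_mol[[j]], , drop = FALSE],
                           f$box)
        } else {
          sqrt(sum(min_image_vec(cen[j, ] - cen[i, ], f$box)^2))
        }
        linked[i, j] <- linked[j, i] <- d <= cutoff
      }
    }
    g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    tab <- table(factor(sizes, levels = seq_len(n_sol)))
    as.numeric(tab)  # molecules in clusters of each size
  })
  mean_hist <- Reduce(`+`, per_frame) / length(per_frame)
  names(mean_hist) <- seq_len(n_sol)
  monomer <- mean(vapply(per_frame, function(h) h[1L] / n_sol, numeric(1)))
  structure(list(histogram = mean_hist[mean_hist > 0],
                 monomer_fraction = monomer, per_frame = per_frame,
                 n_solute = n_sol),
            class = "cluster_distribution")
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat(sprintf("<cluster_distribution> %d solute molecules, monomer fraction %.3f\n",
              x$n_solute, x$monomer_fraction))
  print(x$histogram)
  invisible(x)
}

#' Drop an initial fraction of trajectory frames
#'
#' Mirrors the common practice of analyzing only the equilibrated tail of a
#' production run.
#'
#' @param traj An [md_traj].
#' @param discard Fraction of frames (from the start) to drop, in \[0, 1).
#' @return The truncated [md_traj].
#' @export
discard_initial <- function(traj, discard = 0) {
  stopifnot(inherits(traj, "md_traj"), discard >= 0, discard < 1)
  n <- length(traj$frames)
  keep <- (floor(n * discard) + 1L):n
  md_traj(traj$frames[keep], traj$times[keep])
}
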