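#' Ground truth for a synthetic small-angle diffraction curve
#'
#' Defaults emulate a gel-phase anionic bilayer measured between 0.05 and
#' 0.6 inverse Angstrom: headgroup position 19.08 A with the conventional
#' 3 A headgroup width (steric thickness 50.16 A), a 6 A chain trough of
#' relative amplitude -0.8, and 2 percent relative counting noise.
#'
#' @param edp An [edp]; default `edp(19.08, 3, 6, -0.8)`.
#' @param scale Positive intensity multiplier.
#' @param background Constant additive intensity.
#' @param q_grid Scattering vector grid, inverse Angstrom, inside (0, 2].
#' @param noise_fraction Relative Gaussian noise level (>= 0).
#' @return An object of class `saxd_truth`.
#' @export
saxd_truth <- function(edp = membranr::edp(19.08, 3, 6, -0.8), scale = 1,
                       background = 0.05,
                       q_grid = seq(0.05, 0.6, length.out = 276),
                       noise_fraction = 0.02) {
  stopifnot(inherits(edp, "edp"))
  if (any(q_grid <= 0) || any(q_grid > 2)) {
    stop("q_grid must lie in (0, 2] 1/A (model singular at q = 0)", call. = FALSE)
  }
  if (scale < 0) stop("scale must be >= 0", call. = FALSE)
  if (noise_fraction < 0) stop("noise_fraction must be >= 0", call. = FALSE)
  structure(list(edp = edp, scale = scale, background = background,
                 q_grid = sort(q_grid), noise_fraction = noise_fraction),
            class = "saxd_truth")
}

#' Generate a synthetic small-angle diffraction curve
#'
#' Forward model for diffuse scattering of positionally uncorrelated
#' bilayers: y = scale |F(q)|^2 / q^2 + background, perturbed by Gaussian
#' noise with standard deviation `noise_fraction * y`; that standard
#' deviation is stored as `y_err`.
#'
#' @param truth A [saxd_truth].
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return An [xy_curve] with the truth parameters recorded in `meta`.
#' @export
generate_saxd_curve <- function(truth = saxd_truth(), seed = 1) {
  stopifnot(inherits(truth, "saxd_truth"))
  q <- truth$q_grid
  clean <- model_intensity(q, truth$edp, truth$scale, truth$background)
  sd_y <- truth$noise_fraction * pmax(clean, 1e-12)
  y <- if (truth$noise_fraction > 0) {
    with_seed(seed, clean + stats::rnorm(length(q), 0, sd_y))
  } else clean
  xy_curve(q, y, y_err = if (truth$noise_fraction > 0) sd_y else NULL,
           meta = list(x_unit = "1/A", generator = "saxd",
                       Z_H = truth$edp$Z_H, sigma_H = truth$edp$sigma_H,
                       sigma_C = truth$edp$sigma_C, rho_r = truth$edp$rho_r,
                       scale = truth$scale, background = truth$background,
                       noise_fraction = truth$noise_fraction, seed = seed))
}

#' Ground truth for a synthetic heating thermogram
#'
#' Defaults emulate a pure anionic phospholipid scan: a weak pretransition
#' (onset 9 C: center 10.0 C, sd 0.5 C, 3 kJ/mol) and the main
#' gel-to-fluid transition (onset 22.3 C: center 23.1 C, sd 0.4 C,
#' 27.2 kJ/mol) on a zero baseline, sampled every 0.01 C. Peaks are
#' symmetric Gaussians normalized to unit area so each peak's integral above
#' baseline equals its area parameter and the tangent onset of a Gaussian
#' peak has the closed form center - 2 sd.
#'
#' @param peaks Data frame with columns `center` (C), `width` (Gaussian sd,
#'   C), `area` (kJ/mol).
#' @param baseline Length-2 `c(intercept, slope)` of the linear baseline.
#' @param T_grid Temperature grid (C), covering every peak +/- 5 widths.
#' @param noise_sd Ordinate noise standard deviation.
#' @return An object of class `thermogram_truth`.
#' @export
thermogram_truth <- function(peaks = data.frame(center = c(10.0, 23.1),
                                                width = c(0.5, 0.4),
                                                area = c(3, 27.2)),
                             baseline = c(0, 0),
                             T_grid = seq(0, 35, by = 0.01),
                             noise_sd = 0) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "area") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("peak widths must be > 0", call. = FALSE)
  if (any(peaks$area < 0)) stop("peak areas must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  lo <- min(peaks$center - 5 * peaks$width)
  hi <- max(peaks$center + 5 * peaks$width)
  if (min(T_grid) > lo || max(T_grid) < hi) {
    stop("peak truncated: T_grid must cover all peaks +/- 5 widths",
         call. = FALSE)
  }
  structure(list(peaks = peaks, baseline = baseline, T_grid = sort(T_grid),
                 noise_sd = noise_sd), class = "thermogram_truth")
}

#' Generate a synthetic thermogram
#'
#' @param truth A [thermogram_truth].
#' @param seed Integer seed.
#' @param scan_rate,composition Recorded in the returned [thermogram].
#' @return A [thermogram].
#' @export
generate_thermogram <- function(truth = thermogram_truth(), seed = 1,
                                scan_rate = 60, composition = 0) {
  stopifnot(inherits(truth, "thermogram_truth"))
  Tg <- truth$T_grid
  y <- truth$baseline[1] + truth$baseline[2] * Tg
  for (i in seq_len(nrow(truth$peaks))) {
    y <- y + truth$peaks$area[i] *
      stats::dnorm(Tg, truth$peaks$center[i], truth$peaks$width[i])
  }
  if (truth$noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(Tg), 0, truth$noise_sd))
  }
  thermogram(xy_curve(Tg, y, meta = list(x_unit = "degC", generator = "dsc",
                                         seed = seed)),
             scan_rate = scan_rate, composition = composition)
}

#' Generate a temperature series of synthetic carbonyl spectra
#'
#' Each spectrum is the sum of two Gaussian bands (non-hydrogen-bonded near
#' 1742 cm^-1 and hydrogen-bonded near 1728 cm^-1). The relative weight of
#' the low-wavenumber band follows a logistic sigmoid in temperature
#' centered at `T_m` and rising above it, emulating the increased hydration
#' and hydrogen bonding of the interfacial carbonyls in the fluid phase.
#'
#' @param T_m Transition midpoint (C).
#' @param temps Temperatures of the series (C), non-empty.
#' @param centers Component band centers (cm^-1), inside 1670-1780; default
#'   `c(1742, 1728)` (high = free, low = hydrogen bonded).
#' @param widths Gaussian sd of the two bands (cm^-1).
#' @param weight_range Low-band weight far below and far above `T_m`.
#' @param steepness Sigmoid temperature scale (C).
#' @param wn_grid Wavenumber grid (cm^-1).
#' @param noise_sd Absorbance noise sd.
#' @param seed Integer seed.
#' @return List of [xy_curve] spectra, each with `meta$temperature` set.
#' @export
generate_ftir_series <- function(T_m = 23, temps = seq(10, 36, by = 2),
                                 centers = c(1742, 1728), widths = c(8, 8),
                                 weight_range = c(0.25, 0.75),
                                 steepness = 0.8,
                                 wn_grid = seq(1670, 1780, by = 0.5),
                                 noise_sd = 0, seed = 1) {
  if (!length(temps)) stop("temps must be non-empty", call. = FALSE)
  if (any(centers < 1670) || any(centers > 1780)) {
    stop("centers must lie inside 1670-1780 cm^-1", call. = FALSE)
  }
  c_hi <- max(centers); c_lo <- min(centers)
  w_hi <- widths[which.max(centers)]; w_lo <- widths[which.min(centers)]
  with_seed(seed, lapply(temps, function(Tc) {
    w_low <- weight_range[1] + diff(weight_range) *
      stats::plogis((Tc - T_m) / steepness)
    y <- (1 - w_low) * stats::dnorm(wn_grid, c_hi, w_hi) +
      w_low * stats::dnorm(wn_grid, c_lo, w_lo)
    if (noise_sd > 0) y <- y + stats::rnorm(length(wn_grid), 0, noise_sd)
    xy_curve(wn_grid, y, meta = list(x_unit = "1/cm", temperature = Tc,
                                     generator = "ftir", T_m = T_m,
                                     weight_low = w_low))
  }))
}

#' Specification of a synthetic two-leaflet pseudo-bilayer
#'
#' Defaults emulate the simulated system: 128 lipids split over two leaflets
#' with phosphorus planes at +/- 1.685 nm (phosphorus-phosphorus thickness
#' 3.37 nm), a lateral box of 6.3499 nm (area per lipid 0.63 nm^2), and 14
#' single-site solute molecules planted as 4 monomers plus clusters of
#' 3, 3 and 4 (monomer fraction 4/14). Donor-hydrogen-acceptor triplets are
#' planted in the aqueous region with controlled geometry: `planted_hbonds`
#' of them satisfy the 0.35 nm / 30 degree criterion and all decoys violate
#' it by at least 0.05 nm or 10 degrees.
#'
#' @param n_lipids Even lipid count over both leaflets.
#' @param leaflet_z Phosphorus plane position (nm): planes at +/- leaflet_z.
#' @param carbonyl_offset,methyl_offset Displacement of the carbonyl and
#'   terminal-methyl sites from the phosphorus plane toward the bilayer
#'   center (nm).
#' @param n_solute Number of solute molecules.
#' @param solute_z_band z interval (nm, one leaflet) holding the solutes.
#' @param planted_clusters List of integer vectors partitioning
#'   `1:n_solute` into intended clusters; `NULL` plants 4 monomers + 3 + 3 +
#'   4 when `n_solute` is 14, else all monomers.
#' @param planted_hbonds Number of donor-hydrogen-acceptor triplets built
#'   inside the geometric criterion.
#' @param n_hbond_decoys Additional triplets built to violate the criterion.
#' @param box Orthorhombic box lengths (nm).
#' @param jitter_sd Positional noise applied to lipid sites per frame (nm).
#' @return An object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(n_lipids = 128, leaflet_z = 1.685,
                         carbonyl_offset = 0.45, methyl_offset = 1.55,
                         n_solute = 14, solute_z_band = c(0.2, 0.9),
                         planted_clusters = NULL, planted_hbonds = 6,
                         n_hbond_decoys = 4,
                         box = c(6.3499, 6.3499, 7.0), jitter_sd = 0.05) {
  if (n_lipids %% 2L != 0L) stop("n_lipids must be even", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (leaflet_z >= box[3] / 2) stop("leaflet_z must sit inside the box", call. = FALSE)
  if (is.null(planted_clusters)) {
    planted_clusters <- if (n_solute == 14L) {
      c(as.list(1:4), list(5:7, 8:10, 11:14))
    } else {
      as.list(seq_len(n_solute))
    }
  }
  ids <- sort(unlist(planted_clusters))
  if (!identical(as.integer(ids), seq_len(n_solute))) {
    stop("planted_clusters must partition 1:n_solute exactly once each",
         call. = FALSE)
  }
  structure(list(n_lipids = as.integer(n_lipids), leaflet_z = leaflet_z,
                 carbonyl_offset = carbonyl_offset,
                 methyl_offset = methyl_offset, n_solute = as.integer(n_solute),
                 solute_z_band = sort(solute_z_band),
                 planted_clusters = planted_clusters,
                 planted_hbonds = as.integer(planted_hbonds),
                 n_hbond_decoys = as.integer(n_hbond_decoys),
                 box = as.numeric(box), jitter_sd = jitter_sd),
            class = "bilayer_spec")
}

#' Generate a synthetic two-leaflet trajectory with planted ground truth
#'
#' Lipids carry phosphorus, carbonyl and terminal-methyl sites on a lateral
#' grid around the +/- leaflet planes, jittered per frame by `jitter_sd`.
#' Solute molecules are placed so molecules within one planted cluster are
#' closer than 0.25 nm to a neighbor and different clusters are separated by
#' more than 0.5 nm; donor-hydrogen-acceptor triplets are placed in the
#' aqueous region with exactly `planted_hbonds` of them satisfying the
#' geometric criterion. Solute and triplet coordinates are held fixed across
#' frames so the planted truth holds in every frame.
#'
#' @param spec A [bilayer_spec].
#' @param n_frames Number of frames.
#' @param seed Integer seed; bit-reproducible.
#' @return An [md_traj].
#' @export
generate_bilayer <- function(spec = bilayer_spec(), n_frames = 10, seed = 1) {
  stopifnot(inherits(spec, "bilayer_spec"))
  box <- spec$box
  n_leaf <- spec$n_lipids / 2L
  n_side <- ceiling(sqrt(n_leaf))
  pitch <- box[1] / n_side
  if (box[1] != box[2]) pitch <- min(box[1], box[2]) / n_side

  # cluster layout: chains along x on a lateral grid; spacing must keep
  # different clusters > 0.5 nm apart including across the boundary
  n_cl <- length(spec$planted_clusters)
  max_size <- max(lengths(spec$planted_clusters))
  chain_step <- 0.2
  cl_pitch <- 2.0
  n_col <- max(floor(box[1] / cl_pitch), 0L)
  n_row <- if (n_col >= 1L) ceiling(n_cl / n_col) else 1L
  row_pitch <- box[2] / n_row
  if (n_col < 1L || row_pitch < 1.1 ||
      (max_size - 1) * chain_step + 2 * 0.5 > cl_pitch) {
    stop("box too small to honor the cluster separation guarantees",
         call. = FALSE)
  }
  # hydrogen-bond triplet layout
  n_trip <- spec$planted_hbonds + spec$n_hbond_decoys
  trip_pitch <- 1.5
  t_col <- floor(box[1] / trip_pitch)
  if (n_trip > 0 && (t_col < 1L || ceiling(n_trip / t_col) * trip_pitch > box[2])) {
    stop("box too small to honor the hydrogen-bond separation guarantees",
         call. = FALSE)
  }

  site_masses <- c(phosphorus = 30.974, carbonyl = 28.010,
                   terminal_methyl = 15.035)

  build_static <- function() {
    pos <- NULL; mol_id <- integer(0); kind <- character(0)
    role <- character(0); mass <- numeric(0); aname <- character(0)
    mname <- character(0)
    next_mol <- spec$n_lipids
    # solutes
    for (ci in seq_len(n_cl)) {
      members <- spec$planted_clusters[[ci]]
      cx <- ((ci - 1L) %% n_col + 0.5) * cl_pitch
      cy <- ((ci - 1L) %/% n_col + 0.5) * (box[2] / n_row)
      cz <- mean(spec$solute_z_band)
      for (k in seq_along(members)) {
        pos <- rbind(pos, c(cx + (k - 1) * chain_step -
                              (length(members) - 1) * chain_step / 2, cy, cz))
        mol_id <- c(mol_id, next_mol + members[k])
        kind <- c(kind, "solute"); role <- c(role, "other")
        mass <- c(mass, 484.5); aname <- c(aname, "C1")
        mname <- c(mname, "TMB")
      }
    }
    next_mol <- next_mol + spec$n_solute
    # donor-hydrogen-acceptor triplets in the aqueous region
    if (n_trip > 0) {
      z_wat <- spec$leaflet_z + 0.6
      if (z_wat + 0.05 >= box[3] / 2) z_wat <- box[3] / 2 - 0.1
      for (ti in seq_len(n_trip)) {
        tx <- ((ti - 1L) %% t_col + 0.5) * trip_pitch
        ty <- ((ti - 1L) %/% t_col + 0.5) * trip_pitch
        tz <- if (ti %% 2L == 0L) z_wat else -z_wat
        dDA <- if (ti <= spec$planted_hbonds) 0.30 else 0.45
        # collinear D-H...A along x: angle 0, distance dDA
        pos <- rbind(pos, c(tx, ty, tz),            # donor
                     c(tx + 0.10, ty, tz),          # hydrogen
                     c(tx + dDA, ty, tz))           # acceptor
        mol_id <- c(mol_id, next_mol + 2L * ti - 1L, next_mol + 2L * ti - 1L,
                    next_mol + 2L * ti)
        kind <- c(kind, rep("water", 3L))
        role <- c(role, "donor", "hydrogen", "acceptor")
        mass <- c(mass, 15.999, 1.008, 15.999)
        aname <- c(aname, "OD", "HD", "OA")
        mname <- c(mname, rep("HBW", 3L))
      }
    }
    list(pos = pos, mol_id = mol_id, kind = kind, role = role, mass = mass,
         aname = aname, mname = mname)
  }

  static <- build_static()
  lipid_grid <- expand.grid(ix = seq_len(n_side) - 0.5,
                            iy = seq_len(n_side) - 0.5)[seq_len(n_leaf), ]

  frames <- with_seed(seed, lapply(seq_len(n_frames), function(fr) {
    pos <- NULL; mol_id <- integer(0); kind <- character(0)
    role <- character(0); mass <- numeric(0); aname <- character(0)
    mname <- character(0)
    mol <- 0L
    for (side in c(1, -1)) {
      for (li in seq_len(n_leaf)) {
        mol <- mol + 1L
        x0 <- lipid_grid$ix[li] * pitch
        y0 <- lipid_grid$iy[li] * pitch
        zs <- side * c(spec$leaflet_z,
                       spec$leaflet_z - spec$carbonyl_offset,
                       spec$leaflet_z - spec$methyl_offset)
        jit <- if (spec$jitter_sd > 0) {
          matrix(stats::rnorm(9, 0, spec$jitter_sd), 3, 3)
        } else matrix(0, 3, 3)
        pos <- rbind(pos, cbind(x0, y0, zs) + jit)
        mol_id <- c(mol_id, rep(mol, 3L))
        kind <- c(kind, rep("lipid", 3L))
        role <- c(role, "phosphorus", "carbonyl", "terminal_methyl")
        mass <- c(mass, unname(site_masses))
        aname <- c(aname, "P", "C21", "C3T")
        mname <- c(mname, rep("DMPG", 3L))
      }
    }
    pos <- rbind(pos, static$pos)
    # shift z so coordinates live in [0, box_z) like a simulation box,
    # keeping the bilayer center at box_z/2
    pos[, 3] <- pos[, 3] + box[3] / 2
    md_config(positions = pos, box = box,
              mol_id = c(mol_id, static$mol_id),
              mol_kind = c(kind, static$kind), role = c(role, static$role),
              mass = c(mass, static$mass),
              atom_name = c(aname, static$aname),
              mol_name = c(mname, static$mname))
  }))
  md_traj(frames, times = (seq_len(n_frames) - 1) * 0.1)
}
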