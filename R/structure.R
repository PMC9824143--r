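#' Construct a molecular configuration
#'
#' Positions are in nanometres in an orthorhombic box. Each particle carries a
#' molecule id, a molecule kind (`lipid`, `solute` or `water`), a site role
#' drawn from the closed set `phosphorus`, `carbonyl`, `terminal_methyl`,
#' `donor`, `hydrogen`, `acceptor`, `other`, and a mass in atomic mass units.
#'
#' @param positions N x 3 numeric matrix, nm.
#' @param box Length-3 numeric, orthorhombic box edge lengths in nm.
#' @param mol_id Integer molecule id per particle.
#' @param mol_kind Character, one of `lipid`, `solute`, `water` per particle.
#' @param role Character site role per particle.
#' @param mass Numeric mass per particle (amu).
#' @param atom_name Optional atom names (used for role mapping and writing).
#' @param mol_name Optional residue/molecule names.
#' @return An object of class `md_config`.
#' @export
md_config <- function(positions, box, mol_id, mol_kind, role, mass,
                      atom_name = NULL, mol_name = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be N x 3", call. = FALSE)
  n <- nrow(positions)
  if (!all(is.finite(positions))) stop("positions must all be finite", call. = FALSE)
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be 3 positive edge lengths (orthorhombic)", call. = FALSE)
  }
  mol_id <- as.integer(mol_id)
  stopifnot(length(mol_id) == n, length(mol_kind) == n,
            length(role) == n, length(mass) == n)
  if (anyNA(mol_id)) stop("every particle needs a molecule id", call. = FALSE)
  kinds <- c("lipid", "solute", "water")
  if (!all(mol_kind %in% kinds)) {
    stop("mol_kind must be one of: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  roles <- c("phosphorus", "carbonyl", "terminal_methyl",
             "donor", "hydrogen", "acceptor", "other")
  if (!all(role %in% roles)) {
    stop("role must be one of: ", paste(roles, collapse = ", "), call. = FALSE)
  }
  structure(list(positions = positions, box = box, mol_id = mol_id,
                 mol_kind = as.character(mol_kind), role = as.character(role),
                 mass = as.numeric(mass),
                 atom_name = if (is.null(atom_name)) rep("X", n) else as.character(atom_name),
                 mol_name = if (is.null(mol_name)) rep("MOL", n) else as.character(mol_name)),
            class = "md_config")
}

#' @export
print.md_config <- function(x, ...) {
  cat(sprintf("<md_config> %d particles, %d molecules, box %.3f x %.3f x %.3f nm\n",
              nrow(x$positions), length(unique(x$mol_id)),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param frames List of [md_config] sharing particle count and labeling.
#' @param times Per-frame time stamps in ns, non-decreasing.
#' @return An object of class `md_traj`.
#' @export
md_traj <- function(frames, times = seq_along(frames) - 1) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n0 <- nrow(frames[[1L]]$positions)
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "md_config")) stop("frames must be md_config", call. = FALSE)
    if (nrow(frames[[i]]$positions) != n0) {
      stop(sprintf("frame %d has %d atoms, expected %d", i,
                   nrow(frames[[i]]$positions), n0), call. = FALSE)
    }
  }
  times <- as.numeric(times)
  if (length(times) != length(frames) || is.unsorted(times)) {
    stop("times must be one non-decreasing stamp per frame", call. = FALSE)
  }
  structure(list(frames = frames, times = times), class = "md_traj")
}

#' @export
length.md_traj <- function(x) length(x$frames)

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf("<md_traj> %d frames x %d particles, t in [%g, %g] ns\n",
              length(x$frames), nrow(x$frames[[1]]$positions),
              min(x$times), max(x$times)))
  invisible(x)
}

# Guessed element masses (amu) from the first alphabetic character of the
# atom name; enough for bookkeeping in density profiles.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, K = 39.098)

guess_mass <- function(atom_name) {
  el <- toupper(substr(gsub("^[0-9]+", "", trimws(atom_name)), 1L, 1L))
  m <- .element_masses[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

apply_role_map <- function(atom_name, role_map) {
  role <- rep("other", length(atom_name))
  nm <- trimws(atom_name)
  for (key in names(role_map)) role[nm == key] <- role_map[[key]]
  role
}

default_kind <- function(mol_name, kind_map = list()) {
  kind <- rep("lipid", length(mol_name))
  nm <- trimws(mol_name)
  kind[nm %in% c("SOL", "HOH", "TIP3", "WAT", "SPC")] <- "water"
  for (key in names(kind_map)) kind[nm == key] <- kind_map[[key]]
  kind
}

# ---- GRO ------------------------------------------------------------------

parse_gro_block <- function(lines, offset, role_map, kind_map) {
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms)) {
    stop(sprintf("malformed GRO atom count at line %d", offset + 2L), call. = FALSE)
  }
  if (length(lines) < natoms + 3L) stop("missing box line in GRO file", call. = FALSE)
  at <- lines[3:(2 + natoms)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  aname <- trimws(substr(at, 11, 15))
  xyz <- suppressWarnings(cbind(as.numeric(substr(at, 21, 28)),
                                as.numeric(substr(at, 29, 36)),
                                as.numeric(substr(at, 37, 44))))
  bad <- which(is.na(resid) | rowSums(is.na(xyz)) > 0)
  if (length(bad)) {
    stop(sprintf("malformed GRO fixed columns at line %d", offset + 2L + bad[1L]),
         call. = FALSE)
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3L]), "\\s+")[[1L]]))
  if (length(boxv) < 3L || anyNA(boxv)) {
    stop("missing or malformed GRO box line", call. = FALSE)
  }
  if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9)) {
    stop("triclinic box not supported: off-diagonal box vectors present", call. = FALSE)
  }
  md_config(positions = xyz, box = boxv[1:3], mol_id = resid,
            mol_kind = default_kind(resname, kind_map),
            role = apply_role_map(aname, role_map),
            mass = guess_mass(aname), atom_name = aname, mol_name = resname)
}

# ---- PDB ------------------------------------------------------------------

parse_pdb_block <- function(lines, role_map, kind_map, box) {
  at <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(at)) stop("no ATOM records in PDB frame", call. = FALSE)
  aname <- trimws(substr(at, 13, 16))
  resname <- trimws(substr(at, 18, 21))
  resid <- suppressWarnings(as.integer(substr(at, 23, 26)))
  xyz <- suppressWarnings(cbind(as.numeric(substr(at, 31, 38)),
                                as.numeric(substr(at, 39, 46)),
                                as.numeric(substr(at, 47, 54))))
  bad <- which(is.na(resid) | rowSums(is.na(xyz)) > 0)
  if (length(bad)) {
    stop(sprintf("malformed PDB ATOM record (record %d)", bad[1L]), call. = FALSE)
  }
  md_config(positions = xyz / 10, box = box, mol_id = resid,   # Angstrom -> nm
            mol_kind = default_kind(resname, kind_map),
            role = apply_role_map(aname, role_map),
            mass = guess_mass(aname), atom_name = aname, mol_name = resname)
}

parse_cryst1 <- function(lines) {
  cl <- lines[grepl("^CRYST1", lines)]
  if (!length(cl)) stop("missing CRYST1 box record in PDB file", call. = FALSE)
  a <- as.numeric(substr(cl[1L], 7, 15))
  b <- as.numeric(substr(cl[1L], 16, 24))
  c_ <- as.numeric(substr(cl[1L], 25, 33))
  ang <- c(as.numeric(substr(cl[1L], 34, 40)),
           as.numeric(substr(cl[1L], 41, 47)),
           as.numeric(substr(cl[1L], 48, 54)))
  if (anyNA(c(a, b, c_))) stop("malformed CRYST1 record", call. = FALSE)
  if (any(abs(ang - 90) > 1e-3)) {
    stop("triclinic box not supported: CRYST1 angles differ from 90 degrees",
         call. = FALSE)
  }
  c(a, b, c_) / 10  # Angstrom -> nm
}

#' Read a single configuration from GRO or PDB
#'
#' GRO coordinates are taken as nm; PDB coordinates (and the CRYST1 box) are
#' converted from Angstrom to nm on load. Site roles are assigned from a
#' user-supplied atom-name to role map; unmapped atoms get role `other`.
#'
#' @param path File path.
#' @param format `"gro"` or `"pdb"`; guessed from the extension when missing.
#' @param role_map Named list, atom name -> role (e.g. `list(P = "phosphorus")`).
#' @param kind_map Named list, residue name -> molecule kind; common water
#'   residue names map to `water` automatically, everything else defaults to
#'   `lipid`.
#' @return An [md_config].
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"),
                           role_map = list(), kind_map = list()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "gro") {
    parse_gro_block(lines, 0L, role_map, kind_map)
  } else {
    parse_pdb_block(lines, role_map, kind_map, parse_cryst1(lines))
  }
}

#' Read a multi-frame GRO or PDB trajectory
#'
#' Multi-frame GRO files are concatenated title/count/atoms/box blocks;
#' multi-frame PDB files use MODEL/ENDMDL records with one CRYST1 per file or
#' per model. Labeling (molecule ids, kinds, roles, masses) is taken from the
#' first frame. Frame times are read from a `t=` tag in GRO title lines when
#' present, else 0, 1, 2, ... ns.
#'
#' @inheritParams read_structure
#' @return An [md_traj].
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "pdb"),
                            role_map = list(), kind_map = list()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("no frames: file is empty", call. = FALSE)
  frames <- list()
  times <- numeric(0)
  if (format == "gro") {
    i <- 1L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
      if (is.na(natoms)) {
        stop(sprintf("malformed GRO atom count at line %d", i + 1L), call. = FALSE)
      }
      if (i + natoms + 2L > length(lines)) {
        stop(sprintf("frame %d truncated", length(frames) + 1L), call. = FALSE)
      }
      blk <- lines[i:(i + natoms + 2L)]
      frames[[length(frames) + 1L]] <-
        parse_gro_block(blk, i - 1L, role_map, kind_map)
      tmatch <- regmatches(blk[1L], regexpr("t=\\s*[-0-9.eE+]+", blk[1L]))
      times <- c(times, if (length(tmatch)) {
        as.numeric(sub("t=\\s*", "", tmatch)) / 1000  # GROMACS titles carry ps
      } else length(frames) - 1)
      i <- i + natoms + 3L
    }
  } else {
    box <- parse_cryst1(lines)
    starts <- grep("^MODEL", lines)
    if (!length(starts)) {
      frames <- list(parse_pdb_block(lines, role_map, kind_map, box))
      times <- 0
    } else {
      ends <- grep("^ENDMDL", lines)
      if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL", call. = FALSE)
      for (k in seq_along(starts)) {
        frames[[k]] <- parse_pdb_block(lines[starts[k]:ends[k]],
                                       role_map, kind_map, box)
      }
      times <- seq_along(starts) - 1
    }
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  n0 <- nrow(frames[[1L]]$positions)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$positions) != n0) {
      stop(sprintf("frame %d has %d atoms, expected %d", k,
                   nrow(frames[[k]]$positions), n0), call. = FALSE)
    }
    # labeling is shared: take it from frame 1
    frames[[k]]$mol_id <- frames[[1L]]$mol_id
    frames[[k]]$mol_kind <- frames[[1L]]$mol_kind
    frames[[k]]$role <- frames[[1L]]$role
    frames[[k]]$mass <- frames[[1L]]$mass
  }
  md_traj(frames, times)
}

#' Write a configuration or trajectory as GRO
#'
#' @param x An [md_config] or [md_traj].
#' @param path Output path.
#' @param title Title line written per frame.
#' @return `path`, invisibly.
#' @export
write_gro <- function(x, path, title = "membranr configuration") {
  frames <- if (inherits(x, "md_traj")) x$frames else list(x)
  times <- if (inherits(x, "md_traj")) x$times else 0
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    n <- nrow(f$positions)
    writeLines(sprintf("%s t= %.4f", title, times[k] * 1000), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       f$mol_id %% 100000L, substr(f$mol_name, 1, 5),
                       substr(f$atom_name, 1, 5), seq_len(n) %% 100000L,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}
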