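#' Read a species / charge / radius configuration
#'
#' The configuration is a YAML file with four top-level blocks:
#' `species` (per-species lists of `residues` and/or `atoms` names used to
#' classify atoms), `charges` (`by_atom` and `by_species` tables, elementary
#' charges), `radii` (`by_atom` and `by_element` Van der Waals radii,
#' Angstrom) and optionally `masses` (`by_atom` plus `default`, amu).
#' Force-field naming dialects vary, so nothing is hard-coded: the package
#' ships a configuration for its own synthetic fixtures
#' (`system.file("extdata", "synthetic_species.yaml", package = "poreclog")`)
#' and a generic CHARMM-flavoured one for real systems
#' (`system.file("extdata", "charmm_species.yaml", package = "poreclog")`).
#'
#' @param path path to a YAML configuration file.
#' @return a named list with elements `species`, `charges`, `radii`,
#'   `masses`.
#' @seealso [read_trajectory()]
#' @export
read_species_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (block in c("species", "charges", "radii"))
    if (is.null(cfg[[block]]))
      stop("config is missing the '", block, "' block", call. = FALSE)
  .check_species(names(cfg$species))
  cfg$masses <- cfg$masses %||% list(default = 1)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default configuration for synthetic fixtures
#' @return config list, see [read_species_config()].
#' @export
synthetic_species_config <- function() {
  read_species_config(system.file("extdata", "synthetic_species.yaml",
                                  package = "poreclog", mustWork = TRUE))
}

# classify atoms: atom-name rules take precedence over residue rules
.assign_species <- function(name, residue, rules) {
  species <- rep("OTHER", length(name))
  for (sp in names(rules)) {
    r <- rules[[sp]]
    if (length(r$residues)) species[residue %in% r$residues] <- sp
  }
  for (sp in names(rules)) {
    r <- rules[[sp]]
    if (length(r$atoms)) species[name %in% r$atoms] <- sp
  }
  species
}

.table_get <- function(tab, keys) {
  out <- rep(NA_real_, length(keys))
  tab <- unlist(tab)
  if (length(tab)) {
    hit <- match(keys, names(tab))
    out[!is.na(hit)] <- tab[hit[!is.na(hit)]]
  }
  out
}

.lookup_radius <- function(name, element, radii) {
  r <- .table_get(radii$by_atom, name)
  miss <- is.na(r)
  if (any(miss)) r[miss] <- .table_get(radii$by_element, element[miss])
  if (anyNA(r))
    stop("no Van der Waals radius for atom name(s): ",
         paste(unique(name[is.na(r)]), collapse = ", "),
         " - extend the 'radii' block of the config (no silent default)",
         call. = FALSE)
  unname(r)
}

.lookup_charge <- function(name, species, charges) {
  q <- .table_get(charges$by_atom, name)
  miss <- is.na(q)
  if (any(miss)) q[miss] <- .table_get(charges$by_species, species[miss])
  if (anyNA(q))
    stop("no partial charge for atom name(s): ",
         paste(unique(name[is.na(q)]), collapse = ", "),
         " - extend the 'charges' block of the config", call. = FALSE)
  unname(q)
}

.lookup_mass <- function(name, masses) {
  m <- .table_get(masses$by_atom, name)
  m[is.na(m)] <- masses$default %||% 1
  unname(m)
}

#' Build per-atom metadata from names and residues
#'
#' @param name,residue character vectors of atom and residue names.
#' @param config configuration list from [read_species_config()].
#' @param element optional element symbols used as radius fallback.
#' @return data.frame with columns `atom_id`, `name`, `residue`, `species`,
#'   `charge` (e), `vdw_radius` (Angstrom), `mass` (amu).
#' @export
atom_metadata <- function(name, residue, config, element = NULL) {
  stopifnot(length(name) == length(residue))
  if (is.null(element)) element <- toupper(gsub("[^A-Za-z].*$", "", name))
  species <- .assign_species(name, residue, config$species)
  meta <- data.frame(
    atom_id = seq_along(name),
    name = name, residue = residue, species = species,
    charge = .lookup_charge(name, species, config$charges),
    vdw_radius = .lookup_radius(name, element, config$radii),
    mass = .lookup_mass(name, config$masses),
    stringsAsFactors = FALSE)
  if (any(!is.finite(meta$charge)))
    stop("non-finite charge in configuration", call. = FALSE)
  if (any(meta$vdw_radius <= 0))
    stop("Van der Waals radii must be > 0", call. = FALSE)
  meta
}

#' Construct a trajectory object from in-memory components
#'
#' @param atoms data.frame from [atom_metadata()].
#' @param xyz numeric matrix, `n_frames x 3*n_atoms`, bio3d ordering
#'   (x1, y1, z1, x2, ...), Angstrom.
#' @param box numeric matrix `n_frames x 3` of per-frame box lengths
#'   (Lx, Ly, Lz), Angstrom.
#' @param frame_interval time between saved frames, ps.
#' @param times optional frame times, ps; defaults to
#'   `(0:(n-1)) * frame_interval`.
#' @return object of class `"trajectory"`.
#' @export
new_trajectory <- function(atoms, xyz, box, frame_interval = 40,
                           times = NULL) {
  xyz <- as.matrix(xyz)
  box <- matrix(as.numeric(box), ncol = 3)
  .assert_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  n_atoms <- nrow(atoms)
  if (ncol(xyz) != 3L * n_atoms)
    stop("format error: trajectory has ", ncol(xyz) / 3,
         " atoms but topology has ", n_atoms, call. = FALSE)
  if (nrow(box) != nrow(xyz))
    stop("need one box per frame", call. = FALSE)
  if (any(box <= 0)) stop("box components must be > 0", call. = FALSE)
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * frame_interval
  if (is.unsorted(times, strictly = TRUE))
    stop("frames must be strictly time-ordered", call. = FALSE)
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(abs(dt - frame_interval) > 1e-6 * frame_interval))
      stop("frame times inconsistent with frame_interval", call. = FALSE)
  }
  structure(list(atoms = atoms, xyz = xyz, box = box, times = times,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' Load a PDB + DCD trajectory with atom metadata
#'
#' Reads the topology and frames, checks that atom counts agree, and
#' assigns species, partial charge and Van der Waals radius to every atom
#' from the configuration (an atom name absent from the radius or charge
#' tables is an error, never silently defaulted).
#'
#' @param topology_path PDB file.
#' @param trajectory_path DCD file; must carry a unit cell block (the
#'   readers tolerate per-frame box fluctuations).
#' @param config configuration list, see [read_species_config()].
#' @param frame_interval time between saved frames, ps (DCD headers do not
#'   reliably store physical time).
#' @return a `"trajectory"` object: list with `atoms` (metadata
#'   data.frame), `xyz` (`n_frames x 3N`), `box` (`n_frames x 3`), `times`
#'   (ps) and `frame_interval`.
#' @export
read_trajectory <- function(topology_path, trajectory_path,
                            config = synthetic_species_config(),
                            frame_interval = 40) {
  pdb <- bio3d::read.pdb(topology_path)
  xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
  cell <- bio3d::read.dcd(trajectory_path, cell = TRUE, verbose = FALSE)
  elesy <- pdb$atom$elesy
  if (is.null(elesy) || all(is.na(elesy) | elesy == "")) elesy <- NULL
  else elesy <- toupper(trimws(elesy))
  atoms <- atom_metadata(trimws(pdb$atom$elety), trimws(pdb$atom$resid),
                         config, element = elesy)
  new_trajectory(atoms, unclass(xyz), cell[, 1:3, drop = FALSE],
                 frame_interval = frame_interval)
}

#' Select atom indices by species
#'
#' @param traj a `"trajectory"`.
#' @param species character vector of species names among
#'   `WATER, ION_K, ION_CL, PEPTIDE, PORE, LIPID, OTHER`.
#' @return sorted unique 1-based atom indices.
#' @export
select_atoms <- function(traj, species) {
  if (length(species) == 0) stop("species set must be non-empty",
                                 call. = FALSE)
  species <- .check_species(species)
  sort(unique(which(traj$atoms$species %in% species)))
}

#' Coordinates of one frame
#' @param traj a `"trajectory"`.
#' @param i frame index.
#' @return `n_atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= nrow(traj$xyz))
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, dt = %g ps\n",
              nrow(x$atoms), nrow(x$xyz), x$frame_interval))
  cat("  species:",
      paste(sprintf("%s=%d", names(table(x$atoms$species)),
                    table(x$atoms$species)), collapse = " "), "\n")
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}
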