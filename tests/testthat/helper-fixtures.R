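# Shared fixture builders and independent oracles.

# minimal atom metadata table for hand-built trajectories
toy_atoms <- function(n, species = "ION_K", charge = 1, radius = 1.5,
                      mass = 1) {
  data.frame(atom_id = seq_len(n),
             name = rep_len(species, n), residue = rep_len(species, n),
             species = rep_len(species, n),
             charge = rep_len(charge, n),
             vdw_radius = rep_len(radius, n), mass = rep_len(mass, n),
             stringsAsFactors = FALSE)
}

# trajectory from a list of n_atoms x 3 coordinate matrices
toy_traj <- function(frames, atoms, box = c(100, 100, 100), dt = 40) {
  xyz <- t(vapply(frames, function(f) as.vector(t(f)),
                  numeric(3 * nrow(atoms))))
  if (length(frames) == 1) xyz <- matrix(xyz, nrow = 1)
  new_trajectory(atoms, xyz,
                 matrix(rep(box, each = length(frames)), ncol = 3),
                 frame_interval = dt)
}

# occupancy map directly from a 3D array (for filter unit tests)
map_from_array <- function(values, cell = c(1, 1, 1), origin = c(0, 0, 0),
                           stage = "NORMALIZED") {
  g <- grid_spec(origin, dim(values), cell)
  poreclog:::.new_map(g, values, stage)
}

# brute-force oracle: occupied-cell count for one sphere by exhaustive
# lattice enumeration over the whole grid
sphere_cells_oracle <- function(center, radius, grid) {
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$cell[1]
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$cell[2]
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$cell[3]
  cc <- as.matrix(expand.grid(cx, cy, cz))
  d2 <- (cc[, 1] - center[1])^2 + (cc[, 2] - center[2])^2 +
    (cc[, 3] - center[3])^2
  sum(d2 <= radius^2)
}

# independent oracle for directional accessibility: exhaustive monotone-z
# reachability on a directed graph (igraph), 6-connectivity
monotone_mask_oracle <- function(open, direction, seed_slice = NULL) {
  n <- dim(open)
  id <- array(seq_along(open), n)
  ed <- list()
  add <- function(i1, i2, both) {
    keep <- open[i1] & open[i2]
    e <- cbind(i1[keep], i2[keep])
    if (both) e <- rbind(e, e[, 2:1, drop = FALSE])
    ed[[length(ed) + 1]] <<- e
  }
  if (n[1] > 1) add(id[-n[1], , , drop = FALSE], id[-1, , , drop = FALSE],
                    both = TRUE)
  if (n[2] > 1) add(id[, -n[2], , drop = FALSE], id[, -1, , drop = FALSE],
                    both = TRUE)
  if (n[3] > 1) {
    lo <- id[, , -n[3], drop = FALSE]; hi <- id[, , -1, drop = FALSE]
    if (direction == "trans_to_cis") add(lo, hi, both = FALSE)
    else add(hi, lo, both = FALSE)
  }
  edges <- do.call(rbind, ed)
  g <- igraph::make_empty_graph(n = prod(n), directed = TRUE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  k0 <- if (!is.null(seed_slice)) seed_slice
        else if (direction == "trans_to_cis") 1L else n[3]
  seeds <- which(open & slice_indicator(n, k0))
  mask <- array(FALSE, n)
  if (length(seeds)) {
    d <- igraph::distances(g, v = seeds, mode = "out")
    mask[apply(is.finite(d), 2, any)] <- TRUE
  }
  mask
}

slice_indicator <- function(n, k) {
  s <- array(FALSE, n); s[, , k] <- TRUE; s
}

# plain (non-monotone) 3D flood fill from a slice, undirected BFS
floodfill_oracle <- function(open, seed_slice) {
  n <- dim(open)
  id <- array(seq_along(open), n)
  ed <- list()
  add <- function(i1, i2) {
    keep <- open[i1] & open[i2]
    ed[[length(ed) + 1]] <<- cbind(i1[keep], i2[keep])
  }
  if (n[1] > 1) add(id[-n[1], , , drop = FALSE], id[-1, , , drop = FALSE])
  if (n[2] > 1) add(id[, -n[2], , drop = FALSE], id[, -1, , drop = FALSE])
  if (n[3] > 1) add(id[, , -n[3], drop = FALSE], id[, , -1, drop = FALSE])
  edges <- do.call(rbind, ed)
  g <- igraph::make_empty_graph(n = prod(n), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  seeds <- which(open & slice_indicator(n, seed_slice))
  mask <- array(FALSE, n)
  if (length(seeds)) {
    d <- igraph::distances(g, v = seeds)
    mask[apply(is.finite(d), 2, any)] <- TRUE
  }
  mask
}

# standard synthetic cylinder fixture: dense lattice fill -> normalized map
lattice_cylinder_map <- function(shape = "cylinder", cell = 1, radius = 5,
                                 length = 50, half_width = 13,
                                 bead_radius = 0, bead_z = NULL) {
  geom <- pore_geometry(shape, radius = radius, length = length)
  pore <- make_pore(geom)
  if (bead_radius > 0)
    pore <- insert_obstruction(pore, bead_radius, z_range = bead_z)
  st <- make_trajectory(pore,
                        electrolyte_spec(n_water = Inf,
                                         placement = "lattice"),
                        n_frames = 1)
  nxy <- round(2 * half_width / cell)
  grid <- grid_spec(origin = c(-half_width, -half_width, 0),
                    dims = c(nxy, nxy, round(length / cell)),
                    cell = rep(cell, 3))
  ctr <- round(nxy / 2); zc <- round(length / cell)
  if (bead_radius > 0 && !is.null(bead_z)) {
    # bulk slab on the axis but outside the obstructed z range
    zb <- if (bead_z[1] >= 6) c(2, bead_z[1] - 2)
          else c(bead_z[2] + 2, length - 2)
    bulk <- c(ctr - 1, ctr + 2, ctr - 1, ctr + 2,
              max(1, round(zb[1] / cell)), round(zb[2] / cell))
  } else {
    bulk <- c(ctr - 1, ctr + 2, ctr - 1, ctr + 2,
              round(0.2 * zc), round(0.8 * zc))
  }
  occupancy_map(st$trajectory, grid = grid, bulk_region = bulk)
}
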