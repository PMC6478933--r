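#' Define a regular analysis grid
#'
#' The grid is the analysis window: cell `(i, j, k)` (1-based) covers the
#' half-open box `origin + ((i-1) dx, i dx) x ...` and its center sits at
#' `origin + ((i - 1/2) dx, ...)`.
#'
#' @param origin lower corner `(x, y, z)`, Angstrom.
#' @param dims number of cells `(nx, ny, nz)`.
#' @param cell cell edge lengths `(dx, dy, dz)`, Angstrom; default 1 A
#'   cubic cells.
#' @return object of class `"grid_spec"`.
#' @export
grid_spec <- function(origin, dims, cell = c(1, 1, 1)) {
  origin <- as.numeric(origin); cell <- as.numeric(cell)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(cell) == 3, length(dims) == 3)
  if (any(!is.finite(origin))) stop("grid origin must be finite",
                                    call. = FALSE)
  if (any(cell <= 0)) stop("cell sizes must be > 0", call. = FALSE)
  if (any(dims < 1)) stop("grid dims must be >= 1", call. = FALSE)
  structure(list(origin = origin, cell = cell, dims = dims),
            class = "grid_spec")
}

.grid_equal <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) && all(abs(a$cell - b$cell) < tol) &&
    all(a$dims == b$dims)
}

#' z coordinates of slice centers of a grid
#' @param grid a `"grid_spec"`.
#' @return numeric vector of length `dims[3]`.
#' @export
grid_z_centers <- function(grid) {
  grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$cell[3]
}

.new_map <- function(grid, values, stage, bulk = NULL) {
  structure(list(grid = grid, values = values, stage = stage, bulk = bulk),
            class = "occupancy_map")
}

#' Rasterize one frame onto the grid
#'
#' Marks a cell occupied when it lies within a Van der Waals radius of at
#' least one selected atom.  Two membership tests are offered: `"center"`
#' (cell center inside the sphere, the Volmap-style default) and
#' `"overlap"` (sphere intersects the cell cube at all).  Atoms outside the
#' grid bounding box are ignored: the grid is the analysis window.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom) of the selected
#'   atoms, or a `"trajectory"` (then give `frame` and `atoms`).
#' @param radii per-atom Van der Waals radii (recycled if length 1).
#' @param grid a [grid_spec()].
#' @param mode membership test, `"center"` or `"overlap"`.
#' @param frame,atoms frame index and atom indices when `coords` is a
#'   trajectory.
#' @return binary `"occupancy_map"` (stage `BINARY_FRAME`).
#' @export
rasterize_frame <- function(coords, radii = NULL, grid,
                            mode = c("center", "overlap"),
                            frame = NULL, atoms = NULL) {
  mode <- match.arg(mode)
  if (inherits(coords, "trajectory")) {
    traj <- coords
    if (is.null(frame)) stop("give 'frame' when rasterizing a trajectory",
                             call. = FALSE)
    if (is.null(atoms)) atoms <- seq_len(nrow(traj$atoms))
    coords <- frame_coords(traj, frame)[atoms, , drop = FALSE]
    radii <- traj$atoms$vdw_radius[atoms]
  }
  coords <- matrix(as.numeric(coords), ncol = 3)
  vals <- array(0, dim = grid$dims)
  if (nrow(coords) == 0) return(.new_map(grid, vals, "BINARY_FRAME"))
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (is.null(radii)) stop("need per-atom radii", call. = FALSE)
  radii <- rep_len(as.numeric(radii), nrow(coords))
  if (any(radii <= 0)) stop("radii must be > 0", call. = FALSE)

  d <- grid$cell; n <- grid$dims
  # continuous grid coordinates of the atoms (cell center k has coord k-1/2)
  u <- sweep(coords, 2, grid$origin)
  u <- sweep(u, 2, d, "/")
  occ <- vals > 1  # logical array, all FALSE
  for (r in unique(radii)) {
    sel <- which(radii == r)
    nmax <- ceiling(r / d + if (mode == "overlap") 1 else 0.5)
    off <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2],
                                 -nmax[3]:nmax[3]))
    base <- floor(u[sel, , drop = FALSE] - 0.5) + 1  # cell holding nearest center
    # candidate cell indices: n_sel x n_offsets per dimension
    ci <- lapply(1:3, function(k) outer(base[, k], off[, k], "+"))
    # distance from atom to cell center (or to cell cube in overlap mode)
    dist2 <- 0
    for (k in 1:3) {
      dd <- (ci[[k]] - 0.5 - u[sel, k]) * d[k]
      if (mode == "overlap") dd <- pmax(abs(dd) - d[k] / 2, 0)
      dist2 <- dist2 + dd * dd
    }
    hit <- dist2 <= r ^ 2
    inb <- ci[[1]] >= 1 & ci[[1]] <= n[1] & ci[[2]] >= 1 & ci[[2]] <= n[2] &
      ci[[3]] >= 1 & ci[[3]] <= n[3]
    keep <- which(hit & inb)
    if (length(keep))
      occ[cbind(ci[[1]][keep], ci[[2]][keep], ci[[3]][keep])] <- TRUE
  }
  vals[occ] <- 1
  .new_map(grid, vals, "BINARY_FRAME")
}

#' Average per-frame binary maps
#'
#' @param maps list of binary `"occupancy_map"`s on the same grid.
#' @return `"occupancy_map"` with stage `AVERAGED` (values in `[0, 1]`).
#' @export
average_maps <- function(maps) {
  if (length(maps) < 1) stop("need at least one map", call. = FALSE)
  g <- maps[[1]]$grid
  for (m in maps)
    if (!.grid_equal(m$grid, g))
      stop("maps must share a grid", call. = FALSE)
  s <- Reduce(`+`, lapply(maps, `[[`, "values"))
  .new_map(g, s / length(maps), "AVERAGED")
}

#' Normalize an averaged map by its bulk value
#'
#' Divides by the mean averaged occupancy over a user-configured bulk
#' region (an axis-aligned box in grid indices), so the map reads as a
#' density relative to bulk electrolyte.
#'
#' @param map an `AVERAGED` `"occupancy_map"`.
#' @param bulk_region integer vector `c(i1, i2, j1, j2, k1, k2)` of
#'   inclusive 1-based cell index ranges.
#' @return `"occupancy_map"` with stage `NORMALIZED`; the bulk value is
#'   stored in `$bulk`.
#' @export
normalize_bulk <- function(map, bulk_region) {
  stopifnot(inherits(map, "occupancy_map"))
  if (map$stage != "AVERAGED")
    stop("normalize_bulk() expects an AVERAGED map", call. = FALSE)
  b <- as.integer(bulk_region)
  if (length(b) != 6 || any(b[c(1, 3, 5)] > b[c(2, 4, 6)]))
    stop("bulk_region must be c(i1,i2,j1,j2,k1,k2) with lo <= hi",
         call. = FALSE)
  n <- map$grid$dims
  if (b[1] < 1 || b[3] < 1 || b[5] < 1 || b[2] > n[1] || b[4] > n[2] ||
      b[6] > n[3])
    stop("bulk_region outside grid", call. = FALSE)
  bulk <- mean(map$values[b[1]:b[2], b[3]:b[4], b[5]:b[6]])
  if (bulk <= 0)
    stop("degenerate normalization: bulk region has zero mean occupancy",
         call. = FALSE)
  .new_map(map$grid, map$values / bulk, "NORMALIZED", bulk = bulk)
}

#' Averaged (and optionally normalized) occupancy map of a trajectory
#'
#' Convenience wrapper: rasterizes the selected atoms frame by frame,
#' averages, and (when `bulk_region` is given) normalizes by the bulk.
#'
#' @param traj a `"trajectory"`.
#' @param atoms atom indices (e.g. from [select_atoms()]); default: all
#'   water and ion atoms, the electrolyte.
#' @param grid a [grid_spec()].
#' @param frames frame indices to use; default all.
#' @param bulk_region optional bulk box for [normalize_bulk()].
#' @inheritParams rasterize_frame
#' @return an `"occupancy_map"`, stage `AVERAGED` or `NORMALIZED`.
#' @export
occupancy_map <- function(traj, atoms = NULL, grid, frames = NULL,
                          bulk_region = NULL, mode = "center") {
  if (is.null(atoms))
    atoms <- select_atoms(traj, c("WATER", "ION_K", "ION_CL"))
  if (is.null(frames)) frames <- seq_len(nrow(traj$xyz))
  radii <- traj$atoms$vdw_radius[atoms]
  acc <- array(0, dim = grid$dims)
  for (f in frames) {
    m <- rasterize_frame(frame_coords(traj, f)[atoms, , drop = FALSE],
                         radii, grid, mode = mode)
    acc <- acc + m$values
  }
  out <- .new_map(grid, acc / length(frames), "AVERAGED")
  if (!is.null(bulk_region)) out <- normalize_bulk(out, bulk_region)
  out
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("occupancy_map [%s]: %d x %d x %d cells of %.2g x %.2g x %.2g A\n",
              x$stage, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$cell[1], x$grid$cell[2], x$grid$cell[3]))
  cat(sprintf("  occupied fraction: %.3f; value range [%.3g, %.3g]\n",
              mean(x$values > 0), min(x$values), max(x$values)))
  if (!is.null(x$bulk)) cat(sprintf("  bulk value: %.4g\n", x$bulk))
  invisible(x)
}
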