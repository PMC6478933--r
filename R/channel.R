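#' Directional accessibility of the electrolyte channel
#'
#' Formalizes "accessible when moving from one entrance towards the other"
#' as monotone-z reachability on the open cells of a normalized occupancy
#' map: a cell belongs to the `trans_to_cis` mask iff a path of
#' face-adjacent open cells (occupancy strictly above `theta`) leads from a
#' seed cell in the entrance slice to it with non-decreasing z
#' (non-increasing for `cis_to_trans`); lateral steps at constant z are
#' unrestricted.  This excludes reentrant electrolyte pockets directed
#' towards the opposite side while keeping lateral lobes.  With
#' `connectivity = 26`, diagonal lateral and diagonal upward steps are also
#' allowed.
#'
#' @param map a `NORMALIZED` (or `AVERAGED`) `"occupancy_map"`.
#' @param direction `"trans_to_cis"` (seeds at the z-min slice, the trans
#'   barrel entrance) or `"cis_to_trans"` (seeds at z-max, the vestibule).
#' @param theta open threshold: a cell is open when `value > theta`.
#'   Default 0, i.e. any strictly positive normalized occupancy.
#' @param seed_slice entrance slice index; defaults to 1 or `dims[3]`
#'   according to `direction`.
#' @param seed_center,seed_radius optional lateral disk (Angstrom, in grid
#'   x/y coordinates) restricting the seeds to around the pore axis, to
#'   avoid seeding in bulk outside the pore.
#' @param connectivity 6 (faces) or 26 (faces + edges + corners).
#' @return object of class `"accessibility_mask"`: list with `grid`,
#'   logical array `mask`, `direction`, `theta`.
#' @export
directional_accessibility <- function(map,
                                      direction = c("trans_to_cis",
                                                    "cis_to_trans"),
                                      theta = 0, seed_slice = NULL,
                                      seed_center = NULL, seed_radius = NULL,
                                      connectivity = 6) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "occupancy_map"))
  if (!is.numeric(theta) || theta < 0) stop("theta must be >= 0",
                                            call. = FALSE)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26",
                                        call. = FALSE)
  n <- map$grid$dims
  open <- map$values > theta
  if (is.null(seed_slice))
    seed_slice <- if (direction == "trans_to_cis") 1L else n[3]
  seed_slice <- as.integer(seed_slice)
  if (seed_slice < 1 || seed_slice > n[3])
    stop("seed slice outside grid", call. = FALSE)

  seed2d <- matrix(TRUE, n[1], n[2])
  if (!is.null(seed_radius)) {
    if (is.null(seed_center)) seed_center <- map$grid$origin[1:2] +
        n[1:2] * map$grid$cell[1:2] / 2
    xc <- map$grid$origin[1] + (seq_len(n[1]) - 0.5) * map$grid$cell[1]
    yc <- map$grid$origin[2] + (seq_len(n[2]) - 0.5) * map$grid$cell[2]
    seed2d <- outer((xc - seed_center[1])^2, (yc - seed_center[2])^2,
                    "+") <= seed_radius^2
  }

  diag2d <- connectivity == 26
  mask <- array(FALSE, dim = n)
  korder <- if (direction == "trans_to_cis") seed_slice:n[3]
            else seed_slice:1
  prev <- NULL
  for (k in korder) {
    op <- open[, , k]
    init <- if (is.null(prev)) op & seed2d
            else op & .vertical_pred(prev, diag2d)
    mask[, , k] <- .grow_lateral(init, op, diag2d)
    prev <- mask[, , k]
  }
  if (!any(mask))
    warning("no open seed cells: accessibility mask is empty")
  structure(list(grid = map$grid, mask = mask, direction = direction,
                 theta = theta, connectivity = connectivity),
            class = "accessibility_mask")
}

# union of 4- (or 8-) neighbour shifts of a logical matrix
.shift_any <- function(m, diag = FALSE) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  out[-1, ] <- out[-1, ] | m[-nx, , drop = FALSE]
  out[-nx, ] <- out[-nx, ] | m[-1, , drop = FALSE]
  out[, -1] <- out[, -1] | m[, -ny, drop = FALSE]
  out[, -ny] <- out[, -ny] | m[, -1, drop = FALSE]
  if (diag) {
    out[-1, -1] <- out[-1, -1] | m[-nx, -ny, drop = FALSE]
    out[-1, -ny] <- out[-1, -ny] | m[-nx, -1, drop = FALSE]
    out[-nx, -1] <- out[-nx, -1] | m[-1, -ny, drop = FALSE]
    out[-nx, -ny] <- out[-nx, -ny] | m[-1, -1, drop = FALSE]
  }
  out
}

# cells of a slice reachable by one vertical step from the previous slice:
# directly below for 6-connectivity, below or diagonally below for 26
.vertical_pred <- function(prev, diag) {
  if (diag) prev | .shift_any(prev, TRUE) else prev
}

# lateral flood fill: grow 'init' within the open cells of one slice
.grow_lateral <- function(init, open, diag = FALSE) {
  reach <- init & open
  repeat {
    grown <- reach | (open & .shift_any(reach, diag))
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

#' Intersect two accessibility masks
#'
#' The through-channel is the intersection of the trans-to-cis and
#' cis-to-trans accessible pores.
#'
#' @param a,b `"accessibility_mask"`s on the same grid.
#' @return `"accessibility_mask"` with direction `"intersection"`.
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "accessibility_mask"),
            inherits(b, "accessibility_mask"))
  if (!.grid_equal(a$grid, b$grid))
    stop("masks must share a grid", call. = FALSE)
  structure(list(grid = a$grid, mask = a$mask & b$mask,
                 direction = "intersection", theta = a$theta,
                 connectivity = a$connectivity),
            class = "accessibility_mask")
}

#' Restrict a normalized map to the accessible channel
#'
#' @param map a `NORMALIZED` `"occupancy_map"`.
#' @param mask an (intersection) `"accessibility_mask"` on the same grid.
#' @return object of class `"channel_map"`: the map values on masked
#'   cells, zero elsewhere.
#' @export
apply_mask <- function(map, mask) {
  stopifnot(inherits(map, "occupancy_map"),
            inherits(mask, "accessibility_mask"))
  if (!.grid_equal(map$grid, mask$grid))
    stop("map and mask must share a grid", call. = FALSE)
  v <- map$values
  v[!mask$mask] <- 0
  structure(list(grid = map$grid, values = v, mask = mask$mask),
            class = "channel_map")
}

#' One-call pocket filtering
#'
#' Computes both directional masks, intersects them and applies the result,
#' yielding the filtered through-channel map.
#'
#' @inheritParams directional_accessibility
#' @return a `"channel_map"`.
#' @export
accessible_channel <- function(map, theta = 0, seed_center = NULL,
                               seed_radius = NULL, connectivity = 6) {
  tc <- directional_accessibility(map, "trans_to_cis", theta = theta,
                                  seed_center = seed_center,
                                  seed_radius = seed_radius,
                                  connectivity = connectivity)
  ct <- directional_accessibility(map, "cis_to_trans", theta = theta,
                                  seed_center = seed_center,
                                  seed_radius = seed_radius,
                                  connectivity = connectivity)
  apply_mask(map, intersect_masks(tc, ct))
}

#' @export
print.accessibility_mask <- function(x, ...) {
  cat(sprintf("accessibility_mask [%s]: %d / %d cells open (theta = %g)\n",
              x$direction, sum(x$mask), length(x$mask), x$theta))
  invisible(x)
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("channel_map: %d accessible cells on %d x %d x %d grid\n",
              sum(x$mask), x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}
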