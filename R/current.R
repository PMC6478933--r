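#' Windowed displacement ionic current
#'
#' For each consecutive frame pair, the average current over the window
#' `[t, t + dt]` is `I(t) = 1 / (dt * Lz) * sum_i q_i * dz_i`, with `q_i`
#' the partial charge (elementary charges), `dz_i` the z displacement
#' (Angstrom) and `Lz` the box height.  Displacements are minimum-image
#' unwrapped by default (an atom crossing the periodic boundary would
#' otherwise contribute a spurious `~Lz` jump).  `Lz` is taken per window
#' from the first frame of the pair (NPT boxes fluctuate); currents are
#' returned in nA.
#'
#' @param traj a `"trajectory"` with charges in its metadata.
#' @param atoms atom indices to sum over; default: all electrolyte (water
#'   and ion) atoms.  An empty selection gives an all-zero trace.
#' @param unwrap logical, minimum-image unwrap z displacements.
#' @param species label stored on the trace (`"TOTAL"`, `"K"`, `"CL"`, ...).
#' @return object of class `"current_trace"`: data.frame with `t` (window
#'   start, ps) and `I` (nA); attributes `window` (ps), `species`, `Lz`.
#' @export
displacement_current <- function(traj, atoms = NULL, unwrap = TRUE,
                                 species = "TOTAL") {
  stopifnot(inherits(traj, "trajectory"))
  nf <- nrow(traj$xyz)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  if (is.null(atoms))
    atoms <- select_atoms(traj, c("WATER", "ION_K", "ION_CL"))
  dt <- traj$frame_interval
  t0 <- traj$times[-nf]
  if (length(atoms) == 0) {
    out <- data.frame(t = t0, I = 0)
  } else {
    q <- traj$atoms$charge[atoms]
    if (anyNA(q)) stop("missing charge for selected atoms", call. = FALSE)
    zc <- 3 * atoms  # z columns in bio3d xyz ordering
    z <- traj$xyz[, zc, drop = FALSE]
    dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
    Lz <- traj$box[-nf, 3]
    if (unwrap) dz <- dz - Lz * round(dz / Lz)
    I <- as.vector(dz %*% q) / (dt * Lz) * .E_PER_PS_NA
    out <- data.frame(t = t0, I = I)
  }
  attr(out, "window") <- dt
  attr(out, "species") <- species
  attr(out, "Lz") <- mean(traj$box[, 3])
  class(out) <- c("current_trace", "data.frame")
  out
}

#' Species-restricted displacement current
#'
#' Restricts the displacement-current sum to the atoms of one species
#' (e.g. the K+ or Cl- partial current).
#'
#' @inheritParams displacement_current
#' @param species one species name, e.g. `"ION_K"`.
#' @return a `"current_trace"` (zero trace when the species has no atoms).
#' @export
species_current <- function(traj, species, unwrap = TRUE) {
  species <- .check_species(species)
  stopifnot(length(species) == 1)
  idx <- which(traj$atoms$species == species)
  label <- switch(species, ION_K = "K", ION_CL = "CL", species)
  displacement_current(traj, atoms = idx, unwrap = unwrap, species = label)
}

#' Mean current with transient discard and block-averaged error
#'
#' Time-averages `I(t)` over windows starting at `t >= discard`.  Because
#' successive windows are autocorrelated, the standard error is estimated
#' by block averaging: the retained windows are grouped into blocks of
#' `block` ps and the SE is the SEM of the block means.  With fewer than
#' two full blocks the plain SEM of the windows is used instead (flagged
#' via the `"blocked_se"` attribute).
#'
#' @param trace a `"current_trace"`.
#' @param discard transient to discard, ps.
#' @param block block length for the error estimate, ps (default 8000,
#'   i.e. 8 ns).
#' @return list with `mean` (nA), `se` (nA), `n_windows`, `n_blocks`.
#' @export
mean_current <- function(trace, discard = 0, block = 8000) {
  stopifnot(inherits(trace, "current_trace"))
  keep <- trace$t >= discard
  if (!any(keep))
    stop("discard (", discard, " ps) >= trace duration", call. = FALSE)
  I <- trace$I[keep]
  n <- length(I)
  dt <- attr(trace, "window")
  per_block <- max(1L, floor(block / dt))
  nb <- floor(n / per_block)
  if (nb >= 2) {
    bm <- vapply(seq_len(nb), function(i)
      mean(I[((i - 1) * per_block + 1):(i * per_block)]), numeric(1))
    se <- stats::sd(bm) / sqrt(nb)
    blocked <- TRUE
  } else {
    se <- if (n > 1) stats::sd(I) / sqrt(n) else 0
    blocked <- FALSE
  }
  structure(list(mean = mean(I), se = se, n_windows = n, n_blocks = nb),
            blocked_se = blocked)
}

#' Relative current blockage
#'
#' `blockage = (I0 - I) / I0`, the relative drop of the mean ionic current
#' when an analyte occupies the pore.
#'
#' @param I_mean mean current with the analyte, nA (or the list returned
#'   by [mean_current()]).
#' @param I0_mean empty-pore mean current, nA.
#' @return object of class `"blockage_result"`: list with `I_mean`,
#'   `I0_mean`, `blockage`.
#' @export
blockage <- function(I_mean, I0_mean) {
  if (is.list(I_mean)) I_mean <- I_mean$mean
  if (is.list(I0_mean)) I0_mean <- I0_mean$mean
  .assert_scalar_num(I_mean, "I_mean")
  .assert_scalar_num(I0_mean, "I0_mean")
  if (I0_mean == 0)
    stop("degenerate reference: empty-pore current is zero", call. = FALSE)
  structure(list(I_mean = I_mean, I0_mean = I0_mean,
                 blockage = (I0_mean - I_mean) / I0_mean),
            class = "blockage_result")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace [%s]: %d windows of %g ps, mean %.4g nA\n",
              attr(x, "species"), nrow(x), attr(x, "window"), mean(x$I)))
  invisible(x)
}

#' @export
print.blockage_result <- function(x, ...) {
  cat(sprintf("current blockage: %.4f  (I = %.4g nA, I0 = %.4g nA)\n",
              x$blockage, x$I_mean, x$I0_mean))
  invisible(x)
}
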