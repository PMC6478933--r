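#' Available cross-section area profile A(z)
#'
#' Sums the filtered channel map over x and y on each z slice:
#' `A_z = sum_{x,y} Mtilde * dx * dy`.  Fractional (sub-bulk) occupancies
#' contribute fractionally.
#'
#' @param channel a `"channel_map"` (or a normalized `"occupancy_map"`,
#'   e.g. for an unfiltered profile).
#' @param z_range optional `c(z_lo, z_hi)` in Angstrom restricting the
#'   slices (slice centers within the closed interval).
#' @return object of class `"area_profile"`: data.frame with `slice`
#'   (grid slice index), `z` (slice center, Angstrom), `A` (Angstrom^2),
#'   plus attributes `dz` and `grid`.
#' @export
area_profile <- function(channel, z_range = NULL) {
  stopifnot(inherits(channel, c("channel_map", "occupancy_map")))
  g <- channel$grid
  A <- apply(channel$values, 3, sum) * g$cell[1] * g$cell[2]
  z <- grid_z_centers(g)
  keep <- seq_along(z)
  if (!is.null(z_range)) {
    stopifnot(length(z_range) == 2)
    keep <- which(z >= z_range[1] & z <= z_range[2])
    if (!length(keep))
      stop("empty z_range: no slice centers in [",
           z_range[1], ", ", z_range[2], "]", call. = FALSE)
  }
  out <- data.frame(slice = keep, z = z[keep], A = A[keep])
  attr(out, "dz") <- g$cell[3]
  attr(out, "grid") <- g
  class(out) <- c("area_profile", "data.frame")
  out
}

#' Quasi-1D pore resistance
#'
#' Discretizes `R = integral rho(z) / A(z) dz` over the slices of an area
#' profile with constant electrolyte resistivity:
#' `R = sum_i rho * dz / A_i`.  Access resistances are neglected.  A fully
#' blocked slice (`A = 0`) gives `+Inf`, flagged via the `"blocked"`
#' attribute.
#'
#' @param profile an [area_profile()].
#' @param rho electrolyte resistivity (arbitrary units; default 1 - the
#'   clogging estimator is rho-independent, absolute resistances are only
#'   meaningful if a measured resistivity is supplied).
#' @param z_range optional `c(z_lo, z_hi)` summation window (Angstrom);
#'   must be covered by the profile.
#' @return resistance (units `rho * Angstrom^-1`), with attribute
#'   `"blocked"`.
#' @export
quasi1d_resistance <- function(profile, rho = 1, z_range = NULL) {
  stopifnot(inherits(profile, "area_profile"))
  .assert_scalar_num(rho, "rho", positive = TRUE)
  dz <- attr(profile, "dz")
  A <- profile$A
  if (!is.null(z_range)) {
    stopifnot(length(z_range) == 2, z_range[1] < z_range[2])
    if (z_range[1] < min(profile$z) - dz / 2 ||
        z_range[2] > max(profile$z) + dz / 2)
      stop("profile does not cover z_range", call. = FALSE)
    A <- A[profile$z >= z_range[1] & profile$z <= z_range[2]]
    if (!length(A)) stop("empty z_range", call. = FALSE)
  }
  blocked <- any(A == 0)
  R <- if (blocked) Inf else sum(rho * dz / A)
  structure(R, blocked = blocked)
}

#' Pore-clogging estimator
#'
#' `b = 1 - R0 / R`, with `R` the quasi-1D resistance of the clogged pore
#' and `R0` that of the empty pore.  A blocked pore (`R = +Inf`) gives
#' `b = 1`; `R < R0` yields `b < 0`, which is permitted but flagged as
#' anomalous.
#'
#' @param R_clogged,R_empty resistances from [quasi1d_resistance()].
#' @return object of class `"clogging_result"`: list with `R_tilde`,
#'   `R0_tilde`, `b`.
#' @export
clogging_estimator <- function(R_clogged, R_empty) {
  R_clogged <- as.numeric(R_clogged); R_empty <- as.numeric(R_empty)
  if (!(R_clogged > 0) || !(R_empty > 0))
    stop("resistances must be > 0", call. = FALSE)
  if (!is.finite(R_empty))
    stop("empty-pore resistance must be finite", call. = FALSE)
  b <- if (is.infinite(R_clogged)) 1 else 1 - R_empty / R_clogged
  if (b < 0)
    warning(sprintf(
      "anomalous clogging b = %.4g < 0 (clogged pore less resistive than empty)",
      b))
  structure(list(R_tilde = R_clogged, R0_tilde = R_empty, b = b),
            class = "clogging_result")
}

#' Clogging from two area profiles
#'
#' Convenience wrapper computing both resistances on a common window and
#' the estimator.
#'
#' @param profile_clogged,profile_empty [area_profile()]s.
#' @inheritParams quasi1d_resistance
#' @return a `"clogging_result"`.
#' @export
pore_clogging <- function(profile_clogged, profile_empty, rho = 1,
                          z_range = NULL) {
  clogging_estimator(quasi1d_resistance(profile_clogged, rho, z_range),
                     quasi1d_resistance(profile_empty, rho, z_range))
}

#' Clogging of a trans-truncated pore
#'
#' Recomputes both resistances with the summation starting `z_cut_offset`
#' Angstrom above the trans entrance, emulating a pore whose barrel is cut
#' on the trans side (removing, in alpha-Hemolysin, the secondary barrel
#' constriction about 20 A from the native trans entrance).
#'
#' @inheritParams pore_clogging
#' @param z_cut_offset height of the cut above the trans entrance,
#'   Angstrom (default 20).
#' @param z_range full summation window before the cut; defaults to the
#'   profile extent.
#' @return a `"clogging_result"`.
#' @export
truncated_clogging <- function(profile_clogged, profile_empty, rho = 1,
                               z_cut_offset = 20, z_range = NULL) {
  stopifnot(inherits(profile_clogged, "area_profile"))
  dz <- attr(profile_clogged, "dz")
  if (is.null(z_range))
    z_range <- range(profile_clogged$z) + c(-dz / 2, dz / 2)
  if (z_cut_offset < 0) stop("z_cut_offset must be >= 0", call. = FALSE)
  if (z_range[1] + z_cut_offset >= z_range[2])
    stop("cut offset reaches past the pore: z_lo + offset must be < z_hi",
         call. = FALSE)
  cut_range <- c(z_range[1] + z_cut_offset, z_range[2])
  pore_clogging(profile_clogged, profile_empty, rho, cut_range)
}

#' @export
print.clogging_result <- function(x, ...) {
  cat(sprintf("pore clogging: b = %.4f  (R = %.4g, R0 = %.4g)\n",
              x$b, x$R_tilde, x$R0_tilde))
  invisible(x)
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("area_profile: %d slices, z in [%.1f, %.1f] A, dz = %g A\n",
              nrow(x), min(x$z), max(x$z), attr(x, "dz")))
  cat(sprintf("  A: min %.2f, median %.2f, max %.2f A^2\n",
              min(x$A), stats::median(x$A), max(x$A)))
  invisible(x)
}
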