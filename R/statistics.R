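.pkg_cache <- new.env(parent = emptyenv())

#' Amino-acid physicochemical property table
#'
#' All 20 standard residues with Van der Waals residue volume (A^3),
#' apparent (solution) residue volume (A^3), theoretical maximum solvent
#' accessible surface area (A^2) and hydrophobicity class
#' (`HYDROPHOBIC`, `POLAR`, `POSITIVE`, `NEGATIVE`).  Sources and caveats
#' are documented in the shipped data file
#' (`system.file("extdata", "aa_properties.tsv", package = "poreclog")`).
#'
#' @param positive_his class Histidine as `POSITIVE` instead of the
#'   default `POLAR` (class membership at physiological pH is debatable).
#' @return data.frame with one row per residue.
#' @export
aa_properties <- function(positive_his = FALSE) {
  if (is.null(.pkg_cache$aa)) {
    path <- system.file("extdata", "aa_properties.tsv",
                        package = "poreclog", mustWork = TRUE)
    .pkg_cache$aa <- utils::read.delim(path, comment.char = "#",
                                       stringsAsFactors = FALSE)
  }
  tab <- .pkg_cache$aa
  if (positive_his) tab$hclass[tab$code == "H"] <- "POSITIVE"
  tab
}

#' Look up one amino acid by one-letter code
#'
#' @param code one-letter amino-acid code (case-insensitive).
#' @inheritParams aa_properties
#' @return one-row data.frame (an `AminoAcidRecord`).
#' @examples
#' aa_lookup("A")$vdw_volume  # 88.6
#' @export
aa_lookup <- function(code, positive_his = FALSE) {
  stopifnot(is.character(code), length(code) == 1)
  tab <- aa_properties(positive_his)
  hit <- tab[tab$code == toupper(code), , drop = FALSE]
  if (nrow(hit) != 1)
    stop("unknown amino-acid code: '", code, "'", call. = FALSE)
  hit
}

#' Replica mean and standard error
#'
#' Treats independent replicas as independent measurements:
#' `sem = sd / sqrt(n)`.  A single replica gives `sem = 0`, flagged via
#' the `single_replica` field.
#'
#' @param values per-replica scalars (e.g. b or blockage values).
#' @param label optional label (e.g. the homopeptide id).
#' @return object of class `"replica_set"`: list with `label`, `values`,
#'   `mean`, `sem`, `n`, `single_replica`.
#' @export
replica_stats <- function(values, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values))
    stop("need at least one finite replica value", call. = FALSE)
  n <- length(values)
  sem <- if (n == 1) 0 else stats::sd(values) / sqrt(n)
  structure(list(label = label, values = values, mean = mean(values),
                 sem = sem, n = n, single_replica = n == 1),
            class = "replica_set")
}

#' Pearson correlation and least-squares line
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return object of class `"correlation_result"`: list with `r`, `slope`,
#'   `intercept`, `n`.
#' @export
pearson_and_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: constant x or y", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(r = stats::cor(x, y),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x)),
            class = "correlation_result")
}

#' Contrast clogging between hydrophobicity classes
#'
#' Per-class means plus a Welch two-sample t test between two chosen
#' classes (default hydrophobic vs polar).  Classes with fewer than two
#' members are excluded with a warning.
#'
#' @param values named numeric vector of per-residue scalars (e.g. b), or
#'   unnamed with `classes` given.
#' @param classes class label per value; default: looked up from the
#'   one-letter names of `values`.
#' @param compare length-2 character, the classes to test.
#' @inheritParams aa_properties
#' @return list with `class_means` (named), `difference`
#'   (`compare[1] - compare[2]`), `statistic`, `p_value`, `compare`.
#' @export
class_contrast <- function(values, classes = NULL,
                           compare = c("HYDROPHOBIC", "POLAR"),
                           positive_his = FALSE) {
  values <- unlist(values)
  if (is.null(classes)) {
    if (is.null(names(values)))
      stop("give 'classes' or name 'values' by one-letter code",
           call. = FALSE)
    tab <- aa_properties(positive_his)
    classes <- tab$hclass[match(toupper(names(values)), tab$code)]
    if (anyNA(classes)) stop("unknown residue codes in names(values)",
                             call. = FALSE)
  }
  stopifnot(length(classes) == length(values), length(compare) == 2)
  counts <- table(classes)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding class(es) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !classes %in% small
    values <- values[keep]; classes <- classes[keep]
  }
  if (!all(compare %in% classes))
    stop("need >= 2 members in both compared classes", call. = FALSE)
  means <- tapply(values, classes, mean)
  tt <- stats::t.test(values[classes == compare[1]],
                      values[classes == compare[2]])
  list(class_means = means,
       difference = unname(means[compare[1]] - means[compare[2]]),
       statistic = unname(tt$statistic), p_value = tt$p.value,
       compare = compare)
}

#' Time-averaged ion / water ratio inside the pore
#'
#' Counts K+ and Cl- ions and water molecules (by their oxygen / bead
#' atom) inside a z interval, optionally restricted to a lateral disk
#' around the pore axis, and returns the ratio of the time-averaged
#' counts.
#'
#' @param traj a `"trajectory"`.
#' @param z_range `c(z_lo, z_hi)`, Angstrom ("narrow pore region").
#' @param radial optional lateral radius (Angstrom) about `center`.
#' @param center lateral pore-axis position `c(x, y)`, default `(0, 0)`.
#' @return list with `ratio`, `mean_ions`, `mean_waters`.
#' @export
ion_water_ratio <- function(traj, z_range, radial = NULL,
                            center = c(0, 0)) {
  stopifnot(inherits(traj, "trajectory"), length(z_range) == 2,
            z_range[1] < z_range[2])
  zmax <- max(traj$box[, 3])
  zmin <- min(0, min(traj$xyz[, seq(3, ncol(traj$xyz), by = 3)]))
  if (z_range[2] < zmin || z_range[1] > zmax)
    stop("pore region does not intersect the simulation box",
         call. = FALSE)
  ions <- select_atoms(traj, c("ION_K", "ION_CL"))
  waters <- select_atoms(traj, "WATER")
  count_in <- function(idx, f) {
    if (!length(idx)) return(0)
    xyz <- frame_coords(traj, f)[idx, , drop = FALSE]
    inz <- xyz[, 3] >= z_range[1] & xyz[, 3] <= z_range[2]
    if (!is.null(radial))
      inz <- inz & (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 <=
        radial^2
    sum(inz)
  }
  nf <- nrow(traj$xyz)
  ni <- mean(vapply(seq_len(nf), function(f) count_in(ions, f), numeric(1)))
  nw <- mean(vapply(seq_len(nf), function(f) count_in(waters, f),
                    numeric(1)))
  if (nw == 0)
    stop("degenerate ratio: no water molecules in the region in any frame",
         call. = FALSE)
  list(ratio = ni / nw, mean_ions = ni, mean_waters = nw)
}

#' Radius of gyration time series and relaxation estimate
#'
#' Mass-weighted radius of gyration per frame, plus a simple relaxation
#' estimate: the first time at which the series enters and stays within a
#' relative band (default +/-5%) of its tail mean (tail: last quarter of
#' the series).  Used to check that a pulled peptide has relaxed before
#' production statistics are accumulated.
#'
#' @param traj a `"trajectory"`.
#' @param atoms peptide atom indices (>= 2 atoms; a single atom gives the
#'   degenerate `Rg = 0`).
#' @param band relative band half-width.
#' @param tail_frac fraction of the series defining the tail mean.
#' @return list with `times` (ps), `rg` (Angstrom), `relaxation_time`
#'   (ps), `tail_mean`.
#' @export
radius_of_gyration <- function(traj, atoms, band = 0.05,
                               tail_frac = 0.25) {
  stopifnot(inherits(traj, "trajectory"), length(atoms) >= 1)
  m <- traj$atoms$mass[atoms]
  nf <- nrow(traj$xyz)
  rg <- vapply(seq_len(nf), function(f) {
    xyz <- frame_coords(traj, f)[atoms, , drop = FALSE]
    com <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  }, numeric(1))
  tail_n <- max(1L, ceiling(tail_frac * nf))
  tail_mean <- mean(rg[(nf - tail_n + 1):nf])
  inband <- abs(rg - tail_mean) <= band * abs(tail_mean)
  stays <- rev(cumprod(rev(inband))) > 0  # TRUE where all later points in band
  relax <- if (any(stays)) traj$times[which(stays)[1]] else NA_real_
  list(times = traj$times, rg = rg, relaxation_time = relax,
       tail_mean = tail_mean)
}

#' Displacement of a constant-velocity steered-MD pull
#'
#' `delta = v * t`, with the pulling speed in Angstrom/ps and the duration
#' in ns (so e.g. 0.025 A/ps for 17 ns moves the pulled atom 425 A).
#'
#' @param v_smd pulling speed, Angstrom/ps.
#' @param t_smd pulling time, ns.
#' @return displacement, Angstrom.
#' @export
smd_displacement <- function(v_smd, t_smd) {
  .assert_scalar_num(v_smd, "v_smd", positive = TRUE)
  .assert_scalar_num(t_smd, "t_smd", positive = TRUE)
  v_smd * t_smd * 1000  # ns -> ps
}

#' @export
print.replica_set <- function(x, ...) {
  cat(sprintf("replica_set%s: mean %.4g +/- %.4g (n = %d%s)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$mean, x$sem, x$n,
              if (x$single_replica) ", single replica" else ""))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation: r = %.3f, fit y = %.4g x + %.4g (n = %d)\n",
              x$r, x$slope, x$intercept, x$n))
  invisible(x)
}
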