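#' Parameterized synthetic pore geometry
#'
#' Describes a model pore on the z axis from `z = 0` to `z = length`: a
#' straight cylinder, an hourglass (linear taper end - waist - end,
#' mimicking a vestibule/constriction profile), or a cylinder with a
#' lateral pocket cavity whose only connection to the channel is a thin
#' neck at the pocket top - a reentrant pocket "directed towards the trans
#' side" that carries no trans-membrane current and should be removed by
#' the accessibility filter.
#'
#' @param shape `"cylinder"`, `"hourglass"`, `"pocketed"`.
#' @param radius channel radius (cylinder/pocketed), Angstrom.
#' @param length pore length, Angstrom.
#' @param radius_end,radius_waist hourglass end and waist radii.
#' @param wall_sphere_radius radius of the frozen wall spheres.
#' @param pocket pocket specification for `"pocketed"`: list with `x`,
#'   `y`, `z` extents (each `c(lo, hi)`, Angstrom) of the cavity and a
#'   `neck` list (same fields) joining cavity and channel.  A default
#'   pocket is supplied.
#' @return object of class `"pore_geometry"`.
#' @export
pore_geometry <- function(shape = c("cylinder", "hourglass", "pocketed"),
                          radius = 5, length = 50, radius_end = 8,
                          radius_waist = 3, wall_sphere_radius = 1.5,
                          pocket = NULL) {
  shape <- match.arg(shape)
  .assert_scalar_num(length, "length", positive = TRUE)
  .assert_scalar_num(wall_sphere_radius, "wall_sphere_radius",
                     positive = TRUE)
  if (shape == "pocketed" && is.null(pocket))
    pocket <- list(x = c(radius + 1, radius + 6), y = c(-2.5, 2.5),
                   z = c(0.3 * length, 0.6 * length),
                   neck = list(x = c(0, radius + 1), y = c(-1.6, 1.6),
                               z = c(0.6 * length - 4, 0.6 * length)))
  g <- structure(list(shape = shape, radius = radius, length = length,
                      radius_end = radius_end, radius_waist = radius_waist,
                      wall_sphere_radius = wall_sphere_radius,
                      pocket = pocket),
                 class = "pore_geometry")
  if (any(radius_profile(g, seq(0, length, by = 1)) <= wall_sphere_radius))
    stop("degenerate geometry: channel radius must exceed the wall sphere radius",
         call. = FALSE)
  g
}

#' Channel radius profile r(z) of a synthetic geometry
#' @param geometry a [pore_geometry()].
#' @param z z coordinates, Angstrom.
#' @return channel radius at each z, Angstrom.
#' @export
radius_profile <- function(geometry, z) {
  L <- geometry$length
  switch(geometry$shape,
         cylinder = ,
         pocketed = rep(geometry$radius, length(z)),
         hourglass = {
           re <- geometry$radius_end; rw <- geometry$radius_waist
           re - (re - rw) * (1 - abs(2 * z / L - 1))
         })
}

#' Build a synthetic pore: frozen wall atoms + analytic area profile
#'
#' Wall spheres (species `PORE`) tile the channel surface on rings spaced
#' `0.8 * wall_sphere_radius` apart (no leaks), with their inner surface
#' tangent to the channel radius `r(z)`.  The exact analytic available
#' area `A(z) = pi r(z)^2` is attached for validation; for a pocketed
#' geometry the analytic profile equals the plain cylinder one, since the
#' pocket is excluded from the through-channel by definition.
#'
#' @param geometry a [pore_geometry()].
#' @return object of class `"synthetic_pore"`: list with `geometry`,
#'   `atoms` (data.frame name/residue/x/y/z/radius), `obstruction`
#'   (NULL), and function `analytic_area(z)`.
#' @export
make_pore <- function(geometry) {
  stopifnot(inherits(geometry, "pore_geometry"))
  rw <- geometry$wall_sphere_radius
  dz <- 0.8 * rw
  zs <- seq(0, geometry$length, by = dz)
  rings <- lapply(zs, function(z) {
    rc <- radius_profile(geometry, z) + rw  # centers; inner surface at r(z)
    n <- max(8L, ceiling(2 * pi * rc / dz))
    phi <- 2 * pi * (seq_len(n) - 1) / n
    cbind(rc * cos(phi), rc * sin(phi), z)
  })
  xyz <- do.call(rbind, rings)
  atoms <- data.frame(name = "WAL", residue = "WAL",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = rw, stringsAsFactors = FALSE)
  pore <- structure(list(geometry = geometry, atoms = atoms,
                         obstruction = NULL),
                    class = "synthetic_pore")
  pore
}

#' Analytic available-area profile of a synthetic pore
#'
#' `pi r(z)^2`, reduced to the annulus `pi (r(z)^2 - r_bead^2)` on slices
#' spanned by a concentric bead-chain obstruction.
#'
#' @param pore a `"synthetic_pore"`.
#' @param z z coordinates, Angstrom.
#' @return areas, Angstrom^2.
#' @export
analytic_area <- function(pore, z) {
  A <- pi * radius_profile(pore$geometry, z)^2
  ob <- pore$obstruction
  if (!is.null(ob) && ob$radius > 0) {
    on_chain <- z >= ob$z_range[1] & z <= ob$z_range[2]
    A[on_chain] <- pmax(A[on_chain] - pi * ob$radius^2, 0)
  }
  A
}

#' Insert a concentric bead-chain obstruction
#'
#' Adds a frozen chain of beads (species `PEPTIDE`) along the pore axis,
#' emulating a homopeptide threaded through the pore.  Beads are spaced at
#' most one bead radius apart, so the chain acts as a solid rod of the
#' bead radius; the analytic available area on chain slices becomes the
#' annulus `pi (r(z)^2 - r_bead^2)`.
#'
#' @param pore a `"synthetic_pore"`.
#' @param bead_radius bead radius, Angstrom (0 = no obstruction).
#' @param z_range axial extent `c(z_lo, z_hi)` of the chain; default: the
#'   whole pore.
#' @return the pore with beads added and `obstruction` set.  A bead radius
#'   at or above the local channel radius triggers a fully-blocked
#'   warning (the geometry is still valid, for `b = 1` tests).
#' @export
insert_obstruction <- function(pore, bead_radius, z_range = NULL) {
  stopifnot(inherits(pore, "synthetic_pore"))
  if (bead_radius < 0) stop("bead_radius must be >= 0", call. = FALSE)
  if (bead_radius == 0) return(pore)
  if (is.null(z_range)) z_range <- c(0, pore$geometry$length)
  zs <- seq(z_range[1], z_range[2], by = bead_radius)
  rmin <- min(radius_profile(pore$geometry, zs))
  if (bead_radius >= rmin)
    warning("bead radius >= channel radius: pore fully blocked on the chain slices")
  beads <- data.frame(name = "BED", residue = "BED",
                      x = 0, y = 0, z = zs, radius = bead_radius,
                      stringsAsFactors = FALSE)
  pore$atoms <- rbind(pore$atoms, beads)
  pore$obstruction <- list(radius = bead_radius, z_range = z_range,
                           n_beads = length(zs))
  pore
}

#' Electrolyte specification for synthetic trajectories
#'
#' @param n_water,n_k,n_cl particle counts (water is a single-bead solvent
#'   particle counted by its oxygen-like bead).  With `"lattice"`
#'   placement, `Inf` means "fill every lattice site", the dense-fill
#'   geometry fixture.
#' @param drift per-species axial drift, Angstrom/ps: named vector with
#'   any of `WATER`, `ION_K`, `ION_CL`.
#' @param diffusion diffusion coefficient, Angstrom^2/ps (Brownian step
#'   s.d. `sqrt(2 D dt)` per coordinate).
#' @param seed integer seed; a fixed seed makes the trajectory
#'   deterministic.
#' @param placement `"random"` (uniform in the fluid volume, Brownian
#'   dynamics) or `"lattice"` (deterministic dense lattice fill, for
#'   geometry fixtures with analytic ground truth).
#' @param lattice_spacing lattice constant for `"lattice"` placement,
#'   Angstrom.  The default 0.5 A keeps the scalloping of the sphere-union
#'   surface below 0.03 A (sagitta `r - sqrt(r^2 - (s/2)^2)` for the 1.4 A
#'   water bead), so the covered volume faithfully tiles the fluid region.
#' @return list of class `"electrolyte_spec"`.
#' @export
electrolyte_spec <- function(n_water = 100, n_k = 0, n_cl = 0,
                             drift = c(WATER = 0, ION_K = 0, ION_CL = 0),
                             diffusion = 0, seed = 1,
                             placement = c("random", "lattice"),
                             lattice_spacing = 0.5) {
  placement <- match.arg(placement)
  stopifnot(n_water >= 0, n_k >= 0, n_cl >= 0, diffusion >= 0)
  dr <- c(WATER = 0, ION_K = 0, ION_CL = 0)
  dr[names(drift)] <- drift
  structure(list(n_water = n_water, n_k = n_k, n_cl = n_cl, drift = dr,
                 diffusion = diffusion, seed = as.integer(seed),
                 placement = placement,
                 lattice_spacing = lattice_spacing),
            class = "electrolyte_spec")
}

# species radii/charges used by the generator (match synthetic_species.yaml)
.SYN <- list(radius = c(WATER = 1.4, ION_K = 1.5, ION_CL = 1.8),
             charge = c(WATER = 0, ION_K = 1, ION_CL = -1),
             name = c(WATER = "OW", ION_K = "K", ION_CL = "CL"),
             residue = c(WATER = "HOH", ION_K = "POT", ION_CL = "CLA"))

# is each point a valid center for a mobile particle of radius 'margin'?
.inside_fluid <- function(pore, pts, margin) {
  g <- pore$geometry
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  z <- pts[, 3] %% g$length
  ok <- rho <= radius_profile(g, z) - margin
  ob <- pore$obstruction
  if (!is.null(ob) && ob$radius > 0)
    ok <- ok & !(z >= ob$z_range[1] & z <= ob$z_range[2] &
                   rho < ob$radius + margin)
  pk <- g$pocket
  if (!is.null(pk)) {
    zpts <- cbind(pts[, 1], pts[, 2], z)
    ok <- ok | .inside_box(zpts, pk, margin) |
      .inside_box(zpts, pk$neck, margin, shrink_lo_x = FALSE)
  }
  ok
}

# boundary-conforming dense fill: per z layer, concentric rings whose
# outermost radius is exactly r(z) - margin (and innermost exactly the
# obstruction boundary), so the union of particle spheres reproduces the
# analytic channel surface up to sub-spacing scalloping
.lattice_points <- function(pore, margin, spacing) {
  g <- pore$geometry
  zs <- seq(spacing / 2, g$length - 1e-9, by = spacing)
  ob <- pore$obstruction
  layers <- lapply(zs, function(z) {
    r_out <- radius_profile(g, z) - margin
    if (r_out <= 0) return(NULL)
    r_in <- 0
    if (!is.null(ob) && ob$radius > 0 &&
        z >= ob$z_range[1] && z <= ob$z_range[2])
      r_in <- ob$radius + margin
    if (r_out < r_in) return(NULL)  # fully blocked layer
    radii <- seq(r_out, r_in, by = -spacing)
    if (r_in > 0 && min(radii) > r_in + 1e-9) radii <- c(radii, r_in)
    if (r_in == 0 && min(radii) > spacing / 2) radii <- c(radii, 0)
    pts <- do.call(rbind, lapply(radii, function(rr) {
      if (rr < 1e-9) return(cbind(0, 0))
      n <- max(6L, ceiling(2 * pi * rr / spacing))
      phi <- 2 * pi * (seq_len(n) - 1) / n
      cbind(rr * cos(phi), rr * sin(phi))
    }))
    cbind(pts, z)
  })
  pts <- do.call(rbind, c(layers, list(matrix(numeric(0), 0, 3))))
  pk <- g$pocket
  if (!is.null(pk)) {
    ext <- .pore_extent(pore)
    nmax <- ceiling(ext$rmax / spacing)
    xs <- spacing * seq(-nmax, nmax)
    box_pts <- as.matrix(expand.grid(x = xs, y = xs, z = zs))
    inpk <- .inside_box(box_pts, pk, margin) |
      .inside_box(box_pts, pk$neck, margin, shrink_lo_x = FALSE)
    pts <- rbind(pts, box_pts[inpk, , drop = FALSE])
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

.inside_box <- function(pts, b, margin, shrink_lo_x = TRUE) {
  (pts[, 1] >= b$x[1] + if (shrink_lo_x) margin else 0) &
    pts[, 1] <= b$x[2] - margin &
    pts[, 2] >= b$y[1] + margin & pts[, 2] <= b$y[2] - margin &
    pts[, 3] >= b$z[1] + margin & pts[, 3] <= b$z[2] - margin
}

.pore_extent <- function(pore) {
  g <- pore$geometry
  rmax <- max(radius_profile(g, seq(0, g$length, by = 1))) +
    g$wall_sphere_radius
  if (!is.null(g$pocket)) rmax <- max(rmax, abs(unlist(g$pocket[c("x", "y")])))
  list(rmax = rmax + 1, Lz = g$length)
}

#' Generate a synthetic electrolyte trajectory through a pore
#'
#' Mobile particles (species `WATER`, `ION_K`, `ION_CL`) move by Brownian
#' steps `drift * dt + N(0, sqrt(2 D dt))`, with reflecting walls at the
#' channel radius profile (a rejected step keeps the previous position)
#' and periodic wrap in z.  Wall and bead atoms are frozen.  With
#' `placement = "lattice"` and zero drift/diffusion the frames are a
#' deterministic dense fill of the fluid volume, giving analytic ground
#' truth for the geometry pipeline.  The expected displacement current of
#' a drift-only trajectory, `sum_i q_i v_i / Lz`, is returned as ground
#' truth.
#'
#' @param pore a `"synthetic_pore"` (see [make_pore()],
#'   [insert_obstruction()]).
#' @param spec an [electrolyte_spec()].
#' @param n_frames number of saved frames.
#' @param frame_interval time between frames, ps.
#' @param dir optional directory: when given, writes `topology.pdb`,
#'   `trajectory.dcd` and `ground_truth.json` there.
#' @return list with `trajectory` (a `"trajectory"`), `ground_truth`
#'   (list: analytic area profile closure, expected current in nA, seed,
#'   box) and `files` (paths or NULL).
#' @export
make_trajectory <- function(pore, spec, n_frames = 2, frame_interval = 40,
                            dir = NULL) {
  stopifnot(inherits(pore, "synthetic_pore"),
            inherits(spec, "electrolyte_spec"))
  ext <- .pore_extent(pore)
  Lbox <- c(2 * ext$rmax, 2 * ext$rmax, ext$Lz)
  counts <- c(WATER = spec$n_water, ION_K = spec$n_k, ION_CL = spec$n_cl)
  if (any(is.infinite(counts)) && spec$placement != "lattice")
    stop("infinite particle counts are only meaningful for lattice placement",
         call. = FALSE)
  species <- rep(names(counts), ifelse(is.finite(counts), counts, 0))

  place <- .with_seed(spec$seed, {
    if (spec$placement == "lattice") {
      sps <- names(counts)[counts > 0]
      pts_by_sp <- lapply(sps, function(sp) {
        pts <- .lattice_points(pore, .SYN$radius[[sp]], spec$lattice_spacing)
        n_want <- counts[[sp]]
        if (is.infinite(n_want)) return(pts)  # dense fill: every site
        if (n_want > nrow(pts))
          stop("placement error: lattice has only ", nrow(pts),
               " sites for ", n_want, " ", sp, " particles", call. = FALSE)
        pts[seq_len(n_want), , drop = FALSE]
      })
      species <- rep(sps, vapply(pts_by_sp, nrow, integer(1)))
      do.call(rbind, pts_by_sp)
    } else {
      out <- matrix(NA_real_, length(species), 3)
      rads <- .SYN$radius[species]
      for (i in seq_along(species)) {
        m <- rads[i]
        placed <- FALSE
        for (try in 1:500) {
          p <- c(stats::runif(2, -ext$rmax, ext$rmax),
                 stats::runif(1, 0, ext$Lz))
          if (!.inside_fluid(pore, matrix(p, 1), m)) next
          if (i > 1) {  # soft excluded volume at placement time only
            prev <- out[seq_len(i - 1), , drop = FALSE]
            d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 +
              (prev[, 3] - p[3])^2
            if (any(d2 < (0.9 * (rads[seq_len(i - 1)] + m) / 2)^2)) next
          }
          out[i, ] <- p; placed <- TRUE; break
        }
        if (!placed)
          stop("placement error: could not place particle ", i,
               " after bounded retries (channel overfilled?)",
               call. = FALSE)
      }
      out
    }
  })
  species <- species[seq_len(nrow(place))]

  n_mob <- nrow(place)
  n_fix <- nrow(pore$atoms)
  margin <- .SYN$radius[species]
  vdrift <- spec$drift[species]
  sigma <- sqrt(2 * spec$diffusion * frame_interval)

  frames <- .with_seed(spec$seed + 1L, {
    fr <- vector("list", n_frames)
    cur <- place
    for (f in seq_len(n_frames)) {
      fr[[f]] <- cur
      if (f == n_frames) break
      prop <- cur
      prop[, 3] <- prop[, 3] + vdrift * frame_interval
      if (sigma > 0)
        prop <- prop + matrix(stats::rnorm(3 * n_mob, 0, sigma), n_mob, 3)
      prop[, 3] <- prop[, 3] %% ext$Lz
      ok <- .inside_fluid(pore, prop, margin)
      if (sigma > 0 && any(!ok)) {
        for (retry in 1:20) {
          bad <- which(!ok)
          if (!length(bad)) break
          p2 <- cur[bad, , drop = FALSE]
          p2[, 3] <- p2[, 3] + vdrift[bad] * frame_interval
          p2 <- p2 + matrix(stats::rnorm(3 * length(bad), 0, sigma),
                            length(bad), 3)
          p2[, 3] <- p2[, 3] %% ext$Lz
          ok2 <- .inside_fluid(pore, p2, margin[bad])
          prop[bad[ok2], ] <- p2[ok2, , drop = FALSE]
          ok[bad[ok2]] <- TRUE
        }
      }
      prop[!ok, ] <- cur[!ok, , drop = FALSE]  # sticky reflection
      cur <- prop
    }
    fr
  })

  # assemble trajectory: frozen pore/bead atoms first, then mobiles
  fix_xyz <- as.matrix(pore$atoms[, c("x", "y", "z")])
  xyz <- t(vapply(frames, function(fr)
    as.vector(t(rbind(fix_xyz, fr))), numeric(3 * (n_fix + n_mob))))
  if (n_frames == 1) xyz <- matrix(xyz, nrow = 1)
  name <- c(pore$atoms$name, .SYN$name[species])
  residue <- c(pore$atoms$residue, .SYN$residue[species])
  cfg <- synthetic_species_config()
  atoms <- atom_metadata(name, residue, cfg)
  box <- matrix(rep(Lbox, each = n_frames), ncol = 3)
  traj <- new_trajectory(atoms, xyz, box, frame_interval = frame_interval)

  q <- .SYN$charge[species]
  gt <- list(
    expected_current_nA =
      sum(q * spec$drift[species]) / Lbox[3] * .E_PER_PS_NA,
    seed = spec$seed, box = Lbox, n_mobile = n_mob,
    placement = spec$placement,
    obstruction = pore$obstruction)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(topology = file.path(dir, "topology.pdb"),
                  trajectory = file.path(dir, "trajectory.dcd"),
                  ground_truth = file.path(dir, "ground_truth.json"))
    bio3d::write.pdb(file = files$topology, xyz = xyz[1, ],
                     resno = seq_along(name), resid = residue,
                     elety = name)
    write_dcd(files$trajectory, xyz, box)
    gt_json <- gt
    gt_json$analytic_area <- data.frame(
      z = seq(0.5, pore$geometry$length - 0.5, by = 1),
      A = analytic_area(pore, seq(0.5, pore$geometry$length - 0.5, by = 1)))
    jsonlite::write_json(gt_json, files$ground_truth, auto_unbox = TRUE,
                         digits = NA)
  }
  list(trajectory = traj, ground_truth = gt, files = files, pore = pore)
}

#' Write a CHARMM-format DCD trajectory
#'
#' Binary DCD writer (Fortran record markers, CHARMM header version 24,
#' per-frame orthorhombic unit-cell block) compatible with common DCD
#' readers, including `bio3d::read.dcd`.
#'
#' @param path output file.
#' @param xyz `n_frames x 3N` coordinate matrix (bio3d ordering).
#' @param box `n_frames x 3` box lengths, Angstrom.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(path, xyz, box) {
  xyz <- as.matrix(xyz)
  box <- matrix(as.numeric(box), ncol = 3)
  nf <- nrow(xyz); natom <- ncol(xyz) / 3
  stopifnot(natom == as.integer(natom), nrow(box) == nf)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L   # unit-cell block present
  icntrl[20] <- 24L  # CHARMM version
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "synthetic trajectory written by poreclog")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(natom), con, size = 4), 4)
  ix <- seq(1, 3 * natom, by = 3)
  for (f in seq_len(nf)) {
    cell <- c(box[f, 1], 0, box[f, 2], 0, 0, box[f, 3])
    rec(function() writeBin(cell, con, size = 8), 48)
    for (k in 0:2)
      rec(function() writeBin(xyz[f, ix + k], con, size = 4), 4 * natom)
  }
  invisible(path)
}
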