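#' Write / read a grid map as OpenDX-style text
#'
#' Portable text serialization of occupancy maps, channel maps and masks
#' (grid metadata plus values, z varying fastest, DX `gridpositions`
#' convention with the origin at the first cell center).
#'
#' @param map an `"occupancy_map"`, `"channel_map"` or
#'   `"accessibility_mask"`.
#' @param path output file.
#' @return `path` (write) / an `"occupancy_map"` (read; stage is taken
#'   from the header comment, masks come back as 0/1 maps).
#' @export
write_dx <- function(map, path) {
  g <- map$grid
  vals <- if (!is.null(map$values)) map$values else map$mask + 0
  stage <- map$stage %||% (map$direction %||% "CHANNEL")
  n <- g$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# poreclog grid map; stage %s", stage),
    sprintf("object 1 class gridpositions counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("origin %.8g %.8g %.8g",
            g$origin[1] + g$cell[1] / 2, g$origin[2] + g$cell[2] / 2,
            g$origin[3] + g$cell[3] / 2),
    sprintf("delta %.8g 0 0", g$cell[1]),
    sprintf("delta 0 %.8g 0", g$cell[2]),
    sprintf("delta 0 0 %.8g", g$cell[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  # DX order: x slowest, z fastest
  v <- as.vector(aperm(vals, c(3, 2, 1)))
  writeLines(paste(formatC(v, format = "g", digits = 9),
                   collapse = " "), con)
  invisible(path)
}

#' @rdname write_dx
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  stage <- sub(".*stage ", "", lines[grepl("^# poreclog", lines)][1])
  cnt <- as.integer(strsplit(sub(".*counts ", "",
                                 lines[grepl("gridpositions", lines)][1]),
                             " ")[[1]])
  orig <- as.numeric(strsplit(sub("^origin ", "",
                                  lines[grepl("^origin", lines)][1]),
                              " ")[[1]])
  deltas <- lines[grepl("^delta", lines)]
  cell <- vapply(1:3, function(i)
    as.numeric(strsplit(sub("^delta ", "", deltas[i]), " ")[[1]])[i],
    numeric(1))
  first <- which(grepl("data follows", lines)) + 1
  v <- as.numeric(unlist(strsplit(paste(lines[first:length(lines)],
                                        collapse = " "), "\\s+")))
  v <- v[!is.na(v)]
  vals <- aperm(array(v, dim = rev(cnt)), c(3, 2, 1))
  g <- grid_spec(orig - cell / 2, cnt, cell)
  if (is.na(stage) || !stage %in% c("BINARY_FRAME", "AVERAGED",
                                    "NORMALIZED"))
    stage <- "NORMALIZED"
  .new_map(g, vals, stage)
}

#' Read a pipeline configuration
#'
#' YAML with blocks: `paths` (topology/trajectory/output dir/species
#' config), `grid` (origin, dims, cell), `selection` (species set), `bulk`
#' (bulk region indices), `channel` (theta, connectivity, seed radius),
#' `conductance` (rho, z_range, z_cut_offset), `current` (discard_ps,
#' block_ps), `synth` (geometry + electrolyte for synthetic stages),
#' `frame_interval`, `seed`.  Missing blocks fall back to defaults.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

.stage_file <- function(out, stage, file) file.path(out, stage, file)

.write_manifest <- function(out, stage, inputs, config) {
  dir <- file.path(out, stage)
  files <- file.path(dir, setdiff(list.files(dir), "manifest.json"))
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("poreclog")),
              config = config,
              inputs = lapply(inputs, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))),
              outputs = lapply(files, function(f)
                list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream artifact '", basename(path),
         "': run stage '", stage, "' first", call. = FALSE)
  path
}

#' Run the analysis pipeline with on-disk artifacts
#'
#' Orchestrates the stages `synth` (generate a synthetic fixture),
#' `occupancy` (averaged + normalized map), `channel` (directional
#' filtering), `clog` (area profiles, resistances, clogging estimator) and
#' `current` (displacement current trace and mean).  Each stage writes its
#' artifact plus a `manifest.json` (input hashes, config echo, package
#' version) under `<output>/<stage>/`, and stages are re-runnable
#' independently; a missing upstream artifact raises an error naming the
#' stage to run first.  Deterministic stages are bit-reproducible for a
#' fixed config.
#'
#' @param config list from [read_pipeline_config()] (or built in code).
#' @param stages subset of `c("synth", "occupancy", "channel", "clog",
#'   "current")`, in pipeline order.
#' @return (invisibly) a list of per-stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "occupancy", "channel",
                                    "clog", "current")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$paths$output %||% stop("config$paths$output required",
                                       call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if ("synth" %in% stages) {
    dir.create(file.path(out, "synth"), showWarnings = FALSE)
    sy <- config$synth %||% list()
    geom <- do.call(pore_geometry, sy$geometry %||% list())
    pore <- make_pore(geom)
    if (!is.null(sy$obstruction))
      pore <- do.call(insert_obstruction, c(list(pore), sy$obstruction))
    es <- sy$electrolyte %||% list()
    if (identical(es$n_water, "all")) es$n_water <- Inf
    spec <- do.call(electrolyte_spec, es)
    mt <- make_trajectory(pore, spec,
                          n_frames = sy$n_frames %||% 2,
                          frame_interval = config$frame_interval %||% 40,
                          dir = file.path(out, "synth"))
    config$paths$topology <- mt$files$topology
    config$paths$trajectory <- mt$files$trajectory
    .write_manifest(out, "synth", character(), config)
    res$synth <- mt
  }

  load_traj <- function() {
    topo <- .need_artifact(config$paths$topology %||%
                             file.path(out, "synth", "topology.pdb"),
                           "synth")
    trj <- .need_artifact(config$paths$trajectory %||%
                            file.path(out, "synth", "trajectory.dcd"),
                          "synth")
    cfg <- if (!is.null(config$paths$species_config))
      read_species_config(config$paths$species_config)
    else synthetic_species_config()
    read_trajectory(topo, trj, cfg,
                    frame_interval = config$frame_interval %||% 40)
  }

  grid_from_config <- function() {
    gc <- config$grid %||% stop("config$grid required", call. = FALSE)
    grid_spec(unlist(gc$origin), unlist(gc$dims),
              unlist(gc$cell %||% c(1, 1, 1)))
  }

  if ("occupancy" %in% stages) {
    dir.create(file.path(out, "occupancy"), showWarnings = FALSE)
    traj <- load_traj()
    grid <- grid_from_config()
    sel <- unlist(config$selection %||%
                    list(c("WATER", "ION_K", "ION_CL")))
    bulk <- unlist(config$bulk %||% stop("config$bulk required",
                                         call. = FALSE))
    map <- occupancy_map(traj, select_atoms(traj, sel), grid,
                         bulk_region = bulk)
    write_dx(map, .stage_file(out, "occupancy", "occupancy.dx"))
    .write_manifest(out, "occupancy",
                    c(config$paths$topology, config$paths$trajectory),
                    config)
    res$occupancy <- map
  }

  if ("channel" %in% stages) {
    dir.create(file.path(out, "channel"), showWarnings = FALSE)
    src <- .need_artifact(.stage_file(out, "occupancy", "occupancy.dx"),
                          "occupancy")
    map <- read_dx(src)
    ch <- config$channel %||% list()
    cm <- accessible_channel(map, theta = ch$theta %||% 0,
                             seed_radius = ch$seed_radius,
                             connectivity = ch$connectivity %||% 6)
    write_dx(cm, .stage_file(out, "channel", "channel.dx"))
    .write_manifest(out, "channel", src, config)
    res$channel <- cm
  }

  if ("clog" %in% stages) {
    dir.create(file.path(out, "clog"), showWarnings = FALSE)
    src <- .need_artifact(.stage_file(out, "channel", "channel.dx"),
                          "channel")
    cm <- read_dx(src)
    cc <- config$conductance %||% list()
    prof <- area_profile(cm, z_range = unlist(cc$z_range))
    utils::write.table(
      data.frame(z = prof$z, A = prof$A, invA = 1 / prof$A),
      .stage_file(out, "clog", "area_profile.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    empty_dx <- cc$empty_channel %||% NULL
    result <- list(R = as.numeric(quasi1d_resistance(prof,
                                                     rho = cc$rho %||% 1)))
    if (!is.null(empty_dx)) {
      prof0 <- area_profile(read_dx(empty_dx),
                            z_range = unlist(cc$z_range))
      clog <- pore_clogging(prof, prof0, rho = cc$rho %||% 1)
      result <- c(result, list(R0 = clog$R0_tilde, b = clog$b))
      if (!is.null(cc$z_cut_offset)) {
        tr <- truncated_clogging(prof, prof0, rho = cc$rho %||% 1,
                                 z_cut_offset = cc$z_cut_offset)
        result$b_truncated <- tr$b
      }
    }
    jsonlite::write_json(result, .stage_file(out, "clog", "clogging.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_manifest(out, "clog", src, config)
    res$clog <- result
  }

  if ("current" %in% stages) {
    dir.create(file.path(out, "current"), showWarnings = FALSE)
    traj <- load_traj()
    cu <- config$current %||% list()
    tot <- displacement_current(traj)
    trK <- species_current(traj, "ION_K")
    trC <- species_current(traj, "ION_CL")
    utils::write.table(
      data.frame(t = tot$t, I_total = tot$I, I_K = trK$I, I_Cl = trC$I),
      .stage_file(out, "current", "current.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    mc <- mean_current(tot, discard = cu$discard_ps %||% 0,
                       block = cu$block_ps %||% 8000)
    jsonlite::write_json(mc, .stage_file(out, "current", "mean_current.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_manifest(out, "current",
                    c(config$paths$topology, config$paths$trajectory),
                    config)
    res$current <- mc
  }

  invisible(res)
}
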