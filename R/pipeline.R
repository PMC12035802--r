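#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Defaults encode
#' the reference conventions: 512-point raster grids, a 10 ns
#' map-averaging window and a 50 ns scalar-summary window at the end of
#' the trajectory, an APL colour-scale centre of 0.64 nm^2, and k = 3
#' release clusters.
#'
#' @param input path to a trajectory in the JSON dialect, or NULL to use
#'   `generator`.
#' @param generator list(kind, args): kind is one of `"flat_bilayer"`,
#'   `"bump_bilayer"`, `"descent"`; args are forwarded to the generator.
#' @param grid raster resolution (>= 16).
#' @param map_window_ns width of the map-averaging window (taken at the
#'   end of the trajectory).
#' @param summary_window_ns width of the scalar-summary window.
#' @param leaflet_cutoff,leaflet_mode see [assign_leaflets_trajectory()].
#' @param apl_color_center display convention recorded in the manifest.
#' @param release list(k, restarts) for [classify_release()].
#' @param seed seed used for generation and clustering.
#' @param selection list(lipid_resname, phosphorus_name) used to build the
#'   lipid selection when loading from file.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            generator = list(kind = "flat_bilayer",
                                             args = list()),
                            grid = 512, map_window_ns = 10,
                            summary_window_ns = 50,
                            leaflet_cutoff = 1.2,
                            leaflet_mode = "every",
                            apl_color_center = 0.64,
                            release = list(k = 3, restarts = 10),
                            seed = 1,
                            selection = list(lipid_resname = "LIP",
                                             phosphorus_name = "P")) {
  cfg <- list(input = input, generator = generator, grid = as.integer(grid),
              map_window_ns = map_window_ns,
              summary_window_ns = summary_window_ns,
              leaflet_cutoff = leaflet_cutoff,
              leaflet_mode = leaflet_mode,
              apl_color_center = apl_color_center, release = release,
              seed = as.integer(seed), selection = selection)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$grid < 16) stop("config error: grid must be >= 16")
  if (cfg$map_window_ns <= 0 || cfg$summary_window_ns <= 0)
    stop("config error: window widths must be positive")
  if (cfg$leaflet_cutoff <= 0)
    stop("config error: leaflet_cutoff must be positive")
  if (is.null(cfg$input) && is.null(cfg$generator))
    stop("config error: either input or generator must be given")
  invisible(TRUE)
}

#' Read a pipeline configuration from JSON
#'
#' Missing fields fall back to the [pipeline_config()] defaults.
#' @param path JSON file.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(pipeline_config)
  args <- list()
  for (nm in names(defaults)) if (nm %in% names(raw)) args[[nm]] <- raw[[nm]]
  do.call(pipeline_config, args)
}

#' Build a lipid selection from a topology
#'
#' Recognises lipids by residue name and locates, per lipid, the
#' phosphorus atom and the acyl-chain carbons/hydrogens by the naming
#' scheme `C<chain><k>` / `H<chain><k><h>` used by the generators.
#'
#' @param topology a [make_topology()].
#' @param lipid_resname residue name of lipids.
#' @param phosphorus_name atom name of the phosphorus bead.
#' @return a `lipid_selection` (see [make_flat_bilayer()]).
#' @export
build_lipid_selection <- function(topology, lipid_resname = "LIP",
                                  phosphorus_name = "P") {
  a <- topology$atoms
  lip_res <- unique(a$resid[a$resname == lipid_resname])
  if (length(lip_res) == 0)
    stop("no lipids with resname '", lipid_resname, "' found")
  lipids <- lapply(lip_res, function(r) {
    idx <- which(a$resid == r)
    p <- idx[a$name[idx] == phosphorus_name]
    if (length(p) != 1)
      stop("lipid residue ", r, " lacks a unique '", phosphorus_name,
           "' atom")
    chains <- list()
    for (ci in 1:2) {
      cn <- idx[grepl(sprintf("^C%d\\d+$", ci), a$name[idx])]
      ks <- as.integer(sub(sprintf("^C%d", ci), "", a$name[cn]))
      cn <- cn[order(ks)]
      hyd <- lapply(seq_along(cn), function(k)
        idx[grepl(sprintf("^H%d%d\\d$", ci, k), a$name[idx])])
      chains[[c("sn1", "sn2")[ci]]] <- list(carbons = cn, hydrogens = hyd)
    }
    list(p = p, chains = chains)
  })
  structure(list(phosphorus = vapply(lipids, function(l) l$p, 0L),
                 lipids = lipids),
            class = "lipid_selection")
}

window_range <- function(frames, width) {
  times <- vapply(frames, function(f) f$time, 0)
  span <- max(times) - min(times)
  if (width > span + 1e-9) return(c(min(times), max(times)))
  # strict "last width ns": a frame exactly at t_max - width is excluded
  c(max(times) - width + 1e-6, max(times))
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Run the analysis pipeline
#'
#' Generates or loads a trajectory, assigns leaflets, and emits thickness
#' and APL maps, a scalar summary (APL per leaflet and overall, membrane
#' thickness, each mean +/- sd over the summary window), order-parameter
#' profiles, mass-density profiles, coil metrics and a release
#' classification where the system contains a nanoparticle/probes. All
#' outputs are plain text and byte-reproducible for a fixed config and
#' seed; `manifest.json` records the package version, seed, config hash
#' and output checksums.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages to run, subset of
#'   `c("leaflets", "maps", "metrics", "release")`.
#' @return invisible list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("leaflets", "maps", "metrics",
                                    "release")) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
  }
  t0 <- proc.time()[3]
  sys <- pipeline_load(config)
  note("load: %d atoms, %d frames (%.2fs)", n_atoms(sys$topology),
       length(sys$frames), proc.time()[3] - t0)
  res <- list()
  outputs <- character(0)
  emit <- function(name) outputs <<- c(outputs, name)

  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  asg <- stage_wrap("leaflets", assign_leaflets_trajectory(
    sys$frames, sys$selection, cutoff = config$leaflet_cutoff,
    mode = config$leaflet_mode))
  note("leaflets: %d flip-flop label changes", asg$flip_flops)
  if ("leaflets" %in% stages) {
    write_leaflets_csv(asg, file.path(outdir, "leaflets.csv"))
    emit("leaflets.csv")
  }
  res$assignment <- asg

  if ("maps" %in% stages) stage_wrap("maps", {
    mw <- window_range(sys$frames, config$map_window_ns)
    sw <- window_range(sys$frames, config$summary_window_ns)
    am <- apl_map(sys$frames, asg, sys$selection, window = mw,
                  grid = config$grid)
    tm <- thickness_map(sys$frames, asg, sys$selection, window = mw,
                        grid = config$grid)
    write_raster_map(am$upper, file.path(outdir, "apl_upper.dat"))
    write_raster_map(am$lower, file.path(outdir, "apl_lower.dat"))
    write_raster_map(tm, file.path(outdir, "thickness.dat"))
    emit("apl_upper.dat"); emit("apl_lower.dat"); emit("thickness.dat")
    if (!is.null(sys$groups$ps)) {
      ol <- project_outline(sys$frames[[length(sys$frames)]],
                            sys$groups$ps, grid = config$grid)
      olm <- new_raster_map(ol + 0, matrix(1, config$grid, config$grid),
                            sys$frames[[1]]$cell, "np_outline")
      write_raster_map(olm, file.path(outdir, "np_outline.dat"))
      emit("np_outline.dat")
    }
    # Table-2-style scalar summary over the summary window
    sidx <- select_window(sys$frames, sw)
    areas <- lapply(sidx, function(fi)
      voronoi_apl(sys$frames[[fi]], labels_for_frame(asg, fi),
                  sys$selection))
    all_a <- do.call(rbind, areas)
    dp <- mean_thickness(sys$frames, asg, sys$selection, window = sw,
                         grid = min(config$grid, 128L))
    summ <- data.frame(
      quantity = c("apl_top_nm2", "apl_bottom_nm2", "apl_nm2", "d_p_nm"),
      mean = fmt_num(c(mean(all_a$area[all_a$leaflet == "upper"]),
                       mean(all_a$area[all_a$leaflet == "lower"]),
                       mean(all_a$area), dp[["mean"]])),
      sd = fmt_num(c(sd(all_a$area[all_a$leaflet == "upper"]),
                     sd(all_a$area[all_a$leaflet == "lower"]),
                     sd(all_a$area), dp[["sd"]])))
    write.csv(summ, file.path(outdir, "summary.csv"), row.names = FALSE,
              quote = FALSE)
    emit("summary.csv")
    res$summary <- summ
    res$apl_map <- am
    res$thickness_map <- tm
    note("maps: window [%g, %g] ns, summary frames %d", mw[1], mw[2],
         length(sidx))
  })

  if ("metrics" %in% stages) stage_wrap("metrics", {
    op <- order_parameters(sys$frames, sys$selection)
    op$s_cd_abs <- fmt_num(op$s_cd_abs)
    op$sd <- fmt_num(op$sd)
    write.csv(op, file.path(outdir, "order_parameters.csv"),
              row.names = FALSE, quote = FALSE)
    emit("order_parameters.csv")
    groups <- list(lipids = which(
      sys$topology$atoms$resname == config$selection$lipid_resname))
    if (!is.null(sys$groups$ps)) groups$ps <- sys$groups$ps
    dp <- mass_density_profile(sys$frames, sys$topology, groups,
                               phosphorus = sys$selection$phosphorus)
    dp$density <- fmt_num(dp$density)
    write.csv(dp, file.path(outdir, "density_profile.csv"),
              row.names = FALSE, quote = FALSE)
    emit("density_profile.csv")
    if (!is.null(sys$groups$ps)) {
      rg <- radius_of_gyration(sys$frames, sys$topology, sys$groups$ps)
      rg$rg <- fmt_num(rg$rg)
      write.csv(rg, file.path(outdir, "rg.csv"), row.names = FALSE,
                quote = FALSE)
      emit("rg.csv")
      dee <- end_to_end(sys$frames, sys$groups$chain_ends)
      dee$d_ee <- fmt_num(dee$d_ee)
      write.csv(dee, file.path(outdir, "dee.csv"), row.names = FALSE,
                quote = FALSE)
      emit("dee.csv")
      com <- com_trajectory(sys$frames, sys$topology, sys$groups$ps,
                            sys$selection, asg)
      com[-1] <- lapply(com[-1], fmt_num)
      write.csv(com, file.path(outdir, "com.csv"), row.names = FALSE,
                quote = FALSE)
      emit("com.csv")
    }
  })

  if ("release" %in% stages && !is.null(sys$groups$probes) &&
      length(sys$groups$probes) >= config$release$k)
    stage_wrap("release", {
      ds <- distance_series(sys$frames, sys$topology, sys$groups$ps,
                            sys$groups$probes)
      feats <- release_feature(ds)
      cls <- classify_release(feats, k = config$release$k,
                              seed = config$seed,
                              restarts = config$release$restarts)
      write_release_csv(cls, file.path(outdir, "release.csv"))
      emit("release.csv")
      res$release <- cls
    })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile()
  writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- list(
    package = "membranemaps",
    version = as.character(packageVersion("membranemaps")),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_md5 = cfg_hash,
    outputs = as.list(unname(tools::md5sum(file.path(outdir, outputs)))),
    log = log)
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

pipeline_load <- function(config) {
  if (!is.null(config$input)) {
    tr <- read_trajectory_json(config$input)
    sel <- build_lipid_selection(tr$topology,
                                 config$selection$lipid_resname,
                                 config$selection$phosphorus_name)
    groups <- list(ps = ps_group(tr$topology),
                   probes = probe_groups(tr$topology),
                   chain_ends = NULL)
    if (length(groups$ps) == 0) groups["ps"] <- list(NULL)
    if (length(groups$probes) == 0) groups["probes"] <- list(NULL)
    return(list(topology = tr$topology, frames = tr$frames,
                selection = sel, groups = groups))
  }
  gen <- config$generator
  args <- if (is.null(gen$args)) list() else as.list(gen$args)
  if (is.null(args$seed)) args$seed <- config$seed
  sys <- switch(gen$kind,
                flat_bilayer = do.call(make_flat_bilayer, args),
                bump_bilayer = do.call(make_bump_bilayer, args),
                descent = do.call(make_descent_system, args),
                stop("config error: unknown generator kind '", gen$kind,
                     "'"))
  if (is.null(sys$groups)) sys$groups <- list(ps = NULL, probes = NULL)
  sys
}

ps_group <- function(topology) which(topology$atoms$resname == "PS")

probe_groups <- function(topology) {
  a <- topology$atoms
  keep <- vapply(topology$molecules,
                 function(m) all(a$resname[m] == "STY"), TRUE)
  topology$molecules[keep]
}

#' Command-line entry point
#'
#' Subcommand interface mirroring [run_pipeline()]:
#' ```
#' generate --config cfg.json --out dir   write trajectory.json + truth.json
#' leaflets|maps|metrics|release|all --config cfg.json --out dir
#' ```
#' A missing `--config` uses the defaults. Returns (invisibly) the exit
#' status: 0 on success, 2 for configuration/usage errors, 1 for
#' computation errors. `inst/cli/membranemaps` wraps this for Rscript use.
#'
#' @param args character vector of command-line arguments.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: membranemaps",
                 "<generate|leaflets|maps|metrics|release|all>",
                 "[--config cfg.json] [--out dir] [--seed n]")
  status <- tryCatch({
    if (length(args) < 1) stop("config error: ", usage)
    cmd <- args[1]
    opts <- list(config = NULL, out = "membranemaps_out", seed = NULL)
    i <- 2
    while (i <= length(args)) {
      key <- sub("^--", "", args[i])
      if (!key %in% names(opts) || i == length(args))
        stop("config error: unknown or incomplete option '", args[i], "'")
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
    cfg <- if (is.null(opts$config)) pipeline_config()
    else read_pipeline_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (cmd == "generate") {
      sys <- pipeline_load(cfg)
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      write_trajectory_json(sys$topology, sys$frames,
                            file.path(opts$out, "trajectory.json"))
      if (!is.null(sys$truth))
        write_ground_truth_json(sys$truth,
                                file.path(opts$out, "truth.json"))
      0L
    } else if (cmd %in% c("leaflets", "maps", "metrics", "release",
                          "all")) {
      stages <- if (cmd == "all")
        c("leaflets", "maps", "metrics", "release") else cmd
      run_pipeline(cfg, opts$out, stages = stages)
      0L
    } else stop("config error: unknown subcommand '", cmd, "'; ", usage)
  }, error = function(e) {
    message(conditionMessage(e))
    if (grepl("config error", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}
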