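## Configuration-driven stage runner: one entry point that executes a named
## analysis stage from a flat config, writes its outputs under a run
## directory, and returns a JSON-serialisable report.  Identical config and
## seed give identical reports.  Stage defaults follow the study constants:
## Poisson ratio 0.4, 500 nm depth, 25 nm box, 1.2 nm cutoffs, oxidation
## fraction 0.48, 300 K.

.stage_params <- list(
  "afm-fit" = list(gamma = 0.4, tip_radius_nm = 10, max_depth_nm = 500,
                   control = NULL),
  "actin-order" = list(window = 32, overlap = 0.5, radius = 1,
                       min_area_px = 0),
  "migration-stats" = list(),
  "go-build" = list(nx = 10, ny = 10, fraction = 0.48, spacing_nm = 0.24),
  "cg-analyze" = list(box_nm = 25, contact_cutoff_nm = 0.6,
                      lj_cutoff_nm = 1.2, lj_mode = "plain_shift",
                      r_switch_nm = 0.9, eps_r = 15, temperature_k = 300,
                      group_a = "actinA", group_b = "actinB"),
  "simulate" = list(generator = NULL)
)

#' Build a validated run configuration
#'
#' @param stage stage name: one of `afm-fit`, `actin-order`,
#'   `migration-stats`, `go-build`, `cg-analyze`, `simulate`.
#' @param inputs named list/character vector of input paths (stage
#'   dependent).
#' @param params named list of stage parameters; unknown keys are rejected
#'   and omitted keys take the stage defaults.
#' @param outdir output directory (created if needed).
#' @param seed integer seed for any stage randomness.
#' @return a `run_config` list.
#' @export
run_config <- function(stage, inputs = list(), params = list(),
                       outdir = tempfile("gomech_run_"), seed = 1) {
  if (!stage %in% names(.stage_params))
    stop(sprintf("unknown stage '%s' (known: %s)", stage,
                 paste(names(.stage_params), collapse = ", ")),
         call. = FALSE)
  defaults <- .stage_params[[stage]]
  extra <- if (stage == "simulate") character(0)
           else setdiff(names(params), names(defaults))
  if (length(extra) > 0)
    stop(sprintf("unknown parameter(s) for stage '%s': %s", stage,
                 paste(extra, collapse = ", ")), call. = FALSE)
  merged <- utils::modifyList(defaults, as.list(params))
  structure(list(stage = stage, inputs = inputs, params = merged,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat `key: value` YAML with the fields of [run_config()].
#'
#' @param path YAML path.
#' @param overrides named list of parameter overrides (e.g. CLI flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  params <- utils::modifyList(y$params %||% list(), overrides)
  run_config(stage = y$stage, inputs = y$inputs %||% list(),
             params = params, outdir = y$outdir %||% tempfile("gomech_run_"),
             seed = y$seed %||% 1)
}

#' Execute a pipeline stage
#'
#' Runs the configured stage, writes its tables/figures under
#' `config$outdir`, writes the report as `report.json`, and returns the
#' report.  The report records the stage, parameters, seed, input paths
#' and the stage's summary numbers; identical config and seed give an
#' identical report.
#'
#' @param config a `run_config` from [run_config()] or [read_run_config()].
#' @return the report, a named list.
#' @export
run_stage <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  result <- switch(config$stage,
    "afm-fit" = {
      ## inputs: named list group -> character vector of curve files
      groups <- config$inputs
      if (length(groups) == 0) stop("afm-fit: no input curves", call. = FALSE)
      fits <- lapply(groups, function(paths) lapply(paths, function(f) {
        cur <- parse_force_curve_file(f, tip_radius = p$tip_radius_nm,
                                      poisson = p$gamma)
        fit_hertz(cur, max_depth = p$max_depth_nm)
      }))
      ctrl <- p$control %||% names(groups)[1]
      summ <- group_stiffness_summary(fits, control = ctrl)
      utils::write.csv(summ, file.path(config$outdir, "stiffness_summary.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        lapply(fits, function(g) lapply(g, unclass)),
        file.path(config$outdir, "fits.json"),
        auto_unbox = TRUE, digits = NA)
      list(summary = summ)
    },
    "actin-order" = {
      img <- read_image_tiff(config$inputs[[1]])
      mask <- make_intensity_mask(img, min_area_px = p$min_area_px)
      field <- local_orientation(img, window = p$window,
                                 overlap = p$overlap, mask = mask)
      qmap <- order_parameter_map(field, radius = p$radius)
      write_qmap_csv(qmap, file.path(config$outdir, "qmap.csv"))
      write_qmap_png(qmap, file.path(config$outdir, "qmap.png"))
      list(mean_q = mean_order_parameter(qmap),
           n_blocks_set = sum(!is.na(qmap$q)),
           mean_intensity = mean_intensity(img, mask))
    },
    "migration-stats" = {
      grp <- lapply(config$inputs, function(f) cohort_stats(read_tracks(f)))
      per_cell <- do.call(rbind, lapply(names(grp), function(g)
        data.frame(group = g, cell_id = names(grp[[g]]$velocity),
                   velocity_um_h = unname(grp[[g]]$velocity))))
      utils::write.csv(per_cell,
                       file.path(config$outdir, "per_cell_velocity.csv"),
                       row.names = FALSE)
      rep <- lapply(grp, function(s)
        list(mean = s$mean, sd = s$sd, median = s$median,
             n_cells = s$n_cells))
      if (all(c("control", "treated") %in% names(grp)))
        rep$inhibition_percent <-
          inhibition_percent(grp$control$mean, grp$treated$mean)
      rep
    },
    "go-build" = {
      sheet <- build_go_sheet(p$nx, p$ny, oxidation_fraction = p$fraction,
                              lattice_spacing = p$spacing_nm,
                              seed = config$seed)
      span <- max(apply(sheet$positions, 2, function(v) diff(range(v))))
      fr <- bead_frame(sheet$positions, box = max(25, ceiling(span) + 2))
      write_gro(fr, file.path(config$outdir, "go_sheet.gro"),
                atom_names = sheet$types, res_names = rep("GO", length(sheet$types)),
                title = "coarse-grained graphene-oxide sheet")
      utils::write.csv(
        data.frame(bead_index = seq_along(sheet$types), type = sheet$types,
                   charge_e = 0, group = "GO"),
        file.path(config$outdir, "go_topology.csv"), row.names = FALSE)
      list(n_beads = length(sheet$types),
           n_sp1 = sum(sheet$types == "SP1"),
           n_sg4 = sum(sheet$types == "SG4"),
           n_bonds = nrow(sheet$bonds))
    },
    "cg-analyze" = {
      frames <- read_xyz(config$inputs$trajectory, box = p$box_nm)
      topo <- read_topology(config$inputs$topology)
      series <- com_distance_series(frames, topo, p$group_a, p$group_b)
      ref <- frames[[1]]
      contacts <- reference_contacts(ref, topo, p$group_a, p$group_b,
                                     cutoff = p$contact_cutoff_nm)
      n_contacts <- vapply(frames, count_contacts, integer(1),
                           contacts = contacts)
      out <- data.frame(series, n_contacts = n_contacts)
      if (!is.null(config$inputs$lj_table)) {
        lj <- read_lj_table(config$inputs$lj_table)
        out$lj_kjmol <- vapply(frames, lj_energy, numeric(1),
                               topology = topo, lj = lj,
                               groupA = p$group_a, groupB = p$group_b,
                               r_cut = p$lj_cutoff_nm, mode = p$lj_mode,
                               r_switch = p$r_switch_nm)
        out$coulomb_kjmol <- vapply(frames, coulomb_energy, numeric(1),
                                    topology = topo, groupA = p$group_a,
                                    groupB = p$group_b,
                                    r_cut = p$lj_cutoff_nm, eps_r = p$eps_r)
      }
      utils::write.csv(out, file.path(config$outdir, "cg_observables.csv"),
                       row.names = FALSE)
      land <- free_energy_2d(out$distance, out$n_contacts,
                             x_bins = max(diff(range(out$distance)) / 20,
                                          1e-3),
                             y_bins = max(diff(range(out$n_contacts)) / 20,
                                          1),
                             temperature = p$temperature_k)
      write_landscape_csv(land, file.path(config$outdir, "landscape.csv"))
      summ <- function(v) list(mean = mean(v),
                               sd = if (length(v) > 1) stats::sd(v) else 0)
      c(list(n_frames = length(frames),
             n_native_contacts = nrow(contacts),
             com_distance = summ(out$distance),
             contacts_retained = summ(n_contacts)),
        if (!is.null(out$lj_kjmol))
          list(lj_energy = summ(out$lj_kjmol),
               coulomb_energy = summ(out$coulomb_kjmol)))
    },
    "simulate" = {
      gen <- p$generator
      if (is.null(gen)) stop("simulate: 'generator' parameter required",
                             call. = FALSE)
      args <- p[setdiff(names(p), "generator")]
      args$seed <- config$seed
      obj <- do.call(match.fun(gen), args)
      stem <- file.path(config$outdir, gen)
      path <- switch(gen,
        gen_force_curve = write_force_curve(obj, paste0(stem, ".txt")),
        gen_filament_image = write_image_tiff(obj, paste0(stem, ".tif")),
        gen_tracks = write_tracks(obj, paste0(stem, ".csv")),
        gen_dimer_frames = {
          write_topology(obj$topology, paste0(stem, "_topology.csv"))
          write_xyz(obj, paste0(stem, ".xyz"))
        },
        stop(sprintf("simulate: no writer for generator '%s'", gen),
             call. = FALSE))
      write_ground_truth(obj, paste0(stem, "_truth.json"))
      list(generator = gen, output = path)
    })
  report <- list(stage = config$stage, seed = config$seed,
                 parameters = config$params,
                 inputs = config$inputs, result = result)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}
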