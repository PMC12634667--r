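# Orchestration: configured runs of the analysis stages with provenance
# (seed, resolved parameter snapshot) and CSV/JSON artifacts.

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
}

.cfg <- function(config, name, default) {
  v <- config[[name]]
  if (is.null(v)) default else v
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches on \code{config$stage}: \code{"geometry"} (porosity / porous
#' volume / hydraulic diameter of a layout), \code{"burst"} (burst-pressure
#' bisection for a fenestra), \code{"transport"} (flow + albumin transient,
#' Pe, permeability, equilibration time), \code{"oxygen"} (steady oxygen
#' field, c_min, tissue OCR), \code{"pom"} (population of models),
#' \code{"collapse"} (scaling collapse of a PoM), \code{"synth"} (synthetic
#' generators). An empty or missing stage is a no-op. Every run writes its
#' resolved configuration and a summary of derived scalars to
#' \code{out_dir}; scalars are also returned invisibly.
#'
#' @param config A named list (or a path readable by
#'   \code{\link{read_run_config}}).
#' @return Invisibly, a list with the stage summary and artifact paths.
#' @export
run_stage <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  stage <- .cfg(config, "stage", "")
  if (identical(stage, "") || length(stage) == 0) {
    return(invisible(list(stage = "none", summary = list())))
  }
  known <- c("geometry", "burst", "transport", "oxygen", "pom", "collapse",
             "synth")
  if (!stage %in% known) {
    stop("schema error: unknown stage '", stage, "' (known: ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  }
  out_dir <- .cfg(config, "out_dir", tempfile("mpsbarrier_run_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfg(config, "seed", 1L))

  summary <- switch(
    stage,
    geometry = {
      lay <- build_pillar_layout(
        n_pillars = .cfg(config, "n_pillars", 8),
        pore_size = .cfg(config, "pore_size", 8),
        region_length = .cfg(config, "region_length", 708),
        region_width = .cfg(config, "region_width", 125),
        height = .cfg(config, "height", 2))
      utils::write.csv(layout_table(lay),
                       file.path(out_dir, "layout.csv"), row.names = FALSE)
      list(pillar_diameter_um = lay$pillar_diameter,
           porosity = porosity(lay),
           porous_volume_um3 = porous_volume(lay),
           pore_hydraulic_diameter_um =
             hydraulic_diameter(lay$height, lay$pore_size))
    },
    burst = {
      kind <- .cfg(config, "fenestra", "straight_channel")
      height <- .cfg(config, "height", 2)
      fen <- if (kind == "pillar_array") {
        fenestra_geometry("pillar_array", height,
                          build_pillar_layout(
                            .cfg(config, "n_pillars", 8),
                            .cfg(config, "pore_size", 8),
                            .cfg(config, "region_length", 708),
                            height = height))
      } else {
        fenestra_geometry("straight_channel", height,
                          .cfg(config, "width", 8))
      }
      fl <- fluid_properties(
        surface_tension = .cfg(config, "surface_tension", 0.072),
        contact_angle = .cfg(config, "contact_angle", 66))
      dom <- valve_domain(fen, dx = .cfg(config, "dx", NULL))
      br <- find_burst_pressure(dom, fl, tol = .cfg(config, "tol", NULL))
      utils::write.csv(br$history, file.path(out_dir, "burst_history.csv"),
                       row.names = FALSE)
      list(burst_pressure_pa = br$burst_pressure, p_star = br$p_star)
    },
    transport = {
      height <- .cfg(config, "height", 2)
      pore <- .cfg(config, "pore_size", 8)
      barrier <- if (.cfg(config, "pillars", TRUE)) {
        fenestra_geometry("pillar_array", height,
                          build_pillar_layout(8, pore, 708, height = height))
      } else {
        fenestra_geometry("straight_channel", height, pore)
      }
      cfg <- transport_config(
        device = device_geometry(barrier = barrier),
        flow_rate = .cfg(config, "flow_rate", 20),
        peclet_length = .cfg(config, "peclet_length", 300))
      fl <- solve_flow(cfg)
      tr <- simulate_solute_transport(cfg, fl,
                                      t_end = .cfg(config, "t_end", 60),
                                      dt = .cfg(config, "dt", 0.05))
      utils::write.csv(tr$trace, file.path(out_dir, "trace.csv"),
                       row.names = FALSE)
      list(vbar_um_s = fl$vbar, peclet = fl$peclet,
           permeability_cm_s = tryCatch(
             permeability_at_half_saturation(tr), error = function(e) NA),
           t_eq_h = tryCatch(
             equilibration_time(tr, .cfg(config, "threshold", 0.95)),
             error = function(e) NA))
    },
    oxygen = {
      geom <- .cfg(config, "geometry", "V3")
      dom <- if (identical(geom, "custom")) {
        tissue_domain("custom", dims = unlist(.cfg(config, "dims", NULL)),
                      n = .cfg(config, "n", NULL))
      } else {
        tissue_domain(geom, n = .cfg(config, "n", NULL))
      }
      par <- oxygen_parameters(
        socr = .cfg(config, "socr", 4.67e-17),
        diffusivity = .cfg(config, "diffusivity", 2e-9))
      sol <- solve_oxygen_steady(dom, par)
      cm <- min_oxygen(sol)
      list(c_min_mol_m3 = as.numeric(cm),
           viable = isTRUE(attr(cm, "viable")),
           tissue_ocr_mol_s = tissue_ocr(sol))
    },
    pom = {
      geoms <- .cfg(config, "geometries", c("V1", "V2", "V3"))
      doms <- lapply(geoms, function(g) tissue_domain(g))
      names(doms) <- geoms
      pom <- run_pom(doms,
                     socr_distribution(
                       mean = .cfg(config, "socr_mean", 4.67e-17),
                       cv = .cfg(config, "socr_cv", 0.69)),
                     oxygen_parameters(
                       diffusivity = .cfg(config, "diffusivity", 2e-9)),
                     n = .cfg(config, "n_pop", 1000), seed = seed)
      utils::write.csv(as.data.frame(pom$B),
                       file.path(out_dir, "pom_B.csv"), row.names = FALSE)
      list(mean_B = as.list(colMeans(pom$B, na.rm = TRUE)),
           failures = length(pom$failures))
    },
    collapse = {
      bpath <- .cfg(config, "pom_csv", NULL)
      if (is.null(bpath)) {
        stop("schema error: collapse stage needs 'pom_csv' and 'masses'",
             call. = FALSE)
      }
      B <- utils::read.csv(bpath)
      masses <- unlist(.cfg(config, "masses", NULL))
      cr <- collapse_distributions(as.list(B), masses,
                                   beta = .cfg(config, "beta", 1),
                                   seed = seed)
      list(delta = cr$delta, alpha = cr$alpha, beta = cr$beta,
           distance = cr$distance)
    },
    synth = {
      spec <- synthetic_spec(seed = seed)
      ge <- synth_geometry_ensemble(spec, .cfg(config, "n", 1000))
      write_synthetic(ge, file.path(out_dir, "geometry_ensemble.csv"))
      list(mean_density = mean(ge$density_per_m3),
           mean_volume_um3 = mean(ge$volume_um3),
           mean_count = mean(ge$cell_count))
    })

  resolved <- config
  resolved$stage <- stage
  resolved$seed <- seed
  jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(stage = stage, summary = summary, out_dir = out_dir))
}
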