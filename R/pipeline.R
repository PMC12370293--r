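#' Read and validate a run configuration
#'
#' Configurations are structured YAML with a top-level `mode` plus per-module
#' parameter blocks. Unknown top-level keys are rejected so that typos fail
#' loudly rather than being silently ignored.
#'
#' Recognised keys: `mode` (`hemodynamics`, `simulate`, `measure`,
#' `junctions`, `full`), `seed`, `input`, `output`, `channel_order`,
#' `pixel_size`, `channel` (geometry block: `width_mm`, `height_um`,
#' `length_mm`), `fluid` (`density`, `viscosity`), `conditions` (list of
#' blocks: `label`, `flow_rate_ul_min`, `outlet_head_cm`, `tube_diameter_mm`,
#' `tube_length_cm`, `include_tube_friction`), `synthetic` (passed to
#' [synthetic_spec()]), `segmentation` (passed to [measure_cells()]),
#' `junctions` (passed to [measure_junctions()]).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  known <- c("mode", "seed", "input", "output", "channel_order", "pixel_size",
             "channel", "fluid", "conditions", "synthetic", "segmentation",
             "junctions")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  modes <- c("hemodynamics", "simulate", "measure", "junctions", "full")
  if (is.null(config$mode) || !config$mode %in% modes)
    stop("config$mode must be one of: ", paste(modes, collapse = ", "),
         call. = FALSE)
  structure(config, class = c("run_config", "list"))
}

.config_geom <- function(config) {
  ch <- config$channel
  channel_geometry(width = (ch$width_mm %||% 1) * 1e-3,
                   height = (ch$height_um %||% 100) * 1e-6,
                   length = (ch$length_mm %||% 17) * 1e-3)
}

.config_fluid <- function(config) {
  fl <- config$fluid
  fluid(density = fl$density %||% 1000, viscosity = fl$viscosity %||% 7.2e-4)
}

.config_conditions <- function(config) {
  lapply(config$conditions, function(cc)
    flow_condition(flow_rate = uL_min(cc$flow_rate_ul_min %||% 0),
                   outlet_head = (cc$outlet_head_cm %||% 0) * 1e-2,
                   tube_diameter = (cc$tube_diameter_mm %||% 1) * 1e-3,
                   tube_length = (cc$tube_length_cm %||% 50) * 1e-2,
                   include_tube_friction =
                     isTRUE(cc$include_tube_friction),
                   label = cc$label))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# provenance sidecar: config hash, seed, package version (no timestamp, so
# identical runs produce byte-identical sidecars)
.write_provenance <- function(config, path) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA)),
             tmp)
  side <- list(config = unclass(config),
               config_md5 = unname(tools::md5sum(tmp)),
               seed = config$seed %||% NA,
               package = "endoflow",
               version = as.character(utils::packageVersion("endoflow")))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Execute a configured pipeline run
#'
#' Runs the stage chain selected by `config$mode` and writes its artifacts
#' (CSV tables, label TIFFs) under `config$output`, together with a
#' provenance sidecar (`provenance.json`: config, config hash, seed, package
#' version) sufficient to re-run the artifact.
#'
#' Modes: `hemodynamics` writes a one-row-per-condition summary CSV
#' (optionally sampled shear and pressure profiles); `simulate` renders the
#' configured synthetic monolayers; `measure` segments and measures stacks
#' (simulated in-memory here, or read from `config$input`); `junctions` adds
#' junction-level metrics; `full` chains simulate, measure, junctions and a
#' condition summary.
#'
#' @param config A [read_run_config()] result, a path, or a config list.
#' @return A named list of the main in-memory results, invisibly; artifacts
#'   are written under `config$output`.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if (config$mode == "hemodynamics") {
    geom <- .config_geom(config)
    fl <- .config_fluid(config)
    conds <- .config_conditions(config)
    if (!length(conds)) stop("hemodynamics mode needs conditions",
                             call. = FALSE)
    summ <- summarize_conditions(geom, fl, conds)
    utils::write.csv(summ, file.path(out_dir, "conditions.csv"),
                     row.names = FALSE)
    for (i in seq_along(conds)) {
      rep <- hemodynamics_report(geom, fl, conds[[i]])
      utils::write.csv(data.frame(x_m = rep$wss_x, tau_pa = rep$wss),
                       file.path(out_dir, sprintf("wss_profile_%d.csv", i)),
                       row.names = FALSE)
      utils::write.csv(data.frame(z_m = rep$pressure_z, p_pa = rep$pressure),
                       file.path(out_dir, sprintf("pressure_profile_%d.csv", i)),
                       row.names = FALSE)
    }
    res$summary <- summ
  } else {
    seed <- config$seed %||% 1L
    syn <- config$synthetic %||% list()
    syn$rng_seed <- syn$rng_seed %||% seed
    if (!is.null(syn$size)) syn$size <- as.integer(syn$size)
    spec <- do.call(synthetic_spec, syn)

    if (config$mode == "simulate") {
      res$manifest <- sweep_monolayers(list(spec), out_dir)
    } else {
      sim <- NULL
      if (!is.null(config$input)) {
        stack <- read_image_stack(config$input,
                                  config$channel_order %||%
                                    c("nuclei", "actin", "ve_cadherin"),
                                  config$pixel_size %||% 0.16)
      } else {
        sim <- generate_monolayer(spec)
        stack <- sim$stack
      }
      seg_args <- config$segmentation %||% list()
      meas <- do.call(measure_cells, c(list(stack = stack), seg_args))
      utils::write.csv(meas$cells, file.path(out_dir, "cells.csv"),
                       row.names = FALSE)
      tiff::writeTIFF(meas$labels$secondary / 65535,
                      file.path(out_dir, "cell_labels.tif"),
                      bits.per.sample = 16L)
      res$cells <- meas$cells
      res$labels <- meas$labels
      if (!is.null(sim)) res$truth <- sim$truth

      if (config$mode %in% c("junctions", "full")) {
        jarg <- config$junctions %||% list()
        jx <- do.call(measure_junctions,
                      c(list(stack = stack,
                             secondary = meas$labels$secondary), jarg))
        utils::write.csv(jx$edges, file.path(out_dir, "edges.csv"),
                         row.names = FALSE)
        utils::write.csv(rbind(jx$fingers, jx$filopodia),
                         file.path(out_dir, "fingers.csv"),
                         row.names = FALSE)
        res$junctions <- jx
      }
      if (config$mode == "full") {
        summ <- summarize_cells(meas$cells)
        utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                         row.names = FALSE)
        res$summary <- summ
      }
    }
  }
  .write_provenance(config, file.path(out_dir, "provenance.json"))
  invisible(res)
}

#' Condition-level summary of per-cell records
#'
#' Grouped mean and sd of every numeric per-cell metric. Groups with fewer
#' than `min_n` cells are flagged (`small_group`), mirroring the practice of
#' analysing at least 50 cells per repeat; single-cell groups have undefined
#' sd.
#'
#' @param cells Per-cell data.frame (e.g. from [measure_cells()]).
#' @param group Optional name of a grouping column; `NULL` summarises all
#'   rows as one group.
#' @param min_n Minimum comfortable group size.
#' @return A data.frame with one row per group x metric: `group`, `metric`,
#'   `n_cells`, `mean`, `sd`, `small_group`.
#' @export
summarize_cells <- function(cells, group = NULL, min_n = 50L) {
  if (!nrow(cells)) stop("no cell records to summarise", call. = FALSE)
  g <- if (is.null(group)) factor(rep("all", nrow(cells)))
       else factor(cells[[group]])
  num <- vapply(cells, is.numeric, logical(1))
  num["cell_id"] <- FALSE
  metrics <- names(cells)[num]
  rows <- lapply(levels(g), function(lv) {
    sub <- cells[g == lv, metrics, drop = FALSE]
    if (!nrow(sub)) {
      warning("empty group '", lv, "' omitted", call. = FALSE)
      return(NULL)
    }
    data.frame(group = lv, metric = metrics, n_cells = nrow(sub),
               mean = vapply(sub, mean, numeric(1), na.rm = TRUE),
               sd = vapply(sub, function(x)
                 if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE)
                 else NA_real_, numeric(1)),
               small_group = nrow(sub) < min_n, row.names = NULL)
  })
  do.call(rbind, rows)
}
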