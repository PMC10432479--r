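# Configuration files, canonical scenario fixtures, and result tables.
#
# Configs are YAML with explicit unit suffixes on every physical quantity
# ("1 um", "2.5 mL/h", "0.4 T"); everything is converted to SI at load
# time.  Results are written as a CSV table plus a JSON metadata sidecar
# carrying the config hash, seed and package version, so every row is
# traceable and re-runnable.

.default_config <- function() {
  list(
    geometry = list(pore_diameter = "3 um",
                    pore_density = "2.12e6 cm^-2",
                    membrane_area = "2.5 cm^2",
                    nife_thickness = "200 nm",
                    backing_thickness = "5 um",
                    n_membranes = 1L),
    flow = list(volumetric_flow_rate = "2.5 mL/h",
                viscosity = "1e-3 Pa.s",
                convention = "inlet_velocity"),
    magnet = list(external_field = "0.4 T",
                  applied_H = "341000 A/m",
                  drive = "B",
                  film_saturation = "6.29e5 A/m",
                  film_thickness = "200 nm"),
    particles = list(strong = list(n_mnps = 15L),
                     weak = list(n_mnps = 1L)),
    scan = list(),
    integrator = list(atol = "2 nm", max_steps = 100000L),
    seed = 1L,
    output = "results",
    label = "run"
  )
}

.known_keys <- function() {
  list(geometry = c("pore_diameter", "pore_density", "membrane_area",
                    "nife_thickness", "backing_thickness", "n_membranes"),
       flow = c("volumetric_flow_rate", "viscosity", "convention"),
       magnet = c("external_field", "applied_H", "drive",
                  "film_saturation", "film_thickness"),
       particles = NULL,
       scan = c("d", "phi", "n", "area", "pore_density", "scenarios",
                "clog_radius", "n_occluded", "convention"),
       integrator = c("atol", "max_steps", "capture_gap", "brownian",
                      "temperature"),
       seed = NULL, output = NULL, label = NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with explicit unit strings, fills defaults
#' for missing entries, validates keys and values, and materializes the
#' domain objects.  An empty file yields the all-defaults configuration.
#'
#' @param path path to a YAML config file, or a list already in config
#'   shape.
#' @return object of class `tenpo_config` with elements `geometry`
#'   ([device_geometry()]), `flow` ([flow_condition()]), `env`
#'   ([magnetic_environment()]), `particles`, `scan`, `integrator`, `seed`,
#'   `output` and `raw` (the merged raw config).
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) path else {
    if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  defs <- .default_config()
  known <- .known_keys()
  extra <- setdiff(names(raw), names(defs))
  if (length(extra)) {
    stop(sprintf("unknown config section(s): %s", paste(extra, collapse = ", ")))
  }
  merged <- utils::modifyList(defs, raw)
  for (sec in names(known)) {
    if (is.null(known[[sec]]) || !is.list(merged[[sec]])) next
    bad <- setdiff(names(merged[[sec]]), known[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", ")))
    }
  }
  g <- merged$geometry
  geometry <- device_geometry(g$pore_diameter, g$pore_density, g$membrane_area,
                              g$nife_thickness, g$backing_thickness,
                              as.integer(g$n_membranes))
  env <- magnetic_environment(merged$magnet$external_field,
                              merged$magnet$applied_H,
                              merged$magnet$drive,
                              merged$magnet$film_saturation,
                              merged$magnet$film_thickness)
  flow <- flow_condition(merged$flow$volumetric_flow_rate,
                         merged$flow$viscosity, geometry,
                         convention = merged$flow$convention)
  particles <- lapply(merged$particles, function(p) {
    particle_complex(n_mnps = p$n_mnps %||% 15,
                     complex_diameter = p$complex_diameter %||% "200 nm",
                     relative_permeability = p$relative_permeability)
  })
  integ <- merged$integrator
  opts <- list(atol = parse_quantity(integ$atol %||% "2 nm", "length"),
               max_steps = as.integer(integ$max_steps %||% 100000L))
  if (!is.null(integ$capture_gap)) {
    opts$capture_gap <- parse_quantity(integ$capture_gap, "length")
  }
  if (isTRUE(integ$brownian)) opts$brownian <- TRUE
  cfg <- list(geometry = geometry, flow = flow, env = env,
              particles = particles,
              scan = parse_scan(merged$scan),
              integrator = opts,
              seed = as.integer(merged$seed),
              output = merged$output,
              label = merged$label %||% "run",
              raw = merged)
  class(cfg) <- "tenpo_config"
  cfg
}

# scan section: unit-suffixed vectors -> SI
parse_scan <- function(s) {
  if (!length(s)) return(list())
  out <- list()
  pq <- function(x, dim) unname(vapply(x, parse_quantity, 0, dimension = dim))
  if (!is.null(s$d)) out$d <- pq(s$d, "length")
  if (!is.null(s$phi)) out$phi <- pq(s$phi, "flow")
  if (!is.null(s$n)) out$n <- as.integer(s$n)
  if (!is.null(s$area)) out$area <- pq(s$area, "area")
  if (!is.null(s$pore_density)) {
    out$pore_density <- pq(s$pore_density, "areal_density")
  }
  if (!is.null(s$scenarios)) out$scenarios <- as.numeric(s$scenarios)
  if (!is.null(s$clog_radius)) out$clog_radius <- pq(s$clog_radius, "length")
  if (!is.null(s$n_occluded)) out$n_occluded <- as.integer(s$n_occluded)
  if (!is.null(s$convention)) out$convention <- s$convention
  out
}

#' @export
print.tenpo_config <- function(x, ...) {
  cat(sprintf("TENPO run config '%s' (seed %d)\n", x$label, x$seed))
  print(x$geometry)
  print(x$flow)
  print(x$env)
  invisible(x)
}

#' Canonical scenario fixtures
#'
#' Ready-to-run configurations for the canonical in-silico experiments:
#'
#' * `diameter_scan`: pore-diameter scan d in {0.6, 1, 3, 12} um at 2.5 mL/h,
#'   pore densities scaled as 2.12e6 (3 um / d)^2 cm^-2 so the mean in-pore
#'   velocity is the same at every diameter.
#' * `flow_scan`: flow-rate scan phi in {0.5, 1, 2.5, 5, 10, 25} mL/h at
#'   d = 1 um.
#' * `membranes`: membrane-number scan n = 1..5 at d = 3 um, 2.5 mL/h.
#' * `clog`: clog study (0, 400, 800 nm radius) on a d = 3 um pore.
#' * `occlusion`: 3 x 3 periodic-cell occlusion study (0..4 of 9 pores
#'   blocked) at d = 3 um.
#'
#' @return named list of `tenpo_config` objects.
#' @export
fixture_scenarios <- function() {
  d_set <- c("0.6 um", "1 um", "3 um", "12 um")
  dens <- function(d_um) sprintf("%.4g cm^-2", 2.12e6 * (3 / d_um)^2)
  base <- list()
  base$diameter_scan <- list(
    label = "diameter_scan",
    geometry = list(pore_diameter = "3 um", pore_density = "2.12e6 cm^-2"),
    scan = list(d = d_set,
                pore_density = lapply(c(0.6, 1, 3, 12), dens),
                phi = "2.5 mL/h", scenarios = c(15, 1))
  )
  base$flow_scan <- list(
    label = "flow_scan",
    geometry = list(pore_diameter = "1 um", pore_density = dens(1)),
    scan = list(d = "1 um", pore_density = list(dens(1)),
                phi = c("0.5 mL/h", "1 mL/h", "2.5 mL/h", "5 mL/h",
                        "10 mL/h", "25 mL/h"),
                scenarios = c(15, 1))
  )
  base$membranes <- list(
    label = "membranes",
    geometry = list(pore_diameter = "3 um", pore_density = "2.12e6 cm^-2",
                    n_membranes = 5L),
    scan = list(d = "3 um", pore_density = list(dens(3)),
                phi = "2.5 mL/h", n = 1:5, scenarios = c(15, 1))
  )
  base$clog <- list(
    label = "clog",
    geometry = list(pore_diameter = "3 um", pore_density = "2.12e6 cm^-2"),
    scan = list(clog_radius = c("0 nm", "400 nm", "800 nm"))
  )
  base$occlusion <- list(
    label = "occlusion",
    geometry = list(pore_diameter = "3 um", pore_density = "2.12e6 cm^-2"),
    flow = list(convention = "device_flux"),
    scan = list(n_occluded = 0:4)
  )
  lapply(base, load_config)
}

config_hash <- function(cfg) {
  txt <- yaml::as.yaml(cfg$raw)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Write a result table with its metadata sidecar
#'
#' Writes `table` as a UTF-8 CSV with a header row and '.' decimal marks,
#' plus a JSON sidecar (`<path>.meta.json`) with the config hash, seed and
#' package version.  Re-reading the CSV reproduces the table; identical
#' config and seed give byte-identical CSV bodies.
#'
#' @param table a data.frame of results (e.g. from [scan_parameters()]).
#' @param path output CSV path.
#' @param config optional `tenpo_config` used to produce the table.
#' @param seed seed recorded in the metadata.
#' @return invisibly, the paths written.
#' @export
write_results <- function(table, path, config = NULL, seed = NULL) {
  if (!is.data.frame(table)) stop("table must be a data.frame")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- list(
    config_hash = if (is.null(config)) NA_character_ else config_hash(config),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    package_version = as.character(utils::packageVersion("tenposim")),
    n_rows = nrow(table),
    written = "run"
  )
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = path, meta = meta_path))
}

#' Read a result table written by [write_results()]
#'
#' @param path CSV path.
#' @return the result data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Run a configured scenario
#'
#' Dispatches on the scan section of a config: capture-rate scans (over d,
#' phi, n, area), clog studies (`clog_radius`) and occlusion studies
#' (`n_occluded`).
#'
#' @param config a `tenpo_config` (or a path to one).
#' @param verbose print per-condition progress.
#' @return a result data.frame (schema depends on the study type).
#' @export
run_scenario <- function(config, verbose = FALSE) {
  if (!inherits(config, "tenpo_config")) config <- load_config(config)
  sc <- config$scan
  if (!is.null(sc$clog_radius)) {
    rows <- lapply(sc$clog_radius, function(rc) {
      ci <- clog_impact_experiment(clog_spec(rc, config$geometry),
                                   config$geometry, config$flow, config$env,
                                   opts = config$integrator)
      data.frame(clog_radius_nm = rc * 1e9,
                 Rs = ci$clogged$strong$R, Rw = ci$clogged$weak$R,
                 dRs = ci$dRs, dRw = ci$dRw, seed = config$seed)
    })
    return(do.call(rbind, rows))
  }
  if (!is.null(sc$n_occluded)) {
    rows <- lapply(sc$n_occluded, function(k) {
      data.frame(n_occluded = k,
                 flux_multiplier = occlusion_flow_multiplier(9, k),
                 drag_increase_pct = occlusion_array_experiment(
                   k, config$geometry, config$flow),
                 seed = config$seed)
    })
    return(do.call(rbind, rows))
  }
  spec <- sc
  if (is.null(spec$d)) spec$d <- config$geometry$pore_diameter
  if (is.null(spec$phi)) spec$phi <- config$flow$volumetric_flow_rate
  if (is.null(spec$convention)) spec$convention <- config$flow$convention
  if (verbose) {
    message(sprintf("scan: %d diameters x %d flow rates x %d membrane counts",
                    length(spec$d), length(spec$phi), length(spec$n %||% 1L)))
  }
  scan_parameters(spec, env = config$env, seed = config$seed,
                  opts = config$integrator)
}
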