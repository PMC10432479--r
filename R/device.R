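# Device geometry and per-pore hydraulics: pore counts, per-pore flux and
# mean velocity, orifice-plus-channel hydraulic resistance, and parallel-pore
# flow redistribution under occlusion.

#' Commercial track-etch pore densities by pore diameter
#'
#' Generic defaults following commercial track-etched membrane
#' specifications: 1e7 cm^-2 at 600 nm, 2e6 cm^-2 at 1 um, 2.12e6 cm^-2 at
#' 3 um, 1e5 cm^-2 at 12 um.  The canonical simulation scenarios override
#' these so that the mean in-pore velocity is held constant across pore
#' diameters (see [fixture_scenarios()]).
#'
#' @param pore_diameter pore diameter in m (or a unit string).
#' @return areal pore density in m^-2.
#' @export
default_pore_density <- function(pore_diameter) {
  d <- parse_quantity(pore_diameter, "length")
  known_d <- c(0.6e-6, 1e-6, 3e-6, 12e-6)
  known_rho <- c(1e7, 2e6, 2.12e6, 1e5) * 1e4   # cm^-2 -> m^-2
  i <- which.min(abs(log(d / known_d)))
  known_rho[i]
}

#' Device geometry of a track-etched magnetic nanopore membrane
#'
#' @param pore_diameter pore diameter d (m or unit string, e.g. `"1 um"`).
#' @param pore_density areal pore density (m^-2 or unit string, e.g.
#'   `"2.12e6 cm^-2"`).  Defaults to [default_pore_density()] for d.
#' @param membrane_area device cross-sectional area a (m^2 or unit string).
#' @param nife_thickness thickness of the NiFe film (default 200 nm).
#' @param backing_thickness thickness of the polycarbonate backing
#'   (default 5 um).
#' @param n_membranes number of membranes stacked in series.
#' @return object of class `tenpo_geometry` with derived fields
#'   `unit_cell_radius` (= (pi * pore_density)^(-1/2)), `pore_pitch`
#'   (= pore_density^(-1/2), square-lattice pitch) and `pore_count`.
#' @export
device_geometry <- function(pore_diameter,
                            pore_density = NULL,
                            membrane_area = "2.5 cm^2",
                            nife_thickness = "200 nm",
                            backing_thickness = "5 um",
                            n_membranes = 1L) {
  d <- parse_quantity(pore_diameter, "length")
  a <- parse_quantity(membrane_area, "area")
  t_film <- parse_quantity(nife_thickness, "length")
  t_back <- parse_quantity(backing_thickness, "length")
  rho <- if (is.null(pore_density)) default_pore_density(d) else
    parse_quantity(pore_density, "areal_density")
  if (!is.finite(d) || d <= 0) stop("invalid geometry: pore_diameter must be > 0")
  if (!is.finite(rho) || rho <= 0) stop("invalid geometry: pore_density must be > 0")
  if (!is.finite(a) || a <= 0) stop("invalid geometry: membrane_area must be > 0")
  if (t_film <= 0 || t_back <= 0) stop("invalid geometry: layer thicknesses must be > 0")
  if (n_membranes < 1) stop("invalid geometry: n_membranes must be >= 1")
  r_cell <- 1 / sqrt(pi * rho)
  if (r_cell <= d / 2) {
    stop("invalid geometry: pores overlap (unit_cell_radius <= d/2)")
  }
  g <- list(
    pore_diameter = d,
    pore_radius = d / 2,
    pore_density = rho,
    membrane_area = a,
    nife_thickness = t_film,
    backing_thickness = t_back,
    membrane_thickness = t_film + t_back,
    n_membranes = as.integer(n_membranes),
    unit_cell_radius = r_cell,
    pore_pitch = 1 / sqrt(rho),
    pore_count = round(rho * a)
  )
  class(g) <- "tenpo_geometry"
  g
}

#' @export
print.tenpo_geometry <- function(x, ...) {
  cat(sprintf("TENPO membrane geometry\n"))
  cat(sprintf("  pore diameter      : %.3g um\n", x$pore_diameter * 1e6))
  cat(sprintf("  pore density       : %.3g cm^-2\n", x$pore_density * 1e-4))
  cat(sprintf("  membrane area      : %.3g cm^2\n", x$membrane_area * 1e4))
  cat(sprintf("  pore count N       : %.3g\n", x$pore_count))
  cat(sprintf("  unit-cell radius   : %.3g um\n", x$unit_cell_radius * 1e6))
  cat(sprintf("  NiFe / backing     : %.0f nm / %.1f um\n",
              x$nife_thickness * 1e9, x$backing_thickness * 1e6))
  cat(sprintf("  membranes in series: %d\n", x$n_membranes))
  invisible(x)
}

#' Number of pores on a membrane
#'
#' N = round(pore_density x membrane_area).
#'
#' @param geometry a [device_geometry()] object.
#' @return pore count (positive, rounded to the nearest integer).
#' @export
pore_count <- function(geometry) {
  stopifnot(inherits(geometry, "tenpo_geometry"))
  n <- round(geometry$pore_density * geometry$membrane_area)
  if (n < 1) stop("invalid geometry: pore count rounds to zero")
  n
}

#' Operating flow condition
#'
#' Two flux conventions are supported for the single-pore unit-cell
#' simulation:
#'
#' * `"device_flux"`: the device flow rate distributes evenly over all
#'   pores, so the unit cell carries per_pore_flux = phi / N and the mean
#'   in-pore velocity is Vz = phi / (N pi (d/2)^2).
#' * `"inlet_velocity"`: the simulation is inflow-velocity-controlled: the
#'   nominal per-pore mean velocity Vz = phi / (N pi (d/2)^2) is applied as
#'   a uniform inflow over the whole unit-cell inlet plane, so the cell
#'   carries per_pore_flux = Vz pi R_cell^2 (larger than phi / N by the
#'   cell-to-pore area ratio).  This reconstructs a velocity-controlled
#'   inlet boundary condition and is the convention used by the canonical
#'   capture scenarios (see the methods vignette).
#'
#' @param volumetric_flow_rate total device flow rate (m^3/s or unit string,
#'   e.g. `"2.5 mL/h"`).
#' @param viscosity dynamic viscosity (Pa s); default water at room
#'   temperature.
#' @param geometry optional [device_geometry()]; if supplied, the derived
#'   per-pore flux and mean in-pore velocity are attached.
#' @param convention flux convention, see Details.
#' @return object of class `tenpo_flow`.
#' @export
flow_condition <- function(volumetric_flow_rate,
                           viscosity = 1.0e-3,
                           geometry = NULL,
                           convention = c("device_flux", "inlet_velocity")) {
  convention <- match.arg(convention)
  q <- parse_quantity(volumetric_flow_rate, "flow")
  mu <- parse_quantity(viscosity, "viscosity")
  if (q < 0) stop("volumetric_flow_rate must be >= 0")
  if (mu <= 0) stop("viscosity must be > 0")
  fl <- list(volumetric_flow_rate = q, viscosity = mu,
             convention = convention,
             per_pore_flux = NA_real_, mean_pore_velocity = NA_real_,
             inlet_velocity = NA_real_)
  if (!is.null(geometry)) {
    n <- pore_count(geometry)
    vz_nominal <- q / (n * pi * geometry$pore_radius^2)
    if (convention == "device_flux") {
      fl$per_pore_flux <- q / n
      fl$inlet_velocity <- fl$per_pore_flux / (pi * geometry$unit_cell_radius^2)
    } else {
      fl$inlet_velocity <- vz_nominal
      fl$per_pore_flux <- vz_nominal * pi * geometry$unit_cell_radius^2
    }
    fl$mean_pore_velocity <- fl$per_pore_flux / (pi * geometry$pore_radius^2)
    fl$nominal_pore_velocity <- vz_nominal
  } else if (convention == "inlet_velocity") {
    stop("inlet_velocity convention requires a geometry")
  }
  class(fl) <- "tenpo_flow"
  fl
}

#' @export
print.tenpo_flow <- function(x, ...) {
  cat(sprintf("Flow condition: %.3g mL/h (viscosity %.3g Pa s)\n",
              x$volumetric_flow_rate / (1e-6 / 3600), x$viscosity))
  if (is.finite(x$mean_pore_velocity)) {
    cat(sprintf("  per-pore flux      : %.3g m^3/s\n", x$per_pore_flux))
    cat(sprintf("  mean pore velocity : %.3g um/s\n",
                x$mean_pore_velocity * 1e6))
  }
  invisible(x)
}

#' Mean flow velocity through a single pore
#'
#' Vz = phi / (N * pi (d/2)^2): the superficial flow rate divided equally
#' over all pores and the pore cross-section.
#'
#' @param geometry a [device_geometry()].
#' @param flow a [flow_condition()] (its geometry-derived fields are ignored;
#'   the velocity is recomputed for `geometry`).
#' @return mean in-pore velocity in m/s.
#' @export
mean_pore_velocity <- function(geometry, flow) {
  stopifnot(inherits(geometry, "tenpo_geometry"), inherits(flow, "tenpo_flow"))
  n <- pore_count(geometry)
  if (n < 1) stop("division error: zero pore count")
  flow$volumetric_flow_rate / (n * pi * geometry$pore_radius^2)
}

#' Hydraulic resistance of a single pore
#'
#' Orifice-plus-channel model: the Sampson end correction 3 mu / r^3 for the
#' converging entry and exit flow, plus the Poiseuille channel term
#' 8 mu L / (pi r^4) across the membrane thickness
#' L = nife_thickness + backing_thickness.
#'
#' @param geometry a [device_geometry()].
#' @param viscosity dynamic viscosity (Pa s).
#' @return resistance dP/Q in Pa s / m^3.
#' @export
pore_hydraulic_resistance <- function(geometry, viscosity = 1.0e-3) {
  stopifnot(inherits(geometry, "tenpo_geometry"))
  mu <- parse_quantity(viscosity, "viscosity")
  r <- geometry$pore_radius
  L <- geometry$membrane_thickness
  3 * mu / r^3 + 8 * mu * L / (pi * r^4)
}

#' Per-open-pore flux multiplier under occlusion
#'
#' With the total flux held fixed and identical pores in parallel, fully
#' blocking `n_occluded` of `n_pores_in_cell` pores redistributes their share
#' over the remaining open pores: multiplier = n / (n - n_occluded).
#'
#' @param n_pores_in_cell pores in the periodic cell (e.g. 9 for a 3x3 cell).
#' @param n_occluded number of fully blocked pores.
#' @return dimensionless per-open-pore flux multiplier (>= 1).
#' @export
occlusion_flow_multiplier <- function(n_pores_in_cell, n_occluded) {
  if (n_pores_in_cell < 1) stop("n_pores_in_cell must be >= 1")
  if (n_occluded < 0 || n_occluded != round(n_occluded)) {
    stop("n_occluded must be a non-negative integer")
  }
  if (n_occluded >= n_pores_in_cell) {
    stop("no flow path: all pores in the cell are occluded")
  }
  n_pores_in_cell / (n_pores_in_cell - n_occluded)
}

#' Diagnostic: lateral flow resistance between neighbouring pores
#'
#' Order-of-magnitude estimate of the in-plane resistance of the thin fluid
#' gap above the membrane between two neighbouring unit cells, modeled as
#' plane-Poiseuille flow through a slot of height `gap_height` and width one
#' pore pitch over a length of one pore pitch: R = 12 mu L / (w h^3) with
#' L = w = pitch.  The gap height above the membrane is not part of the
#' membrane geometry proper, so this is a documented diagnostic only; with
#' gap heights of a few microns it comes out around two orders of magnitude
#' below [pore_hydraulic_resistance()] for a 3 um pore, which is why flow
#' distributes uniformly over the pore array.
#'
#' @param geometry a [device_geometry()].
#' @param gap_height height of the fluid gap above the membrane (m or unit
#'   string; default 25 um, the dead-volume height of a 2.5 cm^2 device at
#'   ~25 uL per membrane).
#' @param viscosity dynamic viscosity (Pa s).
#' @return list with `lateral_resistance`, `pore_resistance` and their ratio.
#' @export
interpore_resistance_diagnostic <- function(geometry,
                                            gap_height = "25 um",
                                            viscosity = 1.0e-3) {
  stopifnot(inherits(geometry, "tenpo_geometry"))
  h <- parse_quantity(gap_height, "length")
  mu <- parse_quantity(viscosity, "viscosity")
  pitch <- geometry$pore_pitch
  r_lat <- 12 * mu * pitch / (pitch * h^3)
  r_pore <- pore_hydraulic_resistance(geometry, mu)
  list(lateral_resistance = r_lat,
       pore_resistance = r_pore,
       ratio = r_lat / r_pore)
}
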