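# The canonical in-silico experiments: capture-rate grids for strongly- vs
# weakly-tagged complexes, multi-membrane chaining, parameter scans,
# force-ratio diagnostics, and occlusion / clogging impact studies.

#' Release grid of 100 complexes above the pore
#'
#' A uniform 10 x 10 square grid of side 2 d, centered on the pore axis at a
#' height of 3 um above the membrane, one release per grid point.  The
#' square lattice cell of the pore array is axisymmetrized to the circular
#' unit cell by the equal-area concentric (square-to-disk) map, which
#' preserves the release-density measure versus enclosed flux; without the
#' map the corner releases of the square grid would fall outside the
#' circular cell.
#'
#' @param geometry a [device_geometry()].
#' @param n_side grid points per side (default 10, i.e. 100 releases).
#' @param height release height above the membrane (default 3 um).
#' @param map apply the equal-area square-to-disk map (default TRUE).
#' @return n^2 x 3 matrix of release positions (m).
#' @export
release_grid <- function(geometry, n_side = 10L, height = 3e-6, map = TRUE) {
  d <- geometry$pore_diameter
  s <- seq(-d, d, length.out = n_side)
  g <- as.matrix(expand.grid(x = s, y = s))
  if (map) {
    g <- square_to_disk(g, geometry$pore_pitch, geometry$unit_cell_radius)
  }
  cbind(g, z = height)
}

# equal-area concentric map from the square lattice cell (side `pitch`) to
# the circular unit cell (radius R_cell = pitch / sqrt(pi)); vectorized
square_to_disk <- function(xy, pitch, r_cell) {
  u <- 2 * xy[, 1] / pitch
  v <- 2 * xy[, 2] / pitch
  if (any(abs(u) > 1 + 1e-9 | abs(v) > 1 + 1e-9)) {
    stop("release grid extends beyond the lattice cell; cannot axisymmetrize")
  }
  r <- numeric(length(u)); phi <- numeric(length(u))
  big_u <- abs(u) >= abs(v)
  r[big_u] <- u[big_u]
  phi[big_u] <- (pi / 4) * ifelse(u[big_u] == 0, 0, v[big_u] / u[big_u])
  r[!big_u] <- v[!big_u]
  phi[!big_u] <- pi / 2 - (pi / 4) * (u[!big_u] / v[!big_u])
  cbind(x = r * r_cell * cos(phi), y = r * r_cell * sin(phi))
}

#' Capture rate of a release ensemble through one membrane
#'
#' Fraction of the release-grid trajectories that end captured.
#' Deterministic given the grid and integrator tolerances.  Trajectories
#' exhausting the step budget are excluded from the fraction with a
#' warning.
#'
#' @param geometry a [device_geometry()].
#' @param flow a [flow_condition()].
#' @param particle a [particle_complex()] (the tagging scenario).
#' @param env a [magnetic_environment()].
#' @param clog optional [clog_spec()].
#' @param grid release positions (default [release_grid()]).
#' @param fcache optional prebuilt [build_field_cache()].
#' @param opts integrator options (see [track_ensemble()]).
#' @return object of class `tenpo_capture`: `R` (capture fraction),
#'   `status` per trajectory, `positions` (final), `condition`.
#' @export
capture_rate <- function(geometry, flow, particle, env = magnetic_environment(),
                         clog = NULL, grid = NULL, fcache = NULL,
                         opts = list()) {
  if (is.null(grid)) grid <- release_grid(geometry)
  if (is.null(fcache)) fcache <- build_field_cache(env, geometry)
  fld <- velocity_field(geometry, flow, clog)
  res <- track_ensemble(grid, particle, fld, fcache, geometry, opts)
  n_bad <- sum(res$status == "max-steps")
  if (n_bad > 0) {
    warning(sprintf("%d trajectories exhausted the step budget and are excluded", n_bad))
  }
  n_ok <- sum(res$status != "max-steps")
  out <- list(R = sum(res$status == "captured") / max(n_ok, 1L),
              status = res$status,
              positions = res$position,
              release = grid,
              time = res$time,
              condition = list(d = geometry$pore_diameter,
                               phi = flow$volumetric_flow_rate,
                               area = geometry$membrane_area,
                               n_mnps = particle$n_mnps,
                               clog = if (is.null(clog)) 0 else clog$clog_radius))
  class(out) <- "tenpo_capture"
  out
}

#' @export
print.tenpo_capture <- function(x, ...) {
  cat(sprintf("Capture: R = %.2f (%d captured / %d resolved; d = %.2g um, phi = %.2g mL/h, %g MNPs)\n",
              x$R, sum(x$status == "captured"), sum(x$status != "max-steps"),
              x$condition$d * 1e6, x$condition$phi / (1e-6 / 3600),
              x$condition$n_mnps))
  invisible(x)
}

# seeded RNG scope that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Cumulative capture across membranes in series
#'
#' Pass 1 releases the canonical grid; complexes not captured re-enter the
#' next membrane at a uniformly random lateral position over the lattice
#' cell (pore placement is independent between membranes, so the offset to
#' the nearest pore of the next membrane is uniform over the pitch x pitch
#' square) at 3 um height, seeded for reproducibility.  Returns the
#' cumulative capture fraction R(k) for k = 1..n.
#'
#' @inheritParams capture_rate
#' @param n number of membranes in series (>= 1).
#' @param seed integer seed for the random re-entry positions.
#' @return list with `R_cum` (length n), `R_pass` (per-pass conditional
#'   capture), `n_remaining`, and `seed`.
#' @export
multi_membrane_capture <- function(geometry, flow, particle,
                                   env = magnetic_environment(),
                                   n = 1L, seed = 1L,
                                   fcache = NULL, opts = list()) {
  if (n < 1 || n != round(n)) stop("invalid membrane count n")
  if (is.null(fcache)) fcache <- build_field_cache(env, geometry)
  d <- geometry$pore_diameter
  fld <- velocity_field(geometry, flow)
  grid <- release_grid(geometry)
  n0 <- nrow(grid)
  captured <- 0L
  R_cum <- numeric(n)
  R_pass <- rep(NA_real_, n)
  n_remaining <- integer(n)
  with_seed(seed, {
    pts <- grid
    for (k in seq_len(n)) {
      if (nrow(pts) > 0) {
        res <- track_ensemble(pts, particle, fld, fcache, geometry, opts)
        n_bad <- sum(res$status == "max-steps")
        if (n_bad > 0) warning(sprintf("membrane %d: %d max-steps trajectories", k, n_bad))
        caught <- sum(res$status == "captured")
        R_pass[k] <- caught / max(nrow(pts), 1L)
        captured <- captured + caught
        n_left <- sum(res$status == "escaped")
      } else {
        n_left <- 0L
        R_pass[k] <- NA_real_
      }
      R_cum[k] <- captured / n0
      n_remaining[k] <- n_left
      if (k < n && n_left > 0) {
        # pore placement is independent between membranes: the lateral
        # position relative to the next pore is uniform over the lattice
        # cell (the pitch x pitch square), axisymmetrized as for the grid
        half <- geometry$pore_pitch / 2
        xy <- cbind(stats::runif(n_left, -half, half),
                    stats::runif(n_left, -half, half))
        xy <- square_to_disk(xy, geometry$pore_pitch, geometry$unit_cell_radius)
        pts <- cbind(xy, z = 3e-6)
      } else {
        pts <- matrix(numeric(0), 0, 3)
      }
    }
  })
  list(R_cum = R_cum, R_pass = R_pass, n_remaining = n_remaining, seed = seed)
}

#' Magnetophoretic-to-drag force ratio at the pore edge
#'
#' Evaluates, at a probe point 100 nm from the pore rim (directly above the
#' rim corner, inside the fluid), the magnetophoretic force on a complex
#' held at the trap and the Stokes drag that the local fluid velocity
#' exerts on a stationary complex, and returns log10 of their ratio.  At
#' the probe the trap force points towards the rim (dominantly in-plane
#' with a downward vertical component); the ratio uses the force magnitude,
#' the quantity that competes with the local drag (using only the vertical
#' component lowers the ratio by about half a decade; see the methods
#' vignette).  The drag is computed from the device per-pore flux
#' (phi / N), the flow the pore carries at the stated device condition.
#' With an unmagnetized film -Inf is returned as a sentinel.
#'
#' @inheritParams capture_rate
#' @param probe_distance distance of the probe above the rim corner
#'   (default 100 nm).
#' @return log10 of |F_mag| / |F_drag| (dimensionless).
#' @export
force_ratio_diagnostic <- function(geometry, flow, particle,
                                   env = magnetic_environment(),
                                   probe_distance = 100e-9) {
  a <- geometry$pore_radius
  probe <- c(a, 0, probe_distance)
  if (probe_distance <= 0) stop("probe point must lie inside the fluid")
  Fm <- magnetophoretic_force(probe, particle, env, geometry)
  flow_dev <- flow_condition(flow$volumetric_flow_rate, flow$viscosity,
                             geometry, convention = "device_flux")
  fld <- velocity_field(geometry, flow_dev)
  v <- evaluate_velocity(fld, probe)
  drag <- 6 * pi * flow$viscosity * particle$radius * sqrt(sum(v^2))
  fmag <- sqrt(sum(Fm^2))
  if (fmag == 0) return(-Inf)
  log10(fmag / drag)
}

#' Scan capture rates over device parameters
#'
#' Runs [capture_rate()] for every combination in the scan specification
#' and both tagging scenarios, one row per condition x scenario.  Failed
#' conditions are recorded (status `"error"`) and the scan continues.
#'
#' @param scan_spec list with any of `d` (pore diameters, m), `phi` (flow
#'   rates, m^3/s), `n` (membrane counts), `area` (membrane areas, m^2),
#'   `pore_density` (either NULL for constant-velocity scaling, a function
#'   of d, or a vector aligned with `d`), and `scenarios` (MNP counts,
#'   default c(15, 1)).
#' @param env a [magnetic_environment()].
#' @param seed seed for multi-membrane re-entry randomness.
#' @param opts integrator options.
#' @return data.frame (one row per condition x scenario) with capture
#'   fractions and outcome counts.
#' @export
scan_parameters <- function(scan_spec, env = magnetic_environment(),
                            seed = 1L, opts = list()) {
  if (length(scan_spec) == 0) {
    return(data.frame(d_um = numeric(0), phi_mL_h = numeric(0),
                      n_membranes = integer(0), area_cm2 = numeric(0),
                      scenario = character(0), n_mnps = numeric(0),
                      R = numeric(0), n_captured = integer(0),
                      n_escaped = integer(0), n_maxsteps = integer(0),
                      seed = integer(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  d_set <- scan_spec$d %||% 3e-6
  phi_set <- scan_spec$phi %||% (2.5 * 1e-6 / 3600)
  n_set <- scan_spec$n %||% 1L
  a_set <- scan_spec$area %||% 2.5e-4
  scen <- scan_spec$scenarios %||% c(15, 1)
  dens <- scan_spec$pore_density %||% canonical_pore_density
  rows <- list()
  for (d in d_set) for (phi in phi_set) for (nmem in n_set) for (ar in a_set) {
    rho <- if (is.function(dens)) dens(d) else dens[match(d, d_set)]
    geom <- try(device_geometry(d, rho, ar, n_membranes = nmem), silent = TRUE)
    if (inherits(geom, "try-error")) next
    fc <- try(build_field_cache(env, geom), silent = TRUE)
    fl <- flow_condition(phi, geometry = geom,
                         convention = scan_spec$convention %||% "inlet_velocity")
    for (nm in scen) {
      part <- particle_complex(nm)
      res <- try({
        if (nmem > 1) {
          mm <- multi_membrane_capture(geom, fl, part, env, n = nmem,
                                       seed = seed, fcache = fc, opts = opts)
          list(R = mm$R_cum[nmem], status = NULL)
        } else {
          capture_rate(geom, fl, part, env, fcache = fc, opts = opts)
        }
      }, silent = TRUE)
      ok <- !inherits(res, "try-error")
      rows[[length(rows) + 1L]] <- data.frame(
        d_um = d * 1e6,
        phi_mL_h = phi / (1e-6 / 3600),
        n_membranes = nmem,
        area_cm2 = ar * 1e4,
        scenario = if (nm == 15) "strong" else if (nm == 1) "weak" else
          sprintf("%g MNPs", nm),
        n_mnps = nm,
        R = if (ok) res$R else NA_real_,
        n_captured = if (ok && !is.null(res$status)) sum(res$status == "captured") else NA_integer_,
        n_escaped = if (ok && !is.null(res$status)) sum(res$status == "escaped") else NA_integer_,
        n_maxsteps = if (ok && !is.null(res$status)) sum(res$status == "max-steps") else NA_integer_,
        seed = seed,
        status = if (ok) "ok" else "error",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Canonical pore density for the pore-diameter scan
#'
#' The pore-diameter scan holds the mean in-pore velocity constant: the
#' density scales as 2.12e6 (3 um / d)^2 cm^-2 from the d = 3 um reference
#' (N = 5.3e6 pores on 2.5 cm^2), so every diameter sees the same mean
#' in-pore velocity at a given total flow rate.
#'
#' @param d pore diameter (m).
#' @return pore density (m^-2).
#' @export
canonical_pore_density <- function(d) {
  2.12e6 * 1e4 * (3e-6 / d)^2
}

#' Occlusion impact in a periodic 3 x 3 pore cell
#'
#' With `n_occluded` of 9 parallel pores fully blocked at fixed total flow,
#' the per-open-pore flux rises by 9 / (9 - n_occluded).  The maximal drag
#' force on a complex entering an open pore is proportional to the maximal
#' fluid speed accessible to the complex center, computed here from the
#' redistributed-flux velocity field; its relative increase is returned in
#' percent.
#'
#' @param n_occluded blocked pores out of 9 (0..4 canonical; error beyond
#'   8).
#' @param geometry a [device_geometry()].
#' @param flow a [flow_condition()].
#' @param particle a [particle_complex()] (sets the accessible-center
#'   standoff from walls).
#' @return percent increase of the maximal drag force.
#' @export
occlusion_array_experiment <- function(n_occluded, geometry, flow,
                                       particle = particle_complex(15)) {
  if (n_occluded > 8) stop("cannot occlude more than 8 of 9 pores")
  mult <- occlusion_flow_multiplier(9, n_occluded)
  max_drag <- function(scale) {
    fl2 <- flow_condition(flow$volumetric_flow_rate * scale, flow$viscosity,
                          geometry, convention = flow$convention %||% "device_flux")
    fld <- velocity_field(geometry, fl2)
    # maximal accessible speed: scan the open-pore lumen reachable by the
    # complex center (one particle radius off the wall)
    a <- geometry$pore_radius - particle$radius
    r <- seq(0, a, length.out = 80)
    z <- seq(-geometry$membrane_thickness, 1e-6, length.out = 120)
    gr <- expand.grid(r = r, z = z)
    v <- fld$vrz(gr$r, gr$z)
    smax <- max(sqrt(v$vr^2 + v$vz^2))
    6 * pi * flow$viscosity * particle$radius * smax
  }
  d0 <- max_drag(1)
  d1 <- max_drag(mult)
  100 * (d1 / d0 - 1)
}

#' Clog impact on capture rates
#'
#' Capture rates for strongly- and weakly-tagged complexes with a clogged
#' pore, minus the unclogged baseline.
#'
#' @param clog a [clog_spec()].
#' @param geometry a [device_geometry()].
#' @param flow a [flow_condition()].
#' @param env a [magnetic_environment()].
#' @param fcache optional prebuilt field cache.
#' @param opts integrator options.
#' @return list with `dRs`, `dRw`, and the four underlying capture runs.
#' @export
clog_impact_experiment <- function(clog, geometry, flow,
                                   env = magnetic_environment(),
                                   fcache = NULL, opts = list()) {
  if (is.null(fcache)) fcache <- build_field_cache(env, geometry)
  # particles creeping around the clog's stagnation zone can take very many
  # small steps; bound the budget (such trajectories are flagged/excluded)
  if (is.null(opts$max_steps)) opts$max_steps <- 30000L
  strong <- particle_complex(15)
  weak <- particle_complex(1)
  base_s <- capture_rate(geometry, flow, strong, env, fcache = fcache, opts = opts)
  base_w <- capture_rate(geometry, flow, weak, env, fcache = fcache, opts = opts)
  clog_s <- capture_rate(geometry, flow, strong, env, clog = clog,
                         fcache = fcache, opts = opts)
  clog_w <- capture_rate(geometry, flow, weak, env, clog = clog,
                         fcache = fcache, opts = opts)
  list(dRs = clog_s$R - base_s$R,
       dRw = clog_w$R - base_w$R,
       baseline = list(strong = base_s, weak = base_w),
       clogged = list(strong = clog_s, weak = clog_w))
}
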