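# Semi-analytic laminar flow through a pore unit cell.
#
# The field is built from a Stokes stream function psi(r, z) =
# psi_w * F(r, z), which makes it exactly divergence-free and gives exact
# flux conservation through every horizontal plane of the unit cell.  Above
# the membrane F interpolates between the pore-mouth profile and the
# far-field uniform superficial profile (r / R_cell)^2 with a Gaussian
# axial blend w(z) = 1 - exp(-(z / zeta)^2) over the orifice-convergence
# length zeta = a (the value that best matches the axisymmetric Stokes
# reference solution).  Because w'(0) = 0, no-slip holds exactly on the
# membrane faces and the pore wall.
#
# Inside the pore the profile develops from the Sampson orifice shape at
# the mouth, F_m(rho) = 1 - (1 - rho^2)^(3/2) (centerline 1.5 Vbar), to the
# fully developed Poiseuille shape F_p(rho) = 2 rho^2 - rho^4 (centerline
# 2 Vbar) with an entrance e-folding length lambda_e = 0.15 a, both fitted
# to the numerical Stokes reference (see the methods vignette).
#
# A clog (sphere of radius rc lodged at the pore rim) is axisymmetrized as
# a flux-equivalent constriction: the open radius narrows to
# ai = sqrt(a^2 - rc^2) (same blocked cross-section pi rc^2 as the sphere)
# over an axial extent ~ rc around the rim plane.  The constriction surface
# is also a capture surface for trajectory work (see the particle-transport
# module); the non-axisymmetric single-sphere geometry itself is not
# resolved, a documented fidelity limit of the axisymmetric unit cell.

#' Clog specification
#'
#' A spherical clog of radius `clog_radius` lodged on the pore rim with its
#' diameter protruding into the lumen (sphere center one clog radius inside
#' the wall at the rim plane).
#'
#' @param clog_radius sphere radius (m or unit string, e.g. `"800 nm"`).
#' @param geometry a [device_geometry()]; the clog must not occlude the
#'   whole pore (clog_radius < d/2).
#' @return object of class `tenpo_clog`.
#' @export
clog_spec <- function(clog_radius, geometry) {
  stopifnot(inherits(geometry, "tenpo_geometry"))
  rc <- parse_quantity(clog_radius, "length")
  a <- geometry$pore_radius
  if (rc < 0) stop("clog_radius must be >= 0")
  if (rc >= a) stop("clog occludes the entire pore (clog_radius >= d/2)")
  cl <- list(clog_radius = rc,
             center = c(a - rc, 0, 0),     # on the rim, protruding inward
             open_radius = sqrt(a^2 - rc^2))
  class(cl) <- "tenpo_clog"
  cl
}

#' Construct the semi-analytic unit-cell velocity field
#'
#' @param geometry a [device_geometry()].
#' @param flow a [flow_condition()].
#' @param clog optional [clog_spec()].
#' @return object of class `tenpo_velocity_field` with elements `vrz(r, z)`
#'   (axisymmetric components) and `v3(points)` (n x 3 Cartesian
#'   velocities).
#' @export
velocity_field <- function(geometry, flow, clog = NULL) {
  stopifnot(inherits(geometry, "tenpo_geometry"), inherits(flow, "tenpo_flow"))
  a <- geometry$pore_radius
  Rc <- geometry$unit_cell_radius
  L <- geometry$membrane_thickness
  q1 <- if (is.finite(flow$per_pore_flux %||% NA_real_)) flow$per_pore_flux else
    flow$volumetric_flow_rate / pore_count(geometry)
  psi_w <- -q1 / (2 * pi)          # flow in -z
  zeta <- a
  rc <- if (is.null(clog)) 0 else clog$clog_radius
  ai <- if (is.null(clog)) a else clog$open_radius

  ae_fun <- function(z) {
    if (rc <= 0) return(rep(a, length(z)))
    a - (a - ai) * exp(-(z / rc)^2)
  }
  dae_fun <- function(z) {
    if (rc <= 0) return(rep(0, length(z)))
    (a - ai) * (2 * z / rc^2) * exp(-(z / rc)^2)
  }

  lambda_e <- 0.15 * a   # entrance development length (Stokes-reference fit)

  vrz <- function(r, z) {
    n <- max(length(r), length(z))
    r <- rep_len(as.numeric(r), n); z <- rep_len(as.numeric(z), n)
    ae <- ae_fun(z); dae <- dae_fun(z)
    rho <- pmin(r / ae, 1)
    inside <- r < ae
    # shape functions: Sampson orifice mouth profile and Poiseuille
    s2 <- pmax(1 - rho^2, 0)
    Fm <- 1 - s2^1.5
    Fp <- 2 * rho^2 - rho^4
    fpm <- ifelse(inside, 3 * rho * sqrt(s2), 0)   # F_m'
    fpp <- ifelse(inside, 4 * rho - 4 * rho^3, 0)  # F_p'
    hm <- ifelse(inside, 3 * sqrt(s2), 0)          # F_m'/rho
    hp <- ifelse(inside, 4 - 4 * rho^2, 0)         # F_p'/rho
    # beyond the unit cell the flow is plain uniform descent
    Finf <- pmin((r / Rc)^2, 1)
    rs <- pmax(r, 1e-30)

    vz <- numeric(n); vr <- numeric(n)
    up <- z >= 0
    if (any(up)) {
      s <- z[up] / zeta
      W <- 1 - exp(-s^2)
      dW <- (2 * z[up] / zeta^2) * exp(-s^2)
      vz[up] <- psi_w * ((1 - W) * hm[up] / ae[up]^2 + 2 * W / Rc^2)
      vr[up] <- -psi_w * dW * (Finf[up] - Fm[up]) / rs[up] +
        psi_w * (1 - W) * fpm[up] * dae[up] / ae[up]^2
    }
    pore <- z < 0 & z >= -L
    if (any(pore)) {
      g <- exp(z[pore] / lambda_e)   # 1 at mouth, -> 0 deep in the pore
      dg <- g / lambda_e
      vz[pore] <- psi_w * (g * hm[pore] + (1 - g) * hp[pore]) / ae[pore]^2
      vr[pore] <- -psi_w * dg * (Fm[pore] - Fp[pore]) / rs[pore] +
        psi_w * (g * fpm[pore] + (1 - g) * fpp[pore]) * dae[pore] / ae[pore]^2
    }
    lo <- z < -L
    if (any(lo)) {
      u <- -(z[lo] + L)
      W <- 1 - exp(-(u / zeta)^2)
      dW <- -(2 * u / zeta^2) * exp(-(u / zeta)^2)
      vz[lo] <- psi_w * ((1 - W) * hp[lo] / ae[lo]^2 + 2 * W / Rc^2)
      vr[lo] <- -psi_w * dW * (Finf[lo] - Fp[lo]) / rs[lo] +
        psi_w * (1 - W) * fpp[lo] * dae[lo] / ae[lo]^2
    }
    vr[r == 0] <- 0
    # solid membrane band and axisymmetrized constriction: zero velocity
    solid <- (r >= ae - 1e-15) & (z <= 0) & (z >= -L)
    vz[solid] <- 0; vr[solid] <- 0
    list(vr = vr, vz = vz)
  }

  fld <- list(geometry = geometry, flow = flow, clog = clog,
              per_pore_flux = q1, psi_w = psi_w, zeta = zeta,
              mean_pore_velocity = q1 / (pi * a^2),
              vrz = vrz)
  class(fld) <- "tenpo_velocity_field"
  fld$v3 <- function(points) evaluate_velocity(fld, points)
  fld
}

#' Evaluate a velocity field at Cartesian points
#'
#' @param field a `tenpo_velocity_field` (or the discrete field returned by
#'   [solve_axisymmetric_stokes()]).
#' @param points n x 3 matrix (or 3-vector) of positions (m).
#' @return n x 3 matrix of velocities (m/s).
#' @export
evaluate_velocity <- function(field, points) {
  P <- as_points(points)
  r <- sqrt(P[, 1]^2 + P[, 2]^2)
  z <- P[, 3]
  v <- field$vrz(r, z)
  out <- cbind(vx = 0, vy = 0, vz = v$vz)
  off <- r > 0
  out[off, 1] <- v$vr[off] * P[off, 1] / r[off]
  out[off, 2] <- v$vr[off] * P[off, 2] / r[off]
  out
}

#' Semi-analytic fluid velocity in the pore unit cell
#'
#' Composite orifice-convergence / in-pore Poiseuille field scaled to the
#' per-pore flux (see [velocity_field()] for the construction).  Positions
#' must lie inside the unit-cell domain (lateral radius within the unit
#' cell, z between the far inflow and outflow regions).
#'
#' @param position 3-vector or n x 3 matrix of positions (m); origin at the
#'   pore center on the membrane top face, flow arriving from z > 0.
#' @param geometry a [device_geometry()].
#' @param flow a [flow_condition()].
#' @param clog optional [clog_spec()]; applies the flux-equivalent
#'   axisymmetric constriction.
#' @return n x 3 matrix of velocities (m/s).
#' @export
semi_analytic_velocity <- function(position, geometry, flow, clog = NULL) {
  P <- as_points(position)
  r <- sqrt(P[, 1]^2 + P[, 2]^2)
  z <- P[, 3]
  L <- geometry$membrane_thickness
  d <- geometry$pore_diameter
  z_top <- max(3.5e-6, 2.2 * d)
  z_bot <- -(L + max(3.5e-6, 2.2 * d))
  if (any(r > 1.501 * geometry$unit_cell_radius | z > 1.5 * z_top | z < 1.5 * z_bot)) {
    stop("position outside the unit-cell domain")
  }
  fld <- velocity_field(geometry, flow, clog)
  evaluate_velocity(fld, P)
}

#' Clogged-pore velocity field (flux-equivalent constriction)
#'
#' The clog's blocked cross-section (pi clog_radius^2) is removed from the
#' open pore area and the full per-pore flux is carried by the remaining
#' opening, so the maximum in-pore speed rises by the area ratio
#' a^2 / (a^2 - rc^2) (a weak increase for clogs up to 800 nm on a 3 um
#' pore).
#'
#' @inheritParams velocity_field
#' @return a `tenpo_velocity_field`.
#' @export
clogged_velocity_perturbation <- function(geometry, flow, clog) {
  stopifnot(inherits(clog, "tenpo_clog"))
  velocity_field(geometry, flow, clog)
}

# numeric flux through the horizontal plane at height z (for invariants)
plane_flux <- function(field, z, r_max = NULL, n = 4000) {
  g <- field$geometry
  if (is.null(r_max)) r_max <- g$unit_cell_radius
  # midpoint rule in r^2 (uniform-area rings)
  u <- (seq_len(n) - 0.5) / n * r_max^2
  r <- sqrt(u)
  v <- field$vrz(r, rep(z, n))
  sum(v$vz) * pi * r_max^2 / n
}
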