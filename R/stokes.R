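# Numerical axisymmetric Stokes reference solver.
#
# Creeping axisymmetric flow satisfies E^4 psi = 0 for the Stokes stream
# function psi, with E^2 = d_rr - (1/r) d_r + d_zz.  The biharmonic problem
# is split into the coupled pair  E^2 psi = chi,  E^2 chi = 0,  discretized
# on a uniform node-centered (r, z) grid of the unit cell.  Boundary
# conditions: psi Dirichlet everywhere (axis 0, outer/membrane psi_w,
# uniform in/outflow profile psi_w r^2/Rc^2); chi = 0 on the axis, the
# shear-free outer boundary and the uniform in/outflow planes; on no-slip
# walls chi is set by Thom's condition chi_W = 2 (psi_P - psi_W) / h^2 and
# relaxed to convergence.  Both elliptic solves share one sparse LU
# factorization (Matrix), so each iteration costs two triangular solves.
#
# The pore wall and membrane faces are snapped to the nearest grid lines;
# an optional clog is included as the flux-equivalent annular obstruction
# (open radius sqrt(a^2 - rc^2) with a circular bump profile over |z| < rc).

#' Solve the axisymmetric Stokes problem on the pore unit cell
#'
#' @param geometry a [device_geometry()].
#' @param flow a [flow_condition()].
#' @param clog optional [clog_spec()] (axisymmetrized annular obstruction).
#' @param nr,nz grid cells in r and z (defaults 256 x 512; coarser grids are
#'   adequate for profile validation).
#' @param z_top,z_bottom domain extents above the membrane top face and
#'   below the membrane bottom face (m); default max(3 um, 2d).
#' @param tol convergence tolerance on the relative stream-function update.
#' @param maxit maximum Thom iterations.
#' @param relax under-relaxation factor for the wall vorticity.
#' @return object of class `tenpo_velocity_field` (discrete) with bilinear
#'   `vrz` interpolation, the grids, the converged residual, and the
#'   dissipation-based pressure drop `delta_p`.
#' @export
solve_axisymmetric_stokes <- function(geometry, flow, clog = NULL,
                                      nr = 256, nz = 512,
                                      z_top = NULL, z_bottom = NULL,
                                      tol = 1e-8, maxit = 4000,
                                      relax = 0.2) {
  stopifnot(inherits(geometry, "tenpo_geometry"), inherits(flow, "tenpo_flow"))
  a <- geometry$pore_radius
  Rc <- geometry$unit_cell_radius
  L <- geometry$membrane_thickness
  d <- geometry$pore_diameter
  if (is.null(z_top)) z_top <- max(3e-6, 2 * d)
  if (is.null(z_bottom)) z_bottom <- max(3e-6, 2 * d)
  q1 <- if (is.finite(flow$per_pore_flux %||% NA_real_)) flow$per_pore_flux else
    flow$volumetric_flow_rate / pore_count(geometry)
  psi_w <- -q1 / (2 * pi)

  hr <- Rc / nr
  r <- seq(0, Rc, by = hr)
  # snap membrane faces to grid lines
  hz0 <- (z_top + L + z_bottom) / nz
  n_top <- max(2L, round(z_top / hz0))
  n_mem <- max(3L, round(L / hz0))
  n_bot <- max(2L, round(z_bottom / hz0))
  hz <- L / n_mem
  z <- seq(-L - n_bot * hz, n_top * hz, by = hz)
  nzv <- length(z); nrv <- length(r)
  ia <- which.min(abs(r - a))          # pore-wall grid line
  a_g <- r[ia]
  j0 <- which.min(abs(z - 0))          # membrane top face line
  jL <- which.min(abs(z + L))          # membrane bottom face line

  # solid mask (TRUE = solid)
  R <- matrix(r, nrv, nzv)
  Z <- matrix(z, nrv, nzv, byrow = TRUE)
  solid <- (R >= a_g - hr / 2) & (Z <= z[j0] + hz / 2) & (Z >= z[jL] - hz / 2)
  if (!is.null(clog) && clog$clog_radius > 0) {
    rc <- clog$clog_radius
    ai <- clog$open_radius
    prof <- a_g - (a_g - ai) * sqrt(pmax(0, 1 - (Z / rc)^2))
    solid <- solid | (abs(Z) <= rc & R >= prof)
  }

  fluid <- !solid
  # unknowns: fluid nodes strictly inside the grid and not wall-adjacent
  # Dirichlet rows; boundary nodes of the rectangle are Dirichlet
  interior <- fluid
  interior[c(1, nrv), ] <- FALSE
  interior[, c(1, nzv)] <- FALSE
  # fluid nodes adjacent to solid remain unknowns; solid nodes adjacent to
  # fluid are Dirichlet walls
  idx <- matrix(0L, nrv, nzv)
  idx[interior] <- seq_len(sum(interior))
  nun <- sum(interior)

  # Dirichlet psi values on all non-unknown nodes
  psi_bc <- matrix(NA_real_, nrv, nzv)
  psi_bc[1, ] <- 0                                   # axis
  psi_bc[nrv, ] <- psi_w                             # outer symmetry boundary
  psi_bc[, nzv] <- psi_w * (r / Rc)^2                # inflow (uniform)
  psi_bc[, 1] <- psi_w * (r / Rc)^2                  # outflow (uniform)
  psi_bc[solid] <- psi_w                             # membrane + clog
  psi_bc[1, ] <- 0

  # chi Dirichlet: 0 on axis/outer/in/outflow, Thom value on walls (updated
  # in the iteration)
  chi_bc <- matrix(0, nrv, nzv)

  # assemble the E^2 operator over unknowns (5-point)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs_map <- list()   # contributions of Dirichlet neighbours
  un <- which(interior, arr.ind = TRUE)
  ri <- un[, 1]; zj <- un[, 2]
  rr <- r[ri]
  kk <- idx[un]
  add <- function(ki, kj, v) {
    ii <<- c(ii, ki); jj <<- c(jj, kj); xx <<- c(xx, v)
  }
  # coefficients
  cE <- 1 / hr^2 - 1 / (2 * rr * hr)   # east  (r + hr)
  cW <- 1 / hr^2 + 1 / (2 * rr * hr)   # west  (r - hr)
  cN <- rep(1 / hz^2, nun)             # z + hz
  cS <- rep(1 / hz^2, nun)             # z - hz
  cP <- rep(-2 / hr^2 - 2 / hz^2, nun)
  add(kk, kk, cP)
  bc_i <- integer(0); bc_j <- integer(0); bc_k <- integer(0); bc_c <- numeric(0)
  nb <- function(di, dj, cc) {
    ni <- ri + di; nj <- zj + dj
    lin <- cbind(ni, nj)
    nidx <- idx[lin]
    isun <- nidx > 0
    add(kk[isun], nidx[isun], cc[isun])
    # Dirichlet contribution
    w <- which(!isun)
    bc_i <<- c(bc_i, ni[w]); bc_j <<- c(bc_j, nj[w])
    bc_k <<- c(bc_k, kk[w]); bc_c <<- c(bc_c, cc[w])
  }
  nb(+1L, 0L, cE); nb(-1L, 0L, cW); nb(0L, +1L, cN); nb(0L, -1L, cS)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nun, nun))
  LU <- Matrix::lu(A)

  dirichlet_rhs <- function(vals) {
    b <- numeric(nun)
    contrib <- bc_c * vals[cbind(bc_i, bc_j)]
    tb <- tapply(contrib, bc_k, sum)
    b[as.integer(names(tb))] <- as.numeric(tb)
    -b
  }

  # wall nodes (Dirichlet psi nodes adjacent to an unknown) for Thom update
  wall <- (solid | col(R) == 1 | col(R) == nzv | row(R) == nrv) & !interior
  # identify, for each wall node, its fluid neighbours among unknowns
  wl <- which(wall & !is.na(psi_bc), arr.ind = TRUE)
  wall_pairs <- NULL
  for (sft in list(c(1, 0, hr), c(-1, 0, hr), c(0, 1, hz), c(0, -1, hz))) {
    ni <- wl[, 1] + sft[1]; nj <- wl[, 2] + sft[2]
    ok <- ni >= 1 & ni <= nrv & nj >= 1 & nj <= nzv
    ok[ok] <- idx[cbind(ni[ok], nj[ok])] > 0
    if (any(ok)) {
      wall_pairs <- rbind(wall_pairs,
                          cbind(wi = wl[ok, 1], wj = wl[ok, 2],
                                fi = ni[ok], fj = nj[ok], h = sft[3]))
    }
  }
  # only true no-slip walls get Thom values (solid surfaces); the rectangle
  # boundaries keep chi = 0
  is_noslip <- solid[cbind(wall_pairs[, 1], wall_pairs[, 2])]
  wall_pairs <- wall_pairs[is_noslip, , drop = FALSE]

  psi <- matrix(0, nrv, nzv)
  psi[!interior] <- psi_bc[!interior]
  psi[interior] <- psi_w * (R[interior] / Rc)^2
  chi <- matrix(0, nrv, nzv)
  chi_wall <- rep(0, nrow(wall_pairs))

  resid <- Inf
  it <- 0
  n_grow <- 0
  while (it < maxit && resid > tol) {
    it <- it + 1
    resid_prev <- resid
    # Thom wall vorticity from current psi
    thom <- 2 * (psi[cbind(wall_pairs[, 3], wall_pairs[, 4])] -
                   psi_bc[cbind(wall_pairs[, 1], wall_pairs[, 2])]) /
      wall_pairs[, 5]^2
    # average multiple fluid neighbours per wall node
    key <- (wall_pairs[, 1] - 1) * nzv + wall_pairs[, 2]
    mthom <- tapply(thom, key, mean)
    wall_chi_new <- as.numeric(mthom[match(key, as.integer(names(mthom)))])
    chi_wall <- (1 - relax) * chi_wall + relax * wall_chi_new
    chi_bc[] <- 0
    chi_bc[cbind(wall_pairs[, 1], wall_pairs[, 2])] <- chi_wall
    # solve E^2 chi = 0
    bchi <- dirichlet_rhs(chi_bc)
    chi_vec <- as.numeric(Matrix::solve(LU, bchi))
    chi[interior] <- chi_vec
    chi[!interior] <- chi_bc[!interior]
    # solve E^2 psi = chi
    bpsi <- dirichlet_rhs(psi_bc) + chi[interior]
    psi_new <- as.numeric(Matrix::solve(LU, bpsi))
    resid <- max(abs(psi_new - psi[interior])) / max(abs(psi_w), 1e-300)
    psi[interior] <- psi_new
    # back off the wall-vorticity relaxation if the iteration grows
    if (is.finite(resid_prev) && resid > resid_prev) {
      n_grow <- n_grow + 1
      if (n_grow >= 3 && relax > 0.02) {
        relax <- relax / 2
        n_grow <- 0
      }
    } else {
      n_grow <- 0
    }
    if (!is.finite(resid)) {
      stop(sprintf("Stokes solver diverged at iteration %d (residual %.3e); reduce `relax`", it, resid))
    }
  }
  if (resid > tol) {
    stop(sprintf("Stokes solver did not converge: residual %.3e after %d iterations (tol %.1e)",
                 resid, it, tol))
  }

  # velocities from psi by central differences
  vz <- matrix(0, nrv, nzv); vr <- matrix(0, nrv, nzv)
  i2 <- 2:(nrv - 1)
  vz[i2, ] <- (psi[i2 + 1, ] - psi[i2 - 1, ]) / (2 * hr) / r[i2]
  vz[1, ] <- 2 * psi[2, ] / hr^2          # axis limit of (1/r) dpsi/dr
  vz[nrv, ] <- (psi[nrv, ] - psi[nrv - 1, ]) / hr / r[nrv]
  j2 <- 2:(nzv - 1)
  vr[, j2] <- -(psi[, j2 + 1] - psi[, j2 - 1]) / (2 * hz) / pmax(R[, j2], hr / 4)
  vr[1, ] <- 0
  vz[solid] <- 0; vr[solid] <- 0

  interp <- function(M) {
    force(M)
    function(rq, zq) {
      rq <- pmin(pmax(rq, 0), max(r)); zq <- pmin(pmax(zq, min(z)), max(z))
      i <- pmin(pmax(findInterval(rq, r), 1L), nrv - 1L)
      j <- pmin(pmax(findInterval(zq, z), 1L), nzv - 1L)
      tr <- (rq - r[i]) / hr; tz <- (zq - z[j]) / hz
      (1 - tr) * (1 - tz) * M[cbind(i, j)] + tr * (1 - tz) * M[cbind(i + 1L, j)] +
        (1 - tr) * tz * M[cbind(i, j + 1L)] + tr * tz * M[cbind(i + 1L, j + 1L)]
    }
  }
  fvr <- interp(vr); fvz <- interp(vz)

  # dissipation-based pressure drop: Phi = int 2 mu e:e dV = dP * Q
  mu <- flow$viscosity
  err <- matrix(0, nrv, nzv); ezz <- matrix(0, nrv, nzv)
  ethth <- matrix(0, nrv, nzv); erz <- matrix(0, nrv, nzv)
  err[i2, ] <- (vr[i2 + 1, ] - vr[i2 - 1, ]) / (2 * hr)
  ezz[, j2] <- (vz[, j2 + 1] - vz[, j2 - 1]) / (2 * hz)
  ethth[i2, ] <- vr[i2, ] / r[i2]
  ethth[1, ] <- err[1, ]
  erz[i2, j2] <- 0.5 * ((vr[i2, j2 + 1] - vr[i2, j2 - 1]) / (2 * hz) +
                          (vz[i2 + 1, j2] - vz[i2 - 1, j2]) / (2 * hr))
  diss <- 2 * mu * (err^2 + ezz^2 + ethth^2 + 2 * erz^2)
  phi_d <- sum(diss * 2 * pi * R) * hr * hz
  delta_p <- if (q1 > 0) phi_d / q1 else 0

  fld <- list(geometry = geometry, flow = flow, clog = clog,
              per_pore_flux = q1, psi_w = psi_w,
              mean_pore_velocity = q1 / (pi * a^2),
              r = r, z = z, psi = psi, chi = chi,
              solid = solid, residual = resid, iterations = it,
              delta_p = delta_p,
              vrz = function(rq, zq) list(vr = fvr(rq, zq), vz = fvz(rq, zq)),
              type = "stokes")
  class(fld) <- "tenpo_velocity_field"
  fld$v3 <- function(points) evaluate_velocity(fld, points)
  fld
}
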