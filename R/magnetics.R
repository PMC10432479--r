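# Magnetostatics of a saturated NiFe film pierced by a cylindrical pore in a
# uniform vertical external field.
#
# An infinite film uniformly magnetized along its normal produces no field
# outside itself (and none inside either, in B), so by Babinet superposition
# the stray field of the pierced film equals MINUS the field of a uniformly
# magnetized disk filling the pore.  The disk field is evaluated with the
# exact solenoid-equivalent closed form (generalized complete elliptic
# integrals, Bulirsch's cel); its spatial derivatives follow from the
# end-loop identity d/dz B_solenoid = mu0 M [b_loop(z - z_bot) -
# b_loop(z - z_top)] together with curl B = 0 and div B = 0 away from the
# film surface, so the gradient of |B|^2 is fully analytic.
#
# Coordinates: membrane top face at z = 0, NiFe film occupying
# -t <= z <= 0 for r >= a (a = pore radius), flow arriving from z > 0.

#' Magnetic drive and film model
#'
#' @param external_field uniform vertical external flux density (T or unit
#'   string).  The headline NdFeB drive is 0.4 T.
#' @param applied_H alternative drive given as a field strength (A/m); used
#'   only when `drive = "H"`, in which case the external flux density is
#'   mu0 * applied_H (341,000 A/m gives ~0.43 T).
#' @param drive `"B"` (default) to drive with `external_field`, `"H"` to
#'   drive with `applied_H`.
#' @param film_saturation saturation magnetization of the NiFe film (A/m or
#'   unit string).  Default 6.29e5 A/m, the A/m equivalent of the film's
#'   ~7900 Gauss saturation (mu0 Ms ~ 0.79 T).
#' @param film_thickness NiFe film thickness (default 200 nm).
#' @return object of class `tenpo_magnet`.
#' @export
magnetic_environment <- function(external_field = "0.4 T",
                                 applied_H = "341000 A/m",
                                 drive = c("B", "H"),
                                 film_saturation = "6.29e5 A/m",
                                 film_thickness = "200 nm") {
  drive <- match.arg(drive)
  b_ext <- parse_quantity(external_field, "flux_density")
  h_app <- parse_quantity(applied_H, "field_strength")
  if (drive == "H") b_ext <- MU0 * h_app
  ms <- parse_quantity(film_saturation, "field_strength")
  tf <- parse_quantity(film_thickness, "length")
  if (b_ext <= 0) stop("external field must be > 0")
  if (ms < 0) stop("film_saturation must be >= 0")
  if (tf <= 0) stop("film_thickness must be > 0")
  env <- list(B_ext = b_ext, applied_H = h_app, drive = drive,
              film_saturation = ms, film_thickness = tf)
  class(env) <- "tenpo_magnet"
  env
}

#' @export
print.tenpo_magnet <- function(x, ...) {
  cat(sprintf("Magnetic environment: B_ext = %.3g T (%s drive), Ms = %.3g A/m, film %.0f nm\n",
              x$B_ext, x$drive, x$film_saturation, x$film_thickness * 1e9))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Bulirsch's generalized complete elliptic integral cel(kc, p, c, s),
# vectorized.  Algorithm of Bulirsch (1969); all four arguments recycle.
bulirsch_cel <- function(kc, p, c, s, tol = 1e-12) {
  n <- max(length(kc), length(p), length(c), length(s))
  kc <- rep_len(as.numeric(kc), n); p <- rep_len(as.numeric(p), n)
  c <- rep_len(as.numeric(c), n);  s <- rep_len(as.numeric(s), n)
  k <- abs(kc)
  bad <- (k == 0)
  k[bad] <- NA_real_
  em <- rep(1, n)
  pp <- p; cc <- c; ss <- s
  neg <- p <= 0
  if (any(neg)) {
    f <- kc[neg]^2
    q <- 1 - f
    g <- 1 - pp[neg]
    f <- f - pp[neg]
    q <- q * (ss[neg] - c[neg] * pp[neg])
    pp[neg] <- sqrt(f / g)
    cc[neg] <- (c[neg] - ss[neg]) / g
    ss[neg] <- -q / (g^2 * pp[neg]) + cc[neg] * pp[neg]
  }
  pos <- !neg
  if (any(pos)) {
    pp[pos] <- sqrt(p[pos])
    ss[pos] <- s[pos] / pp[pos]
  }
  f <- cc
  cc <- cc + ss / pp
  g <- k / pp
  ss <- 2 * (ss + f * g)
  pp <- g + pp
  g <- em
  em <- k + em
  kk <- k
  for (iter in seq_len(80)) {
    if (all(is.na(k) | abs(g - k) <= g * tol)) break
    k <- 2 * sqrt(kk)
    kk <- k * em
    f <- cc
    cc <- cc + ss / pp
    g2 <- kk / pp
    ss <- 2 * (ss + f * g2)
    pp <- g2 + pp
    g <- em
    em <- k + em
  }
  out <- (pi / 2) * (ss + cc * em) / (em * (em + pp))
  out[bad] <- NaN
  out
}

# ---------------------------------------------------------------------------
# Field of a circular current loop of radius a at z = 0, per unit (mu0 I),
# cylindrical components; vectorized over (r, z).  Used for the analytic
# z-derivatives of the disk field and as a quadrature kernel in tests.
loop_field <- function(r, z, a) {
  n <- max(length(r), length(z))
  r <- rep_len(as.numeric(r), n); z <- rep_len(as.numeric(z), n)
  Q <- (a + r)^2 + z^2
  m <- 4 * a * r / Q
  m <- pmin(m, 1 - 1e-15)
  ke <- pracma::ellipke(m)
  K <- ke$k; E <- ke$e
  den <- (a - r)^2 + z^2
  Bz <- (K + E * (a^2 - r^2 - z^2) / den) / (2 * pi * sqrt(Q))
  Br <- numeric(n)
  off <- r > 0
  Br[off] <- z[off] / (2 * pi * r[off] * sqrt(Q[off])) *
    (-K[off] + E[off] * (a^2 + r[off]^2 + z[off]^2) / den[off])
  list(Br = Br, Bz = Bz)
}

# ---------------------------------------------------------------------------
# Field of a uniformly axially magnetized disk (radius a, occupying
# z in [z_bot, z_top], magnetization Ms along +z), via the equivalent
# solenoid closed form (Derby & Olbert).  Vectorized over (r, z).
disk_field <- function(r, z, a, Ms, z_bot, z_top) {
  n <- max(length(r), length(z))
  r <- rep_len(as.numeric(r), n); z <- rep_len(as.numeric(z), n)
  b <- (z_top - z_bot) / 2
  zz <- z - (z_top + z_bot) / 2
  B0 <- MU0 * Ms / pi
  zp <- zz + b; zm <- zz - b
  sp <- sqrt(zp^2 + (r + a)^2); sm <- sqrt(zm^2 + (r + a)^2)
  ap <- a / sp; am <- a / sm
  bp <- zp / sp; bm <- zm / sm
  g <- (a - r) / (a + r)
  kp <- sqrt((zp^2 + (a - r)^2) / (zp^2 + (a + r)^2))
  km <- sqrt((zm^2 + (a - r)^2) / (zm^2 + (a + r)^2))
  Br <- B0 * (ap * bulirsch_cel(kp, 1, 1, -1) - am * bulirsch_cel(km, 1, 1, -1))
  Bz <- B0 * a / (a + r) *
    (bp * bulirsch_cel(kp, g^2, 1, g) - bm * bulirsch_cel(km, g^2, 1, g))
  list(Br = Br, Bz = Bz)
}

# Analytic derivatives of the disk field.  d/dz from the end-loop identity,
# d/dr from curl B = 0 and div B = 0 (valid off the solenoid sheet r = a,
# z in [z_bot, z_top], which lies inside the solid film).
disk_field_grad <- function(r, z, a, Ms, z_bot, z_top) {
  n <- max(length(r), length(z))
  r <- rep_len(as.numeric(r), n); z <- rep_len(as.numeric(z), n)
  lb <- loop_field(r, z - z_bot, a)
  lt <- loop_field(r, z - z_top, a)
  s <- MU0 * Ms
  dBrdz <- s * (lb$Br - lt$Br)
  dBzdz <- s * (lb$Bz - lt$Bz)
  dBzdr <- dBrdz                      # curl-free
  f <- disk_field(r, z, a, Ms, z_bot, z_top)
  dBrdr <- numeric(n)
  off <- r > max(a * 1e-9, 1e-15)
  dBrdr[off] <- -f$Br[off] / r[off] - dBzdz[off]
  dBrdr[!off] <- -dBzdz[!off] / 2     # axis limit from div B = 0
  list(Br = f$Br, Bz = f$Bz,
       dBrdr = dBrdr, dBrdz = dBrdz, dBzdr = dBzdr, dBzdz = dBzdz)
}

#' On-axis flux density of a uniformly magnetized cylinder
#'
#' Closed form for the axial field of a cylinder of radius `radius` and
#' height `thickness`, uniformly magnetized along its axis with
#' magnetization `Ms`, evaluated on the axis at height `z` from the cylinder
#' midplane: Bz = (mu0 Ms / 2) ((z + t/2)/sqrt((z + t/2)^2 + R^2) -
#' (z - t/2)/sqrt((z - t/2)^2 + R^2)).
#'
#' @param Ms magnetization (A/m).
#' @param radius cylinder radius (m).
#' @param thickness cylinder height (m).
#' @param z axial position(s) from the midplane (m).
#' @return axial flux density in T (vectorized over `z`).
#' @export
disk_axial_field <- function(Ms, radius, thickness, z) {
  if (radius <= 0 || thickness <= 0) stop("radius and thickness must be > 0")
  zp <- z + thickness / 2
  zm <- z - thickness / 2
  MU0 * Ms / 2 * (zp / sqrt(zp^2 + radius^2) - zm / sqrt(zm^2 + radius^2))
}

# internal: solid-film test (NiFe layer only; the non-magnetic backing is
# geometrically solid but magnetically inert)
in_film <- function(r, z, geometry, env) {
  (r >= geometry$pore_radius) & (z <= 0) & (z >= -env$film_thickness)
}

# internal cylindrical-component field of the pierced film + external drive
pore_field_rz <- function(r, z, env, geometry) {
  a <- geometry$pore_radius
  t <- env$film_thickness
  d <- disk_field(r, z, a, env$film_saturation, z_bot = -t, z_top = 0)
  list(Br = -d$Br, Bz = env$B_ext - d$Bz)
}

# internal: cylindrical components of grad |B|^2 (analytic)
grad_B2_rz <- function(r, z, env, geometry) {
  a <- geometry$pore_radius
  t <- env$film_thickness
  g <- disk_field_grad(r, z, a, env$film_saturation, z_bot = -t, z_top = 0)
  Btr <- -g$Br
  Btz <- env$B_ext - g$Bz
  gr <- 2 * (g$Br * g$dBrdr - Btz * g$dBzdr)
  gz <- 2 * (g$Br * g$dBrdz - Btz * g$dBzdz)
  list(gr = gr, gz = gz, Br = Btr, Bz = Btz)
}

as_points <- function(position) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3, byrow = TRUE)
  if (ncol(p) != 3) stop("positions must be 3-vectors or an n x 3 matrix")
  p
}

#' Magnetic flux density near a magnetic nanopore
#'
#' Total field B = uniform external drive + stray field of the pierced,
#' saturated NiFe film, computed by Babinet superposition (an infinite
#' axially magnetized sheet contributes nothing outside itself, so the
#' pierced film's stray field is minus the field of a magnetized disk
#' filling the pore).  Axisymmetric; the membrane top face is at z = 0 with
#' the film occupying -film_thickness <= z <= 0.
#'
#' @param position a 3-vector (x, y, z) in m, or an n x 3 matrix.
#' @param env a [magnetic_environment()].
#' @param geometry a [device_geometry()].
#' @return n x 3 matrix of flux density components (T).
#' @export
pore_field <- function(position, env, geometry) {
  p <- as_points(position)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  z <- p[, 3]
  if (any(in_film(r, z, geometry, env))) {
    stop("position inside the magnetic film solid")
  }
  f <- pore_field_rz(r, z, env, geometry)
  out <- cbind(Bx = 0, By = 0, Bz = f$Bz)
  off <- r > 0
  out[off, 1] <- f$Br[off] * p[off, 1] / r[off]
  out[off, 2] <- f$Br[off] * p[off, 2] / r[off]
  out
}

#' Gradient of |B|^2 near a magnetic nanopore
#'
#' The magnetophoretic drive vector: grad |B|^2 evaluated analytically
#' (exact derivatives of the closed-form disk field via the end-loop
#' identity), or by central differences for cross-checking.
#'
#' @inheritParams pore_field
#' @param method `"analytic"` (default) or `"numeric"` (central differences).
#' @param step finite-difference step for `method = "numeric"` (m; must be
#'   <= 1 nm).
#' @return n x 3 matrix of grad |B|^2 components (T^2 / m).
#' @export
grad_B_squared <- function(position, env, geometry,
                           method = c("analytic", "numeric"),
                           step = 0.5e-9) {
  method <- match.arg(method)
  p <- as_points(position)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  z <- p[, 3]
  if (any(in_film(r, z, geometry, env))) {
    stop("position inside the magnetic film solid")
  }
  if (method == "analytic") {
    g <- grad_B2_rz(r, z, env, geometry)
    gr <- g$gr; gz <- g$gz
  } else {
    if (step > 1e-9) stop("central-difference step must be <= 1 nm")
    b2 <- function(rr, zz) {
      f <- pore_field_rz(rr, zz, env, geometry)
      f$Br^2 + f$Bz^2
    }
    gr <- (b2(r + step, z) - b2(pmax(r - step, 0), z)) /
      (step + pmin(r, step))
    gz <- (b2(r, z + step) - b2(r, z - step)) / (2 * step)
  }
  out <- cbind(gx = 0, gy = 0, gz = gz)
  off <- r > 0
  out[off, 1] <- gr[off] * p[off, 1] / r[off]
  out[off, 2] <- gr[off] * p[off, 2] / r[off]
  out
}

# ---------------------------------------------------------------------------
# Cached field interpolant.  Tensor-product (r, z) grid graded towards the
# pore rim (minimum spacing `h_min` at r = a and at the film faces z = 0,
# z = -t, growing geometrically outward), holding grad |B|^2 and the field
# components for bilinear interpolation during particle tracking.

# graded 1-D mesh from x0 covering [x0, x0 + span] with spacing growing
# geometrically from h0 (capped at h_max); returned sorted ascending
graded_seq <- function(x0, span, h0, ratio = 1.06, h_max = Inf) {
  if (span <= 0) return(numeric(0))
  xs <- numeric(0)
  x <- 0
  h <- h0
  while (x < span) {
    x <- min(x + h, span)
    xs <- c(xs, x)
    h <- min(h * ratio, h_max)
  }
  x0 + xs
}

#' Build a cached interpolation grid of the magnetophoretic drive field
#'
#' Precomputes grad |B|^2 (and the field components) on a tensor (r, z) grid
#' graded towards the pore rim, with minimum node spacing `h_min` (default
#' 2 nm) at the rim growing geometrically away from it.  Particle tracking
#' interpolates bilinearly from this cache; direct evaluation remains
#' available through [grad_B_squared()].
#'
#' @param env a [magnetic_environment()].
#' @param geometry a [device_geometry()].
#' @param r_max,z_top,z_bottom domain extents (defaults cover the tracking
#'   unit cell).
#' @param h_min minimum node spacing at the rim (m).
#' @param ratio geometric growth factor of the spacing away from the rim.
#' @return object of class `tenpo_field_cache`.
#' @export
build_field_cache <- function(env, geometry,
                              r_max = NULL, z_top = NULL, z_bottom = NULL,
                              h_min = 2e-9, ratio = 1.06) {
  a <- geometry$pore_radius
  d <- geometry$pore_diameter
  t <- env$film_thickness
  L <- geometry$membrane_thickness
  if (is.null(r_max)) r_max <- 1.05 * max(geometry$unit_cell_radius, sqrt(2) * d)
  if (is.null(z_top)) z_top <- max(3.5e-6, 2.2 * d)
  if (is.null(z_bottom)) z_bottom <- -(L + max(3e-6, 2 * d))
  h_cap <- max(d / 40, 25e-9)
  rg <- sort(unique(c(0, a,
                      a - graded_seq(0, a, h_min, ratio, h_cap),
                      a + graded_seq(0, r_max - a, h_min, ratio, h_cap))))
  rg <- rg[rg >= 0 & rg <= r_max]
  zg <- sort(unique(c(0, -t,
                      graded_seq(0, z_top, h_min, ratio, h_cap),
                      -t - graded_seq(0, -z_bottom - t, h_min, ratio, h_cap),
                      seq(-t, 0, length.out = 41))))
  zg <- zg[zg >= z_bottom & zg <= z_top]
  # The closed form is evaluable everywhere except on the equivalent
  # solenoid sheet (r = a, -t <= z <= 0, inside the solid film wall); nudge
  # those nodes just into the pore so every grid value is finite.  Values at
  # nodes strictly inside the solid are finite but never queried: fluid
  # queries stop at the capture surface one complex radius away.
  R <- matrix(rg, nrow = length(rg), ncol = length(zg))
  Z <- matrix(zg, nrow = length(rg), ncol = length(zg), byrow = TRUE)
  eps <- h_min / 4
  Re <- R
  sheet <- abs(R - a) < eps / 2 & Z <= 0 & Z >= -t
  Re[sheet] <- a - eps
  g <- grad_B2_rz(as.numeric(Re), as.numeric(Z), env, geometry)
  shape <- dim(R)
  cache <- list(
    r = rg, z = zg,
    gr = matrix(g$gr, shape[1], shape[2]),
    gz = matrix(g$gz, shape[1], shape[2]),
    Br = matrix(g$Br, shape[1], shape[2]),
    Bz = matrix(g$Bz, shape[1], shape[2]),
    env = env, geometry = geometry,
    h_min = h_min, ratio = ratio
  )
  class(cache) <- "tenpo_field_cache"
  cache
}

#' @export
print.tenpo_field_cache <- function(x, ...) {
  cat(sprintf("Cached magnetophoretic field grid: %d x %d nodes, r <= %.3g um, z in [%.3g, %.3g] um\n",
              length(x$r), length(x$z), max(x$r) * 1e6,
              min(x$z) * 1e6, max(x$z) * 1e6))
  invisible(x)
}

# bilinear interpolation on the (possibly non-uniform) tensor grid;
# vectorized over query points
interp_cache <- function(cache, r, z) {
  rg <- cache$r; zg <- cache$z
  nr <- length(rg); nz <- length(zg)
  # outside the cached domain the stray field has decayed: zero gradient
  outside <- r > rg[nr] | z < zg[1] | z > zg[nz]
  r <- pmin(pmax(r, rg[1]), rg[nr])
  z <- pmin(pmax(z, zg[1]), zg[nz])
  i <- pmin(pmax(findInterval(r, rg), 1L), nr - 1L)
  j <- pmin(pmax(findInterval(z, zg), 1L), nz - 1L)
  tr <- (r - rg[i]) / (rg[i + 1L] - rg[i])
  tz <- (z - zg[j]) / (zg[j + 1L] - zg[j])
  blend <- function(M) {
    i00 <- cbind(i, j); i10 <- cbind(i + 1L, j)
    i01 <- cbind(i, j + 1L); i11 <- cbind(i + 1L, j + 1L)
    (1 - tr) * (1 - tz) * M[i00] + tr * (1 - tz) * M[i10] +
      (1 - tr) * tz * M[i01] + tr * tz * M[i11]
  }
  out <- list(gr = blend(cache$gr), gz = blend(cache$gz),
              Br = blend(cache$Br), Bz = blend(cache$Bz))
  if (any(outside)) {
    out$gr[outside] <- 0
    out$gz[outside] <- 0
  }
  out
}
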