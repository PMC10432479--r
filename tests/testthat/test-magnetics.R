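# Oracles: the magnetized-disk closed form is checked against direct
# numerical quadrature (surface-charge / current-loop integrals built from
# an independent kernel), and the analytic gradient against central
# differences.

quad_disk_field <- function(r, z, a, Ms, z_bot, z_top) {
  # z'-quadrature of circular-loop fields over the equivalent solenoid
  br <- integrate(function(zp) tenposim:::loop_field(r, z - zp, a)$Br,
                  z_bot, z_top, rel.tol = 1e-11)$value
  bz <- integrate(function(zp) tenposim:::loop_field(r, z - zp, a)$Bz,
                  z_bot, z_top, rel.tol = 1e-11)$value
  mu0 <- 4e-7 * pi
  c(Br = mu0 * Ms * br, Bz = mu0 * Ms * bz)
}

test_that("on-axis disk field matches the surface-charge quadrature oracle", {
  Ms <- 6.29e5; a <- 1.5e-6; t <- 200e-9
  # on-axis field of a charged disk (magnetic surface charge +/- Ms on the
  # end faces), integrated over rings: independent oracle
  ring_on_axis <- function(zrel, a) {
    integrate(function(rp) {
      rp * zrel / (rp^2 + zrel^2)^1.5 / 2
    }, 0, a, rel.tol = 1e-12)$value
  }
  mu0 <- 4e-7 * pi
  for (z in c(0.5e-6, 0.2e-6, 2e-6, -1.2e-6)) {
    # + charge on the face at +t/2, - charge on the face at -t/2
    oracle <- mu0 * Ms * (ring_on_axis(z - t / 2, a) - ring_on_axis(z + t / 2, a))
    expect_equal(disk_axial_field(Ms, a, t, z), oracle, tolerance = 1e-6)
  }
  # unmagnetized: zero
  expect_equal(disk_axial_field(0, a, t, 0.5e-6), 0)
  # dipole far field: decays as |z|^-3
  z1 <- 50e-6; z2 <- 100e-6
  ratio <- disk_axial_field(Ms, a, t, z1) / disk_axial_field(Ms, a, t, z2)
  expect_equal(ratio, (z2 / z1)^3, tolerance = 0.01)
})

test_that("off-axis disk field matches the loop-quadrature oracle to 1e-6", {
  Ms <- 6.29e5; a <- 1.5e-6; t <- 200e-9
  pts <- rbind(c(0.8e-6, 0.3e-6), c(1.45e-6, 0.1e-6),
               c(2.5e-6, -0.5e-6), c(1.6e-6, 0.05e-6), c(0.1e-6, 1e-6))
  for (k in seq_len(nrow(pts))) {
    f <- tenposim:::disk_field(pts[k, 1], pts[k, 2], a, Ms, -t, 0)
    q <- quad_disk_field(pts[k, 1], pts[k, 2], a, Ms, -t, 0)
    expect_equal(f$Br, unname(q["Br"]), tolerance = 1e-6)
    expect_equal(f$Bz, unname(q["Bz"]), tolerance = 1e-6)
  }
})

test_that("pore field obeys the Babinet identity and its limits", {
  env <- magnetic_environment()
  geom <- device_geometry("3 um", "2.12e6 cm^-2")
  t <- env$film_thickness
  # on the axis the total field is B_ext minus the disk axial field
  for (z in c(0.2e-6, 1e-6, -2e-6)) {
    B <- pore_field(c(0, 0, z), env, geom)
    expect_equal(unname(B[1, 3]),
                 env$B_ext - disk_axial_field(env$film_saturation,
                                              geom$pore_radius, t, z + t / 2),
                 tolerance = 1e-10)
    expect_equal(unname(B[1, 1]), 0)
  }
  # far from the pore the field is the uniform drive
  Bfar <- pore_field(c(0, 0, 60e-6), env, geom)
  expect_equal(unname(Bfar[1, ]), c(0, 0, env$B_ext), tolerance = 1e-3)
  # unmagnetized film: uniform drive everywhere
  env0 <- magnetic_environment(film_saturation = "0 A/m")
  B0 <- pore_field(rbind(c(1e-6, 0, 0.3e-6), c(0, 2e-6, -3e-6)), env0, geom)
  expect_equal(unname(B0), cbind(c(0, 0), c(0, 0), c(0.4, 0.4)))
  # positions inside the film solid are rejected
  expect_error(pore_field(c(2e-6, 0, -0.1e-6), env, geom), "film")
})

test_that("field is axisymmetric", {
  env <- magnetic_environment()
  geom <- device_geometry("1 um", "1.908e7 cm^-2")
  r <- 0.7e-6; z <- 0.25e-6
  th <- c(0, 0.7, 2.1, 4.4)
  P <- cbind(r * cos(th), r * sin(th), z)
  B <- pore_field(P, env, geom)
  Bmag <- sqrt(rowSums(B^2))
  Bz <- B[, 3]
  Brad <- B[, 1] * cos(th) + B[, 2] * sin(th)
  expect_equal(max(Bmag) - min(Bmag), 0, tolerance = 1e-15)
  expect_equal(max(Bz) - min(Bz), 0, tolerance = 1e-15)
  expect_equal(max(Brad) - min(Brad), 0, tolerance = 1e-18)
})

test_that("div B vanishes numerically", {
  env <- magnetic_environment()
  geom <- device_geometry("3 um", "2.12e6 cm^-2")
  h <- 0.5e-9
  pts <- rbind(c(1e-6, 0, 0.2e-6), c(1.45e-6, 0, 0.15e-6), c(0.3e-6, 0, -1e-6))
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    div <- 0
    for (i in 1:3) {
      dp <- rep(0, 3); dp[i] <- h
      div <- div + (pore_field(p + dp, env, geom)[1, i] -
                      pore_field(p - dp, env, geom)[1, i]) / (2 * h)
    }
    Bmag <- sqrt(sum(pore_field(p, env, geom)^2))
    expect_lt(abs(div), 1e-3 * Bmag / geom$pore_diameter)
  }
})

test_that("magnetophoretic traps sit at the pore edge for every diameter", {
  env <- magnetic_environment()
  for (d_um in c(0.6, 1, 3, 12)) {
    geom <- canonical_geometry(d_um)
    a <- geom$pore_radius
    r <- seq(0.2 * a, 2.5 * a, length.out = 300)
    f <- tenposim:::pore_field_rz(r, rep(50e-9, 300), env, geom)
    Bmag <- sqrt(f$Br^2 + f$Bz^2)
    r_max <- r[which.max(Bmag)]
    expect_lt(abs(r_max - a) / a, 0.35)
    expect_gt(max(Bmag), env$B_ext)   # a genuine trap above the drive field
  }
})

test_that("analytic grad |B|^2 matches central differences to 1e-4", {
  env <- magnetic_environment()
  geom <- device_geometry("3 um", "2.12e6 cm^-2")
  a <- geom$pore_radius
  pts <- rbind(c(a, 0, 100e-9),
               c(a - 300e-9, 0, 40e-9),
               c(a + 500e-9, 0, 200e-9),
               c(0.4 * a, 0, -2e-6))
  ga <- grad_B_squared(pts, env, geom)
  gn <- grad_B_squared(pts, env, geom, method = "numeric")
  for (k in seq_len(nrow(pts))) {
    expect_equal(ga[k, ], gn[k, ], tolerance = 1e-4)
  }
  # uniform field: zero gradient
  env0 <- magnetic_environment(film_saturation = "0 A/m")
  expect_equal(max(abs(grad_B_squared(c(1e-6, 0, 1e-6), env0, geom))), 0)
})

test_that("grad |B|^2 grows monotonically approaching the rim", {
  env <- magnetic_environment()
  geom <- device_geometry("3 um", "2.12e6 cm^-2")
  a <- geom$pore_radius
  s <- seq(500e-9, 100e-9, by = -25e-9)
  g <- tenposim:::grad_B2_rz(a + s, rep(50e-9, length(s)), env, geom)
  mag <- sqrt(g$gr^2 + g$gz^2)
  expect_true(all(diff(mag) > 0))
})

test_that("the cached interpolant reproduces direct evaluation", {
  env <- magnetic_environment()
  geom <- device_geometry("3 um", "2.12e6 cm^-2")
  fc <- build_field_cache(env, geom)
  a <- geom$pore_radius
  pts <- rbind(c(a - 200e-9, 0, 150e-9),
               c(a + 400e-9, 0, 300e-9),
               c(0.3e-6, 0, 2e-6),
               c(1e-6, 0, -2.5e-6))
  part <- particle_complex(15)
  Fc <- magnetophoretic_force(pts, part, fc)
  Fd <- magnetophoretic_force(pts, part, env, geom)
  for (k in seq_len(nrow(pts))) {
    expect_equal(unname(Fc[k, ]), unname(Fd[k, ]), tolerance = 0.02)
  }
})
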