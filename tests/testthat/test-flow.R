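test_that("semi-analytic field conserves flux through every plane", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)
  fld <- velocity_field(geom, fl)
  q1 <- fld$per_pore_flux
  for (z in c(3e-6, 1e-6, 0.2e-6, 0, -2.6e-6, -5.1e-6, -7e-6)) {
    expect_equal(plane_flux_test(fld, z, geom$unit_cell_radius) / (-q1), 1,
                 tolerance = 0.01)
  }
  # spec flux semantics: the device-flux field carries phi / N per cell
  expect_equal(q1 * pore_count(geom), fl$volumetric_flow_rate)
})

test_that("zero flow gives zero velocity everywhere", {
  geom <- canonical_geometry(3)
  fld <- velocity_field(geom, flow_condition(0, geometry = geom))
  v <- fld$vrz(c(0, 0.5e-6, 2e-6), c(1e-6, -2e-6, 0.5e-6))
  expect_equal(max(abs(c(v$vr, v$vz))), 0)
})

test_that("in-pore profile develops from the orifice shape to Poiseuille", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)
  fld <- velocity_field(geom, fl)
  Vz <- fl$mean_pore_velocity
  # developed centerline speed is twice the mean (Poiseuille peak factor)
  v_mid <- fld$vrz(0, -2.6e-6)$vz
  expect_equal(v_mid, -2 * Vz, tolerance = 1e-4)
  # mouth centerline is the slower orifice profile (1.5 x mean)
  v_mouth <- fld$vrz(0, -1e-9)$vz
  expect_equal(v_mouth, -1.5 * Vz, tolerance = 0.01)
})

test_that("no-slip holds on the membrane faces and pore wall", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)
  fld <- velocity_field(geom, fl)
  Vz <- fl$mean_pore_velocity
  a <- geom$pore_radius
  # velocity evaluated on the solid surfaces vanishes identically
  on_wall <- fld$vrz(c(a, 2e-6, 3e-6), c(-2e-6, 0, -5.2e-6))
  expect_equal(max(abs(c(on_wall$vr, on_wall$vz))), 0)
  # wall-adjacent probes (sub-nm standoff): |v| < 1e-3 Vz
  near <- fld$vrz(c(a - 0.2e-9, 2e-6), c(-2.6e-6, 0.3e-9))
  expect_lt(max(sqrt(near$vr^2 + near$vz^2)), 1e-3 * Vz)
})

test_that("near-wall tangential speed grows linearly with wall distance", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)
  fld <- velocity_field(geom, fl)
  a <- geom$pore_radius
  s <- seq(50e-9, 500e-9, by = 50e-9)
  vt <- abs(fld$vrz(a - s, rep(-2.6e-6, length(s)))$vz)
  fit <- stats::lm(vt ~ s)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(stats::coef(fit)[2], 0)
})

test_that("semi_analytic_velocity validates the domain", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)
  v <- semi_analytic_velocity(c(0, 0, 1e-6), geom, fl)
  expect_equal(dim(v), c(1L, 3L))
  expect_error(semi_analytic_velocity(c(50e-6, 0, 0), geom, fl), "domain")
})

test_that("clogged field: flux-equivalent constriction", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)
  base <- velocity_field(geom, fl)
  # zero clog radius is the unclogged field
  cl0 <- clog_spec(0, geom)
  f0 <- clogged_velocity_perturbation(geom, fl, cl0)
  r <- seq(0, 1.45e-6, length.out = 50)
  expect_equal(f0$vrz(r, rep(-0.5e-6, 50))$vz,
               base$vrz(r, rep(-0.5e-6, 50))$vz)
  # 800 nm clog: maximum in-pore speed rises by less than 50%
  cl8 <- clog_spec("800 nm", geom)
  f8 <- clogged_velocity_perturbation(geom, fl, cl8)
  grid_r <- seq(0, 1.49e-6, length.out = 400)
  vmax0 <- max(abs(base$vrz(grid_r, rep(0, 400))$vz))
  vmax8 <- max(abs(f8$vrz(grid_r, rep(0, 400))$vz))
  expect_gt(vmax8 / vmax0, 1)
  expect_lt(vmax8 / vmax0, 1.5)
  # flux conserved with the clog present
  for (z in c(1e-6, 0, -0.4e-6, -2.6e-6)) {
    expect_equal(plane_flux_test(f8, z, geom$unit_cell_radius) /
                   (-f8$per_pore_flux), 1, tolerance = 0.01)
  }
  # full occlusion rejected
  expect_error(clog_spec("1.6 um", geom), "occludes")
})
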