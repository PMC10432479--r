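test_that("release grid is 100 points at 3 um height spanning 2 d", {
  geom <- canonical_geometry(3)
  g <- release_grid(geom, map = FALSE)
  expect_equal(nrow(g), 100L)
  expect_true(all(g[, 3] == 3e-6))
  expect_equal(max(g[, 1]) - min(g[, 1]), 2 * geom$pore_diameter)
  expect_equal(max(g[, 2]) - min(g[, 2]), 2 * geom$pore_diameter)
  # the axisymmetrized grid fits in the circular unit cell
  gm <- release_grid(geom)
  expect_equal(nrow(gm), 100L)
  expect_true(all(sqrt(gm[, 1]^2 + gm[, 2]^2) <= geom$unit_cell_radius))
  # the equal-area map preserves the enclosed-area measure of each point
  raw_frac <- (2 * pmax(abs(g[, 1]), abs(g[, 2])) / geom$pore_pitch)^2
  map_frac <- (gm[, 1]^2 + gm[, 2]^2) / geom$unit_cell_radius^2
  expect_equal(sort(raw_frac), sort(map_frac), tolerance = 1e-10)
})

test_that("capture rate is deterministic and bit-identical across runs", {
  cr1 <- canonical_capture(3, 1)
  geom <- canonical_geometry(3)
  cr2 <- capture_rate(geom, canonical_flow(geom), particle_complex(1),
                      fcache = cached_field(3))
  expect_identical(cr1$R, cr2$R)
  expect_identical(cr1$status, cr2$status)
  expect_identical(cr1$positions, cr2$positions)
})

test_that("single-membrane chain equals the plain capture rate", {
  geom <- canonical_geometry(3)
  fl <- canonical_flow(geom)
  mm <- multi_membrane_capture(geom, fl, particle_complex(15), n = 1,
                               seed = 7, fcache = cached_field(3))
  expect_equal(mm$R_cum[1], canonical_capture(3, 15)$R)
})

test_that("cumulative capture is non-decreasing in membrane count", {
  geom <- canonical_geometry(3)
  fl <- canonical_flow(geom)
  for (nm in c(15, 1)) {
    mm <- multi_membrane_capture(geom, fl, particle_complex(nm), n = 4,
                                 seed = 11, fcache = cached_field(3))
    expect_true(all(diff(mm$R_cum) >= 0))
    expect_true(all(mm$R_cum >= 0 & mm$R_cum <= 1))
  }
})

test_that("homogenized chains follow the independent-pass closed form", {
  # with uniform-random release on every pass (position-homogenized), the
  # two-membrane cumulative capture matches 1 - (1 - p)^2 for the per-pass
  # probability p, within binomial sampling error over seeds
  geom <- canonical_geometry(3)
  fl <- canonical_flow(geom)
  fc <- cached_field(3)
  fld <- velocity_field(geom, fl)
  part <- particle_complex(15)
  half <- geom$pore_pitch / 2
  n_pts <- 60
  pass_capture <- function(seed) {
    set.seed(seed)
    xy <- tenposim:::square_to_disk(
      cbind(runif(n_pts, -half, half), runif(n_pts, -half, half)),
      geom$pore_pitch, geom$unit_cell_radius)
    res <- track_ensemble(cbind(xy, z = 3e-6), part, fld, fc, geom)
    mean(res$status == "captured")
  }
  p_hat <- mean(sapply(1:10, pass_capture))
  # simulate ten 2-pass homogenized chains
  chain2 <- sapply(11:20, function(s) {
    set.seed(s)
    caught <- 0; alive <- n_pts
    for (k in 1:2) {
      xy <- tenposim:::square_to_disk(
        cbind(runif(alive, -half, half), runif(alive, -half, half)),
        geom$pore_pitch, geom$unit_cell_radius)
      res <- track_ensemble(cbind(xy, z = 3e-6), part, fld, fc, geom)
      caught <- caught + sum(res$status == "captured")
      alive <- sum(res$status == "escaped")
      if (alive == 0) break
    }
    caught / n_pts
  })
  expected <- 1 - (1 - p_hat)^2
  se <- sqrt(expected * (1 - expected) / (n_pts * length(chain2)))
  expect_lt(abs(mean(chain2) - expected), 4 * se + 0.02)
})

test_that("force-ratio diagnostic separates tagging levels by one decade", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)  # device condition
  fr_s <- force_ratio_diagnostic(geom, fl, particle_complex(15))
  fr_w <- force_ratio_diagnostic(geom, fl, particle_complex(1))
  expect_equal(fr_s - fr_w, log10(8.9e-4 / 9e-5), tolerance = 1e-6)
  expect_gt(fr_s, fr_w)
  # unmagnetized film: sentinel
  env0 <- magnetic_environment(film_saturation = "0 A/m")
  expect_identical(force_ratio_diagnostic(geom, fl, particle_complex(15),
                                          env0), -Inf)
  expect_error(force_ratio_diagnostic(geom, fl, particle_complex(15),
                                      probe_distance = -1e-9), "fluid")
})

test_that("empty scan spec gives an empty result table", {
  tab <- scan_parameters(list())
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 0L)
})

test_that("occlusion experiment reproduces the redistribution estimates", {
  geom <- canonical_geometry(3)
  fl <- flow_condition("2.5 mL/h", geometry = geom)
  expect_equal(occlusion_array_experiment(0, geom, fl), 0)
  expect_equal(occlusion_array_experiment(4, geom, fl), 80, tolerance = 1e-6)
  incr1 <- occlusion_array_experiment(1, geom, fl)
  expect_gte(incr1, 11 - 2)
  expect_lte(incr1, 12.5 + 1e-6)
  incr <- sapply(0:4, occlusion_array_experiment, geometry = geom, flow = fl)
  expect_true(all(diff(incr) > 0))
  expect_error(occlusion_array_experiment(9, geom, fl), "occlude")
})
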