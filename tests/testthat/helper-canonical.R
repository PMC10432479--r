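# Shared fixtures for the test suite: canonical geometries, flows and
# cached fields, built once per test run.

.tenpo_test_cache <- new.env(parent = emptyenv())

canonical_geometry <- function(d_um) {
  device_geometry(d_um * 1e-6, canonical_pore_density(d_um * 1e-6),
                  membrane_area = "2.5 cm^2")
}

canonical_flow <- function(geom, phi_mLh = 2.5,
                           convention = "inlet_velocity") {
  flow_condition(phi_mLh * 1e-6 / 3600, geometry = geom,
                 convention = convention)
}

cached_field <- function(d_um, env = magnetic_environment()) {
  key <- sprintf("fc_%g_%g_%g", d_um, env$B_ext, env$film_saturation)
  if (is.null(.tenpo_test_cache[[key]])) {
    .tenpo_test_cache[[key]] <- build_field_cache(env, canonical_geometry(d_um))
  }
  .tenpo_test_cache[[key]]
}

canonical_capture <- function(d_um, n_mnps, phi_mLh = 2.5, ...) {
  key <- sprintf("cr_%g_%g_%g", d_um, n_mnps, phi_mLh)
  if (is.null(.tenpo_test_cache[[key]])) {
    geom <- canonical_geometry(d_um)
    .tenpo_test_cache[[key]] <- capture_rate(
      geom, canonical_flow(geom, phi_mLh), particle_complex(n_mnps),
      fcache = cached_field(d_um), ...)
  }
  .tenpo_test_cache[[key]]
}

# numeric flux through the horizontal plane at height z for any field with
# a vrz evaluator (midpoint rule in r^2)
plane_flux_test <- function(field, z, r_max, n = 4000) {
  u <- (seq_len(n) - 0.5) / n * r_max^2
  r <- sqrt(u)
  v <- field$vrz(r, rep(z, n))
  sum(v$vz) * pi * r_max^2 / n
}
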