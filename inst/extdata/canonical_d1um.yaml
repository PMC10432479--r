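# Canonical single-condition run: d = 1 um pore at 2.5 mL/h on a 2.5 cm^2
# device, pore density chosen so the mean in-pore velocity matches the
# d = 3 um reference (constant-velocity diameter scaling).
label: canonical_d1um
geometry:
  pore_diameter: "1 um"
  pore_density: "1.908e7 cm^-2"
  membrane_area: "2.5 cm^2"
flow:
  volumetric_flow_rate: "2.5 mL/h"
  viscosity: "1e-3 Pa.s"
  convention: inlet_velocity
magnet:
  external_field: "0.4 T"
  film_saturation: "6.29e5 A/m"
  film_thickness: "200 nm"
particles:
  strong: {n_mnps: 15}
  weak: {n_mnps: 1}
seed: 1
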