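# Alpha-helical dispersive amide parameter family (H).
#
# Units and conventions as in OL.yaml. Relative to OL the helical family
# sits at a slightly higher oscillator wavenumber (calculations with it
# blue-shift predicted spectra). Dispersive values are approximate
# defaults in the literature range; verify against the primary
# dipole-interaction-model parameter papers before production use.
name: H
nu0: 54200.0        # ~184.5 nm
D: 1.80e+09
theta: -12.0
static_principal: [1.00, 0.70, 0.40]
isotropic:
  C_aliphatic: 0.878
  O_alcohol: 0.465
  H_aliphatic: 0.135
  H_alcohol: 0.135
  H_amide: 0.135
bandwidth: 6000
placement: o
include_static: true
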