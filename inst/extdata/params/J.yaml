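# Poly-L-proline II dispersive amide parameter family (J).
#
# Units and conventions as in OL.yaml. Relative to OL the PPII family
# sits at a lower oscillator wavenumber (calculations with it red-shift
# predicted spectra). Dispersive values are approximate defaults in the
# literature range; verify against the primary dipole-interaction-model
# parameter papers before production use.
name: J
nu0: 51900.0        # ~192.7 nm
D: 1.85e+09
theta: -6.0
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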