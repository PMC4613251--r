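# "Original" dispersive amide parameter family (OL) for the coupled-dipole
# CD model.
#
# Units: nu0 in cm^-1, D in Angstrom^3 cm^-2, theta in degrees (in the
# amide plane, from the N->C' axis toward the carbonyl-O side),
# polarizabilities in Angstrom^3, bandwidth in cm^-1.
#
# Provenance: the dispersive values below are approximate defaults in the
# range of the published dipole-interaction-model amide parameterizations
# (J. Applequist and co-workers); transcribe the exact values from the
# primary parameter papers before production use. The isotropic atom
# polarizabilities are the NaD-line atom values of Applequist, Carl &
# Fung (J. Am. Chem. Soc. 94, 2952 (1972)): C 0.878, O 0.465, H 0.135.
name: OL
nu0: 53200.0        # ~188 nm
D: 1.90e+09
theta: -9.1
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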