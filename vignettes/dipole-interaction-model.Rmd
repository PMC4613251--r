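---
title: "The coupled-dipole model behind dipolecd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled-dipole model behind dipolecd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipolecd)
```

## The model and its assumptions

`dipolecd` computes protein far-UV absorption and circular dichroism
from classical electromagnetic theory. The molecule is a collection of
polarizable points coupled through their induced dipole fields. Two
kinds of points exist:

* **Dispersive (chromophoric) points.** Each peptide amide N–C′–O group
  is one anisotropic point near the N–C′ bond midpoint. Its
  frequency-dependent part is a single Lorentzian oscillator for the
  π–π* transition, polarized along an in-plane direction θ measured from
  the N→C′ axis toward the carbonyl-oxygen side:
  $a(\bar\nu) = D / (\bar\nu_0^2 - \bar\nu^2 + i\Gamma\bar\nu)$.
  A frequency-independent symmetric residual tensor (principal values in
  the local amide frame) represents the rest of the amide
  polarizability; it lives in the nondispersive block and can be
  switched off (`include_static`).
* **Nondispersive points.** Treated aliphatic atoms — and hydrogens,
  when included — carry scalar polarizabilities fitted at the sodium-D
  line. Their dispersion across the far UV is neglected, which is the
  partially dispersive approximation: their natural frequencies lie far
  above the spectral window.

Assumptions inherited from this construction: only the amide π–π*
transition is dispersive (no n–π* band, so the 222 nm region of helical
spectra is not reproduced); aromatic and other side-chain chromophores
are absent, which is why non-aliphatic residues are mutated to alanine
(`alanize()`) before classification; ligands, metals, sulfur and
phosphorus are ignored; the point-dipole expansion requires
well-separated points, making the model sharply sensitive to bond
geometry — the reason inputs must be energy-minimized structures or
idealized rebuilt fragments, never raw crystal coordinates.

## From structure to spectrum

`classify_units()` finds one amide triad per peptide bond (q = p − 1
for a monomeric chain of p residues), assigns aliphatic C / alcohol O /
H species to isotropic points, and logs everything else with a reason.
`build_unit_set()` places the amide point (`o`, `x`, or `y` placement;
the shifted variants differ from the midpoint by exactly 0.1 Å), builds
the local orthonormal frame, and rotates the oscillator direction and
static tensor into the lab frame. `assemble()` constructs the
partitioned zero-frequency interaction matrix; `reduce_dispersive()`
eliminates the nondispersive block through a factorization of
$A^\circ_{22}$ (never an explicit inverse); `solve_modes()`
diagonalizes; `mode_moments()` and `compute_spectra()` produce
strengths and Lorentzian-sum spectra.

## Numerical choices

**Dimensional scaling of the eigenproblem.** The raw interaction matrix
mixes units: its dispersive diagonal is $\bar\nu_0^2/D$ (cm² Å⁻³) while
couplings are Å⁻³. The eigenproblem is therefore posed on
$G = S^{1/2} A_\mathrm{red} S^{1/2}$ with $S = \mathrm{diag}(D_{is})$,
whose entries are $\bar\nu_{is}^2$ plus $\sqrt{D_{is}D_{jt}}$-weighted
couplings. Its eigenvalues carry cm⁻² exactly, the isolated-oscillator
limit returns $\bar\nu_0$ identically, and for uniform $D$ the scaling
is a similarity transform of the plain Schur complement. The matching
$\sqrt{D}$ weights appear in the mode moments, where they again reduce
to unweighted sums for uniform $D$; `mode_moments(..., amplitudes =
"as-printed")` gives the literal unweighted form.

**Unit contract and the spectral prefactor.** Positions are Å,
polarizability volumes Å³, $D_{is}$ Å³ cm⁻², wavenumbers cm⁻¹. The
CGS conversions (10⁻²⁴ for $D_k$, 10⁻³² for $R_k$, whose magnetic arm
carries one extra length) are folded into the prefactors of the ε and
Δε sums. The constant 6909 = 3 × 2303 is read as containing the ⅓
orientational average, so the independent full-solve extinction uses
the full trace of the complex polarizability over three field
polarizations. Rather than trusting this bookkeeping, the test suite
pins it twice: the isolated oscillator must reproduce its analytic
Lorentzian exactly, and on purely dispersive systems with uniform Γ the
normal-mode sum must agree with the direct complex solve to better than
10⁻⁶ at every grid point. With the + iΓν̄ sign convention absorption
corresponds to a *negative* imaginary polarizability, which the
full-solve route negates.

**Moments over the dispersive subsystem.** Mode moments sum over the
dispersive oscillators only; the back-induced moments of nondispersive
points (dressed-projection corrections) are not added. Consequently the
full-solve equivalence is exact only for chromophore-only systems, and
`full_solve()` — which does retain the nondispersive block — doubles as
the diagnostic for how much that approximation matters on a given
structure.

**Contacts and degenerate modes.** Points closer than 0.5 Å are a hard
error (the point-dipole interaction diverges); separations under 1.5 Å
produce a warning — bonded hydrogens sit at ~1 Å, so hydrogen-bearing
runs always carry this notice. Non-positive eigenvalues
("long-wavelength modes", the model's signature of insufficiently
relaxed geometry) are retained and flagged, excluded from spectra with
a warning, and never silently dropped. Eigenvector signs are fixed
(largest-magnitude component positive) so dumped amplitudes are
byte-reproducible; $D_k$ and $R_k$ are sign-invariant.

**Euler angles.** The relative orientation of successive amide frames
is reported in the z-y-z convention with ψ = 0 at the gimbal points.
Only rotation matrices are used internally, so the convention affects
reporting alone; a reconstruction test holds it to 10⁻⁸.

## Tunable parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `nu0` | cm⁻¹ | 52 000–54 200 by family | π–π* oscillator wavenumber; sets band position |
| `D` | Å³ cm⁻² | ~1.9 × 10⁹ | oscillator strength; sets band intensity |
| `theta` | degrees | −6 to −12 by family | in-plane polarization direction; controls exciton coupling signs |
| `static_principal` | Å³ | (1.0, 0.7, 0.4) | residual amide tensor in the nondispersive block |
| `bandwidth` Γ | cm⁻¹ | 6000 | Lorentzian half-peak width; 4000 is the common alternative |
| `placement` | — | `o` | amide point at midpoint (`o`) or shifted 0.1 Å (`x`, `y`) |
| isotropic α | Å³ | C 0.878, O 0.465, H 0.135 | sodium-D-line atom polarizabilities |

Three editable YAML families ship under `inst/extdata/params` —
original (OL), α-helical (H, slightly blue-shifting), and
poly-L-proline II (J, red-shifting). Their dispersive numbers are
documented as approximate literature-range defaults to be verified
against the primary parameter papers; nothing in the test suite depends
on them — all quantitative tests run on synthetic parameter sets.

## The chain builder as synthetic-data generator

`build_chain()` places backbone atoms by natural extension from an
ideal internal-coordinate table (N–Cα 1.458, Cα–C′ 1.525, C′–N 1.329,
C′=O 1.231 Å and standard angles, all overridable), honoring the
supplied φ/ψ/ω exactly; ω defaults to 180° which forces exactly planar
trans amides. The first residue's φ is geometrically unused (the seed
frame fixes its carbonyl), and the last residue's ψ is recovered from
the carbonyl oxygen on rebuild, which makes
`rebuild_from_structure()` an exact fixed point on builder output.
Correctness rests on round-trip and planarity properties, not on the
particular ideal values: torsions measured from built coordinates equal
the inputs to 10⁻⁶ degrees, and an ideal α-helix (φ = −57°, ψ = −47°)
shows a 1.56 Å rise per residue by an independent principal-axis fit.

What the builder emulates: idealized secondary-structure geometry with
alanine side chains, the input the rebuilt-fragment route produces from
real structures. What it does not emulate: the coordinate noise,
side-chain diversity, solvent effects and crystal-contact distortions
of experimental structures. Green tests on builder fixtures therefore
validate the *machinery* — classification, reduction, spectra,
statistics — and the qualitative helical couplet, but say nothing about
quantitative agreement with measured spectra of real proteins, which
additionally hinges on literature parameter values and
energy-minimized coordinates.

The rebuild route measures backbone torsions per planned fragment
(retaining ω by default; `idealize_omega` flattens it), rebuilds each
fragment with ideal geometry, discards fragments that produce steric
collisions (worst offender first), and declares failure when more than
50% of the protein ends up ignored — mirroring the behavior of rebuild
pipelines on β-rich proteins, where accumulated ideal-geometry strain
produces clashes.

## Design choices where the design was open

* **Proline** amides are treated with the unmodified chromophore
  parameters (the N-alkylation is not reparameterized); a note is
  logged when prolines are present.
* **Static amide tensor**: included in the nondispersive block by
  default, sharing the chromophore's position but exempt from
  self-interaction; a config switch drops it, and on ideal-helix
  fixtures its effect on the spectrum is small.
* **Altloc resolution** keeps the highest-occupancy conformer,
  alphabetical on ties. **Chain breaks**: a peptide bond requires
  consecutive numbering and a C′–N distance under 2 Å.
* **Interpolation for comparison** is linear, and the experimental
  spectrum is resampled onto the calculated grid (never the reverse);
  RMSD follows the plain root-mean-square form over the 180–210 nm
  window, Spearman uses averaged ranks on ties.
* **Grids**: 175–250 nm at 1 nm for the direct route, 176–250 nm at
  2 nm for the rebuilt route.

## Problem sizes

The shipped tests and the acceptance script run on builder fixtures up
to 129 residues, random oscillator systems of ≤ 10 dispersive and ≤ 6
isotropic points (20–100 replicates per property), and dense
eigenproblems well under 200². These sizes were chosen because every
property being checked — sum rules, oracle equivalences, closed forms,
morphology — is size-independent, so small systems prove them as
decisively as protein-scale ones; a full protein (q ≈ 128, ~700
nondispersive points after the united-atom reduction) remains a
sub-minute dense solve.

## Known limitations

No n–π* band; no aromatic side-chain or charge-transfer transitions;
no solvent or vacuum-UV corrections; no frequency dependence of the
nondispersive polarizabilities; no mmCIF input; secondary-structure
fragments for the rebuild route are user input, not auto-detected. The
model's geometric sensitivity is intrinsic: feeding it unminimized
crystal coordinates typically yields flagged long-wavelength modes
rather than a usable spectrum.
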