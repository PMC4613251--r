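Package: dipolecd
Title: Dipole Interaction Model for Far-UV Circular Dichroism of Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical electromagnetic (coupled-dipole) calculation of
    protein absorption and circular dichroism spectra in the far
    ultraviolet. Amide chromophores are reduced to anisotropic polarizable
    points carrying a Lorentzian pi-pi* oscillator and aliphatic atoms to
    isotropic polarizable points; the coupled normal-mode eigenproblem is
    solved after Schur-complement elimination of the nondispersive block,
    yielding mode dipole and rotational strengths and Lorentzian-sum
    epsilon and delta-epsilon spectra per residue. Includes a PDB reader
    and writer built on bio3d, an idealized peptide-chain builder driven
    by backbone torsions, secondary-structure fragment rebuilding with a
    collision-based failure rule, and spectrum comparison statistics
    (windowed RMSD and Spearman rank correlation across proteins).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
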