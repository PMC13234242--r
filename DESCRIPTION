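Package: snntools
Title: Structural and Mass-Spectrometric Analysis of Asparagine-to-Succinimide Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing autocatalytic asparagine-to-succinimide (SNN)
    conversion in proteins. Reads and writes protein structures including the
    nonstandard SNN residue, computes backbone and side-chain torsions,
    contacts, hydrogen bonds, turns and iterative-outlier superpositions,
    scans Asn sites for the near-attack conformation that favours
    intramolecular cyclization, reconstructs metadynamics free-energy
    surfaces from hills files and extracts minimum-free-energy-path
    activation barriers, computes frame-wise trajectory statistics
    (distance distributions, hydrogen-bond occupancies, transition times),
    and provides the peptide/protein monoisotopic mass arithmetic behind
    mass-spectrometric quantification of SNN, intact-Asn and hydrolyzed
    populations (tryptic digestion, charge-state m/z, b/y fragment ions).
    Seed-deterministic generators build ideal-geometry peptides with
    prescribed torsions, hills streams on analytic surfaces with known
    barriers, and trajectories with scripted events, so every stage is
    testable against constructed ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
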