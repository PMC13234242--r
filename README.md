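# snntools

Structural and mass-spectrometric analysis of asparagine-to-succinimide
(SNN) conversion in proteins.

Asparagine residues deamidate through a cyclic succinimide intermediate:
the backbone amide N–H of the following (n+1) residue is deprotonated, the
nitrogen attacks the Asn side-chain carbonyl carbon (CG), and ammonia is
lost (−17.027 Da).  In most proteins the succinimide hydrolyses onward to
Asp/iso-Asp (+0.984 Da vs Asn); in some hyperthermophilic enzymes it is
stable and rigidifies the backbone.  Whether a given Asn converts is
controlled by its three-dimensional context — it must reach a
**near-attack conformation** (CG(n)–N(n+1) < 3.5 Å, with χ1 ≈ +120°,
χ2 ≈ ±90°, ψ ≈ −120° as indicative preferences) — and by neighbouring
side chains able to abstract the n+1 amide proton.

`snntools` is for structural biologists and modellers who need the
computational layers of this analysis as reusable, tested parts:

* **Structures** — PDB/mmCIF reading and writing with the nonstandard
  `SNN` residue kept in the chain at its author number; highest-occupancy
  altloc resolution.
* **Geometry** — IUPAC-signed torsions (φ/ψ/ω, χ1/χ2 including the SNN
  ring mapping), contacts at a distance cutoff, hydrogen bonds
  (distance-only for hydrogen-free crystals, distance+angle for MD
  frames), α/β-turn detection (i→i+4 / i→i+3 C=O⋯H–N), and Kabsch
  superposition with iterative outlier rejection (5 cycles, 2 × RMSD).
* **Site scanning** — `scan_asn_sites()` classifies every Asn/SNN residue
  by near-attack geometry and Ramachandran quadrant;
  `candidate_catalysts()` shortlists residues contacting the site within
  4 Å with structural role hints (direct-base / relay / electrostatic).
* **Metadynamics** — rational switching functions
  s(r) = (1−(r/r₀)⁶)/(1−(r/r₀)¹²), coordination-number collective
  variables with (+0.5, −0.5) combination (reactant (−0.5, −0.5), product
  (+0.5, +0.5)), upper-wall bias, PLUMED-style HILLS file IO, nontempered
  free-energy-surface reconstruction F(s) = −V(s), and
  minimum-free-energy-path barrier extraction (minimax cost on the
  8-connected grid; the activation barrier is a path-maximum quantity).
* **Trajectories** — distance series and 0.01 Å histograms (density and
  cumulative readings), hydrogen-bond occupancies (< 3.5 Å, > 140°),
  transition-time detection with a dwell window, state-point frame
  extraction.
* **Masses** — monoisotopic peptide/protein masses, modification registry
  (ammonia loss −17.0265, deamidation +0.9840, oxidation +15.9949,
  N-terminal acetyl +42.0106), tryptic digestion with missed cleavages and
  semi-specific mode, charge-state m/z, b/y fragment ions, and
  classification of deconvoluted masses into SNN (M−17) / intact (M) /
  hydrolyzed (M+1) populations.
* **Synthetic generators** — seed-deterministic peptide builder with
  prescribed torsions, metadynamics-like hills streams on analytic
  surfaces with exactly known saddle heights, and scripted trajectories;
  these give every layer a constructed ground truth.

## Worked example

Build a tetrapeptide whose Asn carries the side-chain torsions reported
for a deposited near-attack-like site (χ1 = 173.9°, χ2 = −99.6°,
φ = −129.3°, ψ = 148.6°), then scan it:

```r
library(snntools)

s <- build_peptide("ENDL",
                   phi  = c(NA, -129.3, -46.3, -120),
                   psi  = c(140, 148.6, -34.1, NA),
                   chi1 = c(NA, 173.9, NA, NA),
                   chi2 = c(NA, -99.6, NA, NA))
scan_asn_sites(s)
#>   chain resno resid   d_CG_N    phi   psi  chi1  chi2 psi_n1 quadrant
#> 1     A     2   ASN 3.022685 -129.3 148.6 173.9 -99.6  -34.1 top-left
#>   near_attack
#> 1        TRUE
```

The imposed torsions round-trip exactly, and the CG–N(n+1) distance lands
at 3.0 Å — the near-attack distance — without having been imposed: it is
a consequence of the site torsions.

On the mass side, the tryptic peptide spanning such a site (Val at n+1)
gives:

```r
mz(peptide_neutral_mass("VYVDKENVLFK"), 1)
#> [1] 1353.741
fragment_ions("VYVDKENVLFK")[c(7, 15), ]
#>    label series index       mz
#> 7     b7      b     7 848.4148
#> 15    y5      y     5 620.3766
peptide_neutral_mass("VYVDKENVLFK", "snn@7") -
  peptide_neutral_mass("VYVDKENVLFK")
#> [1] -17.02655
```

i.e. the singly protonated precursor at m/z 1353.74, the b7/y5 fragments
bracketing the site residue at 848.41 and 620.38, and the −17.027 Da
ammonia-loss shift that marks succinimide formation.

For the free-energy side, a two-basin surface with an exactly known saddle
is filled by a metadynamics-like walker and the barrier recovered from the
hills alone:

```r
spec <- double_well_surface(barrier = 5, width = 0.08)
surface_saddle(spec)            # exact: 5.0
h   <- gen_hills_on_surface(spec, n_hills = 20000, seed = 1, stride = 100)
fes <- reconstruct_fes(h, spacing = 0.02, estimator = "tail-average",
                       warn_uncovered = FALSE)
min_free_energy_path(fes, c(-0.4, -0.4), c(0.4, 0.4))$barrier
#> ~5 (within a few percent; deposition-granularity noise)
```

See the vignette (`vignettes/succinimide-analysis.Rmd`) for the models,
parameter meanings, estimator choices and limitations.

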