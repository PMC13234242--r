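---
title: "Analysing asparagine-to-succinimide conversion: geometry, free-energy surfaces and mass shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing asparagine-to-succinimide conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snntools)
```

## The problem

Asparagine residues deamidate spontaneously through a five-membered cyclic
imide, the succinimide (SNN): the backbone amide nitrogen of the following
(n+1) residue is deprotonated, attacks the Asn side-chain carbonyl carbon
(CG), and ammonia is lost (−17.027 Da).  The succinimide usually hydrolyses
on to Asp/iso-Asp (+0.984 Da relative to Asn), but in some
hyperthermophilic proteins it is stable and rigidifies the backbone,
raising thermal stability.  Whether a given Asn cyclizes is governed less
by sequence than by three-dimensional context: the site must reach a
"near-attack" conformation, and nearby side chains must be able to abstract
the n+1 amide proton.

`snntools` packages the computational layers of this analysis so that each
one can be run, and tested, in isolation:

1. **structure layer** — read/write PDB and mmCIF with the nonstandard SNN
   residue kept in the chain at its author number;
2. **geometry layer** — torsions, contacts at a cutoff, hydrogen bonds,
   alpha/beta turns, Kabsch superposition with iterative outlier rejection;
3. **site scan** — near-attack classification of every Asn/SNN site,
   Ramachandran quadrants, candidate internal catalysts from the contact
   network;
4. **metadynamics layer** — coordination-number collective variables,
   hills bookkeeping, free-energy-surface (FES) reconstruction, and
   minimum-free-energy-path (MFEP) barrier extraction;
5. **trajectory layer** — distance distributions, hydrogen-bond
   occupancies, transition detection, state-point extraction;
6. **mass layer** — monoisotopic peptide/protein masses, modification
   shifts, tryptic digestion, charge-state m/z, b/y fragments, and
   SNN (M−17) / intact (M) / hydrolyzed (M+1) population assignment;
7. **synthetic generators** — seed-deterministic constructions with known
   ground truth for every input class above.

## Near-attack geometry

The near-attack conformation positions CG of the Asn for intramolecular
attack: the criterion is a CG(n) to backbone-N(n+1) distance below 3.5 Å,
with indicative angular preferences (χ1 ≈ +120°, χ2 ≈ ±90°, ψ ≈ −120°).
The distance is measured to the heavy backbone nitrogen, not the amide
hydrogen, because crystal structures carry no hydrogens.

Which angular criteria are *necessary* is genuinely unsettled: a
double-mutant structure whose site geometry is called near-attack-like has
χ1 = 173.9° and χ2 = −99.6°, far from the χ1 center yet within 40° of the
−90° χ2 center.  The package therefore treats the distance as mandatory
and the angular checks as configuration: `near_attack_criteria(required =
...)` selects which angles gate the verdict (default: none; every angle is
still evaluated and reported as evidence).  The default angular tolerance
of ±40° (circular) is chosen exactly so that the "distance + χ2" mode
admits that deposited double-mutant geometry; strict mode
(`required = c("chi1", "chi2", "psi")`) remains available.

```{r}
s <- build_peptide("ENDL",
                   phi  = c(NA, -129.3, -46.3, -120),
                   psi  = c(140, 148.6, -34.1, NA),
                   chi1 = c(NA, 173.9, NA, NA),
                   chi2 = c(NA, -99.6, NA, NA))
scan_asn_sites(s)
```

Note the round trip: the builder imposes the torsions of the deposited
double-mutant site, and the resulting CG–N(n+1) distance comes out at
3.0 Å — the same value reported for that crystal structure — without any
distance having been imposed directly.

The proton-affinity label of the n+1 residue (`n1_acidity_label()`) is a
configurable ψ-range lookup, because the underlying affinity maps are
external published surfaces; only the default interval [−50°, −10°] →
"moderately-low" ships with the package, as editable configuration rather
than hard-coded science.

## Ideal-geometry peptide builder

`build_peptide()` grows a chain by internal coordinates (NeRF) with ideal
bond lengths/angles and places CB in the L-configuration (the
dihedral(C, N, CA, CB) frame value of −122.6°, matching the ≈ −123°
measured across L residues of deposited structures).  Its fidelity target
is exact torsion round-trip (< 0.1°), not force-field realism: bond
lengths are fixed, there is no relaxation, and steric collapse merely
warns.  Asn/Asp side chains are built to full depth so succinimide-site
geometry can be constructed exactly; other side chains stop at CB/CG.
Consequently, tests that pass on built peptides validate the *measurement
pipeline*, not the conformational preferences of real proteins.

## Superposition

`superpose()` implements the least-squares rigid fit with the common
"5 cycles, cutoff 2" outlier-rejection scheme: after each fit, pairs
deviating by more than `reject_factor` × current RMSD are dropped and the
rest refit.  "Cutoff 2" is interpreted as 2 × current RMSD per cycle
(the usual align semantics); both knobs are arguments.  RMSD is
non-increasing across cycles by construction.  Published RMSDs from
specific alignment tools also depend on their sequence-based pairing, so
agreement with third-party numbers is a tolerance check, not an identity.

## Collective variables and the free-energy surface

A reaction coordinate for deprotonation/cyclization is built from
coordination numbers: the rational switching function

\[ s(r) = \frac{1 - (r/r_0)^6}{1 - (r/r_0)^{12}} \]

is 1 for a formed contact, 0 for a broken one, and `nn/mm` = 0.5 exactly
at \(r = r_0\) (removable singularity).  Each CV combines a forming and a
breaking contact with coefficients (+0.5, −0.5), chosen because that maps
the reactant and product states to (−0.5, −0.5) and (+0.5, +0.5) with
single-pair coordination numbers in [0, 1]; the coefficients are
configurable per CV, and the atom pairs behind each CV are user-supplied
configuration (they are system-specific).  Default switching reference
distances follow the deprotonation use case: 1.34 Å for the proton-transfer
contacts, 1.00 Å where an O–H/N–H bond is broken.  A one-sided harmonic
upper wall (default 5.5 Å, 200 kcal/mol) keeps the reactive partners
together.

Nontempered metadynamics deposits Gaussian hills (default height
0.59 kcal/mol, widths 0.005/0.006 CV units, one hill per 0.1 ps); the
estimator of the free energy is the negated bias, min-shifted to zero.
`reconstruct_fes()` offers two estimators:

* `"sum"` — plain −V at the end of the run (the textbook nontempered
  estimator);
* `"tail-average"` — the time-average of −V over the final fraction of
  the deposition history.  For nontempered runs the instantaneous −V
  carries a sawtooth of amplitude ~ one hill height; averaging over the
  tail suppresses it.  The average reduces to a per-hill weighting
  ((n−i+1)/K for hill i in a tail of K), so it remains a single weighted
  Gaussian sum.

## Minimum free energy path and the activation barrier

An activation barrier is a path-*maximum* quantity, so the default MFEP
cost is minimax: among 8-connected grid paths, minimize the highest free
energy en route.  The exact minimax level is found by threshold
connectivity (nodes admitted in increasing F until start and end join —
equivalent to exhaustive search over all levels), and within the admitted
subgraph the returned path minimizes integrated F (ties by node order).
An `"integrated"` mode (summed-F Dijkstra over the whole grid) is provided
because some path-finding conventions use it; minimax is the default since
the barrier, not the path length, is the quantity of interest.

```{r}
spec <- double_well_surface(barrier = 5, width = 0.08)
h <- gen_hills_on_surface(spec, n_hills = 2000, seed = 1, stride = 20)
fes <- reconstruct_fes(h, spacing = 0.02, warn_uncovered = FALSE,
                       estimator = "tail-average")
path <- min_free_energy_path(fes, c(-0.4, -0.4), c(0.4, 0.4))
path
```

## What the hills generator emulates — and what it does not

`gen_hills_on_surface()` is the oracle for the FES/MFEP machinery: a
Metropolis walker moves on `surface + accumulated bias` and deposits a
hill every `stride` proposals, so the negated hill sum flattens and then
tracks the analytic surface whose saddle height is known exactly
(`surface_saddle()`, dense-grid threshold connectivity on the analytic
form).  Choices and their reasons:

* hill height/widths are 0.59 kcal/mol and 0.005/0.006 CV units — the
  values used for the real deprotonation runs; they are *narrow* relative
  to the basin size, so recovery noise is dominated by deposition
  granularity, not hill overlap;
* Metropolis temperature kT = 0.6 kcal/mol, enough for the biased walker
  to visit both basins;
* proposal step 0.02 CV units and `stride` = 100 proposals per hill: the
  walker must locally re-equilibrate between depositions for the bias to
  converge to −F; too-frequent deposition digs narrow trenches and
  underestimates well depths (we observed exactly this at stride 1);
* the default two-basin surface (`double_well_surface()`) has wells of
  width 0.08 CV units at (±0.4, ±0.4): with 20 000 hills the deposited
  Gaussian volume overfills both wells several times, which the
  tail-averaged estimator needs to be past its transient.

A multiple-walkers option (deposits interleaved from several chains
sharing the bias) exists but does not improve recovery at this hill
budget; the default is a single walker.

The generator is *not* a physics engine: no inertia and no well-tempered
scaling.  Its recovery precision is limited by deposition granularity:
with 0.59 kcal/mol hills against a 5 kcal/mol barrier the single-run
ripple is of order \(\sqrt{h\,k_BT}\approx 0.6\) kcal/mol, so an
individual seed recovers the barrier only to roughly 10%, while the
ensemble mean across ten seeds recovers it to within 5%.  Tightening the
per-seed precision would require smaller hills — a different study
condition, not a different estimator.

## Trajectory statistics

Distance histograms use a default bin width of 0.01 Å and are reported
both as unit-area densities and as cumulative fractions, because printed
"normalized distributions" are ambiguous between the two readings;
`fraction_below()` gives the cumulative reading directly.  Hydrogen-bond
occupancy applies the standard criteria (donor–acceptor < 3.5 Å,
donor–H–acceptor > 140°) per frame; for hydrogen-free crystal structures
the geometry layer instead offers distance-only acceptance, plus an
optional inferred-amide-H mode that places the backbone H on the bisector
so the angle criterion can be applied to crystal input.  Transition
detection reports the earliest time all CVs exceed a threshold and stay
above it for a dwell window (default 0.2 ps) to suppress recrossing noise.
Nearest-frame extraction ties to the earlier frame.

## The mass layer

Peptide masses are sums of monoisotopic residue masses plus water;
`modification_shifts` registers ammonia loss at Asn (−17.0265 Da,
succinimide), deamidation (+0.9840), Met oxidation (+15.9949) and
N-terminal acetylation (+42.0106).  m/z is `(M + z·1.007276)/z`; b/y
fragments obey `b_i + y_(n−i) = M + 2·proton` at every index.  Tryptic
digestion cleaves after K/R except before Pro, with configurable missed
cleavages and a semi-specific mode (one ragged terminus), matching common
search-engine settings.  Deconvoluted neutral masses are assigned to
SNN (M−17.0265), intact (M) or hydrolyzed (M+0.9840) within a 0.05 Da
window; isotope-envelope modelling and deconvolution itself are out of
scope.  Intact-protein masses include the initiator Met unless
`met_excision = TRUE` — numbering of published sites matches the
translated sequence, which is why inclusion is the default.

Observed instrument m/z values are compared with theory within 0.02 Da
(≈ 15 ppm at m/z 1350), consistent with a 10 ppm precursor search
tolerance; digit-exact agreement with printed values is not expected.

## Numerical choices and degenerate inputs

* Torsions are IUPAC-signed, in (−180°, 180°]; collinear middle triplets
  are errors, chain termini give `NA` with a warning.  The convention was
  validated against deposited helix geometry (φ ≈ −60°) and an
  independent torsion implementation.
* Alternate locations resolve to the highest occupancy, ties by altloc
  letter; waters/ions are parsed but excluded from contact searches by
  default.
* Contact searches exclude same-residue pairs and 1-2/1-3 covalent
  neighbours across the peptide bond, so reported contacts are non-bonded.
* Ramachandran quadrant boundaries (0°) are assigned to the positive side,
  making the quadrant map a true partition.
* Outlier rejection keeps an absolute floor (1e−8 Å) on the rejection
  threshold so machine-precision fits do not reject spuriously.
* The FES grid covers hill centers ±4σ or warns; Gaussians are truncated
  at 8σ (relative error < 1e−14).
* Histogram bin edges are anchored at multiples of the bin width with a
  floating-point guard so boundary samples are never dropped.

## Problem sizes used by the test suite

The suite builds peptides of 3–9 residues, trajectories of 10–100 frames,
hills streams of 200–20 000 hills, and FES grids of 81×81 (spacing 0.02
over [−0.8, 0.8]); the barrier-recovery study uses the default double-well
with 20 000 hills across seeds 1–10.  These sizes keep every stage
deterministic and fast while still exercising the full pipelines
end-to-end.

## Known limitations

* The builder's ideal geometry cannot reproduce deposited coordinates
  atom-for-atom; it reproduces *torsions* exactly and distances to within
  the fidelity of ideal bond lengths/angles.
* FES reconstruction and MFEP are limited to 1–2 CVs on uniform grids.
* The mass layer does not model isotope envelopes, retention times, or
  PSM scoring; relative quantification is a counting rule on user-supplied
  PSM tables.
* Crystal-mode hydrogen bonding is distance-only by design; inferred
  amide hydrogens are a geometric idealization.
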