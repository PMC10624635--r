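---
title: "Engineering nucleotide-binding sites from conserved P-loop features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering nucleotide-binding sites from conserved P-loop features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploopkit)
```

## The problem

Walker-A P-loops (G-X1-X2-X3-X4-G-K-[T/S]) are the canonical
phosphate-gripping motif of NTPases.  In hetero-oligomeric machines such as
the V1-ATPase A3B3 ring, only the catalytic subunit carries a functional
P-loop; the homologous non-catalytic subunit carries a degenerated
*pseudo* P-loop at the corresponding position -- same topological slot,
different sequence and backbone geometry, no nucleotide binding.  Restoring
binding at such a pseudo-active site is a stringent test of what actually
defines the motif.  `ploopkit` implements the computational core of that
programme: characterise native P-loops by a small set of conserved
features, transplant a native loop backbone onto the pseudo-loop, place
phosphates under distance restraints, and select designs that keep the
motif's signature.

## The three conserved features

The motif is operationalised as three jointly necessary criteria, all
checked by `detect_ploops()`:

1. **Sequence.**  G-X1-X2-X3-X4-G-K-[T/S], scanned over every chain with
   wildcards free.  An additionally conserved glycine at X3 is pinned by
   default (`required_fixed = c(X3 = "G")`); the lysine-free variant
   G-X1..X4-G-[T/S] is also accepted by `motif_definition()` since both
   forms circulate in the literature.  `'X'` (non-standard residue) never
   satisfies a fixed slot.
2. **Backbone torsion pattern.**  The loop's ABEGO string must equal
   `EBBGAGAA`.  ABEGO classifies each residue by its phi/psi/omega angles:
   `A` (alpha region: phi < 0, -75 <= psi < 50), `B` (extended: phi < 0,
   psi >= 50 or psi < -75), `G` (positive-phi helical: phi >= 0,
   -100 <= psi < 100), `E` (positive-phi extended: the rest of phi >= 0),
   `O` (cis peptide, |omega| < 90), `-` (undefined).  The literature fixes
   only the qualitative regions; the numeric boundaries above follow the
   convention established in backbone-design work and are inclusive on the
   lower edge, so the bins partition torsion space exactly (a property the
   test suite checks on a 1-degree grid).
3. **Orientation.**  Native P-loops sit after a beta strand, and the
   vector from the Calpha of the last strand residue to the Calpha of the
   conserved lysine points *away* from that residue's Calpha-to-Cbeta
   vector.  `orientation_feature()` returns the cosine between the two
   unit vectors; "away" is the strict condition cosine < 0 (a perfectly
   perpendicular lysine does not pass).  The "last strand residue" is
   taken to be the residue immediately preceding the motif in chain order
   -- the package does not assign secondary structure, which keeps the
   criterion deterministic.  A virtual Cbeta is built from N/CA/C with
   ideal tetrahedral geometry when the preceding residue is glycine.

`survey_motifs()` aggregates confirmed hits over a structure set into
per-position residue and ABEGO frequencies, orientation statistics, and
distances from designated motif atoms (backbone amides, Lys NZ, Thr/Ser
OG1/OG) to ligand phosphorus atoms.  A ligand counts as bound when one of
its phosphorus atoms lies within 10 angstrom of the conserved-lysine
Calpha -- a deliberately generous, deterministic cut-off.

## Torsion matching for minimized models

Exact character matching is the default.  Because design pipelines
re-check the pattern after energy minimization, which can push an angle a
few degrees across a bin edge, `detect_ploops()` and `validate_graft()`
also offer a tolerance mode: a residue passes if its (phi, psi) lies
within `torsion_tol` degrees (default 10) of the nearest point of the
required bin, with psi distances measured on the circle.  The default of
10 degrees is small against the >= 100-degree bin widths while absorbing
typical minimization drift.

## Grafting

`graft_loop()` replaces the acceptor range's backbone (N, CA, C, O, CB)
with the donor loop positioned by a Kabsch superposition of anchor Calpha
atoms.  Two anchor policies are provided because the source procedure --
"superimpose the donor subunit onto the acceptor" -- does not pin down the
anchor set:

* `flank_window` (default, k = 4): the k residues on each side of the
  acceptor range paired with the corresponding donor flanks.  Fully
  deterministic, needs no homology.
* `global_ca`: all Calpha atoms shared by author number *outside* the two
  loop ranges.  This reproduces a whole-subunit superposition of two
  homologous chains; the loops themselves are excluded because they differ
  by construction, and including them would bias the least-squares fit
  toward the very segment being replaced.

The report records which mode was used.  Grafted residues keep the
acceptor's author numbering and carry the donor sequence (side chains
truncated at Cbeta; sequence design proper is out of scope, but a designed
sequence can be imposed via `rename_sequence`).  Validation recomputes the
loop ABEGO, the splice C-N bonds (continuity requires 1.33 +/- 0.15
angstrom -- peptide geometry with an engineering margin, since no
minimizer is run), the orientation feature, and a clash count.  For the
clash count, residues within four chain positions of the loop are excluded
from the environment: packing against the splice neighbourhood is already
governed by the torsion and junction criteria, and idealized backbones
make local carbonyl-amide contacts that a minimizer would relax; the count
therefore targets non-local collisions such as the loop plunging into the
core.

## Phosphate placement and design filtering

Distance restraints between loop atoms and ligand phosphorus atoms use a
flat-bottom quadratic: violation = max(0, |d - target| - tolerance),
penalty = sum(weight * violation^2), zero exactly when every distance sits
inside its band.  Restraint values are not hard-coded: they are
regenerated from `survey_motifs()` via `constraints_from_survey()` (target
= survey mean, tolerance = one standard deviation, floored at 0.25
angstrom so a degenerate zero-spread survey still yields a usable band).

`sample_phosphate_poses()` places a rigid di-/tri-phosphate template
(P-P 2.95 angstrom, the bridging-oxygen geometry of ATP) by seeded random
rotation; the translation is proposed so the first restraint's ligand atom
lands uniformly inside that restraint's band around its protein partner,
and the remaining restraints act by rejection.  Every accepted pose is
re-validated through `evaluate_constraints()`, so the sampler can never
return a pose the evaluator would reject.  All randomness flows through
R's default Mersenne-Twister generator seeded once per call, making pose
sets bit-reproducible across platforms.  This is a geometric feasibility
sampler, not a conformer generator: it explores rigid placements only, and
an exhausted attempt budget with zero acceptances raises a feasibility
warning rather than an error.

Steric screening uses Bondi van-der-Waals radii scaled by 0.80 (strict
inequality at the boundary), tolerant of unminimized geometry; atoms named
in the restraint set -- the intended Lys/Ser contacts -- are excluded.

`filter_candidates()` applies the final selection rule: discard candidates
whose loop lost the conserved torsion pattern, then keep those with
binding score strictly below -8.0 (the comparison is strict because the
rule is "less than") and restraint penalty at most `max_penalty` (default
0).  Binding scores are opaque external numbers (e.g. Rosetta ddG values)
read from a table; the package never computes a physical binding energy.

## The synthetic-fixture engine

`build_backbone()` constructs backbones from per-residue (phi, psi, omega)
by sequential internal-coordinate placement with a single fixed table of
ideal bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O
1.231, CA-CB 1.521 angstrom; the Cbeta improper C-N-CA-CB is -122.6
degrees, matching L-amino-acid chirality).  Only self-consistency matters:
`backbone_torsions()` recovers the specification to ~1e-12 degrees, and
the suite verifies < 1e-3 over 1,000 seeded random specs.

`make_motif_fixture()` assembles strand -> loop -> helix chains whose loop
realizes any requested ABEGO string.  Torsions are drawn from seeded
jitter boxes strictly inside each bin, so fixture panels vary while every
residue keeps its intended classification; with the canonical
strand/EBBGAGAA/helix layout the orientation criterion emerges from the
geometry itself (cosines around -0.3 to -0.97 across seeds) rather than
being imposed.  Orientation-negative fixtures are constructed by
reflecting the pre-loop Cbeta through its Calpha, which flips the cosine's
sign while leaving sequence and torsions untouched.
`make_pseudo_loop()` scrambles a loop rigidly in place (rotation about the
loop centroid plus displacement) and renames its residues, leaving the
flanks bit-identical -- grafting the original loop back is then an
exact-restoration test with congruent anchors.

What the fixtures deliberately do not emulate: side chains beyond Cbeta,
solvent, crystallographic disorder, and real packing environments.
Passing the suite therefore demonstrates the correctness of the geometry,
detection, grafting and filtering machinery, not that any particular
native structure will yield a confirmed hit; on real structures the
sequence and torsion criteria behave identically, but loops preceded by
non-strand geometry can fail the orientation criterion by design.

## Numerical choices and degenerate inputs

* Dihedrals use the two-argument arctangent form with the IUPAC sign
  convention, range (-180, 180]; coincident or collinear points raise a
  geometry error rather than returning NaN.
* A chain break is declared when C(i)-N(i+1) exceeds 2.0 angstrom
  (peptide bond ~1.33); torsions spanning a break are undefined, and
  undefined torsions classify as `'-'`, which never matches a pattern
  character.
* Kabsch superposition excludes reflections (rotation determinant +1) and
  refuses rank-deficient point sets and n < 3.
* Alternate locations collapse to the highest-occupancy conformer, ties
  broken by the lexicographically first altloc id, before any geometry is
  computed.
* Author numbering is preserved everywhere; all user-facing ranges are
  author-numbered, 1-based, inclusive.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated
structures: 22-residue single-chain fixtures (a 6-residue strand, the
8-residue loop, an 8-residue helix), panels of 20 positive and 21 negative
fixtures for sensitivity/specificity, 1,000 random specs for the
construction round-trip, 100 random point sets for the superposition
oracle, a 5-structure survey with diphosphate pseudo-ligands, and
5-10-pose sampling runs against ~16 survey-derived restraints.  These
sizes were chosen so each property is exercised well past its edge cases
while the whole suite stays comfortably interactive.

## Known limitations

* No sequence design or packing energetics: binding scores are external
  inputs, and grafted side chains stop at Cbeta.
* No topology-independent structure alignment; `compare_models()` pairs
  residues by author number or by global sequence alignment, so its RMSD
  can differ slightly from aligners that optimise the residue pairing.
* The phosphate sampler is rigid; ribose, base and magnesium coordination
  are out of scope.
* Secondary structure is not assigned; the orientation feature trusts the
  chain-order predecessor to be the "last strand residue", which holds for
  the native P-loop context it models.
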