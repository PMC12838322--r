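---
title: "StabScan: methods and design notes"
author: "StabScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{StabScan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StabScan)
```

## The problem

Thermostable subtilisin-like proteases (keratinases among them) are
stabilized by a recurring set of structural features: networks of surface
ion pairs, proline residues at the i+1 position of Type I β-turns, and
bound Ca²⁺ ions coordinated by clusters of oxygen ligands. Rational
thermostabilization campaigns therefore start from a structural model of
the enzyme and ask a series of geometric questions — which acidic and
basic residues pair up, which of those pairs sit on the surface, where
could a new pair be created, which turns tolerate a proline, and how are
the calcium sites built. StabScan implements that question battery as a
reusable, fully testable pipeline, together with a synthetic-structure
builder that plants every feature class at known geometry so each stage
can be validated without any external structure.

## Structure model and PDB policy

Structures are held in a `ProteinStructure` object: a flat heavy-atom
table (chain, author residue number, insertion code, residue and atom
name, element, coordinates, occupancy) plus a separate table for bound
metal ions. The PDB reader applies a fixed policy:

* hydrogens and waters are discarded — every analysis downstream is
  heavy-atom based;
* alternate locations collapse to the highest-occupancy copy, ties going
  to the alphabetically first altloc identifier;
* HETATM records for Ca, Zn, Na, Mg and K are routed to the ion table, so
  polymer analyses can never confuse an ion with a ligand atom;
* author numbering is preserved verbatim. Mature-chain numbering (from
  the first residue of the processed enzyme) is a property of the input
  model, not something the parser invents.

The writer emits fixed-width v3.3 records; a parse–write–parse cycle is
idempotent and coordinates survive at the format's 0.001 Å precision.

## Solvent accessibility

SASA is computed with the sphere-point (Shrake–Rupley) method: for each
atom, quasi-uniform points are placed on the sphere of radius
r~vdW~ + r~probe~ and the accessible fraction is the fraction of points
inside no neighbouring expanded sphere. Defaults are a 1.4 Å water probe
and 960 points per atom; van der Waals radii are C 1.70, N 1.55, O 1.52,
S 1.80 Å.

Two numerical choices matter:

* **Deterministic points.** The point set is a Fibonacci spiral — no
  random number generator, so results are bitwise reproducible.
* **Coordinate-hashed lattice spin.** If all atoms share one lattice
  orientation, the quantization error at occlusion boundaries correlates
  between neighbouring atoms and summed areas acquire an
  orientation-dependent bias close to 1%. Each atom's lattice is
  therefore spun by a rotation hashed from its own coordinates. This
  keeps the result a pure function of the coordinates (disjoint fragments
  stay exactly additive) while decorrelating the quantization, which
  brings the rigid-body variation of summed areas under 0.5% at 960
  points. An isolated sphere matches 4π(r+probe)² essentially exactly,
  and two overlapping spheres match the spherical-cap closed form within
  a fraction of a percent.

Relative solvent accessibility (RASA) of a residue is its side-chain SASA
as a percentage of a "random coil" reference: the side-chain SASA of the
same residue type at the centre of an extended Gly-X-Gly tripeptide
(φ = −140°, ψ = 135°, canonical rotamer), computed with the same probe
and point count, cached after the first call. Glycine uses its Cα as the
side-chain proxy, following common RASA practice. Residues (or ion
pairs, below) with RASA ≥ 20% count as solvent exposed. The references
are computed internally rather than shipped as a table, which makes RASA
self-consistent across probe radii and point counts; absolute agreement
with analytic SASA programs is not claimed, and residues near the 20%
line may classify differently than under another program's reference
table. Bound ions are excluded from the SASA calculation by default (a
switch includes them), since published models of calcium-bound enzymes
differ in whether ions are present at all.

## Ion pairs and ionic networks

Charged side-chain atoms are Asp OD1/OD2 and Glu OE1/OE2 (acidic) versus
Lys NZ and Arg NE/NH1/NH2 (basic). For every acidic × basic residue
pair the minimum over charged-atom distances is taken; one ion pair per
residue pair, whatever the number of atom contacts. Pairs at ≤ 4.0 Å are
salt bridges, pairs above that but at ≤ 8.0 Å are long-range ion pairs —
both boundaries inclusive. Histidine is excluded by default (a switch
enables it): thermophilic-enzyme ion-pair censuses are conventionally
Lys/Arg-based, and mixing His in changes every count. The pair RASA is
the arithmetic mean of the two members' RASA, and the ≥ 20% exposure rule
applies to it unchanged.

Ionic networks are the connected components of the residue graph whose
edges are the detected pairs; a component qualifies as a network when it
contains at least two pairs, and isolated single pairs are reported
separately. Component finding is delegated to igraph and is verified
against an independent union-find oracle in the tests; assembly is
order-independent. Basic residues that appear in no pair are reported as
engineering anchors — creating a partner for them is the cheapest way to
add a surface pair.

## β-turns and proline candidates

A four-residue window (consecutive numbering, complete backbones) is a
β-turn when Cα(i)–Cα(i+3) ≤ 7.0 Å and its two central residues are not
helical. The helix veto is a (φ, ψ) window heuristic: a residue is
helical when its dihedrals are within 40° of (−63°, −42°) and it sits in
a run of at least four such residues; the veto is switchable because
full secondary-structure assigners draw the helix boundary slightly
differently, and turn counts on real models should be read with a ±1
allowance for that reason.

Turn types come from the standard dihedral-window taxonomy. Ideal
(φ₁, ψ₁, φ₂, ψ₂) values are: I (−60, −30, −90, 0); II (−60, 120, 80, 0);
I′ (60, 30, 90, 0); II′ (60, −120, −80, 0); VIII (−60, −30, −120, 120).
A window matches a type when all four angles are within ±30° of ideal,
with at most one angle allowed up to ±45°; types are tried in the order
listed and the first match wins (the order is fixed purely for
determinism — the canonical quadruples are mutually exclusive at these
tolerances); everything else is type IV (other).

Proline at i+1 of a Type I turn lowers the conformational entropy of the
unfolded state and is one of the most reliable single-point
stabilizations. The candidate generator emits X→P for every Type I turn
whose i+1 residue is not already proline and is not in a caller-supplied
exclusion set. The exclusion set is deliberately explicit — catalytic
residues and metal-ligand turns must be named by the user, because the
tool does not infer function from geometry.

## Calcium sites and grafts

A site analysis reports every oxygen atom within 3.0 Å of a supplied ion
coordinate, labelled `side_chain` (atom name starting OD/OE/OG/OH) or
`main_chain_carbonyl` (name "O"), sorted by distance. The 3.0 Å cutoff
sits comfortably above typical Ca–O coordination bonds (2.3–2.6 Å) and
below the next shell. Ion coordinates are always explicit inputs:
whether a predicted model carries ions, and where, depends on how it was
produced, so the package never guesses them.

Graft verification compares the observed shell on a mutant model against
the expected (residue, atom, role) triples of the design. The verdict is
satisfied exactly when nothing expected is missing; extra ligands are
listed but do not fail the graft, since recruiting an additional
carbonyl is common and harmless.

## Surface Asp/Glu scan and consensus aggregation

The scan looks for positions where a new acidic residue could pair with
an existing basic residue: a candidate T→Asp/Glu requires T to be
exposed (RASA ≥ 20%), not Gly/Pro/Cys (no Cβ, backbone-critical, or
disulfide risk), not already acidic, not excluded, and its Cβ within
8 Å + reach of the partner's nearest charged nitrogen, where reach is the
Cβ-to-carboxylate-oxygen span of the proposed residue in an extended
rotamer (Asp 2.5 Å, Glu 3.9 Å). No rotamer search is performed; the
screen is deliberately permissive, because its output is a shortlist for
human triage, and partners that currently have no pair at all are
flagged as priorities. Lowering the RASA threshold can only add
candidates, never remove one.

External stability predictors are consumed as minimal TSV tables
(columns `wt`, `position`, `mut`), one per tool. Records merge by
(position, wt, mut); a wild-type disagreement between tools is an error,
because it almost always means mismatched numbering (propeptide offset).
Consensus selection keeps records supported by at least k tools
(default 2), sorted by support, then position. No energy scoring is
layered on top: tool support plus the categorical rationale is the
ranking, matching how such campaigns are actually triaged.

## The synthetic builder: what it does and does not emulate

Backbones are grown by internal-coordinate (NeRF) extension with one
self-consistent ideal-geometry set (N–CA 1.458, CA–C 1.525, C–N 1.329 Å;
angles N-CA-C 111.2°, CA-C-N 116.6°, C-N-CA 121.7°; carbonyl O in the
peptide plane), so measuring φ/ψ/ω on the output reproduces the input
spec to numerical precision. Side chains come from rigid canonical
(mostly all-trans) rotamer templates for all 20 standard residues,
placed on the backbone frame with L-chirality; the proline ring is
placed approximately, without closure refinement.

Fixture generators plant: minimum O–N distances between an acidic and a
basic tripeptide, to ±0.05 Å, by iterated rigid translation along the
closest-contact axis with a 2.5 Å clash guard; burial, by tiling alanine
residues tangentially on a sphere (centroids at 6 Å by default) around a
centre residue — 30 shell residues push an Asp side chain below 5% RASA,
while the bare tripeptide sits at 100% by construction; and
coordination shells, by pointing serine hydroxyls at near-octahedral
directions around a calcium ion. Generation is deterministic given the
seed argument (default 0).

What the fixtures do **not** emulate: packed protein cores, real rotamer
distributions, hydrogen-bond geometry, chain context around turns, or
predicted-model error. Passing the suite therefore demonstrates that the
geometry, the classification rules and the aggregation logic are
correct — not that any particular predicted structure of a real enzyme
is accurate, nor that absolute RASA values match a specific legacy
program.

## Problem sizes and determinism

The validation suite runs entirely on synthetic inputs: clusters of up
to twelve charged tripeptides (≈ 200–500 atoms) for the ion-pair oracle
comparisons, 1,000 random pair graphs for the network oracle, 166-atom
burial shells for the RASA bracket, and five synthetic predictor tables
of ~15 mutations each for the consensus checks. All randomized tests fix
their seeds; all SASA numbers are bitwise reproducible at fixed inputs.
The same conditions are recomputed from scratch by
`scripts/acceptance.R`, which accepts a seed and writes its measured
quantities as JSON.

## Known limitations

* Absolute RASA depends on the internal Gly-X-Gly reference; only the
  self-consistent percentages, not cross-program absolute values, are
  meaningful.
* The helix veto is a heuristic, not a full secondary-structure
  assignment; turn censuses on real models can differ by about one turn
  from assigners built on hydrogen-bond patterns.
* The surface-acidic scan is a geometric feasibility screen; it
  over-proposes by design and performs no rotamer or electrostatics
  modelling.
* No bond perception, protonation, symmetry expansion, or mmCIF input.
* Ion placement is out of scope everywhere: coordinates must be given.
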