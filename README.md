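# StabScan

Structure-based screening of candidate stabilizing mutations for
proteins, built around the analyses used to thermostabilize
subtilisin-like proteases (keratinases): surface ion pairs and ionic
networks, relative solvent accessibility, Type I β-turn proline design,
Ca²⁺-site coordination analysis with graft verification, a surface
Asp/Glu substitution scan, and consensus aggregation of external
stability-predictor mutation lists. A synthetic-structure builder plants
every feature class at known geometry, so the entire pipeline is
validated end to end with no external data.

## Who it is for

Protein engineers working from a structural model (experimental or
predicted) who want the standard geometric census behind a rational
thermostabilization campaign — which charged residues pair, what is
exposed, where a proline or a new acidic residue could go, and how the
calcium sites are coordinated — as reproducible, scriptable R functions
rather than a chain of web servers.

## The core definitions

* **Ion pairs.** For each Asp/Glu × Lys/Arg residue pair, the minimum
  charged-atom distance d = min over O–N atom pairs (Asp OD1/OD2,
  Glu OE1/OE2 vs Lys NZ, Arg NE/NH1/NH2). d ≤ 4.0 Å is a salt bridge,
  4.0 < d ≤ 8.0 Å a long-range ion pair. Connected components of the
  pair graph with ≥ 2 pairs are ionic networks.
* **RASA.** Relative solvent accessibility of a residue =
  100 × SASA(side chain) / SASA(side chain in extended Gly-X-Gly),
  probe 1.4 Å; residues and pairs (pair RASA = mean of the two members)
  with RASA ≥ 20% are exposed. SASA uses a deterministic sphere-point
  (Shrake–Rupley) method, 960 points per atom.
* **β-turns.** Four consecutive residues with Cα(i)–Cα(i+3) ≤ 7 Å, not
  helical in the middle; type from the (φ₁, ψ₁, φ₂, ψ₂) windows
  (Type I ideal: −60, −30, −90, 0; ±30°, one angle up to ±45°). Type I
  turns without a proline at i+1 are proline-substitution candidates.
* **Ca²⁺ sites.** All oxygen atoms within 3.0 Å of a supplied ion
  coordinate, split into side-chain and main-chain-carbonyl ligands;
  graft designs are verified as expected-vs-observed ligand sets.
* **Consensus.** Mutations proposed by ≥ k of several predictors
  (default k = 2), merged by (position, wt, mut).

## Worked example

Plant a salt bridge at 3.5 Å, detect and annotate it, then find a
planted Type I β-turn and its proline candidate:

```r
library(StabScan)

fx <- makeSaltBridgeFixture("ASP", "LYS", 3.5)
s  <- fx$structure
s
#> ProteinStructure: combined synthetic structure
#>   6 residues in 2 chain(s) [A,B], 33 heavy atoms, 0 bound ion(s)

sr    <- computeRasa(computeSasa(s))
pairs <- annotateExposure(detectIonPairs(s), rasaVector(sr))
pairs
#>   acid_key acid_resid acid_resno base_key base_resid base_resno min_dist
#> 1      A/2        ASP          2      B/2        LYS          2      3.5
#>      category pair_rasa exposed
#> 1 salt_bridge  81.80812    TRUE
```

The planted Asp2–Lys2 contact comes back at exactly its target distance,
classifies as a salt bridge (d ≤ 4 Å), and the pair is exposed: both
side chains of the free-standing tripeptides are far above the 20% RASA
line, so their mean (81.8%) is too.

```r
turn <- buildBackbone(dihedralSpec(
  c("GLY", "ALA", "SER", "GLY", "ALA", "GLY"),
  phi = c(NA, -140, -60, -90, -140, -140),
  psi = c(135, 135, -30, 0, 135, NA)))
tt <- detectBetaTurns(turn)
tt[, c("resno_i", "resid_i1", "phi1", "psi1", "ca_dist", "type")]
#>   resno_i resid_i1 phi1 psi1 ca_dist type
#> 1       2      SER  -60  -30 4.86908    I

proposeProlineCandidates(tt)
#>   position key wt mut category
#> 1        3 A/3  S   P turn_pro
```

The canonical (−60, −30)/(−90, 0) window is recovered as a single
Type I turn (Cα(i)–Cα(i+3) = 4.87 Å), and the serine at its i+1
position is proposed for the S3P substitution.

```r
cf   <- makeCoordinationFixture(6, 2.4)
site <- analyzeCaSite(cf$structure, cf$ion)
head(site$ligands, 3)
#>   key resid resno elety dist       role
#> 1 L/1   SER     1    OG  2.4 side_chain
#> 2 L/2   SER     2    OG  2.4 side_chain
#> 3 L/3   SER     3    OG  2.4 side_chain
```

All six planted hydroxyl oxygens are reported at 2.4 Å from the ion and
nothing else enters the 3.0 Å shell.

A thin shell front end for real models lives at
`inst/scripts/stabscan` (`stabscan sasa model.pdb --tsv rasa.tsv`,
`stabscan ionpairs model.pdb`, `stabscan turns`, `stabscan casite
model.pdb --ion x,y,z`).

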