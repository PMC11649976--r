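---
title: "The CYP2J2 fused hexagonal-grid Template model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CYP2J2 fused hexagonal-grid Template model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyptemplate)
```

## The model

CYP2J2 is a human cytochrome P450 with a distinctive substrate profile:
it oxidizes the terminal portions of slender molecules (astemizole,
terfenadine), a set of small drugs (benzphetamine, chlorzoxazone,
*R*-5-hydroxythalidomide) and endobiotics such as arachidonic acid, while
closely related structures (*R*- and *S*-thalidomide) are not turned
over.  The Template approach models the enzyme's ligand-accessible space
not as a 3D protein structure but as a flat fused grid of hexagonal cells
("Rings") assembled empirically from overlaid substrate structures, with
a small set of interaction rules that decide whether a flattened ligand
sitting on the grid is metabolized, and where.

`cyptemplate` makes that system executable.  The canonical CYP2J2
geometry ships as data; ligands load as hydrogen-free molecular graphs;
placements map atoms to grid vertices plus a depth bucket; a rule engine
produces a categorical verdict with per-rule evidence.

### Geometry

The grid has 21 core Rings (`A`–`U`) and nine extension regions (`eB`,
`eC`, `eE`, `eJ`, `eL`, `eO`, `eP`, `eR`, `eU`).  Ring-size — the
distance between two opposite hexagon edges — is the unit of length, so
lattice edges are $1/\sqrt{3}$ units.  Depth is discretised into three
buckets between the two parallel walls: `facial` (viewer side), `mid`,
and `rear` (heme-access side).  The slab thickness (Width-gauge) is 1.5
Ring-size; `rear_depth - facial_depth = width_gauge` is a validated
invariant.

Named features:

* **Site of oxidation** — numbered positions 2–4 on the bottom row
  (right boundary position 4); the heme-bound oxygen attacks from the
  rear at the bottom.
* **Shelf** — a plateau whose top edge runs from the Left-end to
  position 10 (the upper junction of Rings A and E).  The space under it
  is closed; its top edge is a stabilizing contact.
* **Left-end** — the left border polyline rising from the Shelf to the
  top-left corner of Ring S (anchor 54'); good substrates are fixed
  against it.
* **Entrance** — the line between anchors 49' and 54' on the top
  border, where ligands enter before descending.
* **Trigger-residue** — a mobile element, modelled as a
  0.5 × 0.5 × 3 Ring-size pillar, that appears from the Rear-wall near
  `eB` and migrates leftward along `eB → C → B`, never entering Ring A.

The printed source for the geometry is a figure, not a coordinate table,
so the packaged definition is a transcription: the cell layout was
reconstructed from the ring adjacencies implied by all of the worked
placement traces, and the numbering was chosen so that every textual
anchor holds (54 numbered positions; site spanning 2–4 with right
boundary 4; position 10 at the A/E junction bounding the Shelf; primed
border anchors 11' and 48'–54', with the Entrance between 49' and 54').
That transcription is canonical data: it is shipped in
`inst/extdata/cyp2j2_template.yaml`, validated on load, and every
downstream result is deterministic given it.  The corner count works out
exactly — the 21 core rings have 62 corners, of which 8 are primed
border anchors and 54 are numbered.

```{r}
t2j2 <- load_template()
t2j2
```

### Ligand graphs and functional classes

Ligands load from SMILES or SDF/MOL through ChemmineR/Open Babel;
hydrogens are stripped (the Template places heavy atoms only) and atom
order follows the input, so fixture atom indices are stable.  Three
annotation classes drive the rules:

* **Lactone-like ring atoms** — cyclic esters and cyclic imides
  (thalidomide-class rings), treated as ionizable at neutral pH.  They
  are barred from Rear-wall and Trigger contact.
* **Heme-ligating heteroatoms** — pyridine/azole-type aromatic nitrogens
  and primary/secondary non-amide amines; lone pairs that can coordinate
  the heme iron instead of being oxidized.
* **Candidate oxidation sites** — C–H carbons, thioether sulfurs
  (S-oxidation) and tertiary non-amide amines (N-oxidation /
  N-dealkylation).

The split of nitrogen chemistry between the last two classes is a design
decision the source system leaves informal.  It is the simplest rule set
that reproduces the published verdicts simultaneously: danazol's
isoxazole N and norfloxacin's terminal piperazine N–H inhibit (they
ligate, and nothing else oxidizable shares the site region), while
thioridazine's thioether S and carfentanil's tertiary piperidine N are
substrates (they are themselves the oxidation targets).

### The rules

A placement is evaluated by independent rules, each returning
pass/fail with atom-level evidence:

| rule | gate? | content |
|------|-------|---------|
| `R_WIDTH` | mandatory | all atoms within the Width-gauge slab |
| `R_PLURAL_REAR` | mandatory | ≥ 2 non-lactone atoms in Rear-wall contact |
| `R_RING_B` | mandatory | occupancy at Ring B (junction corners count) |
| `R_SITE` | mandatory | an oxidizable atom at positions 2–4 |
| `R_TRIGGER` | mandatory | Trigger-residue fastens the ligand |
| `R_LACTONE` | mandatory | no lactone-like atom at Rear-wall / Trigger |
| `R_LEFT_END` | mandatory, relaxable | an atom on the Left-end polyline |
| `R_DESCENT` | mandatory, relaxable | vertical descent unobstructed |
| `R_SHELF` | stabilizing | no atom under the Shelf; edge contact scores |

Facial-wall and Shelf contacts are stabilizing evidence, not gates —
linezolid is a substrate without Shelf contact.  A placement passing all
gates with a non-empty site evidence set is a `GOOD_SUBSTRATE`
(evidence atoms = predicted sites of oxidation); an admissible placement
failing a gate is a `POOR_SUBSTRATE`; `INHIBITOR` takes precedence when
a heme-ligating atom occupies the site region and no other oxidizable
atom shares it; a structure that cannot be kept in the slab is a
`NON_LIGAND`.

The Trigger simulation halts at the first (rightmost) path ring occupied
by a non-lactone atom — the residue "ceases after the ligand contact" —
and additionally reports pillar support when atoms sit in the Rings
K/J/O region above its approach position (the upper parts of bent
ligands rest on the pillar).

Two reductions deserve a note.  First, the Ring-B rule and the Trigger
gate express one mechanism: the residue can migrate only as far as
Ring B, so fastening requires Ring-B occupancy.  The ablation switch
`rule_config(disable = "ring_b")` therefore drops both, which is what
makes the thalidomide negative control flip to `GOOD_SUBSTRATE` rather
than stalling on the trigger gate.  Second, `R_DESCENT` — ligands
descend from the Entrance without changing conformation — reduces under
straight vertical translation to the static half-plane barriers (the
closed under-Shelf space; the border beyond the Left-end): no occupiable
vertex lies under the Shelf, and conformation thickness is `R_WIDTH`'s
job, so the rule is evaluated as those static checks.

### Scores

The score is a weighted contact count: rear 2, facial 1, shelf 1,
left-end 2, site 3, pillar 1 (configurable; the weights are this
package's own invention, since the source system ranks sittings only
qualitatively), plus a fixed bonus when every gate passes so good
placements always outrank poor ones of the same ligand.  The magnolin
pair is the calibration example: the M-2 sitting (4-O-demethylation of
the trimethoxyphenyl ring, with Left-end, Rear-wall and Shelf contacts
of the dimethoxyphenyl end) outscores the M-1 sitting, matching the
observed near-selectivity.

```{r}
fx <- load_fixture_set(template = t2j2)
names(fx) <- vapply(fx, `[[`, "", "name")
rep <- run_fixture_suite(t2j2, fx)
rep[rep$name %in% c("Magnolin", "Magnolin (M-1)"),
    c("name", "observed", "score")]
```

### The placement search

The embedding model is discrete: atoms map to lattice vertices, bonds to
lattice edges, and depth buckets are free per atom.  For graphs up to
the atom cap (default 10) whose rings are honeycomb-embeddable the
enumeration is exhaustive and is verified in the test suite against an
independent brute-force oracle (plain index-order enumeration over all
vertex assignments, filtered by the same admissibility predicate) on
dozens of generated toy graphs.  Five-membered rings and bridged cages
cannot map bond-to-edge on a honeycomb; drug-sized ligands therefore
fall back to a deterministic off-corner beam search in which bonded
atoms may share a vertex region (at most two atoms per vertex) within a
1.2 Ring-size tolerance — the discrete counterpart of atoms "placed not
exactly at the corner".  The search is heuristic and flagged as such in
its output; completeness is claimed only for the strict model.

The conformer gate is a strain proxy standing in the criterion slot of
an external force-field value: half the mean of squared relative
bond-length deviations and squared angular deviations (radians, from the
120° lattice angle) of the flattened depiction.  The 0.5 rescale is the
calibration that maps the accept threshold to 0.1 in proxy units: clean
planar depictions score ≤ 0.08, while fused/bridged systems that the
Template accepts in flattened form (danazol's steroid core, the
adamantane of STS-135) land just under the gate, and grossly distorted
coordinates are rejected.

### Bi-molecule binding

Two non-identical ligands can co-occupy the Template: the
pro-metabolized molecule at the Site of oxidation and a trigger molecule
behind it.  The source statements about their contact are in tension
("need to have a slight overlapping point(s)" vs "situated behind,
without direct contacts"); the package resolves this as 2D-projection
overlap with depth separation — shared vertices with different depth
buckets — which satisfies both readings.  A trigger molecule reaching
into positions 2–4 always invalidates the complex (it is not oxidized).
A valid overlap in the stabilizing region (left border / upper support
rings) is `STABILIZING`; an invalid complex whose trigger footprint
blocks an alternative sitting of the pro ligand is `COMPETING`.  The
arachidonate / 7-deaDox pair reproduces both effects: 5,6-oxidation
enhanced, 14,15-oxidation suppressed.

## Fixtures: what they are and what they show

The packaged fixture file transcribes the worked placements: the
24-reaction construction set plus the extended group.  SMILES are
transcriptions of published 2D drawings (a few structures without
machine-readable sources are flagged as approximate and carry no
expectations).  Atom-to-vertex assignments are *partial*,
figure-resolution transcriptions: only atoms anchoring a described
contact (rear contacts, the site atom, the Ring-B atom, border contacts,
the heme-ligating atom) are pinned, and bonded pinned atoms are checked
against the 1.2 Ring-size tolerance.  Stereo labels live in record names
only; the 2D heavy-atom graph is achiral, and mirror-image sittings are
distinct transcribed placements, exactly as the drawings treat them.

Passing the concordance suite therefore shows that the encoded rules
reproduce the published verdict *given the published sitting*; it does
not show that the search would discover those sittings unaided, nor
anything about ligands outside the corpus.  The synthetic toy-ligand
generator (chains, small rings, ring-plus-tail graphs with occasional
heteroatoms) exists to exercise search completeness and rule invariants,
not to emulate drug-like chemistry: real ligands differ in ring fusion,
flexibility and heteroatom density, which is why the fixture corpus, not
the generator, carries the scientific weight.

## Numerical choices and problem sizes

Tolerances: lattice identity is exact (integer vertex keys); edge-length
validation at $10^{-9}$; bonded-atom tolerance 1.2 Ring-size in
figure-resolution placements and in the beam search, strict adjacency in
the exhaustive model.  Ties in the ranked predictions break by the
lexicographic order of assignment signatures, making every pipeline
deterministic for a fixed configuration; the only randomness anywhere is
the toy-ligand generator's seed.  The test and acceptance runs use the
full canonical template for rule evaluation and a trimmed four-ring
template (17 vertices) with toy graphs of 2–6 atoms for the
search-oracle equivalence — sizes at which exhaustive enumeration is
itself the specification of correctness.

## Limitations

* The geometry is a transcription of a printed figure; positions are
  correct relative to every textual anchor, but individual coordinates
  have figure resolution only.
* The beam search is a heuristic: it can miss the best sitting of a
  large flexible ligand, and its depth assignment maximizes the score
  within the model rather than modelling conformer energetics.
* No kinetics: verdicts and scores are categorical/ordinal, not
  rate predictions.
* Molecules that exceed the accessible area (cyclosporin-class) are
  outside the model; oversized sittings are reported via the width rule,
  not by a 3D volume test.
* Templates for other CYP isoforms are representable by the same schema
  but are not shipped.
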