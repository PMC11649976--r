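# cyptemplate

Fused hexagonal-grid Template modelling of CYP2J2 ligand metabolism.

Human CYP2J2 oxidizes an unusual range of ligands — slender drugs like
astemizole and terfenadine at their terminal portions, small molecules like
chlorzoxazone and benzphetamine, and endobiotics like arachidonic acid —
while rejecting close analogues (thalidomide is not metabolized although
*R*-5-hydroxythalidomide is). The Template approach explains this with a 2D
model instead of a 3D structure: the enzyme's ligand-accessible space is a
fused grid of hexagonal cells ("Rings" `A`–`U` plus extension regions)
between two walls 1.5 Ring-size apart (the **Width-gauge**), with named
features — the **Site of oxidation** at Positions 2–4, the **Shelf** ending
at Position 10, the **Left-end** border, the **Entrance** line 49′–54′ — and
a mobile **Trigger-residue** that migrates from the `eB` region leftward, at
most to Ring B and never into Ring A, to fasten a descended ligand.

`cyptemplate` is an executable implementation of that system:

* the canonical CYP2J2 grid as validated, serializable data
  (`load_template()`, `validate_template()`);
* the hyphen-linked placement notation, e.g. `A(B)-E(G)-eE-F-L`
  (`parse_placement()`, `serialize_placement()`, `rings_occupied()`);
* annotated heavy-atom ligand graphs from SMILES/SDF with lactone-like,
  heme-ligating and oxidizable-atom tagging (`load_ligand()`,
  `tag_functional_groups()`, `flatten_conformer()`);
* a rule engine classifying a placement as good substrate / poor substrate /
  inhibitor / non-ligand with per-rule evidence and predicted sites of
  oxidation (`atom_placement()`, `evaluate_placement()`);
* the Trigger-residue simulation with pillar support of bent ligands
  (`simulate_trigger()`, `pillar_support()`);
* a constrained graph-to-lattice placement search with an independent
  brute-force oracle (`enumerate_embeddings()`, `brute_force_oracle()`,
  `predict_ligand()`);
* bi-molecule (pro-metabolized + trigger molecule) co-placement evaluation
  (`evaluate_bimolecule()`);
* the worked placements as machine-readable fixtures with a concordance
  suite (`load_fixture_set()`, `run_fixture_suite()`), and a small CLI
  (`inst/cli/cyptemplate`).

## A worked example

Replay the chlorzoxazone 6-oxidation sitting (`Rings B-A-E-eE`) and inspect
the verdict:

```r
library(cyptemplate)
t2j2 <- load_template()
fx <- load_fixture_set(template = t2j2)
names(fx) <- vapply(fx, `[[`, "", "name")

p <- fixture_placement(fx[["Chlorzoxazone"]], t2j2)
evaluate_placement(p, t2j2)
#> <verdict> GOOD_SUBSTRATE (score 112)
#>   R_WIDTH       pass all atoms within Facial- and Rear-walls
#>   R_PLURAL_REAR pass 3 non-lactone Rear-wall contact(s)
#>   R_RING_B      pass Ring B occupied
#>   R_SITE        pass oxidizable atom(s) at Site of oxidation
#>   R_LEFT_END    pass Left-end contact
#>   R_SHELF       pass 1 Shelf contact(s) (stabilizing)
#>   R_LACTONE     pass lactone restriction satisfied
#>   R_DESCENT     pass vertical descent from Entrance unobstructed
#>   R_TRIGGER     pass trigger residue fastened at ring C
#>   predicted oxidation site atom(s): 4
```

The chlorine atom sits at Ring B (vertex 8, a B/C junction corner), three
non-lactone atoms touch the Rear-wall, the benzoxazolone ring oxygen rests
on the Shelf/Left-end corner, the Trigger-residue fastens on the first occupied path ring,
and the predicted site of oxidation is atom 4 — the aromatic C–H at the
6-position, i.e. exactly the reported 6-oxidation. The same machinery run
over the whole fixture corpus:

```r
rep <- run_fixture_suite(t2j2, fx)
c(records = nrow(rep), concordance = mean(rep$concordant))
#>     records concordance
#>          30           1
```

and the thalidomide discrimination collapses, as it should, when the Ring-B
fastening requirement is ablated
(`run_fixture_suite(t2j2, fx, config = rule_config(disable = "ring_b"))`).

## Repository layout

```
R/                      implementation (geometry, notation, ligands, rules,
                        trigger, search, bi-molecule, fixtures, reports)
inst/extdata/           canonical template + fixture transcriptions (YAML)
inst/cli/cyptemplate    command-line front end
tests/testthat/         unit, property and end-to-end suites
vignettes/              the methods vignette (model, assumptions, limits)
scripts/acceptance.R    headline-quantity reproduction script
```
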