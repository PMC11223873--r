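# pathsense

Retrobiosynthetic design of **biosensor-detectable pathways**.

Transcription-factor biosensors can only sense the small set of molecules
known to act as allosteric effectors. `pathsense` extends that set: given a
**target** bio-based compound, it searches for short enzymatic routes that
convert the target into an **effector** of an allosteric transcription
factor, so the target's concentration can be read out indirectly through
the biosensor. The intended users are synthetic biologists and metabolic
engineers choosing sensing circuits for screening and dynamic pathway
regulation in a microbial chassis.

## What it computes

Starting from each detectable compound (effector), the engine expands the
metabolic space **backward** with retro reaction rules — generalized
enzymatic transformations written as reaction SMARTS, each with a
*diameter* (atom-vicinity radius around the reaction centre; larger =
more specific) and a *penalty score* in [0, 1] (rule quality; lower =
better). Because backward expansion is combinatorial, the search is a
**Monte Carlo tree search** guided by Tanimoto similarity

    T(a, b) = |bits(a) ∩ bits(b)| / |bits(a) ∪ bits(b)|

between each new node's Morgan fingerprint and the target molecule.
Once the target is reached, the tree is collapsed into a bipartite
compound/reaction **scope graph**, and the distinct pathways are
enumerated under the *shortest-branch rule* (at every branched compound
node only the producing branches of minimal step count survive, and the
pathways are all their combinations). Each pathway is

* **ranked** by its worst step — the global score is the *maximum* step
  penalty, sorted ascending, with ties broken by the summed steady-state
  flux of the pathway's precursors, then by length;
* **classified** against the chassis metabolome: every compound becomes
  `target`, `effector`, `precursor` (present in the chassis or in a
  producible whitelist), `supplement` (consumed but never produced and
  not in the chassis — must be fed in the medium) or `intermediate`.

Results export as SBML Level 3 (species roles and InChI in annotations),
Cytoscape-style network JSON, and per-step enzyme-selection query links.

## Requirements and installation

R (>= 4.3) with `data.table`, `jsonlite`, `xml2`, `optparse`, plus a
`python` on the PATH with **RDKit** — all chemical identity,
fingerprinting and SMARTS rule application is delegated to a batched
RDKit helper process (`inst/python/chemtool.py`). If `python-libsbml` is
importable, exported SBML is additionally schema-validated through it.

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "pathsense", load_package = "installed")'
```

## Worked example

No database download is needed: the package ships a seeded toy-chemistry
generator whose ground-truth pathways are verified by exhaustive BFS at
generation time.

```r
library(pathsense)

toy <- generate_toy_chemistry(seed = 8, n_compounds = 10, branching = 1.7)
#> <toy chemistry seed 8: 10 compounds, 17 retro rules, 3 pair(s)>

pair     <- toy$pairs[[1]]
effector <- compound(toy$compounds$smiles[toy$compounds$key == pair$effector_key])
target   <- compound(toy$compounds$smiles[toy$compounds$key == pair$target_key])
effector
#> <compound NQPDZGIKBAWPEJ-UHFFFAOYSA-N: CCCCC(=O)O (NQPDZGIKBAWPEJ-UHFFFAOYSA-N), 15 fp bits>
target
#> <compound QTBSBXVTEAMEQO-UHFFFAOYSA-N: CC(=O)O (QTBSBXVTEAMEQO-UHFFFAOYSA-N), 7 fp bits>

tree <- mcts_search(effector, target, toy$rules,
                    search_config(max_depth = 10, iterations = 500, seed = 42))
tree
#> <search tree: 21 nodes, 9 hit(s), 334 iteration(s), status 'ok'>

scope <- build_scope(tree)
#> <scope: 9 compounds (7 on-chain), 14 reactions,
#>  QTBSBXVTEAMEQO-UHFFFAOYSA-N -> NQPDZGIKBAWPEJ-UHFFFAOYSA-N>

chassis  <- chassis_metabolome(toy$chassis_keys, "toy_chassis")
pathways <- rank_pathways(lapply(enumerate_pathways(scope),
                                 classify_pathway, chassis = chassis))
pathways[[1]]
#> <pathway: 2 step(s) [TR001 > TR016], global score 0.663, classified>
pathways[[1]]$roles
#> QTBSBXVTEAMEQO-...      "target"      (acetate, the producible)
#> NQPDZGIKBAWPEJ-...      "effector"    (valerate, the detectable)
#> FERIUCNNQQJTOY-...      "precursor"   (in the chassis)
#> XLYOFNOQVPJJNP-...      "precursor"   (water, in the chassis)

enzyme_query_links(pathways[[1]], "https://selenzyme.example.org/query")
#> [1] "https://selenzyme.example.org/query?rxn=CC%28%3DO%29O.O%3E%3ECCCC%28%3DO%29O"
#> [2] "https://selenzyme.example.org/query?rxn=CCCC%28%3DO%29O%3E%3ECCCCC%28%3DO%29O"
```

The best pathway converts the target in two steps into the effector; its
global score 0.663 is the penalty of its worst rule. `export_sbml()` and
`export_network_json()` write the interchange artifacts.

## Command line

```sh
LAUNCHER=$(Rscript -e 'cat(system.file("exec","pathsense",package="pathsense"))')
Rscript "$LAUNCHER" fixtures --seed 3 --n-compounds 10 --out toyfix
Rscript "$LAUNCHER" find --target toy02 --producibles toyfix/producibles.tsv \
    --effectors toyfix/effectors.tsv --rules toyfix/rules.csv \
    --chassis toyfix/chassis.tsv --out results_run
Rscript "$LAUNCHER" summary results_run
Rscript "$LAUNCHER" export --run results_run --pair 1 --format sbml \
    --chassis toyfix/chassis.tsv --out pathway.sbml.xml
```

Exit codes: `0` success, `2` input/usage error, `3` no pair connected.
Every run writes a `manifest.json` (seed, configuration, input digests);
identical inputs and seed reproduce byte-identical pathway tables.

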