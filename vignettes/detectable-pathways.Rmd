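---
title: "Designing biosensor-detectable pathways: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing biosensor-detectable pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Allosteric transcription factors turn the concentration of one small
molecule — their effector — into a genetic readout, but the catalogue of
known effectors is small. A target compound outside that catalogue can
still be sensed *indirectly* if a short enzymatic route converts it into
an effector. `pathsense` finds, ranks and exports such detectable
pathways for a chosen target, effector catalogue, retro rule set and
chassis organism.

## The procedure and its assumptions

**Backward expansion.** Retro reaction rules are generalized enzymatic
transformations written as reaction SMARTS with exactly one product-side
template. Applying a rule to a compound predicts the substrate set of a
forward reaction producing it. Rules carry a *diameter* (even, 0–16):
the bond radius of chemical context encoded around the reaction centre,
so higher diameters are more specific; and a *penalty score* in [0, 1],
lower meaning a more reliable rule. The engine assumes rule sets are
mono-component (cofactors stripped), as in RetroRules-style tables; a
predicted substrate set may still contain several molecules, and all of
them enter the pathway graph.

**Identity.** Compounds are compared by canonical key (InChIKey computed
by RDKit), never by SMILES string, because rule products arrive as
arbitrary SMILES that must match metabolome entries. Chassis membership
optionally ignores stereochemistry (first InChIKey block), since
metabolite lists are inconsistent about stereo annotation; this is the
default and is configurable per chassis object.

**Guided search.** The expansion from the effector toward the target is
a Monte Carlo tree search. The exact policy is fixed here as: UCT
selection (`value/visits + c*sqrt(log(parent visits)/visits)`, unvisited
children first, ties on canonical key); expansion materialises *all*
rule applications of the selected leaf at once; the rollout is depth-0 —
a new node is scored immediately by the Tanimoto similarity of its
Morgan fingerprint to the target, with terminal hits pinned at 1. This
is the simplest policy consistent with Tanimoto-guided node scoring, and
it makes the search fully deterministic: the `seed` in `search_config()`
is recorded for provenance and would only matter for stochastic policy
variants. When an application predicts several substrates, the tree
chains through the one most similar to the target (ties to the smaller
key); the remaining substrates ride on the edge as side compounds and
re-enter classification as precursors or supplements. A node whose key
equals the target's is a terminal hit and is not expanded further; an
optional similarity threshold (< 1) enables fuzzy hits but is off by
default because effector structures are exact.

**Enumeration.** The scope graph keeps exactly the compounds and
reactions on some root-to-hit path, merged on canonical keys. Pathways
are read in the forward production direction (target first). The
shortest-branch rule — keep, at each branched compound, only the
producing branches of minimal step count, then combine — is implemented
as enumeration over the shortest-path DAG of the scope: a simple path
whose total length equals the BFS distance necessarily reaches every one
of its nodes at that node's BFS level, so the two formulations coincide.
The per-pair pathway cap (default 1000) truncates after a deterministic
(score, length, rule-id) ordering and logs the suppressed count.

**Ranking.** Rule scores are penalties, so a pathway is only as good as
its worst step: the global score is the maximum step penalty and sorts
ascending. How the penalty term combines with precursor flux is not
pinned down by any single convention, so the two are composed
lexicographically behind one comparator (score, then descending summed
precursor flux with default 1 per unknown key, then length, then rule
ids); a weighted variant would be a one-line change in
`rank_pathways()`. No flux-balance analysis is performed: the flux map
is a user-supplied two-column file, and with none supplied the term
simply counts precursors.

**Classification.** Roles are assigned with fixed precedence: target and
effector keep their roles; chassis (or whitelist) members become
precursors — deliberately even when also produced in-pathway, since an
endogenous supply exists; compounds consumed but never produced become
supplements; everything else is an intermediate. The mapping is total,
mutually exclusive and exhaustive, which the acceptance suite asserts on
every fixture pathway.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_diameter`, `max_diameter` | 2, 16 | rule specificity window (bonds around the reaction centre) |
| `iterations` | 400 | MCTS budget per producible/effector pair |
| `max_depth` | 6 | pathway length cap, in backward steps |
| `exploration_constant` | 1/sqrt(2) | UCT exploration/exploitation balance |
| `similarity_threshold` | 1.0 | target-hit criterion; below 1 enables fuzzy hits |
| `max_pathways` | 1000 | per-pair enumeration cap |
| `pathsense.fp_radius` / `pathsense.fp_bits` | 2 / 2048 | Morgan fingerprint family for the guidance score (session options; the source material does not fix a fingerprint, so this is exposed as a tunable) |

## What the synthetic generator emulates — and what it does not

`generate_toy_chemistry()` builds a closed universe of linear alkanes,
alcohols, aldehydes, acids and amines (chain length 1–10, at most 50
molecules) connected by a random DAG of retro rules. Each toy rule is
*fully specified*: its product pattern pins every hydrogen count, which
is the diameter-16 limit where a rule describes one whole molecule, so
each rule matches exactly its intended product and the universe is
closed under rule application. About a third of edges carry water or
ammonia as a side substrate so that multi-substrate steps and the
supplement/precursor machinery are exercised. `branching <= 1` produces
a linear chain (one producing edge per compound); larger values draw
`1 + rpois(branching - 1)` producing edges. At generation time the
designed network is verified by an exhaustive backward BFS in the
chemistry kernel — the applications actually produced by SMARTS matching
must equal the designed edges — and ground-truth pathway sets are
recomputed from those verified applications with an independent BFS/DFS.

A green oracle-equivalence test therefore establishes that search, scope
construction and shortest-branch enumeration are exact on closed, small,
acyclic chemistries. It does *not* establish behaviour under promiscuous
low-diameter rules (where one rule matches many substrates), ring
chemistry, stereochemistry, tautomerism, or database-scale universes
where the iteration budget, the expansion cap and the pathway cap all
bind. Two deliberate consequences surface in the tests: the
BFS-completeness property is asserted on mono-substrate toys with the
deepest reachable target, because (a) the search never expands past a
terminal hit, so compounds lying strictly behind the target are
unreachable by design, and (b) on multi-substrate edges the tree chains
through the most target-similar substrate only.

## Numerical and engineering choices

* All chemistry (parsing, canonicalization, fingerprints, SMARTS
  application) runs in RDKit via a batched subprocess
  (`inst/python/chemtool.py`); there is no R-native cheminformatics
  stack of comparable coverage. Results are memoised per session, and
  each search prefetches its reachable space (bounded by
  `max_expansion_compounds`, default 5000 molecules) in a single kernel
  launch, so the per-call process cost is amortised.
* Tanimoto of two all-zero fingerprints is defined as 1 (identical empty
  bit sets) to avoid 0/0; it only arises for degenerate toy molecules.
* De-duplication keeps one application per distinct substrate set,
  retaining the lowest penalty then the lexicographically smallest rule
  id — RetroRules-style sets encode one parent reaction at many
  diameters, and naive use multiplies identical edges.
* Every ordering in the engine (children, applications, pathways,
  exports) uses radix sorts on canonical keys or rule ids, so identical
  inputs reproduce byte-identical outputs; the CLI derives one RNG seed
  per pair from the master seed and the pair's keys, making per-pair
  results independent of pair iteration order.
* Exported SBML is Level 3 Version 1 with roles, keys, InChIs and rule
  penalties in a namespaced annotation; compatibility with any specific
  downstream genetic-design workflow's annotation schema is unverified.
  Validation uses libsbml when importable and falls back to structural
  checks otherwise.

## Known limitations

No thermodynamic feasibility or enzyme-availability filtering; no
flux-balance analysis; no transposition tables across pairs (each pair
searches its own tree); the similarity threshold applies to hits only,
not to pruning; and headline database-scale statistics are out of reach
at desk scale by design — the validation here is property-based, on
synthetic chemistries with exhaustively known answers.
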