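---
title: "Predicting gut-bacterial flavonoid metabolism from enzyme promiscuity"
author: "FlavoPredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gut-bacterial flavonoid metabolism from enzyme promiscuity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FlavoPredict)
```

## The model

Flavonoids are not natural substrates of gut-bacterial enzymes, yet gut
communities methylate, hydroxylate, hydrogenate and ring-cleave them. The
working hypothesis of this package is *enzyme promiscuity*: an enzyme that
performs an atom-group transformation on its natural substrate can perform
the same local transformation on a non-natural substrate that presents the
same local atom environment. The unit of prediction is therefore not a
reaction but a **transformation operator**:

* a **reaction center** — the changed atom with the largest conserved
  neighbourhood;
* a **pattern** — the substrate-side atoms within two bonds of the center,
  with their atom types, charges and the bonds induced among them;
* an **edit script** — primitive edits (add/remove atom, add/remove bond,
  change bond order, change atom type) expressed against pattern node ids.

Operators are mined from atom-mapped reactant–product pairs
(`deriveOperators()`), applied wherever their pattern matches
(`matchSites()`, `applyOperator()`), and chained for at most two rounds
(`predictMetabolites()`), by analogy with two-step phase I/II xenobiotic
metabolism. Deeper recursion is deliberately excluded: without a reasoning
engine to rank reactions, the product space explodes combinatorially and
the two-round cap is the point at which predictions remain interpretable.

Atoms are typed by a closed vocabulary encoding element plus local
environment (`atomTypeVocabulary()`): `C.arom`, `C.carbonyl`,
`O.hydroxyl`, and so on. Matching is **exact** on the center label and on
the (bond order, atom type) multisets of both shells; no wildcard
relaxation is applied. This mirrors a fixed two-shell promiscuity pattern;
looser matching would trade precision for recall and is intentionally not
a default.

## Graph-level conventions

* **Implicit hydrogens.** Only heavy atoms are represented; `implicit_h`
  is derived from a fixed element→valence table (C4, N3, O2, S2, P5,
  halogens 1), with aromatic bonds contributing 1.5 to the used valence.
  A benzene carbon keeps one hydrogen; a ring-fusion carbon with three
  aromatic bonds keeps none.
* **Aromaticity.** Aromatic bonds are a fifth bond-order label, not an
  alternating Kekulé pattern. A single normalisation pass at parse time
  relabels every six-membered all-carbon ring with alternating single and
  double bonds as aromatic, so `C1=CC=CC=C1` and `c1ccccc1` yield the same
  graph and the same canonical key. Heteroaromatic rings are honoured when
  the input declares them (lowercase SMILES); the normalisation pass
  itself is deliberately conservative and does not attempt a general
  aromaticity perception.
* **Stereochemistry is ignored** throughout: the transformations modelled
  here are constitutional.
* **Canonical keys.** Deduplication needs an isomorphism-invariant key
  without an external compound registry. `canonicalKey()` subdivides each
  bond into an order-coloured vertex, canonicalises the coloured graph
  (BLISS), and serialises labels plus edges in canonical order. Key
  equality is cross-checked against VF2 isomorphism, and against a
  brute-force permutation oracle on small graphs, in the test suite.

## Derivation details and edge cases

The **change region** is the maximal connected set of atoms whose type,
charge, incident bonds or mapped existence differs between the two sides
of a pair; one operator is emitted per region and direction. Multi-site
reactions therefore split into reusable single-site operators. The
**center** is the changed *mapped* atom with the most conserved mapped
atoms within two bonds; ties break on the smallest canonical atom rank, so
derivation is deterministic. Two degenerate cases emit nothing (with a
logged message): a region with no mapped atom (a detached co-substrate or
co-product, e.g. free water) and a region whose edits would reach beyond
the second shell of every candidate center — the pattern language simply
cannot express such an operator.

The pattern includes *unmapped* substrate-side atoms within two bonds of
the center. This is required for removal operators: the atom to be removed
must be present (and locatable) in any substrate the operator applies to,
and the round-trip invariant — every derived operator regenerates its
source product at its source site — holds only under this convention.

Matching is an anchored monomorphism: pattern atoms map to distinct
substrate atoms, all pattern bonds must exist with equal order, and extra
substrate bonds among matched atoms are permitted (a chain-derived pattern
may match a ring). Matched sites are reported up to substrate
automorphism; the equivalence test colours the substrate by (atom label,
orbit of the assigned pattern node) and asks VF2 for a colour-preserving
self-isomorphism, so the two hydroxyls of catechol count once while the
four aromatic hydroxyl environments of quercetin count separately.
Products that would exceed an element's valence are dropped with a typed
condition and counted, not silently lost.

## Filtering and ordering

`FilterPolicy` removes trivial products by canonical key (water, CO2,
ammonia, glucose in `defaultFilterPolicy()`) and can restrict output to a
catalogued key set; the blocklist wins where both apply. Every output
table is sorted by (round, substrate key, operator id, product key), so
runs are bit-reproducible; the same discipline (canonical-key sorting,
seeded RNG, manifests with config hashes) applies to all pipeline stages.

## Organism mapping

EC numbers are matched on their first three fields. The fourth field names
the natural substrate or cofactor — precisely the specificity that
promiscuity prediction sets aside. Wildcards are accepted in the fourth
field only. `capabilityTable()` counts strain–enzyme *incidences*: a
strain carrying k distinct matching isozymes contributes k to a taxon's
numerator, which is then divided by the taxon's strain count. (Counting
strains instead of incidences is the other defensible convention; the
package asserts and tests the incidence one.) Genus-level tables aggregate
to phylum level exactly when weighted by strain counts — an arithmetic
identity the tests enforce, distinct from any biological claim about
taxonomic coherence.

## Similarity, clustering, embedding

Atom-pair descriptors are *binary* (type, type, topological distance)
feature sets with a 7-bond cap — counts and longer ranges add little at
these molecule sizes and binary presence is the most reproducible choice
when the reference binning is unspecified. Tanimoto similarity turns into
dissimilarity as 1 − s. Single linkage (via `stats::hclust`) clusters
reaction pairs; cutting the tree at height h yields the connected
components of the graph joining items at dissimilarity ≤ h. The closed
interval is chosen so that a cut at 0 returns exact-descriptor duplicates
and a cut at 1 returns a single cluster. By default reaction pairs are
described by their reactant side (configurable), since the query compound
is a substrate.

Classical MDS is Torgerson double centering (`stats::cmdscale`); negative
eigenvalues are truncated, coordinates are centered, and asking for more
dimensions than there are positive eigenvalues is an error — except for an
all-zero matrix, which embeds every item at the origin. The association
between structural and reaction-profile dissimilarities is a Pearson
correlation over the strict upper triangles with a Mantel permutation test
(`vegan::mantel`, 9999 permutations by default, seed mandatory); reaction
profiles are Jaccard dissimilarities over applicable-operator id sets —
one concrete, documented operationalisation of "predicted reaction
patterns".

## Homolog screen

"Sequence similarity" is operationalised as global (Needleman–Wunsch)
percent identity: matches divided by alignment columns, BLOSUM62, gap
opening 10, extension 0.5 — standard protein-alignment defaults, and a
positive-substitution similarity mode is available as an alternative. The
screen applies a *strict* > threshold (a candidate at exactly 80 % is
excluded). The tree method is neighbour joining on 100 − identity: no tree
method is canonical for this task, and NJ is the standard distance-based
choice that provably reconstructs additive matrices; the tests hold it to
exactly that.

## What the synthetic generators emulate — and what they do not

`genReactionCorpus()` emulates a reaction knowledge base at desk scale:
each pair is a decorated scaffold plus the product of one planted
transformation (aromatic hydroxylation, O-methylation, N-acetylation; an
aromatic chlorination serves as a decoy), with the exact conserved-atom
map recorded. Decoration attaches random alkyl/hydroxyalkyl chains at an
attachment atom at least three bonds from the center, so planted patterns
are recovered *exactly* — by construction, and the tests verify it. Real
reaction databases are messier: imperfect atom maps, multi-region
reactions, cofactor conventions, and atom-type vocabularies that drift
between releases. Passing the recovery tests therefore demonstrates the
correctness of the derivation/matching machinery, not robustness to curation
noise. Scaffold chemistry is valence-correct but not otherwise screened
for plausibility; the pipeline's contracts are graph-level.

`genOrganismMatrix()` plants EC carriers exactly and draws background ECs
from three-digit classes disjoint from the planted ones — adequate for
verifying the matching arithmetic, unrealistic as an EC frequency model.
`genHomologSet()` mutates by point substitution only (no indels), so
alignment identity equals the substitution-level target up to rounding.

Default study conditions used by the acceptance checks: corpora of 50
reactions over 10 scaffolds with the 3 planted patterns (recovery run
across 5 seeds at 30 reactions each), 1000 random ≤7-item matrices for the
clustering oracle, 50 random planar points for MDS recovery, a 24-strain
matrix, and 120-residue homolog sets at 95/85/70 % identity. These sizes
exercise every code path while keeping the whole suite inside a coffee
break on one CPU.

## The fixture pathway

The compound panel (`flavonoidFixtures()`) carries the naringenin C-ring
cleavage pathway — naringenin → naringenin chalcone → phloretin →
3,4-HPPA + phloroglucinol, plus the direct naringenin → phloretin
flavanone-cleaving reduction — and an O-methylation pair
(catechol → guaiacol). Pathway pairs are marked irreversible (the
catabolic direction), and the derived library reproduces the pathway under
two-round prediction: chalcone in round 1; phloretin in round 2 (round 1
with the direct reduction); 3,4-HPPA and phloroglucinol only when the
direct route frees a round for the hydrolytic ring fission. The same
methylation operator applied to quercetin yields isorhamnetin and
tamarixetin among its four products — the two methylated quercetin
metabolites long known from mammalian plasma. A worked run is shown in the
README; `scripts/acceptance.R` recomputes all of it from scratch.

```{r pathway, eval = FALSE}
fx  <- flavonoidFixtures()
lib <- fixtureOperatorLibrary()
predictMetabolites(fx$naringenin, lib, rounds = 2,
                   policy = defaultFilterPolicy())
```

## Known limitations

* Exact shell matching misses near-miss sites (e.g. a pattern demanding a
  free ortho-hydroxyl will not fire on its methylated analogue); that is
  the intended precision/recall trade-off of the two-shell model.
* Atom typing after an edit trusts the edit script; types of atoms
  *adjacent* to the region are not re-perceived. Consistent inputs give
  consistent outputs, but adversarial operator libraries can create
  graphs whose types a fresh perception pass would assign differently.
* The aromatic normalisation pass handles the common benzene-type case
  only; five-membered and fused heteroaromatic Kekulé inputs should be
  written with explicit aromatic labels.
* No reaction ranking: all pattern matches are reported, and two rounds
  are a hard cap.
* Site deduplication uses pattern-node orbits combined with a substrate
  colour isomorphism; in pathological symmetric cases this can merge
  sites slightly more aggressively than the strict joint-automorphism
  definition. None of the shipped fixtures or generators exhibits such a
  case.
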