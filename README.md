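# FlavoPredict

Gut bacteria transform dietary flavonoids — naringenin, quercetin and their
relatives — into metabolites the host tissue cannot make on its own:
methylated and hydroxylated derivatives, and, through cleavage of the
central heterocyclic C-ring, chalcones, dihydrochalcones and phenolic acids
such as 3-(4-hydroxyphenyl)propionic acid (3,4-HPPA). Which community
members can run which step is mostly unknown, because flavonoids are not
the natural substrates of the responsible enzymes. FlavoPredict is an R
package for *enzyme-promiscuity* prediction of this chemistry: it is aimed
at microbiome and natural-product researchers who want to go from a
reaction knowledge base plus a strain collection to testable hypotheses
about who metabolizes what, and through which enzyme.

## What it computes

**Atom-group transformation operators.** From an atom-mapped
reactant–product pair, the package identifies the change region — the
connected set of atoms whose type, charge or bonding differs between the
two sides — and summarises it as an operator: the reaction-center atom
type, its first- and second-shell neighbourhood pattern (exact multisets of
(bond order, atom type)), and an edit script (add/remove atoms and bonds,
change orders and types) expressed against the pattern. Reactions are
treated as reversible unless declared otherwise, so each pair yields
forward and reverse operators. An operator applied at its own source site
regenerates the recorded product exactly — a package-wide invariant.

**Two-round prediction with filtering.** Operators match a new substrate
wherever center and shells agree exactly (sites equivalent under a
substrate automorphism are reported once); the edit script then proposes a
product. Products feed one further round — mirroring two-step phase I/II
xenobiotic metabolism — and pass a filter policy that removes trivial
co-products (water, CO2, simple sugars) and can restrict output to a
catalogued metabolite set. Chemically invalid edits (valence violations)
are dropped and counted.

**Organism mapping.** Candidate enzymes travel with each operator as EC
numbers. A strain × EC incidence matrix with taxonomy links predictions to
organisms at three-digit EC resolution (the fourth digit encodes the
natural substrate, which is exactly what promiscuity relaxes), and
`capabilityTable()` tabulates matching enzymes per taxon, normalised by the
taxon's strain count.

**Similarity machinery.** Atom-pair descriptors — binary (type, type,
topological distance) features capped at 7 bonds — compared by the Tanimoto
coefficient, single-linkage clustering to shortlist reaction pairs
co-clustering with a query compound, classical (Torgerson) MDS maps, and a
Mantel-style permutation test for the association between structural and
predicted-reaction dissimilarities.

**Homolog screen.** Needleman–Wunsch global percent identity (BLOSUM62)
against a reference such as a plant chalcone synthase, a strict >80 %
screen, and a neighbour-joining tree on 100 − identity.

**Synthetic data.** Seeded generators produce reaction corpora with planted
operators (ground truth included), organism–enzyme matrices with planted
carriers, and mutated homolog sets at controlled identity, so the entire
analysis runs offline and every recovery claim is checkable.

## Worked example

Predict two rounds of gut-bacterial naringenin metabolism with the built-in
pathway operator library, then name the products that match known
compounds:

```r
library(FlavoPredict)
fx  <- flavonoidFixtures()
lib <- fixtureOperatorLibrary()
rec <- predictMetabolites(fx$naringenin, lib, rounds = 2,
                          policy = defaultFilterPolicy())
known <- vapply(fx, canonicalKey, character(1))
rec$compound <- names(known)[match(rec$product_key, known)]
rec[, c("operator_id", "round", "ec_numbers", "compound")]
```

```
             operator_id round       ec_numbers            compound
1    op.direct_reduction     1          1.3.1.-           phloretin
5           op.ring_open     1 5.5.1.6;2.3.1.74 naringenin_chalcone
9       op.retro_claisen     2          3.7.1.4      phloroglucinol
10      op.retro_claisen     2          3.7.1.4                hppa
11 op.chalcone_reduction     2          1.3.1.-           phloretin
...
```

(22 further rows are O-methylation products and round-2 derivatives without
a named fixture.) Read it as the C-ring cleavage pathway: ring opening
gives naringenin chalcone in round 1; hydrogenation of the chalcone — or
direct flavanone-cleaving reduction — gives phloretin; hydrolytic ring
fission of phloretin yields 3,4-HPPA (the B-ring acid) plus phloroglucinol
(the A-ring product) by round 2. Each row carries the EC numbers of the
candidate enzymes, which map onto strains:

```r
m <- genOrganismMatrix(seed = 1, n_strains = 12,
                       planted = list("2.3.1.74" = c(2L, 7L)))
organismsFor(c("5.5.1.6", "2.3.1.12"), m)
#> [1] "strain_002" "strain_007"
```

Strains 2 and 7 carry chalcone synthase (EC 2.3.1.74), which matches the
query 2.3.1.12 at three digits — the promiscuity premise in one line.

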