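---
title: "Reconstructing gene-family evolution across whole-genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-family evolution across whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohnologr)
```

## The problem

Vertebrate gene families were shaped by two rounds of whole-genome
duplication (WGD) on the vertebrate stem (1R/2R), a third round on the
teleost stem (3R) and a fourth in salmonids (4R), overlaid with tandem
duplications, gene losses and pseudogenizations specific to individual
lineages. Deciding whether two paralogs are ohnologs (WGD products) or
tandem copies, and on which branch each gain or loss happened, requires
combining several kinds of evidence: the branching order of gene trees
relative to the species tree, presence/absence patterns across species,
and the co-occurrence of neighboring gene families on related chromosomal
regions (paralogons). `ohnologr` implements each evidence stream as a
separate, testable module and adds a simulator that generates genomes with
a known history, so every inference step can be validated against truth.

The package ships a complete worked example: the vertebrate TRPV
ion-channel family (subtypes TRPV1–9 plus the ancestral metazoan clades),
with a 25-species tree, a subtype-by-species presence matrix, and an
executable event history whose propagation reproduces each species'
published repertoire, from the three genes of the spotted gar to the
fifteen of *Xenopus tropicalis*.

## The scenario engine

An event history is an ordered list of per-branch events. Branches are
identified by the label of the branch's child node; the root label
addresses the root branch, which is how the basal 1R/2R rounds are placed
before the first split. Propagation walks the tree in preorder; on each
branch, events apply in listed order to the repertoire inherited from the
parent:

* `wgd` duplicates every **coding** lineage (a pseudogene is dead weight
  and is not re-duplicated);
* `local_duplication` inserts `copies` extra copies of one target lineage;
* `loss` removes a lineage, `pseudogenization` flips its status — both
  affect only the branch's subtree, and targeting a lineage that does not
  exist there is an error, not a no-op.

Copy naming follows the field's conventions: 3R ohnolog pairs get `a`/`b`
suffixes (Zfin convention), 4R pairs get `α`/`β`, and lineage-specific
serial duplicates get a lineage prefix plus index (`m`, `sau`, `am`, `ch`,
`po`, `cy` for mammal, sauropsid, amphibian, chondrichthyan, Polypteridae
and cyclostome). The mammalian second TRPV5 copy carries the alias TRPV6.
Where the literature pins labels by synteny rather than creation order
(e.g. which 3R copy is "a"), the fixture uses explicit name maps so the
output matches the published labels deterministically. Counts exclude
pseudogenes unless asked, because published per-species totals count
functional genes.

`diff_vs_observed()` closes the loop: it compares a propagated repertoire
set against an observed presence matrix cell by cell. A matrix row naming
a base subtype aggregates lineages by subtype; a row naming a specific
paralog (the fixture's `sauTRPV5-2`) is matched by lineage name. `unknown`
cells match anything: the fixture encodes lamprey TRPV1 as unknown (its
absence may be an assembly artifact) while the history encodes an explicit
cyclostome loss, and the two encodings are consistent by construction.

## Dollo reconstruction

Each presence-matrix row is reconstructed under Dollo parsimony: one gain,
any number of losses, losses minimized. Pseudogene cells count as present
— a recognizable pseudogene proves the lineage persisted. The gain sits at
the MRCA of non-absent species unless a `gain_constraint` forces an older
node; the constraint is deliberately an input rather than something Dollo
invents, because the evidence for an older origin comes from a different
stream (gene-tree branching order via `infer_gain_constraint()`). The
TRPV9 case is the motivating example: presence alone puts its gain at the
elasmobranch ancestor, while its position as sister clade to TRPV3 pushes
the gain to the gnathostome ancestor, turning one loss into two (the
holocephalan and osteichthyan stems).

The minimal loss set is found in closed form: inside the gain subtree,
every maximal subtree free of present leaves that contains at least one
absent leaf receives exactly one loss. Ties created by unknown states are
broken toward the deepest placement (the MRCA of the subtree's absent
leaves) and flagged `ambiguous` when equally minimal rootward placements
exist. The test suite checks the minimal count against an exhaustive
subset-enumeration oracle on ~700 random trees and state columns.

## Reconciliation and WGD-window timing

`lca_reconcile()` is textbook LCA reconciliation on rooted binary trees:
an internal gene-tree node whose species image equals a child's image is a
duplication; losses are the species-tree edges skipped along gene-tree
edges (`d − 1` under a speciation, `d` under a duplication). Unrooted
input is rejected rather than silently rooted. Duplications are then timed
by where they map: a WGD-tagged branch gives `WGD:<tag>` (the fixture's
root branch carries both 1R and 2R, which are jointly reported as
`WGD:1R/2R` — they are not separable on a single stem branch), an untagged
terminal branch gives `lineage_specific`, an untagged internal branch
`local_prewindow`. Synteny corroboration of ohnolog status is a separate
module by design; tree timing alone cannot distinguish a WGD ohnolog from
a contemporaneous tandem copy.

## Synteny and paralogon detection

The synteny module works on gene coordinate tables (0-based half-open
internally; GFF3 converted at the file boundary). Neighbor windows span 10
Mb on either side of a focal gene — the scale at which WGD-era synteny is
conventionally screened. Candidate neighbor families need at least 2
genome-wide members and at most 4 (the 2R quartet expectation); families
of size 3–4 are flagged as extended-search finds. Paralogon assembly is
greedy co-occurrence: starting from seed chromosomes, add the chromosome
sharing the most candidate families with the accepted set, requiring at
least 2 shared families with some accepted region, capped at 4 regions
(raise the cap for post-3R/4R genomes). Gene order within a region is
deliberately ignored: WGD paralogon evidence is family co-occurrence, not
collinearity, because intra-chromosomal rearrangement scrambles order long
before it scrambles content. Ties break deterministically (shared count,
then member count, then chromosome name).

`compare_synteny()` reduces each species' table to focal-gene and
neighbor-family statuses (`present`/`duplicated`/`missing`/`pseudogene`)
and, when the focal gene is missing, checks whether its two expected
flanking families are directly adjacent — the signature of a clean loss as
opposed to an assembly gap.

## The simulator: a stated world

`simulate_genomes()` evolves chromosomes of genes along a rooted binary
species tree: WGDs on designated branches copy every chromosome, with each
new gene copy retained independently with probability
`wgd_retention_prob` (originals are kept — a family never goes extinct
through non-retention alone); tandem duplications insert adjacent copies;
losses delete genes or, with probability `pseudogenization_prob`, keep
them as pseudogenes; rearrangements are contiguous-block inversions or
cut-and-paste translocations. Event counts per branch are Poisson with
the configured rates — per branch, not per unit length, since the trees
carried no calibrated lengths. Coordinates use a fixed 10 kb gene span and
90 kb intergenic gap: windows and hulls then behave like a sparse
vertebrate gene map without modelling real gene-density variation.

The simulator emulates retention/loss/rearrangement structure, not
sequence evolution: there is no rate variation, no gene-tree estimation
error, no assembly fragmentation. A green recovery test therefore
establishes that the inference machinery is correct *given true gene
trees and complete genomes* — it does not establish robustness to
phylogenetic error, which the underlying comparative method handles by
manual curation and which is out of scope here. No quantitative retention
or loss rates are published for the system the fixture describes, so test
regimes sweep retention 1.0–0.3 with per-branch event rates of order 1 —
the regime in which vertebrate WGD case studies operate (most ohnolog
pairs resolved, a minority retained).

With losses active, a realized duplication is only *observable* when both
copies keep extant descendants, and loss-pruning can move a surviving
duplication's LCA image below its true branch. The recovery tests
therefore compare reconciliation output against the truth log's
observable duplications, with expected placements computed by an
independent pedigree-walk oracle; no-loss regimes are additionally
compared verbatim to the logged branches.

## Numerical and design choices

* Unlabelled internal tree nodes get deterministic preorder auto-labels
  (`N<k>`), so event files remain stable across runs.
* Strand is carried through all formats but used by no algorithm
  (inversions flip it in the simulator); the synteny comparisons here are
  orientation-blind.
* The fixture species tree is fully resolved; where the underlying
  comparative evidence is agnostic the resolution follows the standard
  backbone (e.g. Polypteridae sister to Neopterygii, Esociformes sister
  to Salmoniformes). Dollo accepts multifurcations; reconciliation
  requires binary trees and says so.
* The mammalian TRPV5 duplication is placed on the mammalian stem with a
  platypus-terminal loss of the first copy, reproducing both the inferred
  pre-prototherian timing and the single gene observed in platypus.
* Degenerate inputs fail loudly: empty matrices, unknown state tokens,
  events on unknown branches, and losses of non-existent lineages are
  errors with positions named, never silent coercions.

## Known limitations

* Real-genome paralogon statistics (retained-gene totals per species)
  require the original per-gene coordinates, which are not redistributable
  here; they are exercised through constructed toys with the published
  multiplicity structure and through simulation.
* LCA reconciliation takes gene trees as given; there is no bootstrap
  propagation, rooting search, or rate-aware (ML/Bayesian) reconciliation.
* Dollo is parsimony only — no gain/loss rate model — matching how the
  comparative argument is actually made for this family.
* The greedy paralogon assembler is exact on clean quartets and degrades
  gracefully, but it is a screening tool, not an optimal clustering of
  arbitrary rearranged genomes.
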