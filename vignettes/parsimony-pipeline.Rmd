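---
title: "Equally weighted parsimony for morphological matrices: models, search and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equally weighted parsimony for morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Morphological phylogenetics of fossil groups — aetosaurs are the motivating
case here — is still dominated by equally weighted maximum parsimony on small
discrete matrices: a few dozen operational taxonomic units (OTUs) scored for
on the order of a hundred characters, with heavy missing data, occasional
polymorphic cells, and a handful of characters declared additive (ordered).
The inference asks for the set of *most parsimonious trees* (MPTs): unrooted
topologies minimizing the total number of character-state changes. Everything
downstream — strict consensus, clade supports, wildcard diagnosis — is a
function of that set. `mpsearch` implements the whole chain as tested,
seed-reproducible R code.

## Scoring model

A cell of the matrix is a *state set* over the integer alphabet 0–9. A `?` or
`-` is fully missing and behaves as the whole alphabet of its character; a
polymorphic cell `[02]` is treated as ambiguity (the leaf may take any one of
the listed states), which is the conventional treatment of bracketed cells in
TNT-style matrices, not as fixed polymorphism.

Per character, the minimum number of changes on a tree is computed by:

* **unordered characters** — the Fitch set pass (any state-to-state change
  costs 1). On binary trees the classical intersection/union recursion is
  exact, including ambiguous leaves.
* **ordered (additive) characters** — the Farris interval pass on the integer
  state line, where a change from state $i$ to $j$ costs $|i-j|$. A
  polymorphic cell enters as the smallest enclosing interval of its states:
  this keeps the interval dynamic program exact and errs on the conservative
  (cheaper) side. One visible consequence: for non-polymorphic cells an
  ordered score can never undercut the unordered score of the same column,
  but a polymorphic cell such as `[02]` admits the intermediate state 1 for
  free under ordering, so the inequality does not extend to polymorphic
  columns.
* **trees with polytomies** — a generalized Sankoff dynamic program with the
  appropriate cost matrix (unit or $|i-j|$). This is exact on
  multifurcations, where the plain Fitch recursion is not defined, and it is
  what keeps collapsed trees scoreable.

The two specialized passes and the Sankoff program agree exactly on binary
trees; the test suite enforces this against a brute-force enumeration of all
internal-node state assignments on small trees, and against an independent
parsimony implementation (phangorn).

Tree length is invariant under the choice of display root, so the outgroup
(e.g. *Postosuchus kirkpatricki* in the aetosaur protocol, with
*Revueltosaurus callenderi* as second outgroup) affects only how trees are
drawn and written, never how they are scored.

## Search

The search replicates the "traditional search" protocol of TNT-based studies:

1. **Wagner addition.** A replicate draws a random addition sequence, builds
   the unique 3-taxon tree, and inserts each further taxon on the branch that
   minimizes the length increase, ties broken by the replicate RNG.
2. **TBR swapping.** The neighborhood of a binary tree is every
   tree-bisection-reconnection: cut any branch, suppress the cut endpoints,
   and reconnect every branch of one fragment to every branch of the other.
   A strictly better neighbor restarts swapping immediately; equal-length
   trees are kept up to the per-replicate hold (default 10).
3. **Pooling and final round.** Replicate results at the overall best length
   are pooled and swapped once more with the hold limit lifted, up to the
   global tree-buffer cap (default 10,000 — desk-scale memory, far above any
   plausible MPT count for matrices of this size). Without this final round,
   MPT counts would be artifacts of the per-replicate hold.
4. **Collapsing and identity.** Each tree is collapsed by rule 1 and the set
   is deduplicated; two trees are the same topology when their non-trivial
   bipartition sets are equal. MPT counts therefore refer to distinct
   collapsed topologies.

The default configuration (`search_config()`) is 100 replicates, hold 10,
rule-1 collapse — the protocol used for the published aetosaur matrix. The
worked analysis under `analysis/` and the acceptance script run 10–20
replicates on 10–12-taxon simulated matrices, which saturates those search
spaces while keeping a full rerun in minutes on one core; the exhaustive
oracle (all $(2n-5)!!$ topologies, feasible to 9 taxa) is what establishes
that the scaled-down searches still find true optima.

### Rule-1 collapsing

A branch is collapsed when its *minimum* length over all most-parsimonious
reconstructions is zero, computed per character from the Sankoff down-pass
and up-pass cost vectors of the two fragments the branch separates. The
package contracts one zero-minimum branch at a time and re-evaluates:
contracting several such branches simultaneously can increase the rescored
length of the collapsed tree when no single reconstruction puts zero changes
on all of them at once. Sequential re-evaluated contraction provably
preserves the length, and makes collapsing idempotent; both properties are
asserted in the tests. This is a deliberate departure from condensation
tools that contract all flagged branches in one pass.

## Consensus, supports, stability

* **Strict (Nelsen) consensus** is the tree displaying exactly the
  bipartitions common to all MPTs, built from the intersected split set.
* **Bremer (decay) supports** are computed from suboptimal pools: TBR
  closure over all distinct topologies within `k_max` (default 6) extra
  steps of the optimum. A clade's support is the smallest excess $k$ at
  which some pooled tree lacks it; clades surviving the whole pool report as
  `NA` (">k_max"). The pool construction was chosen over converse-constraint
  searches because it is directly checkable against the exhaustive-oracle
  definition (minimum length of any topology lacking the clade, minus the
  optimum) at small taxon counts, and the tests do exactly that. Bremer
  values computed this way cannot be *under*estimates; an unsaturated pool
  (buffer cap hit) could overestimate, and the report flags saturation.
* **Positional instability (PCR-style).** A taxon's *position* in a tree is
  the partition of the remaining leaves induced by its attachment node —
  for a binary attachment, the bipartition of the branch it sits on. Across
  the MPT set the package counts distinct positions and measures the
  *resolution gain* of pruning the taxon: resolved nodes of the reduced
  strict consensus (taxon pruned from every MPT, set deduplicated) minus
  resolved nodes of the full consensus with the taxon pruned. Taxa are
  ranked by gain, then position count; `greedy_prune()` iterates the
  ranking, re-evaluating after each pruning, until no pruning gains
  resolution. This is the greedy reduced-consensus variant of positional
  congruence reduction; the full character-congruence refinement (IterPCR)
  is intentionally out of scope.
* **A priori vs a posteriori.** Excluding taxa *a priori* removes matrix
  rows and requires a re-run of the search (stage 2 of the pipeline);
  pruning *a posteriori* drops leaves from the already-found MPTs. The
  two-stage pipeline (`run_mp_pipeline()`) uses both, in that order, the way
  the aetosaur analysis does: exclusion of the ranked unstable taxa, re-run,
  then a posteriori pruning of any remaining two-position wildcard. On the
  reduced system the pruned trees are rescored and the minimal ones carry
  the final Bremer computation.

## The synthetic-data generator

`simulate_matrix()` evolves each character by placing a fixed number of
change events on branches of a uniform random topology: ordered characters
step ±1 (reflecting at the ends of the state line), unordered characters
jump to another state uniformly. Event counts rather than continuous-time Mk
rates were chosen because the number of true changes is exactly the quantity
parsimony responds to; one event per character is homoplasy-free by
construction (the generating tree then attains the global minimum, one step
per character), and the event count is a direct homoplasy dial with no rate
calibration in between.

Defaults emulate the structure of the aetosaur-grade matrix the package is
aimed at: 28 OTUs × 83 characters, 7/83 additive, mostly binary characters
with some 3–4-state ones, two events per character and 30% missing cells
(fossil-typical), 2% polymorphic cells. What the generator does *not*
emulate: correlated characters, ascertainment bias ("variable characters
only" filtering), state-dependent missingness (missing cells concentrated in
fragmentary taxa), or author-style character constructions. Passing tests on
simulated data therefore demonstrate algorithmic correctness and protocol
behavior, not that any empirical matrix will behave comparably.

## Numerical and degenerate-input choices

* All state sets are bitmasks over 0–9; missing cells are expanded to the
  full alphabet of their character at scoring time.
* Characters with no observed state (all-missing columns) get a one-state
  alphabet and never contribute cost.
* Matrices with constant rows collapse to a star tree of length 0; searches
  and consensus handle 3-taxon trees and single-tree sets.
* Label matching is whitespace/underscore-insensitive throughout (TNT files
  use underscores where display names use spaces); labels with other
  unusual characters are quoted in Newick output.
* Tie-breaking (equal-length Wagner insertions, replicate order) is drawn
  from the single run seed, so seeded runs are bit-reproducible; reports
  embed the seed and an MD5 digest of the matrix.
* TNT `ccode` character indices are 0-based (the TNT convention); NEXUS
  `TYPESET` indices and every user-facing index in edits and reports are
  1-based, matching the `character:state` notation of published scoring
  lists.

## Replication mode and its guard

The two published search results this package is built to reproduce (34 MPTs
at 205 steps on the 28-taxon matrix; 6 MPTs at 193 steps after excluding the
three unstable taxa) depend on the deposited supplementary matrix, which is
not redistributable inside the package. `analysis/05_replication.R` runs the
full protocol when that file is supplied. Two guards matter:

* the matrix must carry its ordering declaration (`ccode`/`TYPESET`) for the
  seven additive characters — their identity lives in the source matrix's
  publication, and a run that silently treats them as unordered is not a
  replication, so `require_ordering = TRUE` refuses it;
* every reported number is re-derived from the stored trees by
  `verify_report()` before the report is written.

## Known limitations

* Pure-R TBR rescoring every neighbor is comfortable to ~15 taxa and usable
  to ~28 with patience; there is no incremental rescoring and no
  ratchet/sectorial/fusing strategy (the replicated protocol uses none).
* Bremer pools grow quickly with `k_max` and taxon count; the buffer cap
  bounds memory and is reported when hit.
* No implied weighting, no step matrices beyond ordered/unordered, no
  continuous or Dollo characters, no bootstrap/jackknife resampling, and no
  majority-rule consensus — these are outside the replicated protocol.
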