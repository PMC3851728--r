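---
title: "Parsimony cladistics of expression profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony cladistics of expression profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladexpr)
```

## The model

`cladexpr` applies cladistic parsimony to bulk expression profiles of a
disease cohort. The underlying model is deliberately minimal:

* Healthy tissue defines, per gene, an empirical normal range — the minimum
  and maximum over the healthy specimens' (log-ratio) values. Anything
  inside or on the boundary of that range is the ancestral condition;
  anything strictly outside is a derived condition, in one of two
  directions.
* Each disease specimen is a taxon described by binary characters, two per
  gene (`over`, `under`). A hypothetical all-ancestral taxon roots the
  analysis: it represents "healthy expression at every gene" and plays the
  role of an outgroup.
* Specimens sharing derived states are grouped: a most-parsimonious
  cladogram minimizes the number of independent expression changes needed
  to explain the observed states. Shared (clade-level) changes are
  synapomorphies; changes on terminal branches are specimen-specific.

The model's key assumptions, stated plainly: that being outside the healthy
min–max is biologically meaningful for every gene regardless of its
variance; that aberrations accumulate (the Camin–Sokal default forbids
reversion to normal along a path); and that shared aberrations reflect
shared process rather than coincidence. The heterogeneity diagnostics (tie
counts, terminal fraction) exist precisely because the last assumption
often fails in advanced degenerative disease.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `min_obs` | `normal_range()` | 3 | a min–max from fewer than 3 healthy values is degenerate; such genes are flagged excluded, not dropped silently |
| bounds | `polarize()` | inclusive | equality with the healthy extreme reads as "within normal"; only strict exceedance is derived |
| missing values | `polarize()` | `?` | absence of evidence is not evidence of normality; `?` contributes the cheapest consistent state during scoring |
| `criterion` | `parsimony_search()` | `camin_sokal` | polarization designates normal as ancestral; irreversibility matches that polarity. `wagner` (free reversals) is available for sensitivity analysis |
| `max_trees` | `parsimony_search()` | 1000 | cap on retained equally parsimonious topologies; tree identity is topology only |
| `swap` | `parsimony_search()` | `spr` | SPR plus root-reattachment moves; `nni` is faster but weaker |
| `ratchet` | `parsimony_search()` | 10 | parsimony-ratchet iterations (re-optimization under perturbed character weights) to escape local optima |
| `n_starts` | `parsimony_search()` | 5 | addition-sequence replicates; plateaus are merged at the global best length |

Expression values carry whatever scale the input had (log2 ratios in the
motivating data); polarization only compares values within a gene, so any
strictly increasing per-gene transform leaves the characters unchanged (a
property the test suite checks).

## Search design

Scoring is an exact two-state dynamic program per character with the root
fixed at the ancestral state; under Camin–Sokal the parent-1 → child-0
transition is forbidden. An independent closed form (the number of maximal
all-derived subtrees per character) cross-checks the irreversible scores.

For at most 12 taxa, branch-and-bound enumerates the rooted topology space
(the ancestor is fixed first, remaining taxa are inserted on every edge;
partial-tree length is monotone, so subtrees exceeding the incumbent are
pruned) and returns *all* most-parsimonious topologies.

The heuristic is stepwise addition (ties broken by the first position in a
deterministic preorder edge traversal) followed by hill climbing. A single
stepwise + swap pass — the textbook recipe — proved insufficient on random
matrices: SPR hill climbs stall in local optima one or two steps short of
the optimum. Three standard remedies are therefore on by default, and the
test suite holds the combination to *equality* with branch-and-bound on
random 9-taxon matrices:

1. the SPR neighborhood is completed with root-reattachment moves (the
   irreversible criterion is root-dependent, so moving the ancestor's
   attachment point changes the score and must be searchable);
2. a parsimony ratchet: a random quarter of the characters is doubled in
   weight, the tree re-optimized, the true weights restored and
   re-optimized, accepting ties so the search drifts between optima;
3. addition-sequence replicates with merged tie plateaus.

Everything is deterministic given the configuration: random orders and
ratchet weights derive from the `seed` argument through a local RNG that
does not disturb the caller's stream. Equally parsimonious trees are
collected by breadth-first plateau exploration and deduplicated by a
canonical Newick form; "the first tree" (used when a single cladogram must
be reported) is the first discovered at the final best length, which is
reproducible. Note that tie plateaus need not be connected under SPR, so
when the tie set is truncated or disconnected the retained set is a subset
of all MP trees — the tests assert best-length equality and subset
correctness, not tie-set equality.

## Synapomorphy mapping

Under Camin–Sokal the minimal irreversible labeling is unique: a node is
derived iff every observed leaf below it is derived and at least one is.
Under Wagner, ambiguity is resolved conservatively: after computing exact
per-subtree costs, states are assigned top-down taking the parent's state
where it is among the cheapest completions and the ancestral state 0 on
ties. A clade is therefore credited with a change only when strictly
required, and the count of ambiguous (node, character) optimizations is
reported separately. Node identity everywhere is the sorted leaf-name set,
stable across runs and machines.

## The synthetic generator

`simulate_cohort()` emulates the structure the analysis assumes: per-gene
Gaussian baselines (`mu ~ N(0,1)`, `sigma = 0.5`), a normal cohort whose
realized min–max defines the range, subtypes with planted shared
aberrations, and per-specimen private aberrations. Two deliberate design
choices remove detection stochasticity so that recovery tests exercise the
phylogenetic machinery and nothing else:

* planted aberrations are displaced `shift` baseline standard deviations
  beyond the *realized* normal extreme (default `shift = 3`), so
  polarization detects every planted aberration by construction;
* disease baselines are clamped into the realized normal range, so
  non-planted values never polarize as derived.

Defaults describe the clean recovery scenario: 500 genes, 20 normals, three
subtypes of five specimens with 20 shared aberrations each, no private
noise. The heterogeneity regime studied in the acceptance checks uses 5
shared aberrations per subtype and 200 private aberrations per specimen —
private picks collide across specimens (collisions are recorded in the
truth object), creating spurious shared characters that outnumber the
subtype signal and produce tied cladograms and broken monophyly.

What the generator does *not* model: per-gene variance heterogeneity beyond
the single `sigma`, correlated gene modules, dye-bias or other two-color
array artifacts, batch structure, or macular/extramacular pairing. Passing
recovery tests therefore show that the pipeline recovers planted structure
under its own assumptions; they say nothing about detection power against
realistic microarray noise, where the min–max cutoff is sensitive to single
outlying normals.

One property sometimes expected of such generators does not hold here:
*more private noise does not monotonically increase the number of tied
trees*. With zero noise the branching order inside each planted clade is
entirely unresolved, so the tie plateau is combinatorially huge; noise both
creates homoplasy ties and resolves within-clade order. The monotone
quantity is homoplasy itself (excess length over one change per character),
and that is what the test suite asserts.

Reproducibility uses one global seed from which per-stage sub-seeds (gene
parameters, normals, disease baselines, planted picks, private picks,
missingness mask) are derived additively, all below 2^31; changing one
stage's draws therefore does not reshuffle the others wholesale.

## Numerical and degenerate-input choices

* All-missing genes get an `NA` range and are excluded by `min_obs`;
  an entirely excluded gene set is an error, as is an empty normal or
  disease set.
* Characters in which no specimen is derived are removed before search
  (they carry no grouping information and only inflate the matrix).
* Duplicate character columns are weight-compressed before search; scores
  are integer arithmetic throughout (no floating-point lengths).
* PHYLIP export truncates names to 10 characters and errors on collisions
  rather than renaming silently; a sidecar file maps names back.
* `rf_distance` counts nontrivial *splits* (both sides ≥ 2), so the rooting
  taxon itself never contributes; this matches the unrooted
  Robinson–Foulds convention and is cross-checked against `phangorn`.
* Probe-level rows are used as-is by default; `collapse_probes()` (median
  per symbol) is provided but off, keeping the character space auditable.
* Macular and extramacular normals are pooled within tissue when defining
  ranges; `subset_tissue()` is the supported way to analyze tissues
  separately, mirroring the separate-polarization design.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: 100 (tests)
or 50 (script) random 9-leaf, 50-character matrices under both criteria
against branch-and-bound; 1000+ random (tree, character) closed-form
instances; one clean 500-gene recovery cohort; five 15-specimen
heterogeneity cohorts with ~1000 characters each; and the exhaustive
hypergeometric check for universes up to N = 12. These sizes were chosen to
exercise every code path at full stringency while completing a desk-scale
run in a few minutes.

## Limitations

* The min–max cutoff has no error model: one aberrant "normal" specimen
  widens a gene's range permanently. A robust-quantile variant would be a
  natural extension but is deliberately out of scope to keep the character
  definition transparent.
* No branch lengths, no support values, no statistical tests of competing
  topologies; congruence reporting is descriptive.
* The enrichment stage is a generic hypergeometric over-representation over
  user-supplied GMT collections; it does not reproduce any proprietary
  pathway knowledge base.
* Heuristic search guarantees are empirical, not formal: equality with the
  exhaustive oracle is demonstrated on randomized test beds, not proven.
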