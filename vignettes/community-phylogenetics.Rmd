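---
title: "Phylogenetic turnover across a landscape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic turnover across a landscape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloturn)
```

## The scientific question

Whether the standing diversity of a species-rich region was generated
mostly by allopatric or by sympatric speciation leaves a statistical
trace in how communities are assembled. Allopatric speciation places
sister species in distinct ranges, so closely related species tend not
to co-occur, and — after ranges expand and overlap again — phylogenetic
turnover between communities carries little spatial structure.
Sympatric speciation makes sister species co-occur, so recently formed
clades sit in spatial aggregations: turnover measured near the tips of
the phylogeny (betaMNTD) rises with distance between communities, and
groups of communities connected by significantly *low* turnover mark
the regions where diversification happened.

`phyloturn` implements the full analysis chain needed to test this on
tree-community survey data: building and age-calibrating a community
phylogeny from a backbone megatree, alpha and beta phylogenetic
metrics with permutation nulls, distance-matrix inference, detection
of spatial aggregations, and — because real survey compilations are
rarely reusable — a ground-truth simulator that generates landscapes
under either speciation mode.

## Trees: grafting, calibration, resolution

**Grafting** (`graft_taxa`) attaches a family/genus/species taxon list
to a backbone whose interior nodes are named with families and genera,
the way taxonomy-based megatree tools do: a taxon joins its genus node
when present, otherwise a new genus node is created under its family;
taxa whose family is unknown are reported and skipped; everything in
the backbone without grafted descendants is pruned. Congeners form a
polytomy at the genus node. Matching is case-insensitive with
punctuation normalized, because literature species lists mix
conventions.

**Calibration** (`calibrate_bladj`) fixes named nodes at their table
ages (tips at 0) and places every undated node on a path between two
fixed-age nodes so that successive ages are equally spaced: with `k`
undated nodes between ages `a > b`, node `i` from the older end gets
`a - i (a - b) / (k + 1)`. One genuinely open choice is what to do
when an undated node has several nearest dated descendants at
different depths; `phyloturn` gives the node the *oldest* of the
per-path candidate ages. This keeps every child strictly younger than
its parent (so branch lengths are positive by construction) and
reduces to the closed formula on chains. Conflicting calibrations — a
dated node at or above the age of its nearest dated ancestor — are
hard errors: silently clamping ages would corrupt every downstream
distance.

**Random resolution** (`resolve_polytomies`) turns each multifurcation
into dichotomies by sequential random pairing (uniform over the three
rooted resolutions of a trifurcation), then assigns the new nodes ages
by the same even-spacing rule with *every pre-existing node anchored
at its current age*. Resolution is therefore local: tip-to-tip
distances change only for pairs whose most recent common ancestor was
inside a former polytomy. Single-child chain nodes (a family whose
only genus has one species) are collapsed afterwards, which leaves
path distances untouched and makes the output strictly bifurcating.
The seed is a mandatory argument because the intended use is a
replicated sensitivity analysis.

Newick parsing and writing are implemented natively (recursive
descent) rather than through an external reader because grafted trees
legitimately contain those singleton chains, which mainstream Newick
readers mangle, and because parse errors should report character
offsets.

## Metrics and the null model

All metrics are presence–absence, computed from the cophenetic matrix
of the calibrated tree (entries are twice the age of the pair's most
recent common ancestor, in Myr):

* `mpd` — mean distance over all distinct pairs within a community;
  dominated by deep splits.
* `mntd` — mean distance from each member to its nearest relative in
  the same community; sensitive to recent splits.
* `beta_mpd` — mean over all cross pairs of two communities. Taxa
  shared by both communities contribute zero self-distances (the
  `comdist` convention). This matters: for strongly overlapping
  communities betaMPD is pulled toward zero, which is intended — the
  quantity measures turnover, and shared taxa are non-turnover.
* `beta_mntd` — mean over the taxa of both communities of the
  distance to the nearest taxon of the opposite community, zero for
  shared taxa; symmetric because both directions are averaged.
* `jaccard` — shared over union, the taxonomic companion measure.

Standardized effect sizes (`null_ses`) use the unconstrained null
model: each randomization relabels the taxon pool by a random
bijection, preserving both community sizes and the number of shared
taxa, and recomputes the metric. betaNRI and betaNTI are the
*negated* standardized effect sizes of betaMPD and betaMNTD, so
positive values mean lower turnover than chance; `|index| > 1.96`
(configurable) flags significance. When the null has zero variance
(for example on a star phylogeny, or for two identical communities,
where the shared-structure-preserving shuffle reproduces the observed
configuration exactly) the pair is flagged degenerate and no
significance call is made.

The per-pair randomization stream is derived by hashing the two
community ids with the run seed, so `all_pair_metrics` results do not
depend on the order communities are supplied in, and pairs can be
processed in chunks. The inner loop (metric recomputation over
hundreds of shuffles per pair) is in C++; everything else is R.

## Statistics

`mantel_test` correlates the lower triangles of two distance matrices
and permutes rows and columns of one matrix simultaneously; the
p-value is two-sided, `(1 + #{|r*| >= |r|}) / (1 + n_perm)`.
`partial_mantel` residualizes both triangle vectors on the
conditioners (any number), correlates the residuals — with one
conditioner this equals the closed-form first-order partial
correlation — and permutes the residual matrix of the first argument,
re-residualizing after each permutation. Default `n_perm` is 9999.

`anova_oneway` is the classical one-way F test; the compact letter
display comes from all pairwise Welch t-tests with Holm correction,
with letters assigned to maximal cliques of the
not-significantly-different graph. Welch + Holm was chosen over Tukey
HSD because group variances of turnover summaries are routinely
unequal; the letters are reported alongside the raw pairwise
decisions, so the choice is swappable.

`fit_glm` is a Gaussian identity-link model fit by least squares —
appropriate because responses are log10-transformed first
(`log10_transform` refuses non-positive values rather than fudging
with an epsilon) and checked with `normality_check` (Shapiro–Wilk).
`aicc` implements `-2 logL + 2k + 2k(k+1)/(n-k-1)` with `k` counting
intercept, slopes and the error variance. `dredge_glm` fits every
predictor subset including the null model and reports AICc, deltas
and Akaike weights.

A caution worth stating explicitly: with `n = 100` an irrelevant
candidate predictor is spuriously retained by AICc with probability
near `P(F(1, 96) > 2.17) ≈ 0.14`, so the exact generating model tops
the table in only ~86% of replicates per distractor. Model-selection
"recovery" rates should always be read against that baseline; the
acceptance script reports both the distractor-free and one-distractor
rates.

`concordance` (OLS slope plus squared Pearson correlation of paired
outcomes) is the summary used for the two sensitivity analyses: small
versus large pooling modes, and resolved versus unresolved trees.

## Pooling and pairwise structures

Literature surveys identify most but not all stems to species, and
they name the remainder inconsistently. `pool_taxa` canonicalizes
morphotype tags ("sp.", "sp. 1", "cf. ...") and supports the two
standard conventions: a *small* dataset where the same
genus-plus-tag merges across surveys (risking lumping genuinely
different morphotypes) and a *large* dataset where every survey's
morphotype stays separate (risking splitting the same one). Distinct
tags within one survey never merge, fully identified binomials always
do, and large-mode taxa map onto small-mode taxa by dropping the
survey suffix — which is what makes the small/large concordance
analysis well defined.

Geographic distances are haversine great-circle distances with Earth
radius 6371 km; climate differences are absolute pairwise differences
in native units (°C, mm). All pair tables carry `n(n-1)/2` rows keyed
by community ids and can be pivoted to symmetric matrices
(`pairs_to_matrix`) for the Mantel machinery.

## Aggregations

The field procedure for finding spatial aggregations is visual:
plot the significantly-low-turnover pairs on a map and circle the
clusters. The minimal formalization consistent with that is a graph:
communities are nodes, pairs with betaNTI (or betaNRI) above the
threshold are edges, aggregations are connected components
(`significant_low_pairs`, `connected_components`), labeled by their
smallest member so labeling is deterministic. Singleton communities
remain their own aggregation, so one-member groups are representable
in the within/between summary (`within_between_summary`), whose
single-pair groups report a mean but no standard deviation.
Components cannot shrink as the threshold drops; that monotonicity is
property-tested.

## The simulator

`simulate_dataset` builds the whole ground-truth object: a calibrated
tree, a community matrix, site climate, and true region labels. Its
defaults are the study conditions the package is validated under —
5 regions spread along a ~3000 km latitudinal arc, 10 communities per
region, 300 species, crown age 60 Myr — and they are not meant to be
nudged per analysis.

* **Tree**: pure birth. Founding lineages (default 3 per region) split
  at exponential waiting times; ages are rescaled so the root sits at
  the crown age. Extinction is deliberately absent: the tested logic
  concerns co-occurrence of extant sisters, and extinction only adds
  nuisance variance.
* **Ranges**: a founder occupies each community of its natal region
  with probability `founder_occupancy` (0.8). At a sympatric split
  both daughters inherit the parent's communities, each independently
  shedding a fraction `range_loss` (0.1) of them but always retaining
  a common anchor community — so sister species co-occur by
  construction, while ranges evolve enough that communities within a
  region are similar-but-not-identical. Without that range evolution
  every descendant of a founder would occupy exactly the founder's
  communities, making communities within a region either identical
  (degenerating the null) or different by whole root-depth clades;
  neither is a structure any real survey shows. At an allopatric
  split the parent's regions are divided between the daughters
  (vicariance), or — for a single-region parent — one daughter jumps
  to a different region, so sisters never co-occur before dispersal.
* **Dispersal**: after the tree completes, each species colonizes each
  unoccupied community with probability
  `dispersal_prob * exp(-d / dispersal_scale)` (`d` = km to the
  nearest occupied community). The default is the pure exponential
  kernel (`dispersal_prob = 1`, `dispersal_scale = 50` km, an order
  of magnitude under the ~675 km region spacing). The ceiling
  parameter exists because *any* finite kernel scale leaves a
  spatially structured colonization gradient that a Mantel test over
  ~1200 pairs will detect; the broad-secondary-contact scenario
  (ranges overlap with no spatial structure) is
  `dispersal_scale = Inf, dispersal_prob < 1`.
* **Climate**: MAT linear in latitude, MAP linear in longitude, plus
  independent Gaussian noise; habitat classes are temperature
  terciles. Climate differences therefore correlate with distance by
  construction, as they do along any real latitudinal gradient.
* **Tree degradation**: real community phylogenies are not fully
  resolved or fully dated. Interior nodes above `dated_above_frac`
  (0.4) of the root age are always dated anchors — deep backbone
  nodes are the fossil-calibrated ones — plus a fraction
  `dated_fraction` (0.6) of the shallow nodes; a fraction
  `collapse_fraction` (0.25) of the remaining undated nodes is
  collapsed into its parent, producing genus-style polytomies. The
  delivered tree is then recalibrated with `calibrate_bladj`, exactly
  the path a field dataset takes.
* Communities that end up empty (possible, though rare, with
  sub-complete founder occupancy) cause the whole dataset to be
  redrawn from a derived seed, with a message.

`expected_signature_check` runs the diagnostics that separate the
scenarios — Mantel correlation of betaMNTD (and Jaccard) with
distance, and the within- versus between-region betaMNTD contrast —
and compares them with the mode's predicted signature. A
single-region landscape is flagged inconclusive rather than scored.

What the simulator does *not* emulate: abundances carry no
information (presence–absence metrics are the analysis path),
sampling effort is uniform across communities, climate does not feed
back on ranges (no environmental filtering), and there is no
extinction or explicit genetics of sympatric divergence. Passing the
scenario-recovery tests therefore shows that the pipeline detects the
co-occurrence signature of speciation mode under dispersal
limitation; it does not show robustness to sampling bias or
filtering, which real compilations certainly contain.

## Numerical choices and degenerate inputs

* Calibration conflicts, non-positive values passed to the log
  transform, metrics on singleton communities, empty taxon sets,
  collinear model matrices and zero-variance distance triangles are
  all errors, never silent repairs.
* Degenerate permutation nulls (zero variance) are flagged, excluded
  from significance calls and from aggregation edges.
* SES thresholds default to 1.96 but are arguments everywhere.
* Per-pair RNG streams are derived from a polynomial hash of the
  sorted community ids plus the run seed, keeping results independent
  of input order while fully reproducible.
* Mantel defaults to 9999 permutations; the validation suites use
  999/199 to keep runtimes proportionate.

## Problem sizes used by the validation suites

The test and acceptance suites run at deliberately reduced but
statistically meaningful sizes, chosen once: metric oracles on 200
random instances of up to 12 tips; null-model calibration with 1000
replicates of 500 randomizations each; Mantel type-I error over 1000
null simulations of 20 communities at 999 permutations; 500
model-selection repetitions; 50 replicates per speciation scenario
(20 with full null-model aggregation detection at 199 randomizations)
at the full 5 x 10 x 300 study geometry; and 100 resolution seeds for
the concordance analysis. The resolution-sensitivity dataset uses a
binary founding radiation with a heavy load of shallow polytomies
(half the shallow nodes collapsed): concordance near 1 is a property
of taxonomy-style polytomies under dated anchors, and resolving a
*deep basal* polytomy genuinely moves MPD — a caveat that applies to
the field procedure itself.

## Known limitations

* The aggregation formalization (connected components) is the
  minimal reading of a visual procedure; a single spurious edge can
  merge two aggregations, which is why the significance threshold and
  the degenerate-pair exclusion matter.
* Pair observations entering the regression-style analyses are not
  independent (each community participates in `n - 1` pairs). The
  Mantel machinery accounts for this by permutation; the GLM/AICc
  path does not, and a multiple-membership random-effects analogue is
  deliberately out of scope.
* bladj even spacing is a convention, not an estimate; where several
  dated descendants disagree, the oldest-candidate rule is one
  defensible choice among several.
* The two-sided Mantel p-value is slightly conservative for the
  directional hypotheses tested here.
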