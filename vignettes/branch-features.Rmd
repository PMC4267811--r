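---
title: "Phylogenetic branches as conservation features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic branches as conservation features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchplan)
```

## The problem

Groundwater invertebrate faunas (stygofauna) are dominated by undescribed,
narrowly endemic species, which makes classical species-based systematic
conservation planning unworkable: there are no species lists, and most taxa
occur at one or two sampling points. branchplan implements an alternative
currency. Given a rooted phylogeny of whatever can be sequenced from each
site — individuals, haplotypes, morphotypes — *every branch of the tree*
becomes a conservation feature. A branch is present at a planning unit (PU;
here, a groundwater monitoring bore) whenever at least one tip descending
from it was recorded there. The phylogenetic diversity (PD) of a set of
units is then the summed length of the branches they jointly cover, always
including the paths connecting the represented tips to the root.

Formally, for branch $b$ with length $\ell_b$ and a unit set $S$,

$$\mathrm{PD}(S) \;=\; \sum_{b\,:\,\exists\,p \in S,\; x_{bp} = 1} \ell_b,$$

where $x_{bp}$ is the branch-by-unit incidence. Because a tip's presence
implies the presence of every branch on its root path, incidence rows of
ancestral branches dominate those of their descendants elementwise; PD is
monotone and submodular in $S$, which the test suite checks as invariants.

## Feature weights (SPF)

Reserve selectors of the Marxan family penalise unmet features by a species
penalty factor (SPF). We weight each branch by its relative length,
$w_b = \ell_b / D$ with $D$ the tree depth, so that on a clock-like
(ultrametric) tree the weights along any root-to-tip path sum to exactly 1.
For non-ultrametric input $D$ is the maximum root-to-tip distance — the
only choice that keeps every path sum at or below 1 — and the package warns,
since the normalisation is exact only for clock trees. A tree of depth 0
cannot be normalised and is an error. Zero-length branches are retained as
features of weight 0: they can never change PD, but keeping them makes the
Marxan export a faithful image of the tree.

## The annealing selector

The selector minimises, per run,

$$\mathrm{Score}(S) = \sum_{p \in S} c_p \;+\; \beta \sum_{b \text{ unmet}} w_b,$$

with every branch carrying a representation target of 1 and unit costs
$c_p$ defaulting to 1. A boundary-length term is deliberately absent:
sampling points have no shared boundaries. Three numerical choices needed
to be made that standard Marxan practice leaves open:

* **Penalty scale $\beta$.** Taken literally, weights that are at most 1
  against unit costs would make the empty reserve optimal. Marxan rescales
  penalties internally; we make the scaling explicit, with the default
  `"auto"` $= 10\,\max_p c_p / \min_{w_b > 0} w_b$, so that covering any
  branch of positive weight is always worth one unit's cost. Under equal
  costs and a cost cap the annealer then behaves as PD maximisation within
  the cap, which is how the selector is meant to be read.
* **Cap semantics.** A cost cap of $k$ with unit costs means "at most $k$
  units", enforced as a hard constraint: proposed additions that would
  breach the cap become swap moves. This matches the reading of cost
  restrictions as directly limiting how many units may be selected.
* **Schedule.** Initial temperature is adaptive (the standard deviation of
  100 sampled random-move score deltas), cooling is geometric down to
  $10^{-4}$ of the initial temperature over the run (default 100000
  iterations), and each run finishes with a deterministic steepest-descent
  pass over single adds, removes and swaps, so every reported solution is
  locally optimal. Defaults are configurable via `anneal_schedule()`.

Across runs (default 500) the per-unit *selection frequency* — the fraction
of best-per-run solutions containing the unit — estimates irreplaceability.
A unit that alone holds a branch whose weight exceeds anything else on
offer reaches frequency 1 at any cap, the behaviour expected of sites
carrying the deepest branches.

## Greedy summed-PD heuristic and rarefaction

`greedy_summed_pd()` is the classical complementarity ranking: pick the
unit with the highest PD, then repeatedly the unit with the largest PD
gain. Ties (gains equal within $10^{-9}$) are broken uniformly at random,
and once the accumulation reaches total PD the remaining zero-gain units
are appended in random order, so every replicate yields a full permutation
and average ranks are defined for all units. The default 100 replicates
summarise the tie-driven variability.

`expected_pd_exact()` is the matching null model: the expected PD of $m$
units drawn uniformly without replacement,

$$E[\mathrm{PD}(m)] = \sum_b \ell_b \left(1 -
  \binom{N - n_b}{m} \middle/ \binom{N}{m}\right),$$

with $n_b$ the branch's unit occupancy. Binomial ratios are evaluated in
log space (`lchoose`), so the computation is stable for thousands of
units; per-branch contributions are clamped to $[0, \ell_b]$ to suppress
sign artifacts of floating subtraction. A seeded Monte-Carlo estimator
(`expected_pd_montecarlo()`) provides an independent cross-check, and the
suite verifies the closed form against exhaustive subset enumeration on
every instance small enough to enumerate.

Branches never observed in any unit ($n_b = 0$) contribute to no curve and
are excluded from the "total PD" denominator used for PD fractions, so all
accumulation curves plateau at 1 on represented diversity.

## Synthetic data: what it emulates and what it does not

No field data ships with the package; `simulate_instance()` generates
instances with the statistical structure the method is sensitive to.

* **Trees.** A pure-birth (Yule) tree (via `ape::rphylo`, ultrametric by
  construction) rescaled to unit depth, optionally re-timed by the
  monotone sigmoid age map $t \mapsto t^{g}/(t^{g} + (1-t)^{g})$ applied
  to node ages. With $g = \gamma > 1$, deep divergences move rootward and
  shallow ones tipward, producing *stemmy* trees — compact crown groups
  subtended by long unbranched stems, as in slowly evolving nuclear
  markers. With $g = 1/\gamma$ divergences bunch at mid-depth and length
  shifts into the terminal branches — *tippy* trees, as in fast
  mitochondrial barcodes. The map fixes the endpoints, so ultrametricity
  is preserved exactly; $\gamma = 2$ is the default intensity, strong
  enough that stemmy trees reliably carry more length in the basal half
  of the depth (and on internal edges) than matched Yule trees, and tippy
  trees more on terminal edges.
* **Occupancy.** Each tip's range size is a shifted geometric variate
  capped at the number of units, with the success probability solved
  (`uniroot`) so the mean of the capped distribution equals
  `endemism * n_pus`; occupied units are then drawn uniformly. The default
  `endemism = 0.06` over 26 units puts most tips in one or two bores —
  narrow endemism — while still allowing occasional widespread taxa;
  `endemism = 1` degenerates to every tip everywhere. The default of 26
  planning units matches a realistic bore-field survey; tips-per-unit
  intensity is an order-of-magnitude choice, not calibrated to any survey.

The generator emulates *where branch length sits on the tree* and *how
narrowly tips are distributed*; it does not attempt sequence evolution,
sampling error, spatial autocorrelation among bores, or phylogenetic
signal in range placement (ranges are independent of the tree). Passing
tests therefore demonstrate correctness of the algorithms and the expected
qualitative contrast between tree shapes, not calibrated predictions for
any real aquifer.

With these defaults the contrast mirrors the field observation that
motivates the method: on stemmy trees the two most frequently selected
units capture a clearly larger PD fraction (about 60% in the shipped
acceptance run) than on tippy trees (about 40%), and every additional unit
adds more on tippy trees; the greedy curve dominates rarefaction
everywhere.

## Numerical conventions and degenerate inputs

* Equality of scores and PD values is judged at $10^{-9}$ absolute; the
  ultrametricity check is $10^{-6}$ relative on root-to-tip spread.
* Branch identifiers `b0001…` follow a deterministic preorder (cladewise)
  traversal, so encodings, exports and id maps are stable across runs.
* Empty planning units (no recorded tips) are legal, flagged on input, and
  simply have PD 0; tips present in the tree but missing from the
  occurrence table are treated as globally absent with a warning, which
  supports analysing a subset of surveyed bores.
* Occurrence counts are binarised on input: the encoding is strictly
  presence/absence.
* Marxan export writes `pu.dat`, `spec.dat`, `puvspr.dat` (comma
  delimited, header rows, `puvspr` sorted by unit then feature, amounts
  integer, SPF at 10 significant digits) plus id-map CSVs; writers are
  byte-deterministic. Import accepts commas or tabs and arbitrary feature
  tables; since ancestry is not recoverable from a bare matrix, the
  reported `dominance` flag records row laminarity (every overlapping
  pair of rows nested) as an informational diagnostic only.
* The brute-force oracle `optimal_subset_bruteforce()` refuses instances
  with more than $10^6$ candidate subsets and breaks exact ties
  lexicographically.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
instances up to 64 tips and 26 units for encoding checks, exhaustive
enumeration up to 12 units for rarefaction and annealer optimality, 500
annealing runs of 100000 iterations for selection-frequency results, and
20 matched stemmy/tippy pairs (24 tips, 26 units) for the tree-shape
contrast. These sizes keep every check exact or statistically
well-powered while remaining quick on a single CPU; all of them scale up
by changing the corresponding arguments.

## Known limitations

* The annealer is a stochastic heuristic; optimality is verified only
  against exhaustive enumeration on small instances, and on large ones
  the usual simulated-annealing caveats apply.
* The package does not parse Marxan *output* files or invoke a Marxan
  binary; the internal annealer is the supported solver, with the dat
  files provided for interoperability.
* PD here is strictly the rooted, presence/absence variant; there is no
  abundance weighting and no unrooted alternative.
* The command-line wrapper (`inst/cli/branchplan.R`) exposes the
  simulate/run/compare workflows; finer-grained operations (single PD
  queries, weight tables, Marxan import) are one-line calls in R and are
  not duplicated as subcommands.
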