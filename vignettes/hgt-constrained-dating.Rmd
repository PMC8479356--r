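---
title: "HGT-constrained molecular-clock post-processing: model, parameters, and limitations"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HGT-constrained molecular-clock post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `chronoHGT`, every
tunable parameter together with its default and the reason for it, what the
built-in synthetic-study generator does and does not emulate, the numerical
conventions, and the known limitations. It states no empirical result that
the package's test suite and `scripts/acceptance.R` do not themselves
compute; the code chunks are illustrative and not evaluated when the
vignette is built.

## 1. The compatibility model

A *chronogram* is a rooted, ultrametric, time-calibrated tree. The age of a
node is its distance (in the tree's time unit, conventionally Ma) above the
present; leaves have age 0 and the root carries the oldest age.

A *horizontal gene transfer (HGT) constraint* names a donor clade and a
recipient clade. The biological premise is that a gene moved from a lineage
inside the donor group into the stem or crown of the recipient group, so
the donor group must already have existed when the recipient group arose.
On a single chronogram the constraint is evaluated as a strict ordering of
node ages:

    compatible(t, c)  :=  age_t(donor_c) > age_t(recipient_c)

Each side of a constraint independently refers to either the **crown** age
(age of the most recent common ancestor of the clade's taxa) or the
**total-group** age (age of the parent of that ancestor, i.e. the stem
node). The default is crown/crown, which is the conservative choice: a
donor's crown age is a lower bound on when the transferred gene could have
existed inside the group, so crown-vs-crown compatibility is the hardest
version of the ordering to satisfy. Either side can be switched to
`"total"` per clade when the transfer is inferred to branch from the stem
lineage.

**Tie rule.** Exact age equality is *incompatible in both directions*. Ties
essentially never occur in real posterior samples (ages are continuous),
but they do occur in degenerate synthetic data and after aggressive
rounding; treating a tie as compatible would let a constraint and its
reversal both pass, which breaks the antisymmetry the downstream logic
relies on.

**Deduplication.** Curated transfer sets often contain several gene
families supporting the same donor/recipient pair. Because compatibility
depends only on the pair of (clade, crown-or-total) keys, duplicate
constraints would double-count one ordering in every score. The reader
collapses them to unique pairs by default, recording the merged identifiers
in the retained constraint's note.

## 2. The compatibility matrix, model scores, and calibration flags

For a posterior sample of `T` chronograms (after burn-in) and `C`
deduplicated constraints, the package computes the binary matrix
`M[t, c]`. Three summaries are derived:

* **Per-constraint profile** `p_c = 100 * mean(M[, c])` — the percentage of
  posterior trees satisfying constraint `c`.
* **Model score** `S = mean(p_c)`, which for a complete matrix equals 100
  times the fraction of compatible cells. Posteriors drawn under rate
  models that fit the data better concentrate on chronograms that satisfy
  more of the transfer-implied orderings, so `S` ranks candidate clock
  models on information the calibrations never saw.
* **Supported-constraint count**: the number of constraints with
  `p_c >= 20`. The 20% threshold separates "the posterior gives this
  ordering non-negligible support" from "this ordering is effectively
  excluded"; it is deliberately permissive, because a constraint that is
  genuinely true can still sit well below 50% when the two node ages are
  close.
* **Miscalibration flag**: a constraint with `p_c < 1.2` under *every*
  evaluated model is flagged. A single model rejecting an ordering points
  at that model; all models rejecting it while fitting everything else
  points at the constraint itself or — more interestingly — at a fossil or
  biomarker calibration that is pinning one of the two clades to the wrong
  age. The threshold is strict (about 1 tree in 80) because the flag is an
  accusation against curated external evidence and should fire only on
  near-unanimous rejection.

## 3. Posterior filtering

Filtering treats the constraints as data the original analysis could not
use. For each stringency level `n` in `1..C` the package compiles the set
of trees whose row sum is at least `n`; these sets are nested (the level-
`n+1` set is a subset of the level-`n` set), which `sweepFilter()` exploits
and the tests verify. `selectN()` then picks the largest `n` whose set
still contains at least `minTrees` chronograms (default 25), and
`summarizeAges()` recomputes per-clade posterior means and equal-tailed
credible intervals from that subsample.

* **`minTrees = 25`**: the credible intervals are percentile-based, and 25
  draws is about the minimum at which a 95% equal-tailed interval stops
  being dominated by the two extreme order statistics. Users summarizing
  many clades or needing stable interval widths should raise it.
* **Degenerate case**: if no level keeps `minTrees` trees (every tree
  violates every constraint, or the constraint set is internally
  contradictory), `selectN()` returns 0 and the command-line `filter`
  reports the *unfiltered* summaries with a loud warning rather than
  fabricating a subsample.
* **Interval convention**: ages are reported older bound first
  (`ci_older`, `ci_younger`), matching how deep-time intervals are read.
  Shifts are filtered minus unfiltered, so a negative `delta_mean` means
  the filter moved the node younger and a negative `delta_ci_width` means
  it tightened the interval.

## 4. Reading posterior samples

The reader targets the `datedist` dialect written by PhyloBayes-family
samplers: one newick chronogram per line, with blank lines, bare
tree-count headers, and `#` comment lines skipped. Parameters:

* **`burnInFraction = 0.2`** — the discarded prefix of each chain. The
  count of discarded trees is the *ceiling* of fraction × sample size:
  when in doubt the reader errs toward discarding one more pre-convergence
  tree rather than one fewer. 20% is the conventional default for chains
  whose convergence has already been checked upstream; this package does
  no convergence diagnosis of its own.
* **`tolerance = 1e-6`** — relative ultrametricity tolerance: the spread of
  leaf depths divided by the root age must not exceed it. Text-format
  branch lengths are rounded, so exact ultrametricity cannot be demanded;
  1e-6 admits ordinary 6-significant-digit output while rejecting trees
  that are genuinely non-clock. Node ages are then computed as the
  *maximum* path length to any descendant leaf, which guarantees parent
  age ≥ child age even after rounding.
* **`scale`** — multiplies all branch lengths on input, for samples written
  in units other than the analysis unit (e.g. 1000 for Ga → Ma).
* **`outgroup`** — unrooted trees are rejected, since node ages are
  undefined without a root; supplying an outgroup taxon set roots them
  first. Multiple chains may be pooled with `mergeChains()` after
  per-chain burn-in, preserving chain provenance in the tree names.

## 5. What the synthetic generator emulates — and what it does not

`simulateTrueChronogram()` draws one fixed "true" chronogram under a
Yule (pure-birth) process conditioned on the root age: the topology grows
by splitting a uniformly chosen extant lineage, and the non-root node ages
are i.i.d. truncated-exponential with density proportional to
`exp(-lambda * a)` on `(0, rootAge)`, assigned in descending order. This is
the standard constant-rate speciation null for deep bacterial phylogenies,
where extinction is unidentifiable anyway.

`simulatePosterior()` then emulates a dating posterior by perturbing every
true node age with independent lognormal noise with mean 1 (so the noise is
multiplicative and unbiased on the natural scale) and coefficient of
variation `ageNoiseCV`, followed by a postorder `pmax` repair that restores
parent ≥ child. `plantConstraints()` selects disjoint pairs of internal
nodes and emits constraints that are either true or false *in the
generating tree* according to `trueFraction`, with the ground truth
recorded alongside.

Defaults — `nTaxa = 30`, `birthRate = 0.001` per Ma, `rootAge = 3900` Ma,
`nTrees = 2000`, `ageNoiseCV = 0.15`, `nConstraints = 24`,
`trueFraction = 1` — are chosen so a default study resembles a deep-time
prokaryote dating problem in scale: a root near the age of the oldest
plausible cellular life, a few dozen terminals standing in for phylum-level
sampling, a posterior the size of a typical post-burn-in chain, node-age
uncertainty of a few hundred Ma at deep nodes, and a curated constraint set
of a couple dozen unique transfer pairs. They are also the package's own
choice of problem size: large enough that percentage-scale summaries are
stable, small enough that a full 50-replicate study runs in well under a
minute on one core.

**What the generator deliberately does not emulate** is the *structured*
error of a misspecified relaxed clock. Real rate-model misfit distorts node
ages systematically — whole regions of the tree are stretched or compressed
together, correlated across nodes and biased in a consistent direction —
and that is precisely the error mode HGT filtering is designed to correct:
trees drawn from the distorted posterior that nevertheless satisfy the
transfer orderings are the ones least affected by the distortion. Under the
generator's unbiased independent noise, by contrast, the unfiltered
posterior mean is already a nearly optimal estimator of each true age, and
conditioning on the true orderings can even *bias* the retained trees at
the constraint-defining nodes (trees where noise happened to exaggerate the
donor-minus-recipient gap are preferentially kept). Consequently the
generator is the right tool for verifying the machinery — exactness in the
zero-noise limit, matrix identities, nestedness, model ranking under
different noise levels — but it is *not* a demonstration that filtering
improves point-estimate accuracy, and the package's own whole-tree
RMSE experiment under this generator reflects that. Users should read
filtered-vs-unfiltered shifts on real data as "what the posterior looks
like once it is forced to respect the transfer record", not as a certified
accuracy gain.

A second simplification: all simulated trees share one topology. Real
dating posteriors mix topologies unless the tree was fixed; the package
handles per-tree topologies throughout (clades are re-resolved in every
tree, with a warning and MRCA fallback on non-monophyly), but the generator
does not exercise that path — the unit tests do, with hand-built trees.

## 6. Numerical conventions

* **Credible intervals** use `stats::quantile` type 7 (linear
  interpolation of order statistics), the R default, applied equal-tailed:
  a 95% interval is the 2.5% and 97.5% quantiles. For ages `1, 2, 3, 4`
  this yields `(1.075, 3.925)`.
* **Node ages** are max-depth to a descendant leaf (Section 4), computed
  once per tree in a vectorized postorder pass; samples sharing one
  topology take a fast path that resolves each clade a single time and
  reads all ages from a trees × nodes matrix.
* **Reproducibility**: every stochastic entry point takes a seed; internal
  stages derive sub-seeds as `(seed * 48271 + stage * 9973) mod (2^31 - 1)`
  so that, e.g., the true tree drawn for a configuration does not change
  when only the noise level changes. Seeds must be below 2^31.
* **Output**: all command-line artifacts are plain text (TSV with `#`
  metadata headers, newick, JSON), numerics at 6 significant digits, with
  a run log recording input checksums and package version, so two runs on
  the same inputs are byte-identical.

## 7. Decisions on points the method leaves open

* **Crown vs total-group ages**: evaluated per constraint side
  (Section 1), defaulting to crown/crown, rather than fixing one global
  convention.
* **Multiple chains**: supported by pooling after per-chain burn-in rather
  than requiring pre-concatenated input, so unconverged chains can be
  dropped individually.
* **Non-monophyletic clades**: resolved to the MRCA of the named taxa with
  a warning, rather than erroring, because constraint clades are usually
  defined on a reference taxonomy that individual posterior topologies may
  contradict; `monophylyReport()` quantifies how often.
* **Model comparison output**: models are ranked by score with
  deterministic tie-breaking on the label, so reruns are stable.

## 8. Limitations

* Compatibility is a hard 0/1 cut at strict inequality; there is no notion
  of "nearly compatible", and a constraint violated by 1 Ma counts the
  same as one violated by 1 Ga.
* Constraints are assumed independent; overlapping clades make row sums
  coarser summaries than a joint model of the orderings would be.
* Filtering is importance-free subsetting: the retained trees are not
  reweighted, so the filtered summaries are conditional posteriors under
  an implicit flat acceptance, not a formal joint posterior over clock
  model and transfer record.
* The package trusts the curated transfer directions; a reversed
  donor/recipient assignment silently inverts a constraint. The
  miscalibration flag helps detect this only when every model rejects the
  ordering.
* The generator's accuracy caveat of Section 5: synthetic studies validate
  correctness, not the real-data accuracy benefit of filtering.
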