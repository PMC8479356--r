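# chronoHGT

Horizontal gene transfer (HGT) constraints on Bayesian molecular-clock
posteriors.

## The problem

Bayesian relaxed-clock dating of deep divergences — the origin of crown
Cyanobacteria and oxygenic photosynthesis being the canonical example — is
notoriously sensitive to the branch-rate model (uncorrelated vs
autocorrelated), the tree prior, and the fossil calibrations chosen, with
credible intervals for the same node differing by a billion years across
defensible settings. Horizontal gene transfers provide relative dating
information that is independent of both fossils and geochemistry: a gene
transferred from a donor clade into a recipient clade implies the donor
lineage is at least as old as the recipient. Each sampled chronogram in a
dating posterior either satisfies this ordering ("compatible": the donor's
node age strictly exceeds the recipient's) or violates it.

`chronoHGT` turns a curated set of such donor → recipient constraints into
two post-processing tools for an existing dating posterior:

1. **Empirical model selection.** For a posterior sample of chronograms
   `t = 1..T` and constraints `c = 1..C`, the compatibility matrix is
   `M[t, c] = 1{ age_t(donor_c) > age_t(recipient_c) }`. The per-constraint
   compatibility is `p_c = 100 · Σ_t M[t, c] / T`, and the model score is
   the mean of the `p_c` (equivalently the fraction of compatible cells).
   Posteriors sampled under better-fitting rate models satisfy more of the
   HGT-implied orderings, so models can be ranked on data the calibrations
   never saw. Constraints with near-zero compatibility (< 1.2%) under
   *every* model flag a likely misplaced fossil/biomarker calibration
   rather than model misfit.
2. **Posterior filtering.** For every stringency level `n`, the set of
   trees passing at least `n` constraints is compiled (these sets are
   nested in `n`); the largest `n` that keeps at least `min_trees`
   chronograms is selected, and node-age means and equal-tailed 95%
   credible intervals are recomputed from that subsample, typically
   shifting deep nodes younger and tightening their intervals.

A fixed-topology Yule simulator with planted, ground-truthed constraints
makes every stage testable without any external data.

The package is for molecular-evolution researchers running PhyloBayes-style
dating analyses (the `datedist` one-newick-per-line posterior format is
read natively) who want to exploit curated inter-phylum "index" transfers.

## Worked example

A synthetic study: a 20-taxon chronogram with root age 3900 Ma, a
500-tree pseudo-posterior with 20% age noise, and 10 planted constraints
that are all true in the generating tree.

```r
library(chronoHGT)

cfg    <- simulationConfig(nTaxa = 20, nTrees = 500, ageNoiseCV = 0.2,
                           nConstraints = 10, seed = 42)
truth  <- simulateTrueChronogram(cfg)
sample <- simulatePosterior(truth, cfg)
cons   <- plantConstraints(truth, cfg)

mat <- compatibilityMatrix(sample, cons)
mat
#> CompatibilityMatrix: 500 trees x 10 constraints (89.44% compatible)
round(constraintProfile(mat), 2)
#> HGT_01 HGT_02 HGT_03 HGT_04 HGT_05 HGT_06 HGT_07 HGT_08 HGT_09 HGT_10
#>   98.4  100.0  100.0  100.0   70.8   63.6   61.6  100.0  100.0  100.0
modelScore(mat)
#> [1] 89.44
```

Every constraint is true in the generating tree, but age noise makes the
posterior violate the close-in-age pairs (HGT_05–07) in a third of the
trees. Filtering keeps only the chronograms that respect as many orderings
as possible:

```r
sw <- sweepFilter(mat)
sw
#> FilterSweep over 500 trees, 10 constraints
#>   trees passing >= n: 500 500 500 500 500 500 500 494 386 92
n <- selectN(sw, minTrees = 25)   # most stringent level keeping >= 25 trees
#> [1] 10

crown <- cladeDefinition("crown_focal", cons[[1]]@donor@taxa)
unf <- summarizeAges(sample, clades = list(crown))
fil <- summarizeAges(sample, treesPassing(sw, n), clades = list(crown))
compareFiltered(unf, fil)
#>         clade group_kind delta_mean delta_ci_width
#> 1 crown_focal      crown     -3.352         -46.92
```

The 92 chronograms compatible with all 10 constraints date this focal
crown group at 2374.8 Ma (95% CI 3337.3–1649.9, older bound first) versus
2378.2 Ma (3366.4–1632) unfiltered: a slightly younger mean and a 47 Ma
narrower interval, against a true age of 2388.8 Ma.

The same analysis on real dating output:

```sh
hgt-clock filter --trees chain1.datedist --trees chain2.datedist \
  --clades clades.tsv --constraints hgts.tsv \
  --burn-in 0.2 --min-trees 25 --out results/
```

which writes the sweep table, filtered and unfiltered per-clade summaries,
the per-clade shift table, and a consensus chronogram annotated with
`[&age_mean=...,age_ci={older,younger},age_mean_hgt=...,age_ci_hgt={...}]`
comments.

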