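#' @import methods
#' @importFrom stats quantile rexp runif rlnorm setNames
#' @importFrom utils write.table read.delim packageVersion head tail
NULL

setOldClass("phylo")

#' Chronogram: a rooted ultrametric tree with node ages
#'
#' A `Chronogram` wraps a rooted `ape::phylo` tree whose branch lengths are in
#' units of time (typically Ma) together with a vector of node ages in
#' time-before-present. Leaf ages are exactly 0; every internal node's age is
#' the maximum path length to a descendant leaf, so `age(parent) >= age(child)`
#' holds on every edge even when the text representation of the input tree was
#' rounded. Construct with [computeNodeAges()].
#'
#' @slot phy rooted `phylo` object (binary root).
#' @slot nodeAges numeric vector of ages indexed by ape node number
#'   (tips `1..Ntip`, internals `Ntip+1 .. Ntip+Nnode`); tips are 0.
#' @slot sourceLine integer line of origin in the input file (`NA` if not
#'   file-derived).
#'
#' @seealso [computeNodeAges()], [readDatedist()], [rootAge()]
#' @export
setClass("Chronogram",
  representation(phy = "phylo", nodeAges = "numeric", sourceLine = "integer"),
  validity = function(object) {
    phy <- object@phy
    msg <- character(0)
    if (!inherits(phy, "phylo")) msg <- c(msg, "phy must be a 'phylo' object")
    n <- length(phy$tip.label)
    m <- phy$Nnode
    if (length(object@nodeAges) != n + m)
      msg <- c(msg, "nodeAges length must equal Ntip + Nnode")
    else {
      ages <- object@nodeAges
      if (any(ages[seq_len(n)] != 0))
        msg <- c(msg, "all leaf ages must be exactly 0")
      slack <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
      if (any(slack < 0))
        msg <- c(msg, "node ages must be non-increasing from root to tips")
      if (n >= 2 && ages[n + 1L] <= 0)
        msg <- c(msg, "root age must be positive for a tree with >= 2 leaves")
    }
    if (length(msg)) msg else TRUE
  }
)

#' PosteriorSample: an ordered collection of chronograms
#'
#' Holds the post-burn-in chronograms sampled from one (or several merged)
#' MCMC chains of a Bayesian dating analysis, over a shared leaf set, tagged
#' with free-text model and calibration labels (e.g. `"CIR_nobd"`, `"BE"`).
#'
#' @slot trees list of [Chronogram-class] objects, in sampling order.
#' @slot leafSet character vector of taxon labels (sorted).
#' @slot modelLabel,calibrationLabel free-text tags carried into reports.
#' @slot provenance data.frame with one row per source chain: `file`,
#'   `chain`, `kept`, `discarded`.
#'
#' @seealso [readDatedist()], [mergeChains()], [nTrees()]
#' @export
setClass("PosteriorSample",
  representation(trees = "list", leafSet = "character",
                 modelLabel = "character", calibrationLabel = "character",
                 provenance = "data.frame"),
  validity = function(object) {
    if (length(object@trees) == 0L)
      return("a PosteriorSample must contain at least one tree")
    if (!all(vapply(object@trees, is, logical(1), class2 = "Chronogram")))
      return("all elements of trees must be Chronogram objects")
    ls <- sort(object@leafSet)
    for (i in seq_along(object@trees)) {
      tl <- sort(object@trees[[i]]@phy$tip.label)
      if (!identical(tl, ls))
        return(sprintf("tree %d leaf set differs from the sample leaf set", i))
    }
    TRUE
  }
)

#' CladeDefinition: a named taxon set resolvable to a node age
#'
#' Defines a clade by an explicit, non-empty set of leaf labels plus a group
#' kind: `"crown"` (age of the MRCA of the taxa) or `"total"` (age of the
#' parent of the crown MRCA, i.e. the base of the stem lineage).
#'
#' @slot name clade name.
#' @slot taxa non-empty character vector of leaf labels.
#' @slot groupKind `"crown"` or `"total"`.
#'
#' @seealso [resolveCladeAge()], [readCladeTable()]
#' @export
setClass("CladeDefinition",
  representation(name = "character", taxa = "character", groupKind = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    if (length(object@taxa) == 0L) msg <- c(msg, "taxa must be non-empty")
    if (anyDuplicated(object@taxa)) msg <- c(msg, "taxa must be unique")
    if (length(object@groupKind) != 1L ||
        !object@groupKind %in% c("crown", "total"))
      msg <- c(msg, "groupKind must be 'crown' or 'total'")
    if (length(msg)) msg else TRUE
  }
)

#' ResolvedClade: a clade located in one chronogram
#'
#' The result of resolving a [CladeDefinition-class] in a single tree: the
#' node used for the age (MRCA for crown, its parent for total), the age
#' itself, and whether the taxa are monophyletic (the MRCA's descendant leaf
#' set equals the clade's taxon set exactly).
#'
#' @slot clade the [CladeDefinition-class] that was resolved.
#' @slot treeIndex integer index of the tree within its sample (`NA` for a
#'   standalone tree).
#' @slot node ape node number whose age is reported.
#' @slot age time-before-present.
#' @slot monophyletic logical.
#'
#' @seealso [resolveCladeAge()]
#' @export
setClass("ResolvedClade",
  representation(clade = "CladeDefinition", treeIndex = "integer",
                 node = "integer", age = "numeric", monophyletic = "logical"),
  validity = function(object) {
    if (length(object@age) != 1L || is.na(object@age) || object@age < 0)
      return("age must be a single non-negative number")
    TRUE
  }
)

#' HGTConstraint: a donor-to-recipient relative-age assertion
#'
#' A horizontal gene transfer from a donor clade to a recipient clade implies
#' the donor lineage is at least as old as the recipient; a chronogram is
#' *compatible* with the constraint when the donor node's age is strictly
#' greater than the recipient node's age. The node used on each side follows
#' that clade's `groupKind` (crown by default).
#'
#' @slot id constraint identifier (e.g. `"HGT_07"`).
#' @slot donor,recipient [CladeDefinition-class] objects with distinct taxon
#'   sets.
#' @slot note free text; [dedupConstraints()] records merged ids here.
#'
#' @seealso [isCompatible()], [compatibilityMatrix()], [readConstraintTable()]
#' @export
setClass("HGTConstraint",
  representation(id = "character", donor = "CladeDefinition",
                 recipient = "CladeDefinition", note = "character"),
  validity = function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
      return("id must be a single non-empty string")
    if (setequal(object@donor@taxa, object@recipient@taxa))
      return("donor and recipient taxon sets must not be identical")
    TRUE
  }
)

#' CompatibilityMatrix: trees x constraints boolean table
#'
#' Cell `(t, c)` is `TRUE` when tree `t` of a posterior sample satisfies HGT
#' constraint `c` (donor strictly older than recipient). All downstream
#' quantities -- per-constraint compatibility percentages, model scores,
#' filter sweeps -- derive from this table.
#'
#' @slot values logical matrix, rows = trees (post burn-in), columns =
#'   constraint ids; no missing cells.
#' @slot modelLabel,calibrationLabel carried over from the sample.
#'
#' @seealso [compatibilityMatrix()], [constraintProfile()], [modelScore()],
#'   [sweepFilter()]
#' @export
setClass("CompatibilityMatrix",
  representation(values = "matrix", modelLabel = "character",
                 calibrationLabel = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.logical(v)) return("values must be a logical matrix")
    if (anyNA(v)) return("values must be complete (no missing cells)")
    if (ncol(v) > 0L && is.null(colnames(v)))
      return("columns must be named by constraint id")
    TRUE
  }
)

#' ModelReport: per-model summary of HGT compatibility
#'
#' Summarizes one [CompatibilityMatrix-class]: the compatibility percentage of
#' each constraint, their mean (the model score used for model selection), the
#' number of constraints supported by at least `supportThreshold` percent of
#' the posterior, and the constraints falling below `flagThreshold` percent
#' (candidates for miscalibration when low in *every* model, see
#' [flagMiscalibration()]).
#'
#' @slot modelLabel model tag.
#' @slot perConstraintPct named numeric, percentages in \[0, 100\].
#' @slot overallPct mean of `perConstraintPct`.
#' @slot supportedCount integer count of constraints at or above the support
#'   threshold.
#' @slot flagged character vector of constraint ids below the flag threshold
#'   in this report.
#'
#' @seealso [modelReport()], [flagMiscalibration()]
#' @export
setClass("ModelReport",
  representation(modelLabel = "character", perConstraintPct = "numeric",
                 overallPct = "numeric", supportedCount = "integer",
                 flagged = "character"),
  validity = function(object) {
    p <- object@perConstraintPct
    if (any(p < 0 | p > 100)) return("percentages must lie in [0, 100]")
    if (abs(object@overallPct - mean(p)) > 1e-8)
      return("overallPct must equal the mean of perConstraintPct")
    if (object@supportedCount < 0L || object@supportedCount > length(p))
      return("supportedCount out of range")
    TRUE
  }
)

#' FilterSweep: trees passing at least n constraints, for every n
#'
#' For each stringency level `n` from 1 to the number of constraints,
#' records the set of tree indices whose compatibility row sum is at least
#' `n`. The sets are nested: `perN[[n + 1]]` is a subset of `perN[[n]]`.
#' The most stringent feasible level is chosen with [selectN()].
#'
#' @slot perN list of integer vectors, element `n` holding the indices of
#'   trees passing at least `n` constraints.
#' @slot nTrees total number of trees in the underlying matrix.
#'
#' @seealso [sweepFilter()], [selectN()], [summarizeAges()]
#' @export
setClass("FilterSweep",
  representation(perN = "list", nTrees = "integer"),
  validity = function(object) {
    sets <- object@perN
    if (length(sets) >= 2L) {
      for (n in seq_len(length(sets) - 1L)) {
        if (!all(sets[[n + 1L]] %in% sets[[n]]))
          return(sprintf("per-n sets are not nested at n = %d", n))
      }
    }
    TRUE
  }
)
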