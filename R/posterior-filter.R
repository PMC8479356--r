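# Filtering the posterior to HGT-compatible chronograms and summarizing ages.

#' Compile the sets of trees passing at least n constraints
#'
#' For each stringency level `n` from 1 to the number of constraints, the
#' set of trees whose compatibility row sum is at least `n` is recorded.
#' "Passing n constraints" is cumulative (at least n), so the sets are
#' nested and shrink monotonically as n grows; any combination of
#' constraints may make up a tree's n, which keeps the filter robust against
#' the influence of a single constraint.
#'
#' @param matrix a non-empty [CompatibilityMatrix-class].
#' @return a [FilterSweep-class].
#' @seealso [selectN()], [sweepTable()]
#' @export
sweepFilter <- function(matrix) {
  v <- matrix@values
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("sweep requires at least one tree and one constraint")
  rs <- rowSums(v)
  perN <- lapply(seq_len(ncol(v)), function(n) which(rs >= n))
  new("FilterSweep", perN = perN, nTrees = nrow(v))
}

#' @describeIn sweepFilter trees passing at least `n` constraints.
#' @param sweep a [FilterSweep-class].
#' @param n stringency level (0 returns all trees).
#' @export
treesPassing <- function(sweep, n) {
  if (n == 0L) return(seq_len(sweep@nTrees))
  sweep@perN[[n]]
}

#' @describeIn sweepFilter summary data.frame with columns `n` and
#'   `trees_passing`.
#' @export
sweepTable <- function(sweep) {
  data.frame(n = seq_along(sweep@perN),
             trees_passing = vapply(sweep@perN, length, integer(1)))
}

setMethod("show", "FilterSweep", function(object) {
  counts <- vapply(object@perN, length, integer(1))
  cat(sprintf("FilterSweep over %d trees, %d constraints\n",
              object@nTrees, length(object@perN)))
  cat("  trees passing >= n:", paste(counts, collapse = " "), "\n")
})

#' Select the most stringent feasible number of constraints
#'
#' Returns the largest `n` such that at least `minTrees` chronograms pass at
#' least `n` constraints -- the most stringent filter that still leaves
#' enough trees to estimate age distributions. Returns 0 when even `n = 1`
#' leaves fewer than `minTrees` trees; the caller should then report
#' unfiltered ages with a prominent warning rather than fail.
#'
#' @param sweep a [FilterSweep-class].
#' @param minTrees minimum acceptable subsample size (default 25).
#' @return integer in `0..nConstraints`.
#' @export
selectN <- function(sweep, minTrees = 25) {
  stopifnot(minTrees >= 1)
  counts <- vapply(sweep@perN, length, integer(1))
  ok <- which(counts >= minTrees)
  if (length(ok) == 0L) return(0L)
  max(ok)
}

#' Posterior mean and credible interval of clade ages over a tree subset
#'
#' For each clade, computes the mean and equal-tailed credible interval of
#' its resolved ages over the given subset of trees. Bounds are
#' linear-interpolation percentiles (`stats::quantile` type 7) and reported
#' older bound first, following the conventional "(older-younger)"
#' presentation of node-age CIs.
#'
#' @param sample a [PosteriorSample-class].
#' @param subset integer vector of tree indices (non-empty).
#' @param clades list of [CladeDefinition-class] objects.
#' @param ciLevel credible level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @return data.frame with columns `clade`, `group_kind`, `mean`,
#'   `ci_older`, `ci_younger`, `n_trees`, `filtered` (`TRUE` when the subset
#'   is a proper subset of the sample).
#' @export
summarizeAges <- function(sample, subset = seq_len(nTrees(sample)), clades,
                          ciLevel = 0.95) {
  subset <- as.integer(subset)
  if (length(subset) == 0L)
    stop("empty tree subset: no chronograms pass the filter; lower minTrees ",
         "or relax the constraint set")
  stopifnot(all(subset >= 1L), all(subset <= nTrees(sample)),
            ciLevel > 0, ciLevel < 1)
  am <- cladeAgeMatrix(sample, clades, warn = FALSE)
  a <- (1 - ciLevel) / 2
  filtered <- length(unique(subset)) < nTrees(sample)
  rows <- lapply(seq_along(clades), function(k) {
    x <- am[subset, k]
    q <- quantile(x, c(1 - a, a), names = FALSE, type = 7)
    data.frame(clade = clades[[k]]@name,
               group_kind = clades[[k]]@groupKind,
               mean = mean(x), ci_older = q[1L], ci_younger = q[2L],
               n_trees = length(subset), filtered = filtered,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shift in clade-age summaries caused by HGT filtering
#'
#' @param unfiltered,filtered data.frames from [summarizeAges()] over the
#'   same clades (same order).
#' @return data.frame with per-clade `delta_mean` (filtered minus
#'   unfiltered; negative means the filtered estimate is younger) and
#'   `delta_ci_width` (change in credible-interval width; negative means
#'   more precise).
#' @export
compareFiltered <- function(unfiltered, filtered) {
  if (!identical(unfiltered$clade, filtered$clade) ||
      !identical(unfiltered$group_kind, filtered$group_kind))
    stop("clade lists of the two summaries do not match")
  data.frame(clade = unfiltered$clade,
             group_kind = unfiltered$group_kind,
             delta_mean = filtered$mean - unfiltered$mean,
             delta_ci_width = (filtered$ci_older - filtered$ci_younger) -
               (unfiltered$ci_older - unfiltered$ci_younger),
             stringsAsFactors = FALSE)
}
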