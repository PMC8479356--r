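# Reading/writing datedist-style posterior tree samples and deriving node ages.

#' Derive validated node ages from a rooted tree with branch lengths
#'
#' Converts a rooted `phylo` tree whose branch lengths are in time units into
#' a [Chronogram-class]. The age of every node is the *maximum* path length to
#' a descendant leaf; leaf ages are forced to exactly 0. This convention
#' guarantees `age(parent) >= age(child)` on every edge even when branch
#' lengths were rounded in the text representation. Ultrametricity is checked
#' as the spread of root-to-leaf distances relative to the root age.
#'
#' @param phy rooted `phylo` object with non-negative branch lengths.
#' @param tolerance maximum allowed relative leaf-depth spread,
#'   `(max - min root-to-leaf distance) / root age`. Default `1e-6`: dating
#'   software output is numerically ultrametric but text-rounded.
#' @param scale global multiplier applied to branch lengths (e.g. 1000 to
#'   convert Ga input to Ma). Time units are otherwise opaque to the package.
#' @param sourceLine integer line of origin in an input file, for error
#'   messages and provenance.
#' @return a [Chronogram-class].
#' @examples
#' phy <- ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);")
#' chr <- computeNodeAges(phy)
#' rootAge(chr)  # 3
#' @export
computeNodeAges <- function(phy, tolerance = 1e-6, scale = 1,
                            sourceLine = NA_integer_) {
  if (!inherits(phy, "phylo"))
    stop("'phy' must be a 'phylo' object")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; node ages cannot be derived")
  if (any(phy$edge.length < 0))
    stop("negative branch length found; a chronogram requires non-negative ",
         "branch lengths")
  phy$edge.length <- phy$edge.length * scale
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ages <- numeric(ntip + nnode)
  if (ntip >= 2L || nnode >= 1L) {
    po <- ape::reorder.phylo(phy, "postorder")
    pe <- po$edge[, 1L]
    ce <- po$edge[, 2L]
    len <- po$edge.length
    for (i in seq_along(pe)) {
      cand <- ages[ce[i]] + len[i]
      if (cand > ages[pe[i]]) ages[pe[i]] <- cand
    }
    # ultrametricity: spread of root-to-leaf path lengths relative to root age
    if (ntip >= 2L) {
      depth <- ape::node.depth.edgelength(phy)[seq_len(ntip)]
      spread <- max(depth) - min(depth)
      root <- ages[ntip + 1L]
      if (root <= 0)
        stop("root age is not positive; not a usable chronogram")
      if (spread / root > tolerance)
        stop(sprintf(paste0("tree is not ultrametric within tolerance: ",
                            "leaf-depth spread %.6g relative to root age %.6g ",
                            "(relative spread %.3g > %.3g)"),
                     spread, root, spread / root, tolerance))
    }
  }
  ages[seq_len(ntip)] <- 0
  new("Chronogram", phy = phy, nodeAges = ages,
      sourceLine = as.integer(sourceLine))
}

# classify a datedist line; PhyloBayes emits one newick per line, sometimes
# preceded by a bare sample-count header; '#' lines tolerate user edits
.isSkippableLine <- function(x) {
  grepl("^\\s*$", x) | grepl("^\\s*[0-9]+\\s*$", x) | grepl("^\\s*#", x)
}

.parseDatedistLine <- function(line, lineno) {
  txt <- trimws(line)
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) && grepl("^[^(),:;[:space:]]+;?$", txt)) {
    # degenerate single-leaf tree such as "A;"
    phy <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          edge.length = 0,
                          tip.label = sub(";$", "", txt),
                          Nnode = 1L),
                     class = "phylo")
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop(sprintf("parse error at line %d: not a valid newick string", lineno))
  if (is.null(phy$edge.length) && length(phy$tip.label) == 1L)
    phy$edge.length <- numeric(nrow(phy$edge))
  phy
}

#' Read a datedist-style posterior sample of dated trees
#'
#' Reads a file of sampled dated trees, one newick string per line (the
#' "datedist" output dialect of Bayesian dating software). Blank lines, lines
#' of pure digits (sample-count headers), and lines starting with `#` are
#' skipped. The first `ceiling(burnInFraction * n)` parseable trees are
#' discarded as burn-in; the rest are validated as ultrametric chronograms
#' over a common leaf set, preserving order.
#'
#' @param path path to the tree file.
#' @param burnInFraction proportion in \[0, 1) of trees to discard from the
#'   start of the chain (default 0.2).
#' @param modelLabel,calibrationLabel free-text tags (e.g. `"CIR_nobd"`,
#'   `"BE"`) carried into downstream reports.
#' @param tolerance,scale passed to [computeNodeAges()].
#' @param outgroup optional character vector of taxa to root on when trees
#'   arrive unrooted (basal multifurcation). Without it, unrooted trees are
#'   rejected: donor/recipient ages are meaningless on unrooted trees.
#' @param chain chain identifier recorded in provenance.
#' @return a [PosteriorSample-class].
#' @seealso [mergeChains()], [computeNodeAges()]
#' @export
readDatedist <- function(path, burnInFraction = 0.2, modelLabel = "",
                         calibrationLabel = "", tolerance = 1e-6, scale = 1,
                         outgroup = NULL, chain = basename(path)) {
  stopifnot(is.numeric(burnInFraction), length(burnInFraction) == 1L,
            burnInFraction >= 0, burnInFraction < 1)
  lines <- readLines(path, warn = FALSE)
  keepLine <- which(!.isSkippableLine(lines))
  if (length(keepLine) == 0L)
    stop(sprintf("no parseable newick lines found in '%s'", path))
  phys <- vector("list", length(keepLine))
  for (i in seq_along(keepLine))
    phys[[i]] <- .parseDatedistLine(lines[keepLine[i]], keepLine[i])

  nAll <- length(phys)
  nDiscard <- as.integer(ceiling(burnInFraction * nAll))
  if (nDiscard >= nAll)
    stop(sprintf("burn-in of %d trees leaves no trees out of %d",
                 nDiscard, nAll))
  kept <- seq.int(nDiscard + 1L, nAll)

  trees <- vector("list", length(kept))
  for (j in seq_along(kept)) {
    i <- kept[j]
    phy <- phys[[i]]
    if (length(phy$tip.label) >= 2L && !ape::is.rooted(phy)) {
      if (is.null(outgroup))
        stop(sprintf(paste0("tree %d (line %d) is unrooted (basal ",
                            "multifurcation); supply 'outgroup' to root it"),
                     i, keepLine[i]))
      phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
    }
    trees[[j]] <- tryCatch(
      computeNodeAges(phy, tolerance = tolerance, scale = scale,
                      sourceLine = keepLine[i]),
      error = function(e)
        stop(sprintf("tree %d (line %d): %s", i, keepLine[i],
                     conditionMessage(e)), call. = FALSE))
  }

  leafSet <- sort(trees[[1L]]@phy$tip.label)
  for (j in seq_along(trees)) {
    tl <- sort(trees[[j]]@phy$tip.label)
    if (!identical(tl, leafSet))
      stop(sprintf(paste0("structural error: tree %d has a different leaf ",
                          "set from tree 1"), kept[j]))
  }

  new("PosteriorSample", trees = trees, leafSet = leafSet,
      modelLabel = modelLabel, calibrationLabel = calibrationLabel,
      provenance = data.frame(file = path, chain = chain,
                              kept = length(kept), discarded = nDiscard,
                              stringsAsFactors = FALSE))
}

#' Pool post-burn-in samples from several chains
#'
#' Concatenates the tree lists of independently run chains of the same
#' analysis. All samples must share leaf set, model label and calibration
#' label; burn-in must already have been removed per chain.
#'
#' @param samples list of [PosteriorSample-class] objects.
#' @return a single pooled [PosteriorSample-class]; provenance records each
#'   chain's contribution.
#' @export
mergeChains <- function(samples) {
  if (is(samples, "PosteriorSample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  if (length(samples) == 1L) return(samples[[1L]])
  ref <- samples[[1L]]
  for (s in samples[-1L]) {
    if (!identical(sort(s@leafSet), sort(ref@leafSet)))
      stop("structural error: chains have different leaf sets")
    if (!identical(s@modelLabel, ref@modelLabel) ||
        !identical(s@calibrationLabel, ref@calibrationLabel))
      stop("structural error: chains have different model/calibration labels")
  }
  new("PosteriorSample",
      trees = do.call(c, lapply(samples, function(s) s@trees)),
      leafSet = ref@leafSet, modelLabel = ref@modelLabel,
      calibrationLabel = ref@calibrationLabel,
      provenance = do.call(rbind, lapply(samples, function(s) s@provenance)))
}

#' Write per-tree clade ages to a tab-separated table
#'
#' One row per (tree index, clade) with the resolved age, written at full
#' precision so a read-back reproduces the ages losslessly.
#'
#' @param sample a [PosteriorSample-class].
#' @param clades list of [CladeDefinition-class] objects.
#' @param path output file path.
#' @return invisibly, the data.frame that was written.
#' @export
writeAgeTable <- function(sample, clades, path) {
  am <- cladeAgeMatrix(sample, clades)
  nT <- nTrees(sample)
  df <- data.frame(
    tree_index = rep(seq_len(nT), times = length(clades)),
    clade = rep(vapply(clades, function(x) x@name, character(1)), each = nT),
    group_kind = rep(vapply(clades, function(x) x@groupKind, character(1)),
                     each = nT),
    age = if (length(clades)) as.vector(am) else numeric(0),
    stringsAsFactors = FALSE)
  out <- df
  out$age <- sprintf("%.15g", out$age)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# ---- accessors ---------------------------------------------------------

#' @describeIn Chronogram-class number of leaves.
#' @param x,object a Chronogram.
#' @export
nTips <- function(x) length(x@phy$tip.label)

#' Node ages of a chronogram
#'
#' @param x a [Chronogram-class].
#' @return numeric vector indexed by ape node number; tips first (all 0),
#'   then internal nodes starting at the root.
#' @export
nodeAges <- function(x) x@nodeAges

#' Root age of a chronogram
#'
#' @param x a [Chronogram-class].
#' @return the age of the root node (time before present).
#' @export
rootAge <- function(x) x@nodeAges[length(x@phy$tip.label) + 1L]

#' Underlying phylo topology of a chronogram
#'
#' @param x a [Chronogram-class].
#' @return the `ape::phylo` object (branch lengths in time units).
#' @export
treeTopology <- function(x) x@phy

#' Number of trees in a posterior sample
#'
#' @param x a [PosteriorSample-class].
#' @export
nTrees <- function(x) length(x@trees)

#' Leaf set of a posterior sample
#' @param x a [PosteriorSample-class].
#' @export
leafSet <- function(x) x@leafSet

#' Model label of a sample or compatibility matrix
#' @param x a [PosteriorSample-class] or [CompatibilityMatrix-class].
#' @export
modelLabel <- function(x) x@modelLabel

#' Calibration label of a sample or compatibility matrix
#' @param x a [PosteriorSample-class] or [CompatibilityMatrix-class].
#' @export
calibrationLabel <- function(x) x@calibrationLabel

#' Provenance of a posterior sample
#' @param x a [PosteriorSample-class].
#' @return data.frame with one row per source chain.
#' @export
provenance <- function(x) x@provenance

#' @export
setMethod("length", "PosteriorSample", function(x) length(x@trees))

#' Extract one chronogram from a posterior sample
#' @param x a [PosteriorSample-class].
#' @param i tree index.
#' @export
setMethod("[[", "PosteriorSample", function(x, i) x@trees[[i]])

#' Subset a posterior sample by tree index
#' @param x a [PosteriorSample-class].
#' @param i integer or logical index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PosteriorSample", function(x, i, j, ..., drop = FALSE) {
  initialize(x, trees = x@trees[i])
})

setMethod("show", "Chronogram", function(object) {
  cat(sprintf("Chronogram: %d leaves, root age %.6g\n",
              nTips(object), rootAge(object)))
})

setMethod("show", "PosteriorSample", function(object) {
  cat(sprintf(
    "PosteriorSample: %d trees, %d leaves [model=%s, calibration=%s]\n",
    length(object@trees), length(object@leafSet),
    if (nzchar(object@modelLabel)) object@modelLabel else "-",
    if (nzchar(object@calibrationLabel)) object@calibrationLabel else "-"))
})

# ---- annotated newick output ------------------------------------------

# turn one nodeData row into a "[&k=v,...]" comment; paired columns
# <stem>_older / <stem>_younger collapse to <stem>={older,younger}
.nodeComment <- function(row) {
  cols <- names(row)
  done <- logical(length(cols))
  parts <- character(0)
  for (k in seq_along(cols)) {
    if (done[k]) next
    nm <- cols[k]
    if (grepl("_older$", nm)) {
      stem <- sub("_older$", "", nm)
      j <- match(paste0(stem, "_younger"), cols)
      if (!is.na(j)) {
        parts <- c(parts, sprintf("%s={%.6g,%.6g}", stem,
                                  as.numeric(row[[k]]), as.numeric(row[[j]])))
        done[c(k, j)] <- TRUE
        next
      }
    }
    parts <- c(parts, sprintf("%s=%.6g", nm, as.numeric(row[[k]])))
    done[k] <- TRUE
  }
  paste0("[&", paste(parts, collapse = ","), "]")
}

#' Write a chronogram as newick with per-node annotation comments
#'
#' Writes the tree in newick format with optional square-bracket comment
#' blocks after internal node labels, e.g.
#' `[&age_mean=2977,age_ci={3219,2789}]`, the conventional way to carry
#' posterior summaries (means, credible intervals, filtered re-estimates) on
#' a consensus chronogram.
#'
#' @param x a [Chronogram-class].
#' @param path output file path, or `NULL` to return the string.
#' @param nodeData optional data.frame with a `node` column (ape node
#'   numbers) plus numeric columns; each extra column becomes a `key=value`
#'   entry, and column pairs `<stem>_older`/`<stem>_younger` are written as
#'   `<stem>={older,younger}` following the convention of reporting credible
#'   bounds older first.
#' @return invisibly, the newick string.
#' @export
writeAnnotatedChronogram <- function(x, path = NULL, nodeData = NULL) {
  phy <- x@phy
  ntip <- length(phy$tip.label)
  comments <- character(ntip + phy$Nnode)
  if (!is.null(nodeData)) {
    stopifnot("node" %in% names(nodeData))
    vals <- nodeData[setdiff(names(nodeData), "node")]
    for (r in seq_len(nrow(nodeData)))
      comments[nodeData$node[r]] <- .nodeComment(vals[r, , drop = FALSE])
  }
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  lens <- phy$edge.length
  build <- function(node) {
    if (node <= ntip) {
      lab <- phy$tip.label[node]
    } else {
      es <- kids[[as.character(node)]]
      sub <- vapply(es, function(e)
        paste0(build(phy$edge[e, 2L]), ":",
               sprintf("%.15g", lens[e])), character(1))
      lab <- paste0("(", paste(sub, collapse = ","), ")")
    }
    paste0(lab, comments[node])
  }
  nwk <- paste0(build(ntip + 1L), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}
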