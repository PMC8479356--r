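# Resolving named crown/total-group clades to node ages in each chronogram.

#' Construct a clade definition
#'
#' @param name clade name.
#' @param taxa character vector of leaf labels (must match newick leaf names
#'   exactly; no pattern matching, so resolution is bit-exact reproducible).
#' @param groupKind `"crown"` (age of the taxa's MRCA) or `"total"` (age of
#'   the parent of the MRCA, i.e. including the stem lineage).
#' @return a [CladeDefinition-class].
#' @export
cladeDefinition <- function(name, taxa, groupKind = c("crown", "total")) {
  groupKind <- match.arg(groupKind)
  new("CladeDefinition", name = name, taxa = as.character(taxa),
      groupKind = groupKind)
}

setMethod("show", "CladeDefinition", function(object) {
  cat(sprintf("CladeDefinition '%s' (%s): %d taxa\n", object@name,
              object@groupKind, length(object@taxa)))
})

# descendant tip numbers of 'node', by stack-based descent of the edge matrix
.tipsUnder <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    ch <- kids[[as.character(v)]]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

.parentOf <- function(phy, node) {
  p <- phy$edge[phy$edge[, 2L] == node, 1L]
  if (length(p) != 1L) NA_integer_ else p
}

# locate the node whose age represents the clade in this topology
.cladeNode <- function(phy, clade) {
  idx <- match(clade@taxa, phy$tip.label)
  if (anyNA(idx))
    stop(sprintf("resolution error: taxon '%s' of clade '%s' not in tree",
                 clade@taxa[which(is.na(idx))[1L]], clade@name))
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  if (length(idx) == 1L) {
    if (clade@groupKind == "crown")
      stop(sprintf("undefined-crown error: clade '%s' has a single taxon",
                   clade@name))
    node <- .parentOf(phy, idx)  # total group of one taxon: its stem base
    return(list(node = node, mrca = idx, monophyletic = TRUE))
  }
  mrca <- ape::getMRCA(phy, idx)
  mono <- setequal(.tipsUnder(phy, mrca), idx)
  node <- mrca
  if (clade@groupKind == "total") {
    if (mrca == root)
      stop(sprintf(paste0("undefined-stem error: MRCA of clade '%s' is the ",
                          "root; its stem lineage is unobserved"), clade@name))
    node <- .parentOf(phy, mrca)
  }
  list(node = node, mrca = mrca, monophyletic = mono)
}

#' Resolve a clade to a node age in one chronogram
#'
#' Locates the MRCA of the clade's taxa and reports its age (crown) or the
#' age of its parent node (total group, i.e. base of the stem lineage). If
#' the taxa are not monophyletic in this tree, the MRCA is used anyway and
#' the result is flagged `monophyletic = FALSE` with a warning, rather than
#' erroring -- the age is still well-defined, only its interpretation changes.
#'
#' @param tree a [Chronogram-class].
#' @param clade a [CladeDefinition-class] whose taxa are all present in the
#'   tree.
#' @param treeIndex optional index recorded in the result.
#' @param warn emit a warning on non-monophyly (default `TRUE`).
#' @return a [ResolvedClade-class].
#' @examples
#' chr <- computeNodeAges(ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);"))
#' cladeAge(resolveCladeAge(chr, cladeDefinition("AB", c("A", "B"))))  # 1
#' @export
resolveCladeAge <- function(tree, clade, treeIndex = NA_integer_,
                            warn = TRUE) {
  loc <- .cladeNode(tree@phy, clade)
  if (warn && !loc$monophyletic)
    warning(sprintf("clade '%s' is not monophyletic in this tree; using MRCA",
                    clade@name))
  new("ResolvedClade", clade = clade, treeIndex = as.integer(treeIndex),
      node = as.integer(loc$node), age = tree@nodeAges[loc$node],
      monophyletic = loc$monophyletic)
}

#' @describeIn resolveCladeAge age of a resolved clade.
#' @param x a [ResolvedClade-class].
#' @export
cladeAge <- function(x) x@age

#' @describeIn resolveCladeAge monophyly flag of a resolved clade.
#' @export
isMonophyletic <- function(x) x@monophyletic

setMethod("show", "ResolvedClade", function(object) {
  cat(sprintf("ResolvedClade '%s' (%s): node %d, age %.6g%s\n",
              object@clade@name, object@clade@groupKind, object@node,
              object@age,
              if (object@monophyletic) "" else " [non-monophyletic]"))
})

# TRUE when every tree in the sample shares the first tree's topology; the
# common case for dating output, and the key to resolving each clade once
.sharedTopology <- function(sample) {
  trees <- sample@trees
  e1 <- trees[[1L]]@phy$edge
  t1 <- trees[[1L]]@phy$tip.label
  for (t in trees) {
    if (!identical(t@phy$edge, e1) || !identical(t@phy$tip.label, t1))
      return(FALSE)
  }
  TRUE
}

# trees x (Ntip + Nnode) matrix of node ages; only valid on shared topology
.ageMatrix <- function(sample) {
  len <- length(sample@trees[[1L]]@nodeAges)
  t(vapply(sample@trees, function(t) t@nodeAges, numeric(len)))
}

#' Ages of several clades across every tree of a posterior sample
#'
#' Resolves each clade in each tree and returns the ages as a matrix. When
#' all trees share one topology (the usual case for dating output over a
#' fixed species tree), each clade is located once and its age read off per
#' tree, which makes scoring thousands of trees cheap.
#'
#' @param sample a [PosteriorSample-class].
#' @param clades list of [CladeDefinition-class] objects.
#' @param warn warn once per clade that is non-monophyletic in any tree.
#' @return numeric matrix, trees by clades, with a logical attribute
#'   `"monophyletic"` of the same shape.
#' @export
cladeAgeMatrix <- function(sample, clades, warn = TRUE) {
  nT <- length(sample@trees)
  nC <- length(clades)
  nm <- vapply(clades, function(x) x@name, character(1))
  am <- matrix(NA_real_, nT, nC, dimnames = list(NULL, nm))
  mono <- matrix(TRUE, nT, nC, dimnames = list(NULL, nm))
  if (nC == 0L) {
    attr(am, "monophyletic") <- mono
    return(am)
  }
  if (.sharedTopology(sample)) {
    phy <- sample@trees[[1L]]@phy
    ageMat <- .ageMatrix(sample)
    for (k in seq_len(nC)) {
      loc <- .cladeNode(phy, clades[[k]])
      am[, k] <- ageMat[, loc$node]
      mono[, k] <- loc$monophyletic
    }
  } else {
    for (t in seq_len(nT)) {
      phy <- sample@trees[[t]]@phy
      ages <- sample@trees[[t]]@nodeAges
      for (k in seq_len(nC)) {
        loc <- .cladeNode(phy, clades[[k]])
        am[t, k] <- ages[loc$node]
        mono[t, k] <- loc$monophyletic
      }
    }
  }
  if (warn) {
    bad <- nm[colSums(!mono) > 0L]
    if (length(bad))
      warning("non-monophyletic in at least one tree: ",
              paste(bad, collapse = ", "))
  }
  attr(am, "monophyletic") <- mono
  am
}

#' Fraction of trees in which each clade is monophyletic
#'
#' A guard for samples that are supposed to share one fixed topology: a
#' fraction below 1 means the posterior contains trees in which the named
#' taxa do not form a clade, so their "age" is an MRCA age of a larger group.
#'
#' @param sample a [PosteriorSample-class].
#' @param clades list of [CladeDefinition-class] objects.
#' @return named numeric vector of fractions in \[0, 1\]; a warning names
#'   every clade with a fraction below 1.
#' @export
monophylyReport <- function(sample, clades) {
  if (length(sample@trees) == 0L) stop("sample contains no trees")
  am <- cladeAgeMatrix(sample, clades, warn = FALSE)
  mono <- attr(am, "monophyletic")
  frac <- colMeans(mono)
  low <- names(frac)[frac < 1]
  if (length(low))
    warning("clades not monophyletic in every tree: ",
            paste(sprintf("%s (%.3f)", low, frac[low]), collapse = ", "))
  frac
}

#' Read a clade-definition table
#'
#' Accepts a tab-separated file with columns `name`, `group_kind`
#' (`crown`/`total`) and `taxa` (semicolon-separated leaf labels), or a YAML
#' file holding a list of records with the same fields (`taxa` as a list).
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` vs TSV).
#' @return list of [CladeDefinition-class] objects.
#' @export
readCladeTable <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    return(lapply(recs, function(r)
      cladeDefinition(r$name, unlist(r$taxa),
                      if (is.null(r$group_kind)) "crown" else r$group_kind)))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "group_kind", "taxa")
  if (!all(need %in% names(df)))
    stop("clade table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    cladeDefinition(df$name[i], strsplit(df$taxa[i], ";", fixed = TRUE)[[1L]],
                    df$group_kind[i]))
}
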