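# Scoring chronograms against HGT donor/recipient relative-age constraints.

#' Construct an HGT relative-age constraint
#'
#' @param id constraint identifier.
#' @param donor,recipient [CladeDefinition-class] objects (or the result of
#'   [cladeDefinition()]). The clades' `groupKind` settings decide which node
#'   age is compared on each side; crown/crown is the default and
#'   conservative convention, with total/stem selectable per side for
#'   sensitivity analysis.
#' @param note free text (e.g. the gene families supporting the transfer).
#' @return an [HGTConstraint-class].
#' @export
hgtConstraint <- function(id, donor, recipient, note = "") {
  new("HGTConstraint", id = id, donor = donor, recipient = recipient,
      note = note)
}

setMethod("show", "HGTConstraint", function(object) {
  cat(sprintf("HGTConstraint '%s': %s (%s) -> %s (%s)\n", object@id,
              object@donor@name, object@donor@groupKind,
              object@recipient@name, object@recipient@groupKind))
})

#' Is one chronogram compatible with one HGT constraint?
#'
#' A chronogram is compatible when the donor clade's node age is strictly
#' greater than the recipient clade's node age ("older than" is strict;
#' exact ties -- measure zero in a continuous posterior -- count as
#' incompatible).
#'
#' @param tree a [Chronogram-class].
#' @param constraint an [HGTConstraint-class].
#' @return logical scalar.
#' @examples
#' chr <- computeNodeAges(ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);"))
#' con <- hgtConstraint("h1", cladeDefinition("CD", c("C", "D")),
#'                      cladeDefinition("AB", c("A", "B")))
#' isCompatible(chr, con)  # TRUE: donor age 2 > recipient age 1
#' @export
isCompatible <- function(tree, constraint) {
  d <- resolveCladeAge(tree, constraint@donor, warn = FALSE)
  r <- resolveCladeAge(tree, constraint@recipient, warn = FALSE)
  d@age > r@age
}

#' Score every tree of a posterior sample against every HGT constraint
#'
#' @param sample a [PosteriorSample-class].
#' @param constraints list of [HGTConstraint-class] objects, all resolvable
#'   in every tree.
#' @return a [CompatibilityMatrix-class] with one row per post-burn-in tree
#'   and one column per constraint id; deterministic given the inputs.
#' @seealso [constraintProfile()], [modelScore()], [sweepFilter()]
#' @export
compatibilityMatrix <- function(sample, constraints) {
  ids <- vapply(constraints, function(x) x@id, character(1))
  if (anyDuplicated(ids))
    stop("constraint ids must be unique (see dedupConstraints)")
  donors <- lapply(constraints, function(x) x@donor)
  recips <- lapply(constraints, function(x) x@recipient)
  dAges <- tryCatch(cladeAgeMatrix(sample, donors, warn = FALSE),
                    error = function(e)
                      stop("constraint resolution failed: ",
                           conditionMessage(e), call. = FALSE))
  rAges <- cladeAgeMatrix(sample, recips, warn = FALSE)
  vals <- dAges > rAges
  attr(vals, "monophyletic") <- NULL
  dimnames(vals) <- list(NULL, ids)
  new("CompatibilityMatrix", values = matrix(as.logical(vals), nrow(vals),
                                             ncol(vals),
                                             dimnames = list(NULL, ids)),
      modelLabel = sample@modelLabel,
      calibrationLabel = sample@calibrationLabel)
}

#' @describeIn compatibilityMatrix the underlying logical matrix.
#' @param x a [CompatibilityMatrix-class].
#' @export
compatValues <- function(x) x@values

setMethod("show", "CompatibilityMatrix", function(object) {
  v <- object@values
  cat(sprintf(
    "CompatibilityMatrix: %d trees x %d constraints (%.2f%% compatible)\n",
    nrow(v), ncol(v), if (length(v)) 100 * mean(v) else NA_real_))
})

setMethod("dim", "CompatibilityMatrix", function(x) dim(x@values))

#' Per-constraint compatibility percentages
#'
#' The percentage of sampled chronograms compatible with each constraint:
#' `100 * compatible trees / total trees`.
#'
#' @param matrix a [CompatibilityMatrix-class] with at least one tree.
#' @return named numeric vector of percentages in \[0, 100\].
#' @export
constraintProfile <- function(matrix) {
  v <- matrix@values
  if (nrow(v) == 0L) stop("compatibility matrix has zero trees")
  100 * colMeans(v)
}

#' Overall model compatibility score
#'
#' The mean over constraints of the per-constraint compatibility
#' percentages; for a complete matrix this equals the percentage of
#' compatible (tree, constraint) cells. Used as an empirical criterion for
#' ranking relaxed-clock models: posteriors sampled under a better-fitting
#' rate model satisfy more of the HGT-implied age orderings.
#'
#' @param matrix a [CompatibilityMatrix-class] with at least one tree and
#'   one constraint.
#' @return a percentage in \[0, 100\].
#' @export
modelScore <- function(matrix) {
  v <- matrix@values
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("model score requires at least one tree and one constraint")
  mean(constraintProfile(matrix))
}

#' Count constraints supported by at least a threshold of the posterior
#'
#' @param profile named percentages from [constraintProfile()].
#' @param supportThreshold inclusive percentage threshold (default 20: a
#'   constraint "supported" when compatible with at least 20% of the
#'   posterior space sampled).
#' @return integer count.
#' @export
supportedConstraintCount <- function(profile, supportThreshold = 20) {
  if (length(profile) == 0L) stop("profile must be non-empty")
  sum(profile >= supportThreshold)
}

#' Build a per-model compatibility report
#'
#' @param matrix a [CompatibilityMatrix-class].
#' @param supportThreshold see [supportedConstraintCount()].
#' @param flagThreshold exclusive percentage below which a constraint is
#'   flagged in this report (default 1.2).
#' @return a [ModelReport-class].
#' @export
modelReport <- function(matrix, supportThreshold = 20, flagThreshold = 1.2) {
  p <- constraintProfile(matrix)
  new("ModelReport", modelLabel = matrix@modelLabel, perConstraintPct = p,
      overallPct = mean(p),
      supportedCount = as.integer(sum(p >= supportThreshold)),
      flagged = names(p)[p < flagThreshold])
}

setMethod("show", "ModelReport", function(object) {
  cat(sprintf(
    "ModelReport '%s': overall %.2f%%, %d/%d constraints supported%s\n",
    object@modelLabel, object@overallPct, object@supportedCount,
    length(object@perConstraintPct),
    if (length(object@flagged))
      paste0(", flagged: ", paste(object@flagged, collapse = ", "))
    else ""))
})

#' Flag constraints incompatible under every evolutionary model
#'
#' A constraint with zero or near-zero compatibility across *all* models is
#' unlikely to reflect model misfit; it points instead at a misplaced node
#' calibration pinning the recipient (or donor) to an implausible age. The
#' intended workflow is to re-run the dating without the suspect calibration
#' and compare profiles.
#'
#' @param reports list of [ModelReport-class] objects over identical
#'   constraint sets.
#' @param flagThreshold exclusive percentage threshold (default 1.2).
#' @return character vector of constraint ids whose compatibility is below
#'   `flagThreshold` in every report.
#' @export
flagMiscalibration <- function(reports, flagThreshold = 1.2) {
  if (length(reports) == 0L) stop("at least one model report is required")
  ids <- sort(names(reports[[1L]]@perConstraintPct))
  for (r in reports) {
    if (!identical(sort(names(r@perConstraintPct)), ids))
      stop("model reports cover different constraint sets")
  }
  below <- lapply(reports, function(r)
    names(r@perConstraintPct)[r@perConstraintPct < flagThreshold])
  Reduce(intersect, below)
}

#' Deduplicate HGT constraints to unique donor/recipient clade pairs
#'
#' Several independently detected transfers often imply the same
#' donor-clade/recipient-clade relative-age constraint; duplicated pairs
#' (same clade names and group kinds on both sides) are collapsed to one
#' constraint, with the merged ids recorded in its `note`.
#'
#' @param constraints list of [HGTConstraint-class] objects.
#' @return list of unique [HGTConstraint-class] objects, order of first
#'   appearance.
#' @export
dedupConstraints <- function(constraints) {
  key <- vapply(constraints, function(x)
    paste(x@donor@name, x@donor@groupKind,
          x@recipient@name, x@recipient@groupKind, sep = "\r"), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- constraints[key == k]
    con <- grp[[1L]]
    if (length(grp) > 1L) {
      merged <- paste(vapply(grp, function(x) x@id, character(1)),
                      collapse = ",")
      con@note <- trimws(paste(con@note,
                               sprintf("[merged ids: %s]", merged)))
    }
    out[[length(out) + 1L]] <- con
  }
  out
}

#' Read an HGT-constraint table
#'
#' Tab-separated with columns `id`, `donor_clade`, `recipient_clade`
#' referencing names in a clade table, optional `donor_kind` /
#' `recipient_kind` (`crown`/`total`, defaulting to each clade's own kind)
#' and optional `note`. Duplicate donor/recipient pairs are collapsed via
#' [dedupConstraints()].
#'
#' @param path TSV file path.
#' @param clades list of [CladeDefinition-class] objects the table refers to.
#' @param dedup collapse duplicate clade pairs (default `TRUE`).
#' @return list of [HGTConstraint-class] objects.
#' @export
readConstraintTable <- function(path, clades, dedup = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "donor_clade", "recipient_clade")
  if (!all(need %in% names(df)))
    stop("constraint table must have columns: ", paste(need, collapse = ", "))
  byName <- setNames(clades, vapply(clades, function(x) x@name, character(1)))
  pick <- function(nm, kind) {
    cl <- byName[[nm]]
    if (is.null(cl)) stop(sprintf("unknown clade '%s' in constraint table", nm))
    if (!is.na(kind) && nzchar(kind)) cl@groupKind <- kind
    cl
  }
  cons <- lapply(seq_len(nrow(df)), function(i) {
    dk <- if ("donor_kind" %in% names(df)) df$donor_kind[i] else NA
    rk <- if ("recipient_kind" %in% names(df)) df$recipient_kind[i] else NA
    nt <- if ("note" %in% names(df)) df$note[i] else ""
    hgtConstraint(df$id[i], pick(df$donor_clade[i], dk),
                  pick(df$recipient_clade[i], rk),
                  note = if (is.na(nt)) "" else nt)
  })
  if (dedup) dedupConstraints(cons) else cons
}
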