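# Fixed-topology synthetic chronogram posteriors with planted HGT constraints.

#' Configuration for the synthetic chronogram generator
#'
#' Bundles the parameters of the synthetic study: a pure-birth (Yule) species
#' tree of `nTaxa` leaves conditioned on `rootAge`, a pseudo-posterior of
#' `nTrees` chronograms with multiplicative lognormal node-age jitter of
#' coefficient of variation `ageNoiseCV`, and `nConstraints` planted
#' donor/recipient constraints of which a fraction `trueFraction` hold in
#' the generating chronogram. All randomness flows from `seed` through a
#' per-stage splitting scheme, so each stage is independently reproducible.
#'
#' @param nTaxa number of leaves (>= 3).
#' @param birthRate Yule speciation rate per unit time (default 0.001 per
#'   Ma, a realistic order of magnitude for deep bacterial divergences).
#' @param rootAge age of the root in time units (default 3900, matching a
#'   plausible age for the bacterial root in Ma).
#' @param nTrees posterior sample size.
#' @param ageNoiseCV coefficient of variation of the multiplicative
#'   lognormal age jitter (0 = no noise).
#' @param nConstraints number of planted HGT constraints.
#' @param trueFraction proportion of planted constraints that are true
#'   (donor older) in the generating chronogram; the rest are deliberately
#'   inverted.
#' @param seed integer master seed.
#' @return a `SimulationConfig` list (class `"SimulationConfig"`).
#' @export
simulationConfig <- function(nTaxa = 30, birthRate = 0.001, rootAge = 3900,
                             nTrees = 2000, ageNoiseCV = 0.15,
                             nConstraints = 24, trueFraction = 1,
                             seed = 1L) {
  stopifnot(nTaxa >= 3, birthRate > 0, rootAge > 0, nTrees >= 1,
            ageNoiseCV >= 0, nConstraints >= 0,
            trueFraction >= 0, trueFraction <= 1)
  structure(list(nTaxa = as.integer(nTaxa), birthRate = birthRate,
                 rootAge = rootAge, nTrees = as.integer(nTrees),
                 ageNoiseCV = ageNoiseCV,
                 nConstraints = as.integer(nConstraints),
                 trueFraction = trueFraction, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# per-stage seed derived from the master seed; keeps all seeds < 2^31
.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483647)
}

#' Simulate the true (generating) chronogram
#'
#' Draws a pure-birth topology on `nTaxa` leaves with internal node ages
#' from the Yule construction conditioned on the root age: the non-root
#' divergence ages are i.i.d. truncated-exponential with rate `birthRate`
#' on (0, rootAge) (speciations crowd toward the present), assigned in
#' decreasing order while each new divergence splits a uniformly chosen
#' extant lineage. Deterministic under `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return a [Chronogram-class] with `nTaxa - 1` internal nodes and root age
#'   exactly `config$rootAge`.
#' @export
simulateTrueChronogram <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.stageSeed(config$seed, 1L))
  n <- config$nTaxa
  lam <- config$birthRate
  T0 <- config$rootAge
  # inverse-CDF draws from f(a) proportional to exp(-lambda a) on (0, T0)
  u <- runif(n - 2L)
  agesNR <- -log(1 - u * (1 - exp(-lam * T0))) / lam
  intAges <- c(T0, sort(agesNR, decreasing = TRUE))  # root first

  root <- n + 1L
  nInt <- n - 1L
  parent <- integer(0)
  child <- integer(0)
  active <- c(root, root)  # parents of the two lineages leaving the root
  if (nInt >= 2L) {
    for (k in 2L:nInt) {
      u2 <- n + k
      i <- sample.int(length(active), 1L)
      parent <- c(parent, active[i])
      child <- c(child, u2)
      active[i] <- u2
      active <- c(active, u2)
    }
  }
  # remaining active lineages become the tips
  tips <- seq_len(n)
  parent <- c(parent, active)
  child <- c(child, tips)

  ages <- c(numeric(n), intAges)
  phy <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                        edge.length = ages[parent] - ages[child],
                        tip.label = sprintf("t%02d", tips),
                        Nnode = nInt),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  computeNodeAges(phy)
}

#' Simulate an MCMC-like posterior sample around a true chronogram
#'
#' Produces `nTrees` chronograms sharing the true topology. Each internal
#' node age is multiplied by independent lognormal noise with mean 1 and
#' coefficient of variation `ageNoiseCV`; parent/child monotonicity is then
#' repaired by propagating the maximum of child ages upward, which
#' guarantees valid chronograms while mimicking posterior spread. Leaf ages
#' stay 0. With `ageNoiseCV = 0` every sampled tree equals the truth.
#'
#' @param trueTree a [Chronogram-class] (e.g. from
#'   [simulateTrueChronogram()]).
#' @param config a [simulationConfig()].
#' @param modelLabel,calibrationLabel tags for the returned sample.
#' @return a [PosteriorSample-class] of `config$nTrees` chronograms.
#' @export
simulatePosterior <- function(trueTree, config, modelLabel = "sim",
                              calibrationLabel = "synthetic") {
  stopifnot(is(trueTree, "Chronogram"), inherits(config, "SimulationConfig"))
  set.seed(.stageSeed(config$seed, 2L))
  phy <- trueTree@phy
  n <- length(phy$tip.label)
  nInt <- phy$Nnode
  nT <- config$nTrees
  cv <- config$ageNoiseCV

  intIdx <- n + seq_len(nInt)
  trueInt <- trueTree@nodeAges[intIdx]
  M <- matrix(0, nT, n + nInt)
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    noise <- matrix(rlnorm(nT * nInt, meanlog = -sdl^2 / 2, sdlog = sdl),
                    nT, nInt)
    M[, intIdx] <- noise * rep(trueInt, each = nT)
    # monotonicity repair: postorder max-propagation, vectorized over trees
    po <- ape::reorder.phylo(phy, "postorder")$edge
    for (i in seq_len(nrow(po)))
      M[, po[i, 1L]] <- pmax(M[, po[i, 1L]], M[, po[i, 2L]])
  } else {
    M[, intIdx] <- rep(trueInt, each = nT)
  }

  e1 <- phy$edge[, 1L]
  e2 <- phy$edge[, 2L]
  trees <- vector("list", nT)
  for (t in seq_len(nT)) {
    phyT <- phy
    phyT$edge.length <- M[t, e1] - M[t, e2]
    trees[[t]] <- new("Chronogram", phy = phyT, nodeAges = M[t, ],
                      sourceLine = NA_integer_)
  }
  new("PosteriorSample", trees = trees, leafSet = sort(phy$tip.label),
      modelLabel = modelLabel, calibrationLabel = calibrationLabel,
      provenance = data.frame(file = "<simulated>", chain = "sim",
                              kept = nT, discarded = 0L,
                              stringsAsFactors = FALSE))
}

#' Plant HGT constraints with known ground truth
#'
#' Samples `nConstraints` distinct donor/recipient pairs of disjoint
#' (crown) clades from the internal nodes of the true chronogram. A
#' fraction `trueFraction` are oriented older-to-younger (true in the
#' generating tree); the rest are deliberately inverted. The recorded truth
#' of each constraint is attached as the `"groundTruth"` attribute.
#'
#' @param trueTree a [Chronogram-class].
#' @param config a [simulationConfig()].
#' @return list of [HGTConstraint-class] objects with a named logical
#'   attribute `"groundTruth"` (`TRUE` = donor older in the true tree).
#' @export
plantConstraints <- function(trueTree, config) {
  stopifnot(is(trueTree, "Chronogram"), inherits(config, "SimulationConfig"))
  set.seed(.stageSeed(config$seed, 3L))
  phy <- trueTree@phy
  n <- length(phy$tip.label)
  ages <- trueTree@nodeAges
  internal <- setdiff(n + seq_len(phy$Nnode), n + 1L)  # exclude root
  tipSets <- lapply(internal, function(v) .tipsUnder(phy, v))

  pairs <- list()
  for (i in seq_along(internal)) {
    for (j in seq_along(internal)) {
      if (j <= i) next
      if (length(intersect(tipSets[[i]], tipSets[[j]])) == 0L &&
          ages[internal[i]] != ages[internal[j]])
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) < config$nConstraints)
    stop(sprintf(paste0("insufficient distinct disjoint clade pairs: %d ",
                        "available, %d requested"),
                 length(pairs), config$nConstraints))
  pick <- sample.int(length(pairs), config$nConstraints)
  nTrue <- round(config$trueFraction * config$nConstraints)
  isTrue <- rep(c(TRUE, FALSE), c(nTrue, config$nConstraints - nTrue))

  mkClade <- function(k)
    cladeDefinition(sprintf("clade_n%d", internal[k]),
                    phy$tip.label[tipSets[[k]]], "crown")
  cons <- vector("list", config$nConstraints)
  truth <- logical(config$nConstraints)
  for (q in seq_len(config$nConstraints)) {
    ij <- pairs[[pick[q]]]
    older <- if (ages[internal[ij[1L]]] > ages[internal[ij[2L]]])
      ij[1L] else ij[2L]
    younger <- setdiff(ij, older)
    if (isTrue[q]) {
      donor <- older; recip <- younger
    } else {
      donor <- younger; recip <- older
    }
    cons[[q]] <- hgtConstraint(sprintf("HGT_%02d", q),
                               mkClade(donor), mkClade(recip),
                               note = if (isTrue[q]) "planted true"
                                      else "planted inverted")
    truth[q] <- isTrue[q]
  }
  names(truth) <- vapply(cons, function(x) x@id, character(1))
  attr(cons, "groundTruth") <- truth
  cons
}

#' Write a posterior sample as a datedist-style tree file
#'
#' One newick string per line, preceded by a bare integer header line with
#' the number of trees (tolerated and skipped by [readDatedist()]).
#'
#' @param sample a [PosteriorSample-class].
#' @param path output file path.
#' @param header write the tree-count header line (default `TRUE`).
#' @return invisibly, `path`.
#' @export
writeDatedist <- function(sample, path, header = TRUE) {
  lines <- vapply(sample@trees, function(t)
    ape::write.tree(t@phy, digits = 12), character(1))
  if (header) lines <- c(as.character(length(lines)), lines)
  writeLines(lines, path)
  invisible(path)
}
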