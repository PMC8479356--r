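# Shared fixtures and independent brute-force oracles.

TOY_NWK <- "((A:1,B:1):2,(C:2,D:2):1);"

toyChronogram <- function(nwk = TOY_NWK)
  computeNodeAges(ape::read.tree(text = nwk))

writeTreeFile <- function(lines, path = tempfile(fileext = ".datedist")) {
  writeLines(lines, path)
  path
}

# a 4-leaf ultrametric tree whose AB crown age is 'a' and root age 5
toyTreeWithABAge <- function(a)
  sprintf("((A:%g,B:%g):%g,(C:2,D:2):3);", a, a, 5 - a)

# ---- brute-force oracles, independent of the package internals ---------
# These work directly on the phylo edge matrix with plain loops: root-to-node
# paths by parent lookup, MRCA as the deepest shared path element, node age
# as the maximum branch-length sum down to any descendant leaf.

oracleParent <- function(phy) {
  par <- rep(NA_integer_, length(phy$tip.label) + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))
    par[phy$edge[i, 2L]] <- phy$edge[i, 1L]
  par
}

oraclePathToRoot <- function(par, node) {
  path <- node
  while (!is.na(par[node])) {
    node <- par[node]
    path <- c(path, node)
  }
  path
}

oracleMRCA <- function(phy, tips) {
  par <- oracleParent(phy)
  paths <- lapply(tips, function(t) rev(oraclePathToRoot(par, t)))
  common <- Reduce(intersect, paths)
  common[length(common)]  # deepest shared ancestor
}

# age of 'node' as max path length to a descendant leaf
oracleNodeAge <- function(phy, node) {
  par <- oracleParent(phy)
  # branch length of the edge above each node
  blen <- numeric(length(par))
  for (i in seq_len(nrow(phy$edge)))
    blen[phy$edge[i, 2L]] <- phy$edge.length[i]
  ntip <- length(phy$tip.label)
  best <- 0
  for (tip in seq_len(ntip)) {
    path <- oraclePathToRoot(par, tip)
    if (node %in% path) {
      d <- 0
      v <- tip
      while (v != node) {
        d <- d + blen[v]
        v <- par[v]
      }
      best <- max(best, d)
    }
  }
  best
}

oracleCrownAge <- function(phy, taxa) {
  tips <- match(taxa, phy$tip.label)
  oracleNodeAge(phy, oracleMRCA(phy, tips))
}

oracleStemAge <- function(phy, taxa) {
  tips <- match(taxa, phy$tip.label)
  par <- oracleParent(phy)
  oracleNodeAge(phy, par[oracleMRCA(phy, tips)])
}

# descendant tip labels of every internal node, one clade per bipartition
oracleBipartitionClades <- function(phy) {
  ntip <- length(phy$tip.label)
  par <- oracleParent(phy)
  lapply(ntip + seq_len(phy$Nnode), function(v) {
    tips <- which(vapply(seq_len(ntip), function(t)
      v %in% oraclePathToRoot(par, t), logical(1)))
    phy$tip.label[tips]
  })
}

randomChronogram <- function(nTips, seed) {
  set.seed(seed)
  computeNodeAges(ape::rcoal(nTips))
}

# small synthetic study shared by several test files
smallStudy <- function(seed = 42, nTrees = 200, cv = 0.15, nTaxa = 20,
                       nConstraints = 12, trueFraction = 1) {
  cfg <- simulationConfig(nTaxa = nTaxa, nTrees = nTrees, ageNoiseCV = cv,
                          nConstraints = nConstraints,
                          trueFraction = trueFraction, seed = seed)
  truth <- simulateTrueChronogram(cfg)
  list(config = cfg, truth = truth,
       sample = simulatePosterior(truth, cfg),
       constraints = plantConstraints(truth, cfg))
}
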