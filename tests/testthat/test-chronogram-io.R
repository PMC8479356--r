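test_that("node ages follow the max-depth-to-leaf convention", {
  chr <- toyChronogram()
  phy <- treeTopology(chr)
  ages <- nodeAges(chr)
  expect_equal(rootAge(chr), 3)
  ab <- ape::getMRCA(phy, match(c("A", "B"), phy$tip.label))
  cd <- ape::getMRCA(phy, match(c("C", "D"), phy$tip.label))
  expect_equal(ages[ab], 1)
  expect_equal(ages[cd], 2)
  expect_equal(ages[seq_len(4)], rep(0, 4))
  # age(parent) - age(child) equals the connecting branch length
  expect_equal(ages[phy$edge[, 1]] - ages[phy$edge[, 2]], phy$edge.length)
})

test_that("validation rejects bad branch lengths and non-ultrametric trees", {
  expect_error(computeNodeAges(ape::read.tree(text = "((A:1,B:-1):2,C:3);")),
               "negative branch length")
  expect_error(computeNodeAges(ape::read.tree(text = "((A:1,B:1):2,C:9);")),
               "not ultrametric")
  # sub-tolerance rounding noise is accepted and leaf ages forced to 0
  chr <- computeNodeAges(
    ape::read.tree(text = "((A:1,B:1.0000001):2,C:3.0000001);"),
    tolerance = 1e-6)
  expect_equal(nodeAges(chr)[1:3], rep(0, 3))
  expect_error(computeNodeAges(
    ape::read.tree(text = "((A:1,B:1.0000001):2,C:3.0000001);"),
    tolerance = 1e-9), "not ultrametric")
})

test_that("datedist reading skips headers, applies ceiling burn-in, keeps order", {
  lines <- c("10", "", "# a comment",
             vapply(1:10, function(i) toyTreeWithABAge(i / 4), character(1)))
  path <- writeTreeFile(lines)
  s <- readDatedist(path, burnInFraction = 0.2)
  expect_equal(nTrees(s), 8)
  # first two trees discarded: retained trees start at AB age 3/4
  ab <- cladeDefinition("AB", c("A", "B"))
  ages <- vapply(seq_len(8), function(i)
    cladeAge(resolveCladeAge(s[[i]], ab)), numeric(1))
  expect_equal(ages, (3:10) / 4)
  expect_equal(provenance(s)$discarded, 2L)
  # burn-in monotonicity: larger fraction never retains more trees
  kept <- vapply(c(0, 0.1, 0.25, 0.5, 0.9), function(b)
    nTrees(readDatedist(path, burnInFraction = b)), numeric(1))
  expect_true(all(diff(kept) <= 0))
  expect_error(readDatedist(path, burnInFraction = 0.999), "no trees")
})

test_that("parse and structural errors name the offending line or tree", {
  path <- writeTreeFile(c(toyTreeWithABAge(1), "((A:1,B:1):2", toyTreeWithABAge(2)))
  expect_error(readDatedist(path, burnInFraction = 0), "line 2")
  path2 <- writeTreeFile(c(toyTreeWithABAge(1),
                           "((A:1,B:1):2,(C:2,E:2):1);"))
  expect_error(readDatedist(path2, burnInFraction = 0), "leaf set")
  path3 <- writeTreeFile(c(toyTreeWithABAge(1), "((A:1,B:1):2,(C:2,D:9):1);"))
  expect_error(readDatedist(path3, burnInFraction = 0), "tree 2")
})

test_that("single-leaf lines and unit rescaling are handled", {
  s <- readDatedist(writeTreeFile("A;"), burnInFraction = 0)
  expect_equal(rootAge(s[[1]]), 0)
  # scale converts Ga input to Ma at read time
  s2 <- readDatedist(writeTreeFile(toyTreeWithABAge(1)), burnInFraction = 0,
                     scale = 1000)
  expect_equal(rootAge(s2[[1]]), 5000)
})

test_that("unrooted trees are rejected unless an outgroup is given", {
  path <- writeTreeFile("(A:3,(B:2,C:2):1,D:3);")
  expect_error(readDatedist(path, burnInFraction = 0), "unrooted")
  s <- readDatedist(path, burnInFraction = 0, outgroup = "D")
  expect_true(ape::is.rooted(treeTopology(s[[1]])))
  expect_equal(rootAge(s[[1]]), 3)
})

test_that("writing then reading a sample reproduces all node ages", {
  study <- smallStudy(seed = 11, nTrees = 10, nTaxa = 12, nConstraints = 4)
  path <- tempfile(fileext = ".datedist")
  writeDatedist(study$sample, path)
  back <- readDatedist(path, burnInFraction = 0)
  expect_equal(nTrees(back), 10)
  # node numbering can change across the newick round trip, so compare the
  # sorted age spectra and the root age
  for (i in seq_len(10)) {
    expect_equal(rootAge(back[[i]]), rootAge(study$sample[[i]]),
                 tolerance = 1e-9)
    expect_equal(sort(nodeAges(back[[i]])), sort(nodeAges(study$sample[[i]])),
                 tolerance = 1e-9)
  }
})

test_that("merging chains concatenates trees and records provenance", {
  p1 <- writeTreeFile(vapply(1:10, function(i) toyTreeWithABAge(i / 4),
                             character(1)))
  s1 <- readDatedist(p1, 0.2, chain = "c1")
  s2 <- readDatedist(p1, 0.2, chain = "c2")
  merged <- mergeChains(list(s1, s2))
  expect_equal(nTrees(merged), 16)
  expect_equal(nrow(provenance(merged)), 2)
  expect_identical(mergeChains(list(s1)), s1)
  bad <- readDatedist(writeTreeFile("((A:1,B:1):2,(C:2,E:2):1);"), 0)
  expect_error(mergeChains(list(s1, bad)), "leaf sets")
})

test_that("age tables are complete and consistent with clade resolution", {
  study <- smallStudy(seed = 5, nTrees = 3, nTaxa = 10, nConstraints = 2)
  clades <- list(study$constraints[[1]]@donor, study$constraints[[1]]@recipient,
                 cladeDefinition("all", leafSet(study$sample)))
  path <- tempfile(fileext = ".tsv")
  df <- writeAgeTable(study$sample, clades, path)
  expect_equal(nrow(df), 3 * 3)
  back <- read.delim(path)
  expect_equal(back$age, df$age, tolerance = 1e-12)
  expect_equal(df$age[df$clade == "all"],
               vapply(1:3, function(i) rootAge(study$sample[[i]]), numeric(1)))
  # empty clade list gives a header-only file
  writeAgeTable(study$sample, list(), path)
  expect_equal(nrow(read.delim(path)), 0)
})

test_that("annotated newick carries per-node summaries and stays parseable", {
  chr <- toyChronogram()
  nd <- data.frame(node = c(5, 6), age_mean = c(3, 1),
                   age_ci_older = c(3.2, 1.2), age_ci_younger = c(2.8, 0.9))
  nwk <- writeAnnotatedChronogram(chr, nodeData = nd)
  expect_match(nwk, "age_mean=3", fixed = TRUE)
  expect_match(nwk, "age_ci={3.2,2.8}", fixed = TRUE)
  path <- tempfile(fileext = ".nwk")
  writeAnnotatedChronogram(chr, path, nd)
  reread <- computeNodeAges(ape::read.tree(path))  # ape strips comments
  expect_equal(rootAge(reread), 3)
})
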