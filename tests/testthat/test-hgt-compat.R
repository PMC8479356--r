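cdAB <- cladeDefinition("AB", c("A", "B"))
cdCD <- cladeDefinition("CD", c("C", "D"))

test_that("compatibility is a strict donor-older comparison", {
  chr <- toyChronogram()  # AB crown 1, CD crown 2
  expect_true(isCompatible(chr, hgtConstraint("h", cdCD, cdAB)))
  expect_false(isCompatible(chr, hgtConstraint("h", cdAB, cdCD)))
  # exact age tie counts as incompatible in both directions
  tie <- toyChronogram("((A:2,B:2):1,(C:2,D:2):1);")
  expect_false(isCompatible(tie, hgtConstraint("h", cdAB, cdCD)))
  expect_false(isCompatible(tie, hgtConstraint("h", cdCD, cdAB)))
  # stem/crown pairing follows each clade's groupKind
  stemDonor <- hgtConstraint("h", cladeDefinition("CD", c("C", "D"), "total"),
                             cdAB)
  expect_true(isCompatible(chr, stemDonor))  # stem CD age 3 > crown AB age 1
})

test_that("donor and recipient must differ and resolution errors propagate", {
  expect_error(hgtConstraint("h", cdAB, cladeDefinition("BA", c("B", "A"))),
               "identical")
  chr <- toyChronogram()
  bad <- hgtConstraint("h", cladeDefinition("XZ", c("X", "Z")), cdAB)
  expect_error(isCompatible(chr, bad), "not in tree")
})

test_that("the compatibility matrix is exact per cell and complete", {
  t1 <- toyChronogram("((A:1,B:1):2,(C:2,D:2):1);")  # CD (2) > AB (1)
  t2 <- toyChronogram("((A:2,B:2):1,(C:1,D:1):2);")  # CD (1) < AB (2)
  s <- new("PosteriorSample", trees = list(t1, t2),
           leafSet = c("A", "B", "C", "D"), modelLabel = "m",
           calibrationLabel = "",
           provenance = data.frame(file = "", chain = "", kept = 2L,
                                   discarded = 0L))
  m <- compatibilityMatrix(s, list(hgtConstraint("c1", cdCD, cdAB)))
  expect_identical(as.vector(compatValues(m)), c(TRUE, FALSE))
  expect_equal(unname(constraintProfile(m)), 50)
  # zero constraints give a zero-column matrix
  m0 <- compatibilityMatrix(s, list())
  expect_equal(dim(m0), c(2L, 0L))
})

test_that("model score equals the per-constraint mean and the cell fraction", {
  v <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
              dimnames = list(NULL, c("c1", "c2")))
  m <- new("CompatibilityMatrix", values = v, modelLabel = "m",
           calibrationLabel = "")
  expect_equal(modelScore(m), 75)
  expect_identical(modelScore(m), mean(constraintProfile(m)))
  expect_identical(modelScore(m), 100 * mean(v))
  allT <- new("CompatibilityMatrix",
              values = matrix(TRUE, 8, 3, dimnames = list(NULL, letters[1:3])),
              modelLabel = "m", calibrationLabel = "")
  expect_equal(modelScore(allT), 100)
  expect_equal(unname(constraintProfile(allT)), c(100, 100, 100))
  allF <- new("CompatibilityMatrix",
              values = matrix(FALSE, 4, 2, dimnames = list(NULL, c("a", "b"))),
              modelLabel = "m", calibrationLabel = "")
  expect_equal(modelScore(allF), 0)
  empty <- new("CompatibilityMatrix",
               values = matrix(logical(0), 0, 2,
                               dimnames = list(NULL, c("a", "b"))),
               modelLabel = "m", calibrationLabel = "")
  expect_error(constraintProfile(empty), "zero trees")
})

test_that("support counting uses an inclusive threshold", {
  prof <- c(a = 100, b = 19.9, c = 20.0)
  expect_equal(supportedConstraintCount(prof, 20), 2)
  expect_equal(supportedConstraintCount(prof, 0), 3)
  expect_error(supportedConstraintCount(numeric(0)), "non-empty")
})

test_that("miscalibration flags require near-zero compatibility in every model", {
  mk <- function(lab, p) new("ModelReport", modelLabel = lab,
                             perConstraintPct = p, overallPct = mean(p),
                             supportedCount = sum(p >= 20), flagged = names(p)[p < 1.2])
  r1 <- mk("m1", c(x = 0.0, y = 0.5, z = 50))
  r2 <- mk("m2", c(x = 0.9, y = 40, z = 60))
  r3 <- mk("m3", c(x = 1.1, y = 0.1, z = 70))
  expect_identical(flagMiscalibration(list(r1, r2, r3)), "x")
  expect_identical(flagMiscalibration(list(r1, r2, r3), flagThreshold = 0.5),
                   character(0))
  expect_error(flagMiscalibration(list()), "at least one")
  r4 <- mk("m4", c(x = 0, q = 0))
  expect_error(flagMiscalibration(list(r1, r4)), "different constraint sets")
})

test_that("forward and reverse constraints are never both compatible", {
  for (seed in 1:6) {
    chr <- randomChronogram(8, seed)
    clades <- oracleBipartitionClades(treeTopology(chr))
    clades <- clades[vapply(clades, length, 1L) < 8]
    for (i in seq_along(clades)) {
      for (j in seq_along(clades)) {
        if (i == j || length(intersect(clades[[i]], clades[[j]]))) next
        d <- cladeDefinition("d", clades[[i]])
        r <- cladeDefinition("r", clades[[j]])
        fwd <- isCompatible(chr, hgtConstraint("f", d, r))
        rev <- isCompatible(chr, hgtConstraint("r", r, d))
        expect_false(fwd && rev)
        # coalescent ages never tie exactly, so exactly one direction holds
        expect_true(fwd || rev)
      }
    }
  }
})

test_that("profiles and scores are invariant under tree-order permutation", {
  study <- smallStudy(seed = 9, nTrees = 50, nTaxa = 15, nConstraints = 8)
  m <- compatibilityMatrix(study$sample, study$constraints)
  set.seed(1)
  perm <- sample(50)
  mPerm <- compatibilityMatrix(study$sample[perm], study$constraints)
  expect_identical(constraintProfile(m), constraintProfile(mPerm))
  expect_identical(modelScore(m), modelScore(mPerm))
})

test_that("duplicate donor/recipient pairs collapse to unique constraints", {
  c1 <- hgtConstraint("HGT_01", cdCD, cdAB)
  c2 <- hgtConstraint("HGT_02", cdCD, cdAB)
  c3 <- hgtConstraint("HGT_03", cdAB, cdCD)
  dd <- dedupConstraints(list(c1, c2, c3))
  expect_equal(length(dd), 2)
  expect_match(dd[[1]]@note, "HGT_01,HGT_02")
  # crown vs total on the same clades are distinct constraints
  c4 <- hgtConstraint("HGT_04", cladeDefinition("CD", c("C", "D"), "total"),
                      cdAB)
  expect_equal(length(dedupConstraints(list(c1, c4))), 2)
})

test_that("constraint tables round-trip and deduplicate on read", {
  clades <- list(cdAB, cdCD, cladeDefinition("ABCD", c("A", "B", "C", "D")))
  cpath <- tempfile(fileext = ".tsv")
  writeCladeTable(clades, cpath)
  cons <- list(hgtConstraint("h1", cdCD, cdAB, note = "fam1"),
               hgtConstraint("h2", cdCD, cdAB),
               hgtConstraint("h3", cdAB, cdCD))
  kpath <- tempfile(fileext = ".tsv")
  writeConstraintTable(cons, kpath)
  back <- readConstraintTable(kpath, readCladeTable(cpath))
  expect_equal(length(back), 2)
  expect_equal(back[[1]]@donor@name, "CD")
  expect_match(back[[1]]@note, "h1,h2")
  backRaw <- readConstraintTable(kpath, readCladeTable(cpath), dedup = FALSE)
  expect_equal(length(backRaw), 3)
})
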