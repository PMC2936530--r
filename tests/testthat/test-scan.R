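# A single-marker "map" whose genotypes are given directly; convenient for
# closed-form scan checks.
markerOnlyGeno <- function(alleleVec) {
  mk <- data.frame(marker_id = c("mA", "mB"), chromosome = 1L,
                   position_cM = c(0, 100), position_bp = c(0, 2.5e7))
  a <- cbind(mA = alleleVec, mB = alleleVec)
  rownames(a) <- paste0("l", seq_along(alleleVec))
  new("GenotypeMatrix", alleles = a, map = geneticMap(mk))
}

test_that("the eight-line worked example reproduces the closed form", {
  g <- markerOnlyGeno(rep(c("B", "S"), each = 4))
  y <- c(3, 2, 3, 2, 1, 0, 1, 0)
  sc <- scanIM(y, calcGenoprob(g, stepCM = NULL))
  s <- scanTable(sc)
  expect_equal(s$lod[1], 4 * log10(5), tolerance = 1e-9)
  expect_equal(s$a[1], 1.0, tolerance = 1e-9)
  expect_equal(s$pve[1], 0.8, tolerance = 1e-9)
})

test_that("scan statistics equal the lm() oracle at typed markers", {
  map <- smallMap()
  set.seed(21)
  for (rep in 1:5) {
    g <- simulateRILGenotypes(map, 80, seed = 100 + rep)
    y <- lineTrait(g, "c2_m010", 0.7, 1, seed = 200 + rep)
    sc <- scanTable(scanIM(y, calcGenoprob(g, stepCM = NULL)))
    for (j in sample(length(markerIds(map)), 10)) {
      o <- oracleMarkerFit(unname(y), alleles(g)[, j])
      expect_equal(sc$lod[j], o$lod, tolerance = 1e-9)
      expect_equal(sc$a[j], o$a, tolerance = 1e-9)
      expect_equal(sc$pve[j], o$pve, tolerance = 1e-9)
    }
  }
})

test_that("PVE and LOD satisfy their algebraic identity at every position", {
  map <- smallMap()
  g <- simulateRILGenotypes(map, 60, seed = 31)
  y <- lineTrait(g, "c1_m012", 1, 1, seed = 31)
  sc <- scanIM(y, calcGenoprob(g, stepCM = 2))
  s <- scanTable(sc)
  expect_equal(s$pve, 1 - 10^(-2 * s$lod / sc@n), tolerance = 1e-12)
  expect_true(all(s$lod >= 0))
})

test_that("swapping parent labels negates the additive effect exactly", {
  map <- smallMap()
  g <- simulateRILGenotypes(map, 60, seed = 41)
  y <- lineTrait(g, "c3_m012", 0.8, 1, seed = 41)
  sw <- alleles(g)
  sw[] <- ifelse(sw == "B", "S", "B")
  gSw <- new("GenotypeMatrix", alleles = sw, map = map)
  s1 <- scanTable(scanIM(y, calcGenoprob(g, stepCM = NULL)))
  s2 <- scanTable(scanIM(y, calcGenoprob(gSw, stepCM = NULL)))
  expect_equal(s2$a, -s1$a, tolerance = 1e-12)
  expect_equal(s2$lod, s1$lod, tolerance = 1e-12)
})

test_that("degenerate scan inputs are rejected", {
  map <- smallMap()
  g <- simulateRILGenotypes(map, 30, seed = 51)
  gp <- calcGenoprob(g, stepCM = NULL)
  expect_error(scanIM(rep(1, 30), gp), "constant")
  expect_error(scanIM(rnorm(5), gp), "lines")
  y <- setNames(rnorm(29), rownames(alleles(g))[1:29])
  expect_error(scanIM(y, gp), "RIL030")
})

test_that("permutation thresholds are deterministic and honor boundaries", {
  map <- smallMap()
  g <- simulateRILGenotypes(map, 60, seed = 61)
  y <- lineTrait(g, "c1_m012", 0, 1, seed = 61)
  gp <- calcGenoprob(g, stepCM = NULL)
  s1 <- permutationThreshold(y, gp, nPerm = 200, alpha = 0.05, seed = 7)
  s2 <- permutationThreshold(y, gp, nPerm = 200, alpha = 0.05, seed = 7)
  expect_identical(lodThreshold(s1), lodThreshold(s2))
  expect_gt(lodThreshold(s1), 0)
  # alpha = 1 is the minimum permuted maximum; alpha = tiny the largest
  sMin <- permutationThreshold(y, gp, nPerm = 200, alpha = 1, seed = 7)
  sMax <- permutationThreshold(y, gp, nPerm = 200, alpha = 1e-9, seed = 7)
  expect_lte(lodThreshold(sMin), lodThreshold(s1))
  expect_gte(lodThreshold(sMax), lodThreshold(s1))
  expect_error(permutationThreshold(y, gp, nPerm = 50), "100")
  expect_error(permutationThreshold(y, gp, nPerm = 200, alpha = 0), "alpha")
})

test_that("expected LOD at the true locus grows with population size", {
  map <- smallMap()
  lodAt <- function(n, seed) {
    g <- simulateRILGenotypes(map, n, seed = seed)
    y <- lineTrait(g, "c2_m010", 0.5, 1, seed = seed)
    s <- scanTable(scanIM(y, calcGenoprob(g, stepCM = NULL)))
    s$lod[match("c2_m010", markerIds(map))]
  }
  lods <- vapply(c(50, 126, 253), function(n)
    mean(vapply(1:8, function(r) lodAt(n, 300 + 17 * n + r), numeric(1))),
    numeric(1))
  expect_true(all(diff(lods) > 0))
})

test_that("the planted additive effect is estimated without bias", {
  map <- makeMap(1, 24, 100)
  trueMarker <- "c1_m010"
  j <- match(trueMarker, markerIds(map))
  aHat <- vapply(1:200, function(r) {
    g <- simulateRILGenotypes(map, 253, seed = 700 + r)
    y <- lineTrait(g, trueMarker, 1, 1, seed = 900 + r)
    scanTable(scanIM(y, calcGenoprob(g, stepCM = NULL)))$a[j]
  }, numeric(1))
  expect_lt(abs(mean(aHat) - 1), 0.05)
})

test_that("informative-subset selection maximizes the target effect", {
  map <- smallMap()
  g <- simulateRILGenotypes(map, 100, seed = 71)
  y <- lineTrait(g, "c2_m010", 0.6, 1, seed = 71)
  gp <- calcGenoprob(g, stepCM = NULL)
  full <- selectInformativeSubset(y, gp, nSubset = 100, nIter = 5,
                                  targetChromosome = 2, targetCM = 39,
                                  seed = 1)
  expect_setequal(full$lines, rownames(alleles(g)))
  expect_equal(full$value, full$fullValue)

  sub1 <- selectInformativeSubset(y, gp, nSubset = 50, nIter = 100,
                                  targetChromosome = 2, targetCM = 39,
                                  seed = 2)
  sub2 <- selectInformativeSubset(y, gp, nSubset = 50, nIter = 100,
                                  targetChromosome = 2, targetCM = 39,
                                  seed = 2)
  expect_identical(sub1$lines, sub2$lines)
  expect_gte(sub1$value, sub1$fullValue)
  expect_error(selectInformativeSubset(y, gp, nSubset = 50, nIter = 0,
                                       targetChromosome = 2, targetCM = 39),
               "nIter")
})

test_that("subset selection beats the full population almost always", {
  map <- smallMap()
  hits <- vapply(1:20, function(r) {
    g <- simulateRILGenotypes(map, 80, seed = 500 + r)
    y <- lineTrait(g, "c1_m012", 0.6, 1, seed = 500 + r)
    gp <- calcGenoprob(g, stepCM = NULL)
    s <- selectInformativeSubset(y, gp, nSubset = 40, nIter = 100,
                                 targetChromosome = 1, targetCM = 48,
                                 seed = r)
    s$value >= s$fullValue
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
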