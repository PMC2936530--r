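test_that("indices equal raw line-by-treatment means when nothing is adjusted", {
  map <- makeMap(1, 5, 100)
  g <- simulateRILGenotypes(map, 20, seed = 1)
  ph <- simulatePhenotypes(g, qtlSpec(1, 50, 1, -1), noiseSD = 1, reps = 3,
                           seed = 1)
  idx <- computeConditionIndices(ph)
  raw <- tapply(ph$value, list(ph$line_id, ph$treatment), mean)
  expect_equal(idx$sun, unname(raw[idx$line_id, "sun"]))
  expect_equal(idx$shade, unname(raw[idx$line_id, "shade"]))

  # single plant per line x treatment: index is that plant's value
  ph1 <- simulatePhenotypes(g, noiseSD = 1, reps = 1, seed = 2)
  idx1 <- computeConditionIndices(ph1)
  one <- ph1[ph1$treatment == "sun", ]
  expect_equal(idx1$sun, one$value[match(idx1$line_id, one$line_id)])
})

test_that("a significant balanced chamber shift is removed from the indices", {
  map <- makeMap(1, 5, 100)
  g <- simulateRILGenotypes(map, 30, seed = 3)
  ph <- simulatePhenotypes(g, qtlSpec(1, 50, 1, -1), noiseSD = 1, reps = 4,
                           seed = 3)
  # balanced assignment: replicates alternate chambers within every cell
  ph$chamber <- rep(c("A", "B"), length.out = nrow(ph))
  ph2 <- ph
  ph2$value <- ph2$value + ifelse(ph2$chamber == "A", 10, 0)
  idx <- computeConditionIndices(ph, "chamber")
  idx2 <- computeConditionIndices(ph2, "chamber")
  # the chamber contrast is removed exactly; the remaining discrepancy is a
  # single unidentifiable location constant shared by all lines and
  # treatments, which no downstream index or scan can see
  shift <- mean(idx2$sun) - mean(idx$sun)
  expect_equal(idx2$sun - shift, idx$sun, tolerance = 1e-9)
  expect_equal(idx2$shade - shift, idx$shade, tolerance = 1e-9)
  expect_equal(subtractionIndex(idx2$sun, idx2$shade),
               subtractionIndex(idx$sun, idx$shade), tolerance = 1e-9)
  expect_equal(residualIndex(idx2$sun, idx2$shade),
               residualIndex(idx$sun, idx$shade), tolerance = 1e-9)
})

test_that("structural problems in the phenotype table are reported", {
  map <- makeMap(1, 5, 100)
  g <- simulateRILGenotypes(map, 10, seed = 4)
  ph <- simulatePhenotypes(g, noiseSD = 1, reps = 2, seed = 4)
  drop <- ph$line_id == "RIL003" & ph$treatment == "shade"
  expect_error(computeConditionIndices(ph[!drop, ]), "RIL003")
  ph$shelf <- ifelse(ph$treatment == "sun", "top", "bottom")
  expect_error(computeConditionIndices(ph, "shelf"), "confounded")
  expect_error(computeConditionIndices(ph, "nosuch"), "nosuch")
})

test_that("the Shapiro-Wilk gate transforms only non-normal positive traits", {
  set.seed(71)
  notTransformed <- vapply(1:200, function(i)
    normalityGate(rnorm(253, 50, 1))$transformed, logical(1))
  expect_gte(mean(!notTransformed), 0.95)
  set.seed(72)
  transformed <- vapply(1:200, function(i)
    normalityGate(exp(rnorm(253)))$transformed, logical(1))
  expect_gte(mean(transformed), 0.99)
  # log of a lognormal really is what comes back
  v <- exp(rnorm(253))
  out <- normalityGate(v)
  if (out$transformed) expect_equal(out$values, log(v))
})

test_that("the gate refuses to log non-positive values", {
  set.seed(73)
  v <- c(0, exp(rnorm(200, 0, 2)))
  expect_lt(shapiro.test(v)$p.value, 0.01)
  expect_error(normalityGate(v, trait = "petiole_length"), "petiole_length")
  expect_error(normalityGate(c(1, 2)), "at least 3")
})

test_that("subtraction index is exact arithmetic and shift-invariant", {
  expect_equal(subtractionIndex(5, 3), 2)
  sun <- c(a = 4, b = 7, c = 7)
  expect_equal(subtractionIndex(sun, sun), c(a = 0, b = 0, c = 0))
  expect_error(subtractionIndex(1:3, 1:4), "length")
  expect_error(subtractionIndex(c(a = 1, b = 2), c(b = 1, a = 2)),
               "aligned")
  # adding a constant to every phenotype cancels in the subtraction index
  shade <- c(a = 1, b = 5, c = 2)
  expect_equal(subtractionIndex(sun + 100, shade + 100),
               subtractionIndex(sun, shade))
})

test_that("responsive lines score positive on the subtraction index", {
  # shade accelerates flowering: shade value below sun value
  sun <- c(60, 62, 58)
  shade <- c(50, 49, 51)
  expect_true(all(subtractionIndex(sun, shade) > 0))
})

test_that("residual index matches the least-squares closed form", {
  ri <- residualIndex(c(1, 2, 3), c(1, 1, 2))
  expect_equal(ri, c(-1/6, 1/3, -1/6), tolerance = 1e-12)
  # independent normal-equations oracle on random data
  set.seed(74)
  for (i in 1:10) {
    sun <- rnorm(40); shade <- 0.8 * sun + rnorm(40)
    X <- cbind(1, sun)
    beta <- solve(t(X) %*% X, t(X) %*% shade)
    expect_equal(residualIndex(sun, shade),
                 unname(-(shade - X %*% beta)[, 1]), tolerance = 1e-9)
  }
  expect_equal(residualIndex(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_error(residualIndex(rep(1, 5), rnorm(5)), "constant")
  expect_error(residualIndex(1:2, 1:2), "3 lines")
})

test_that("residual index is centered and orthogonal to the sun index", {
  set.seed(75)
  for (i in 1:20) {
    sun <- rnorm(100); shade <- rnorm(100, 0.5 * sun)
    ri <- residualIndex(sun, shade)
    expect_lt(abs(mean(ri)), 1e-9 * sd(ri))
    expect_lt(abs(cor(ri, sun)), 1e-9)
  }
})

test_that("both shade-avoidance indices agree under the generating model", {
  sc <- simulateScenario(pipelineConfig(), seed = 6)
  idx <- computeTraitIndices(sc$pheno,
                             nuisanceFactors = names(sc$config$nuisance))
  expect_gt(cor(idx$subtraction, idx$residual, method = "spearman"), 0.9)
})
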