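# Small hand-built evidence layers: one candidate chromosome with tiled
# genes, targets on another chromosome, explicit mutual ranks and eQTL CIs.
tinyAnnotation <- function() {
  g <- GenomicRanges::GRanges(
    c(rep("1", 4), rep("2", 3)),
    IRanges::IRanges(start = c(1000, 3000, 5000, 7000, 1000, 3000, 5000),
                     width = 1001),
    strand = "+")
  S4Vectors::mcols(g)$gene_id <- c("cand1", "cand2", "cand3", "cand4",
                                   "t1", "t2", "t3")
  g
}

test_that("interval membership follows the any-overlap rule with exact boundaries", {
  ann <- tinyAnnotation()
  # cand2 spans 3000-4000: ending 1 bp before the interval start excludes it
  expect_equal(candidatesInInterval(ann, 1, 4001, 6000), "cand3")
  expect_true("cand2" %in% candidatesInInterval(ann, 1, 4000, 6000))
  # partial overlap counts for "overlap" but not "within"
  expect_equal(candidatesInInterval(ann, 1, 3500, 4200), "cand2")
  expect_equal(length(candidatesInInterval(ann, 1, 3500, 4200,
                                           rule = "within")), 0L)
  expect_error(candidatesInInterval(ann, 1, 10, 5), "empty")
})

test_that("tiled-gene counts match a brute-force overlap scan", {
  starts <- seq(1, by = 1000, length.out = 200)
  ann <- GenomicRanges::GRanges("3", IRanges::IRanges(starts, width = 501))
  S4Vectors::mcols(ann)$gene_id <- sprintf("g%03d", 1:200)
  left <- starts[40]; right <- starts[79] + 500
  got <- candidatesInInterval(ann, 3, left, right)
  brute <- sprintf("g%03d", which(starts <= right & starts + 500 >= left))
  expect_equal(got, brute)
  expect_length(got, 40)
})

test_that("mutual-rank cutoff is strictly below the threshold", {
  coexpr <- data.frame(gene_a = c("cand1", "cand1", "x", "cand1"),
                       gene_b = c("x", "y", "z", "w"),
                       mutual_rank = c(49.9, 50, 1, 3))
  nb <- coexpressionNeighbors("cand1", coexpr, mrThreshold = 50)
  expect_setequal(names(nb), c("x", "w"))
  expect_warning(nb0 <- coexpressionNeighbors("absent", coexpr), "absent")
  expect_length(nb0, 0)
})

test_that("tightening the mutual-rank threshold never adds neighbors", {
  x <- simulateExpressionCompendium(sprintf("g%02d", 1:40),
                                    sprintf("g%02d", 1:8), rho = 0.6,
                                    nExperiments = 80, seed = 9)
  coexpr <- computeMutualRanks(x)
  for (cand in sample(rownames(x), 15)) {
    n50 <- names(coexpressionNeighbors(cand, coexpr, 50))
    n25 <- names(coexpressionNeighbors(cand, coexpr, 25))
    expect_true(all(n25 %in% n50))
  }
})

test_that("eQTL colocalization keeps exactly the locally-controlled neighbors", {
  ann <- tinyAnnotation()
  eqtl <- data.frame(
    expr_gene = c("t1", "t2", "t3"),
    chromosome = c(1, 2, 1),
    peak_cM = c(0.01, 0.01, 0.03),
    ci_left_bp = c(500, 500, 6500),
    ci_right_bp = c(2500, 2500, 8000))
  nb <- setNames(c(5, 5, 5), c("t1", "t2", "t3"))
  kept <- eqtlColocalizationFilter("cand1", nb, eqtl, ann)  # 1000-2000
  expect_equal(kept$to, "t1")           # t2: wrong chromosome; t3: wrong CI
  expect_equal(kept$from, "cand1")
  kept4 <- eqtlColocalizationFilter("cand4", nb, eqtl, ann) # 7000-8000
  expect_equal(kept4$to, "t3")
  expect_error(eqtlColocalizationFilter("nope", nb, eqtl, ann),
               "annotation")
  expect_warning(
    eqtlColocalizationFilter("cand1", setNames(3, "ghost"), eqtl, ann),
    "ghost")
})

test_that("scan-derived eQTL confidence intervals follow the contiguous rule", {
  mk <- data.frame(marker_id = paste0("m", 1:8), chromosome = 1L,
                   position_cM = seq(0, 70, by = 10),
                   position_bp = seq(0, 70, by = 10) * 1e5)
  map <- geneticMap(mk)
  mkScan <- function(peakCM) {
    grid <- sort(unique(c(mk$position_cM, peakCM)))
    lod <- ifelse(grid == peakCM, 10, 1)
    new("QTLScan", scan = data.frame(chromosome = 1L, position_cM = grid,
                                     lod = lod, a = 1, pve = 0.1),
        n = 100L, trait = "expr1")
  }
  ci <- eqtlCIFromScan(mkScan(44), map)       # inside (m5, m6)
  expect_equal(c(ci$ci_left_bp, ci$ci_right_bp), c(30e5, 60e5))
  expect_equal(ci$expr_gene, "expr1")
  ci <- eqtlCIFromScan(mkScan(4), map)        # first interval
  expect_equal(c(ci$ci_left_bp, ci$ci_right_bp), c(0, 20e5))
})

test_that("GO coherence means sharing a biological-process term", {
  go <- data.frame(
    gene_id = c("cand1", "cand1", "t1", "t2", "cand1", "t3"),
    term = c("circadian rhythm", "flowering", "flowering", "other",
             "nucleus", "nucleus"),
    aspect = c(rep("involved_in", 4), "located_in", "located_in"))
  edges <- data.frame(from = rep("cand1", 3), to = c("t1", "t2", "t3"),
                      mutual_rank = c(2, 3, 4))
  out <- goCoherentEdges(edges, go)
  # t1 shares "flowering"; t2 shares nothing; t3 only a non-process term
  expect_equal(out$coherent, c(TRUE, FALSE, FALSE))
})

test_that("coherence flags equal a brute-force set-intersection loop", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:120)
  go <- data.frame(
    gene_id = sample(genes, 400, replace = TRUE),
    term = sample(sprintf("proc%02d", 1:15), 400, replace = TRUE),
    aspect = sample(c("involved_in", "located_in"), 400, replace = TRUE,
                    prob = c(0.8, 0.2)))
  edges <- data.frame(from = sample(genes, 500, replace = TRUE),
                      to = sample(genes, 500, replace = TRUE),
                      mutual_rank = runif(500, 1, 50))
  out <- goCoherentEdges(edges, go)
  bp <- go[go$aspect == "involved_in", ]
  for (i in seq_len(500)) {
    shared <- length(intersect(bp$term[bp$gene_id == edges$from[i]],
                               bp$term[bp$gene_id == edges$to[i]])) > 0
    if (out$coherent[i] != shared)
      fail(sprintf("edge %d disagrees with the oracle", i))
  }
  succeed()
})

test_that("polymorphism flags separate sequence and cis-regulatory evidence", {
  ann <- tinyAnnotation()
  poly <- data.frame(gene_id = "cand1", non_synonymous = TRUE)
  eqtl <- data.frame(expr_gene = c("cand2", "cand3"),
                     chromosome = c(1, 2),
                     peak_cM = c(0.015, 0.01),
                     ci_left_bp = c(2500, 500),
                     ci_right_bp = c(4500, 2500))
  fl <- polymorphismFlags(c("cand1", "cand2", "cand3", "cand4"), poly,
                          eqtl, ann)
  expect_equal(fl$non_synonymous, c(TRUE, FALSE, FALSE, FALSE))
  # cand2's own eQTL covers its span (3000-4000): cis; cand3 maps elsewhere
  expect_equal(fl$cis_eqtl, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fl$polymorphic, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("assembly ranks by coherent connections with documented tie-breaks", {
  flags <- data.frame(gene_id = c("cand1", "cand2", "cand3"),
                      non_synonymous = c(FALSE, TRUE, FALSE),
                      cis_eqtl = c(FALSE, FALSE, TRUE),
                      polymorphic = c(FALSE, TRUE, TRUE))
  edges <- data.frame(
    from = c("cand1", "cand1", "cand1", "cand2"),
    to = c("t1", "t2", "t3", "t1"),
    mutual_rank = c(2, 3, 4, 5),
    coherent = c(TRUE, TRUE, FALSE, TRUE))
  net <- assembleAndRank(c("cand1", "cand2", "cand3"), edges, flags)
  rk <- ranking(net)
  # the hub wins despite not being polymorphic; flags reported separately
  expect_equal(rk$gene_id, c("cand1", "cand2", "cand3"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$n_coherent_edges, c(2L, 1L, 0L))
  expect_false(rk$polymorphic[1])
  # conservation: coherent <= total edges
  expect_true(all(rk$n_coherent_edges <= rk$n_edges))
  # cis-eQTL emits a self-loop of its own type
  e <- net@edges
  expect_true(any(e$from == "cand3" & e$to == "cand3" & e$type == "cis"))
  # only connected nodes enter the graph
  expect_true(all(igraph::degree(networkGraph(net)) >= 1))
})

test_that("equal-evidence candidates order deterministically by id", {
  flags <- data.frame(gene_id = c("candB", "candA"),
                      non_synonymous = FALSE, cis_eqtl = FALSE,
                      polymorphic = FALSE)
  edges <- data.frame(from = c("candB", "candA"), to = c("t1", "t2"),
                      mutual_rank = 1, coherent = TRUE)
  rk <- ranking(assembleAndRank(c("candB", "candA"), edges, flags))
  expect_equal(rk$gene_id, c("candA", "candB"))
})

test_that("empty networks are valid and warn", {
  flags <- data.frame(gene_id = "cand1", non_synonymous = FALSE,
                      cis_eqtl = FALSE, polymorphic = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      mutual_rank = numeric(), coherent = logical())
  expect_warning(net <- assembleAndRank("cand1", edges, flags), "empty")
  expect_equal(nrow(net@nodes), 0)
  expect_equal(ranking(net)$n_edges, 0L)
})

test_that("GO coloring and eQTL filtering commute", {
  sc <- simulateScenario(pipelineConfig(), seed = 17)
  cands <- candidatesInInterval(
    sc$annotation, sc$truth$chromosome,
    cMToBp(sc$map, sc$truth$chromosome, sc$truth$positionCM) - 5e5,
    cMToBp(sc$map, sc$truth$chromosome, sc$truth$positionCM) + 5e5)
  filterThenColor <- colorThenFilter <- list()
  for (cand in cands) {
    nb <- suppressWarnings(coexpressionNeighbors(cand, sc$coexpr))
    if (!length(nb)) next
    kept <- eqtlColocalizationFilter(cand, nb, sc$eqtl, sc$annotation)
    filterThenColor[[cand]] <- goCoherentEdges(kept, sc$go)
    pre <- goCoherentEdges(
      data.frame(from = cand, to = names(nb), mutual_rank = unname(nb)),
      sc$go)
    colorThenFilter[[cand]] <-
      pre[pre$to %in% kept$to, c("from", "to", "mutual_rank", "coherent")]
  }
  a <- do.call(rbind, filterThenColor)
  b <- do.call(rbind, colorThenFilter)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[order(a$from, a$to), ], b[order(b$from, b$to), ])
})

test_that("planted targets are kept and co-expressed-only decoys removed", {
  sc <- simulateScenario(pipelineConfig(), seed = 19)
  tr <- sc$truth
  nb <- coexpressionNeighbors(tr$regulator, sc$coexpr)
  expect_true(all(tr$targets %in% names(nb)))
  expect_true(all(tr$decoyCoexpressed %in% names(nb)))
  kept <- eqtlColocalizationFilter(tr$regulator, nb, sc$eqtl,
                                   sc$annotation)
  expect_true(all(tr$targets %in% kept$to))            # recall 1
  expect_false(any(tr$decoyCoexpressed %in% kept$to))  # decoys filtered
  # the decoys survive nowhere in the assembled network
  net <- buildCandidateNetwork(
    sc$annotation, tr$chromosome,
    cMToBp(sc$map, tr$chromosome, tr$positionCM) - 5e5,
    cMToBp(sc$map, tr$chromosome, tr$positionCM) + 5e5,
    sc$coexpr, sc$eqtl, sc$go, sc$polymorphisms)
  expect_false(any(tr$decoyCoexpressed %in% net@edges$to))
  rk <- ranking(net)
  expect_equal(rk$gene_id[1], tr$regulator)
  expect_gte(rk$n_coherent_edges[1], length(tr$targets))
})

test_that("an unannotated regulator vanishes from the coherent ranking", {
  sc <- simulateScenario(pipelineConfig(), seed = 23)
  tr <- sc$truth
  goBlind <- sc$go[sc$go$gene_id != tr$regulator, ]
  net <- buildCandidateNetwork(
    sc$annotation, tr$chromosome,
    cMToBp(sc$map, tr$chromosome, tr$positionCM) - 5e5,
    cMToBp(sc$map, tr$chromosome, tr$positionCM) + 5e5,
    sc$coexpr, sc$eqtl, goBlind, sc$polymorphisms)
  rk <- ranking(net)
  expect_equal(rk$n_coherent_edges[rk$gene_id == tr$regulator], 0L)
})
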