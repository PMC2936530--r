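#' Pipeline configuration
#'
#' One structured configuration drives both the synthetic-data generator
#' and the analysis so that a whole run is reproducible from a single seed.
#' Analysis defaults follow the field's conventional constants (genome-wide
#' alpha 0.05, Shapiro-Wilk gate at p < 0.01, 2-LOD support interval,
#' mutual-rank cutoff 50, 126-line informative subset); the default
#' permutation count is 1,000 to keep a full run fast (raise
#' \code{nPerm} to 10,000 for publication-scale thresholds).  Generator
#' defaults plant one G×E QTL (effect 0 in sun, -1 in shade: the B allele
#' accelerates development under shade, giving a positive shade-avoidance
#' index) at the regulator locus on chromosome 2, one constitutive QTL on
#' chromosome 4, and the default expression module (rho = 0.8, 12 targets)
#' around the regulator.
#'
#' @param ... overrides for any default listed below.
#' @return list of class \code{sarnetConfig}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # genome / population
    nLines = 253, nChromosomes = 5, markersPerChromosome = 116,
    chromLengthCM = 100, bpPerCM = 2.5e5,
    # planted truth
    truth = groundTruth(chromosome = 2, positionCM = 40, nTargets = 12,
                        effectSun = 0, effectShade = -1),
    extraQtl = qtlSpec(4, 50, 0.5, 0.5),   # constitutive, sun==shade
    # phenotype generation
    nuisance = list(chamber = c(-0.5, 0.5),
                    flat = seq(-0.35, 0.35, length.out = 8),
                    measurer = c(-0.25, 0.25)),
    noiseSD = 1, lineSD = 1, gxeSD = 1.4, reps = 4,
    treatmentMeans = c(sun = 60, shade = 50),
    trait = "flowering_time",
    # expression / annotation layers
    nExperiments = 200, nBackgroundGenes = 200, nIntervalGenes = 100,
    windowBp = 1.6e6, nRandomEqtl = 20,
    # analysis
    screenAlpha = 0.05, pThreshold = 0.01, applyGate = TRUE,
    stepCM = 1, nPerm = 1000, alpha = 0.05, drop = 2,
    mrThreshold = 50, intervalRule = "overlap", scanIndex = "residual",
    nSubset = 126)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$drop >= 0,
            cfg$mrThreshold > 0, cfg$noiseSD >= 0)
  structure(cfg, class = "sarnetConfig")
}

#' Null-scenario configurations
#'
#' \code{type = "no_qtl"} removes every planted QTL (the scan should find
#' no peak above threshold and the network stage is skipped);
#' \code{type = "no_module"} keeps the QTL but plants no expression module
#' or target eQTLs (the network stage runs, but no candidate should accrue
#' more than stray coherent edges).
#'
#' @param type which null to generate.
#' @param ... further overrides passed to \code{\link{pipelineConfig}}.
#' @return a \code{sarnetConfig}.
#' @export
nullConfig <- function(type = c("no_qtl", "no_module"), ...) {
  type <- match.arg(type)
  if (type == "no_qtl") {
    truth <- groundTruth(chromosome = 2, positionCM = 40, nTargets = 0,
                         effectSun = 0, effectShade = 0,
                         nDecoyCoexpressed = 0)
    pipelineConfig(truth = truth, extraQtl = qtlSpec(1, 0, 0, 0)[0, ], ...)
  } else {
    truth <- groundTruth(chromosome = 2, positionCM = 40, nTargets = 0,
                         effectSun = 0, effectShade = -1,
                         nDecoyCoexpressed = 0)
    pipelineConfig(truth = truth, ...)
  }
}

#' Generate every pipeline input for one scenario
#'
#' Runs the full generator stack: map, RIL genotypes, plant-level
#' phenotypes (planted QTL at the regulator locus plus any extra QTL),
#' annotation / GO / polymorphism / eQTL layers, the expression compendium
#' with its planted module, and the mutual-rank table.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param seed root seed; every generator stage derives its own stream.
#' @return list: \code{map}, \code{geno}, \code{pheno}, \code{annotation},
#'   \code{go}, \code{polymorphisms}, \code{eqtl}, \code{compendium},
#'   \code{coexpr}, \code{truth}, \code{config}, \code{seed}.
#' @export
simulateScenario <- function(config = pipelineConfig(), seed = 1L) {
  map <- makeMap(config$nChromosomes, config$markersPerChromosome,
                 config$chromLengthCM, config$bpPerCM, seed = seed)
  geno <- simulateRILGenotypes(map, config$nLines, seed = seed)
  qtl <- qtlSpec(config$truth$chromosome, config$truth$positionCM,
                 config$truth$effectSun, config$truth$effectShade)
  qtl <- qtl[qtl$effect_sun != 0 | qtl$effect_shade != 0, , drop = FALSE]
  if (!is.null(config$extraQtl) && nrow(config$extraQtl))
    qtl <- rbind(qtl, config$extraQtl)
  pheno <- simulatePhenotypes(geno, qtl, nuisance = config$nuisance,
                              noiseSD = config$noiseSD,
                              lineSD = config$lineSD, gxeSD = config$gxeSD,
                              reps = config$reps,
                              treatmentMeans = config$treatmentMeans,
                              trait = config$trait, seed = seed)
  layers <- buildAnnotationLayers(config$truth, map,
                                  nBackgroundGenes = config$nBackgroundGenes,
                                  nIntervalGenes = config$nIntervalGenes,
                                  windowBp = config$windowBp,
                                  nRandomEqtl = config$nRandomEqtl,
                                  seed = seed)
  truth <- layers$truth
  moduleGenes <- c(truth$regulator, truth$targets, truth$decoyCoexpressed)
  if (truth$nTargets == 0 && !length(truth$decoyCoexpressed))
    moduleGenes <- character()
  compendium <- simulateExpressionCompendium(
    S4Vectors::mcols(layers$annotation)$gene_id, moduleGenes,
    rho = truth$rho, nExperiments = config$nExperiments, seed = seed)
  coexpr <- computeMutualRanks(compendium)
  list(map = map, geno = geno, pheno = pheno,
       annotation = layers$annotation, go = layers$go,
       polymorphisms = layers$polymorphisms, eqtl = layers$eqtl,
       compendium = compendium, coexpr = coexpr, truth = truth,
       config = config, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Indices -> four genome scans (sun, shade, subtraction, residual) with a
#' permutation threshold on the reported index -> 2-LOD support interval ->
#' candidate network and hub ranking, with an optional artifact directory.
#' The network stage is skipped (with a report note) when the reported
#' scan's peak does not reach its genome-wide threshold.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param seed root seed.
#' @param outdir directory for stage artifacts, or \code{NULL} to skip
#'   writing.
#' @param scenario optionally, a pre-generated (or loaded) scenario list as
#'   returned by \code{\link{simulateScenario}} / \code{\link{loadInputs}};
#'   generated from \code{config} and \code{seed} when omitted.
#' @return list of class \code{sarnetReport}: per-index scan summaries, the
#'   interval, the ranking, a ground-truth comparison block (when truth is
#'   available), and the objects themselves.
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 1L,
                        outdir = NULL, scenario = NULL) {
  if (is.null(scenario)) scenario <- simulateScenario(config, seed)
  config <- scenario$config
  idx <- computeTraitIndices(scenario$pheno,
                             nuisanceFactors = names(config$nuisance),
                             screenAlpha = config$screenAlpha,
                             applyGate = config$applyGate,
                             pThreshold = config$pThreshold)
  gp <- calcGenoprob(scenario$geno, stepCM = config$stepCM)
  indexCols <- c("sun", "shade", "subtraction", "residual")
  scans <- list()
  for (ic in indexCols) {
    v <- setNames(idx[[ic]], idx$line_id)
    scans[[ic]] <- scanIM(v, gp, trait = paste(config$trait, ic, sep = "_"))
  }
  v <- setNames(idx[[config$scanIndex]], idx$line_id)
  scans[[config$scanIndex]] <- permutationThreshold(
    v, gp, nPerm = config$nPerm, alpha = config$alpha, seed = seed,
    scan = scans[[config$scanIndex]])
  main <- scans[[config$scanIndex]]
  s <- scanTable(main)
  pk <- which.max(s$lod)
  significant <- s$lod[pk] >= lodThreshold(main)

  interval <- NULL
  network <- NULL
  note <- NULL
  if (significant) {
    interval <- supportInterval(main, scenario$map, drop = config$drop)
    network <- buildCandidateNetwork(
      scenario$annotation, interval@chromosome, interval@leftBp,
      interval@rightBp, scenario$coexpr, scenario$eqtl, scenario$go,
      scenario$polymorphisms, mrThreshold = config$mrThreshold,
      rule = config$intervalRule)
  } else {
    note <- "no peak above threshold; network stage skipped"
  }

  truthBlock <- NULL
  tr <- scenario$truth
  if (!is.null(tr) && !is.na(tr$regulator)) {
    truthBlock <- list(regulator = tr$regulator)
    if (!is.null(interval)) {
      regBp <- cMToBp(scenario$map, tr$chromosome, tr$positionCM)
      truthBlock$regulator_in_interval <-
        interval@chromosome == tr$chromosome &&
        regBp >= interval@leftBp && regBp <= interval@rightBp
    }
    if (!is.null(network)) {
      rk <- ranking(network)
      i <- match(tr$regulator, rk$gene_id)
      truthBlock$regulator_rank <- if (is.na(i)) NA_integer_ else rk$rank[i]
      truthBlock$regulator_coherent_edges <-
        if (is.na(i)) 0L else rk$n_coherent_edges[i]
    }
  }

  summaries <- lapply(scans, function(sc) {
    st <- scanTable(sc)
    i <- which.max(st$lod)
    list(trait = sc@trait, chromosome = st$chromosome[i],
         peak_cM = st$position_cM[i], lod = st$lod[i], a = st$a[i],
         pve = st$pve[i],
         threshold = if (is.na(lodThreshold(sc))) NULL else lodThreshold(sc))
  })
  report <- structure(
    list(seed = seed, scan_summaries = summaries, significant = significant,
         note = note,
         interval = if (is.null(interval)) NULL else list(
           chromosome = interval@chromosome, left_cM = interval@leftCM,
           right_cM = interval@rightCM, left_bp = interval@leftBp,
           right_bp = interval@rightBp, peak_cM = interval@peakCM,
           peak_lod = interval@peakLod),
         ranking = if (is.null(network)) NULL else ranking(network),
         truth = truthBlock,
         indices = idx, scans = scans, intervalObject = interval,
         network = network, scenario = scenario),
    class = "sarnetReport")

  if (!is.null(outdir)) writeArtifacts(report, outdir)
  report
}

# Write every stage artifact of a report into a directory.
writeArtifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- report$scenario
  fp <- function(f) file.path(outdir, f)
  writeMapTSV(sc$map, fp("map.tsv"))
  writeGenoCSV(sc$geno, fp("genotypes.csv"))
  writePhenotypesTSV(sc$pheno, fp("phenotypes.tsv"))
  writeIndicesTSV(report$indices, fp("indices.tsv"))
  for (nm in names(report$scans))
    writeScanTSV(report$scans[[nm]], fp(paste0("scan_", nm, ".tsv")))
  main <- report$scans[[sc$config$scanIndex]]
  jsonlite::write_json(
    list(threshold = lodThreshold(main), alpha = main@alpha,
         n_perm = main@nPerm), fp("threshold.json"),
    auto_unbox = TRUE, digits = NA)
  writeGFF3Genes(sc$annotation, fp("annotation.gff3"))
  writeCompendiumTSV(sc$compendium, fp("compendium.tsv"))
  writeCoexprTSV(sc$coexpr, fp("coexpression.tsv"))
  writeEqtlTSV(sc$eqtl, fp("eqtl.tsv"))
  writeGOTSV(sc$go, fp("go.tsv"))
  writePolymorphismsTSV(sc$polymorphisms, fp("polymorphisms.tsv"))
  if (!is.null(report$intervalObject))
    writeIntervalBED(report$intervalObject, fp("interval.bed"))
  if (!is.null(report$network)) {
    writeSIF(report$network, fp("network.sif"))
    writeGraphML(report$network, fp("network.graphml"))
    writeRankingTSV(ranking(report$network), fp("ranking.tsv"))
  }
  truth <- sc$truth
  jsonlite::write_json(truth[!vapply(truth, is.function, logical(1))],
                       fp("truth.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  jsonlite::write_json(
    report[c("seed", "scan_summaries", "significant", "note", "interval",
             "truth")],
    fp("report.json"), auto_unbox = TRUE, digits = NA, null = "null",
    force = TRUE)
  invisible(outdir)
}

#' Load and cross-validate pipeline inputs from files
#'
#' Reads the artifacts of a previous (or external) run and enforces
#' referential integrity: every genotype marker must be on the map, eQTL
#' and GO gene ids are checked against the annotation (warning on unknown
#' ids), and malformed files fail with the offending entity named.
#'
#' @param dir directory holding \code{map.tsv}, \code{genotypes.csv},
#'   \code{phenotypes.tsv}, \code{annotation.gff3}, \code{compendium.tsv},
#'   \code{coexpression.tsv}, \code{eqtl.tsv}, \code{go.tsv},
#'   \code{polymorphisms.tsv} (as written by \code{\link{runPipeline}}).
#' @param config analysis configuration to attach.
#' @return a scenario list as from \code{\link{simulateScenario}} (without
#'   planted truth).
#' @export
loadInputs <- function(dir, config = pipelineConfig()) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", f)
    p
  }
  map <- readMapTSV(need("map.tsv"))
  geno <- readGenoCSV(need("genotypes.csv"), map)
  pheno <- readPhenotypesTSV(need("phenotypes.tsv"))
  annotation <- readGFF3Genes(need("annotation.gff3"))
  compendium <- readCompendiumTSV(need("compendium.tsv"))
  coexpr <- readCoexprTSV(need("coexpression.tsv"))
  eqtl <- readEqtlTSV(need("eqtl.tsv"))
  go <- readGOTSV(need("go.tsv"))
  poly <- readPolymorphismsTSV(need("polymorphisms.tsv"))
  ids <- S4Vectors::mcols(annotation)$gene_id
  bad <- setdiff(eqtl$expr_gene, ids)
  if (length(bad))
    warning("eQTL record(s) for unannotated gene(s): ",
            paste(head(bad, 5), collapse = ", "))
  bad <- setdiff(go$gene_id, ids)
  if (length(bad))
    warning("GO record(s) for unknown gene(s): ",
            paste(head(bad, 5), collapse = ", "))
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath)) {
    tr <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    structure(tr, class = "sarnetTruth")
  } else NULL
  list(map = map, geno = geno, pheno = pheno, annotation = annotation,
       go = go, polymorphisms = poly, eqtl = eqtl,
       compendium = compendium, coexpr = coexpr, truth = truth,
       config = config, seed = NA_integer_)
}

#' @export
print.sarnetReport <- function(x, ...) {
  cat("sarnet pipeline report (seed ", x$seed, ")\n", sep = "")
  for (s in x$scan_summaries)
    cat(sprintf("  %-30s peak chr%d @ %5.1f cM  LOD %6.2f  a %+.3f  PVE %4.1f%%%s\n",
                s$trait, s$chromosome, s$peak_cM, s$lod, s$a, 100 * s$pve,
                if (!is.null(s$threshold))
                  sprintf("  (threshold %.2f)", s$threshold) else ""))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$interval))
    cat(sprintf("  interval: chr%d %.1f-%.1f cM (%.0f-%.0f bp)\n",
                x$interval$chromosome, x$interval$left_cM,
                x$interval$right_cM, x$interval$left_bp,
                x$interval$right_bp))
  if (!is.null(x$ranking) && nrow(x$ranking)) {
    top <- x$ranking[1, ]
    cat(sprintf("  top candidate: %s (%d coherent / %d edges)\n",
                top$gene_id, top$n_coherent_edges, top$n_edges))
  }
  if (!is.null(x$truth)) {
    cat("  ground truth: regulator", x$truth$regulator)
    if (!is.null(x$truth$regulator_rank))
      cat(", rank", x$truth$regulator_rank)
    if (!is.null(x$truth$regulator_in_interval))
      cat(", in interval:", x$truth$regulator_in_interval)
    cat("\n")
  }
  invisible(x)
}
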