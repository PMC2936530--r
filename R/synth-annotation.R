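#' Describe the planted ground truth of a synthetic scenario
#'
#' The ground truth names the planted regulator locus (a genome position on
#' the map), the size of its target module, the decoy structure used for
#' specificity testing, and the planted QTL effects.  Gene identifiers are
#' assigned later by \code{\link{buildAnnotationLayers}}, which completes
#' this object.
#'
#' @param chromosome,positionCM genome position of the regulator (and of the
#'   planted shade-avoidance QTL).
#' @param nTargets number of regulated target genes (eQTL at the regulator
#'   locus, shared GO term).
#' @param effectSun,effectShade planted additive QTL effects per
#'   environment (trait units).
#' @param nDecoyCoexpressed module members with no eQTL anywhere
#'   (co-expressed-only decoys; must be removed by the eQTL filter).
#' @param nDecoyPolymorphic interval genes flagged polymorphic but outside
#'   the module (polymorphic-but-hub-less decoys).
#' @param rho within-module correlation of the expression module.
#' @param moduleGOTerm the biological-process GO-Slim term shared by the
#'   regulator and its targets.
#' @return list of class \code{sarnetTruth}.
#' @export
groundTruth <- function(chromosome = 2, positionCM = 40, nTargets = 12,
                        effectSun = 0, effectShade = -1,
                        nDecoyCoexpressed = 2, nDecoyPolymorphic = 2,
                        rho = 0.8, moduleGOTerm = "circadian rhythm") {
  structure(list(chromosome = chromosome, positionCM = positionCM,
                 nTargets = nTargets, effectSun = effectSun,
                 effectShade = effectShade,
                 nDecoyCoexpressed = nDecoyCoexpressed,
                 nDecoyPolymorphic = nDecoyPolymorphic, rho = rho,
                 moduleGOTerm = moduleGOTerm,
                 regulator = NA_character_, targets = character(),
                 decoyCoexpressed = character(),
                 decoyPolymorphic = character()),
            class = "sarnetTruth")
}

# CI under the contiguous-interval rule: the marker interval(s) containing
# the peak plus one adjacent interval on each side, truncated at chromosome
# ends, in bp via marker anchors.  A peak sitting exactly on an interior
# marker owns both abutting intervals.
contiguousIntervalCI <- function(map, chromosome, peakCM) {
  m <- markers(map)
  sub <- m[m$chromosome == chromosome, ]
  if (nrow(sub) < 2) stop("chromosome ", chromosome, " has fewer than 2 markers")
  pos <- sub$position_cM
  if (peakCM < pos[1] || peakCM > pos[length(pos)])
    stop("peak at ", peakCM, " cM is outside the anchored marker range")
  lo <- findInterval(peakCM, pos)               # interval (lo, lo+1] index
  hi <- lo
  if (peakCM == pos[lo] && lo > 1) lo <- lo - 1L  # on-marker: both intervals
  if (lo >= length(pos)) { lo <- length(pos) - 1L; hi <- lo }
  left <- max(1L, lo - 1L)
  right <- min(length(pos), hi + 2L)
  c(left_bp = sub$position_bp[left], right_bp = sub$position_bp[right])
}

#' Generate annotation, GO, polymorphism and eQTL evidence layers
#'
#' Tiles genes along the physical map: a dense window of
#' \code{nIntervalGenes} genes around the planted regulator locus (the
#' candidate-interval neighborhood) and \code{nBackgroundGenes} spread over
#' the rest of the genome.  Targets are drawn from the background genes off
#' the regulator's chromosome.  The regulator and all targets share the
#' module GO term (aspect \code{involved_in}); every target receives an
#' eQTL whose peak is the marker nearest the regulator and whose confidence
#' interval follows the contiguous-interval rule; the regulator is flagged
#' non-synonymous and (when it has targets) gets a cis-eQTL at its own
#' locus.  Decoy structure and background noise records (random GO terms,
#' scattered polymorphisms, random trans-eQTLs) are planted for specificity
#' testing.
#'
#' @param truth a \code{\link{groundTruth}} skeleton.
#' @param map a \linkS4class{GeneticMap}.
#' @param nBackgroundGenes genes tiled outside the regulator window.
#' @param nIntervalGenes genes tiled within the regulator window.
#' @param windowBp width of the dense window centered on the regulator.
#' @param geneSpanBp span of each gene (1-based inclusive coordinates).
#' @param nRandomEqtl random background trans-eQTL records.
#' @param backgroundPolymorphRate fraction of genes flagged non-synonymous
#'   at random.
#' @param nGOTerms size of the random GO-Slim term pool.
#' @param regulatorCisEqtl plant a cis-eQTL for the regulator (default: yes
#'   whenever the module has targets).
#' @param seed integer seed.
#' @return list with elements \code{annotation} (a
#'   \code{\link[GenomicRanges]{GRanges}} with \code{gene_id} metadata),
#'   \code{go} (data.frame gene_id/term/aspect), \code{polymorphisms}
#'   (data.frame gene_id/non_synonymous), \code{eqtl} (data.frame
#'   expr_gene/chromosome/peak_cM/ci_left_bp/ci_right_bp) and \code{truth}
#'   (the completed ground truth with gene ids filled in).
#' @export
buildAnnotationLayers <- function(truth, map, nBackgroundGenes = 200,
                                  nIntervalGenes = 100, windowBp = 1.6e6,
                                  geneSpanBp = 2000, nRandomEqtl = 20,
                                  backgroundPolymorphRate = 0.1,
                                  nGOTerms = 20,
                                  regulatorCisEqtl = truth$nTargets > 0,
                                  seed = 1L) {
  mk <- markers(map)
  if (!truth$chromosome %in% mk$chromosome)
    stop("regulator chromosome ", truth$chromosome, " is not on the map")
  chrRange <- range(mk$position_cM[mk$chromosome == truth$chromosome])
  if (truth$positionCM < chrRange[1] || truth$positionCM > chrRange[2])
    stop("regulator position ", truth$positionCM,
         " cM is outside the mapped range of chromosome ", truth$chromosome)
  set.seed(deriveSeed(seed, "annotation"))

  regBp <- cMToBp(map, truth$chromosome, truth$positionCM)
  chrLenBp <- vapply(split(mk$position_bp, mk$chromosome), max, numeric(1))
  chrs <- as.integer(names(chrLenBp))

  # dense window of interval genes around the regulator
  wStart <- max(1, regBp - windowBp / 2)
  starts <- round(seq(wStart, wStart + windowBp - geneSpanBp,
                      length.out = nIntervalGenes))
  interval <- data.frame(chromosome = truth$chromosome, start = starts,
                         end = starts + geneSpanBp - 1L)

  # background genes tiled over the whole genome, skipping the window
  perChr <- pmax(1L, round(nBackgroundGenes * chrLenBp / sum(chrLenBp)))
  bg <- do.call(rbind, lapply(seq_along(chrs), function(i) {
    s <- round(seq(1, chrLenBp[i] - geneSpanBp, length.out = perChr[i]))
    data.frame(chromosome = chrs[i], start = s, end = s + geneSpanBp - 1L)
  }))
  inWindow <- bg$chromosome == truth$chromosome &
    bg$end >= wStart & bg$start <= wStart + windowBp
  bg <- bg[!inWindow, ]

  genes <- rbind(interval, bg)
  genes <- genes[order(genes$chromosome, genes$start), ]
  genes$gene_id <- sprintf("g%d_%05d", genes$chromosome,
                           seq_len(nrow(genes)))
  rownames(genes) <- NULL

  # the regulator is the interval gene nearest its planted locus
  intIdx <- which(genes$chromosome == truth$chromosome &
                    genes$start >= wStart & genes$end <= wStart + windowBp + 1)
  regRow <- intIdx[which.min(abs(
    (genes$start[intIdx] + genes$end[intIdx]) / 2 - regBp))]
  regulator <- genes$gene_id[regRow]
  # the regulator IS the causal locus: recenter its span on the planted
  # position (the shift is < half the tile spacing, so gene order is kept)
  genes$start[regRow] <- max(1, round(regBp - geneSpanBp / 2))
  genes$end[regRow] <- genes$start[regRow] + geneSpanBp - 1L

  offChr <- genes$gene_id[genes$chromosome != truth$chromosome]
  if (length(offChr) < truth$nTargets + truth$nDecoyCoexpressed)
    stop("not enough background genes off the regulator chromosome")
  picks <- sample(offChr, truth$nTargets + truth$nDecoyCoexpressed)
  targets <- if (truth$nTargets) picks[seq_len(truth$nTargets)] else character()
  decoyCo <- if (truth$nDecoyCoexpressed)
    picks[truth$nTargets + seq_len(truth$nDecoyCoexpressed)] else character()
  decoyPoly <- if (truth$nDecoyPolymorphic) {
    pool <- setdiff(genes$gene_id[intIdx], regulator)
    sample(pool, min(truth$nDecoyPolymorphic, length(pool)))
  } else character()

  # GO layer: module term for regulator+targets, random terms elsewhere,
  # plus off-aspect rows that the coherence stage must ignore
  pool <- sprintf("process_%02d", seq_len(nGOTerms))
  goRows <- list()
  for (g in genes$gene_id) {
    terms <- sample(pool, sample(1:3, 1))
    goRows[[g]] <- data.frame(gene_id = g, term = terms,
                              aspect = "involved_in")
  }
  go <- do.call(rbind, goRows)
  if (!is.na(regulator) && length(targets))
    go <- rbind(go, data.frame(gene_id = c(regulator, targets),
                               term = truth$moduleGOTerm,
                               aspect = "involved_in"))
  compartments <- data.frame(gene_id = sample(genes$gene_id, 30, replace = TRUE),
                             term = "nucleus", aspect = "located_in")
  go <- rbind(go, compartments)
  go <- unique(go)
  rownames(go) <- NULL

  # polymorphism layer
  polyGenes <- unique(c(regulator, decoyPoly,
                        sample(genes$gene_id,
                               round(backgroundPolymorphRate * nrow(genes)))))
  polymorphisms <- data.frame(gene_id = polyGenes, non_synonymous = TRUE,
                              stringsAsFactors = FALSE)

  # eQTL layer: targets map to the marker nearest the regulator
  peakIdx <- nearestMarker(map, truth$chromosome, truth$positionCM)
  peakCM <- mk$position_cM[peakIdx]
  ci <- contiguousIntervalCI(map, truth$chromosome, peakCM)
  eqtl <- data.frame(expr_gene = character(), chromosome = integer(),
                     peak_cM = numeric(), ci_left_bp = numeric(),
                     ci_right_bp = numeric(), stringsAsFactors = FALSE)
  for (t in targets)
    eqtl <- rbind(eqtl, data.frame(expr_gene = t,
                                   chromosome = truth$chromosome,
                                   peak_cM = peakCM, ci_left_bp = ci[1],
                                   ci_right_bp = ci[2]))
  if (regulatorCisEqtl && !is.na(regulator))
    eqtl <- rbind(eqtl, data.frame(expr_gene = regulator,
                                   chromosome = truth$chromosome,
                                   peak_cM = peakCM, ci_left_bp = ci[1],
                                   ci_right_bp = ci[2]))
  if (nRandomEqtl > 0) {
    exclude <- c(targets, decoyCo, regulator)
    rg <- sample(setdiff(genes$gene_id, exclude), nRandomEqtl)
    for (g in rg) {
      chr <- sample(chrs, 1)
      sub <- mk[mk$chromosome == chr, ]
      pk <- sub$position_cM[sample(nrow(sub), 1)]
      rci <- contiguousIntervalCI(map, chr, pk)
      eqtl <- rbind(eqtl, data.frame(expr_gene = g, chromosome = chr,
                                     peak_cM = pk, ci_left_bp = rci[1],
                                     ci_right_bp = rci[2]))
    }
  }
  rownames(eqtl) <- NULL

  annotation <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chromosome),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = "+")
  S4Vectors::mcols(annotation)$gene_id <- genes$gene_id
  S4Vectors::mcols(annotation)$type <- "gene"

  truth$regulator <- regulator
  truth$targets <- targets
  truth$decoyCoexpressed <- decoyCo
  truth$decoyPolymorphic <- decoyPoly
  list(annotation = annotation, go = go, polymorphisms = polymorphisms,
       eqtl = eqtl, truth = truth)
}
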