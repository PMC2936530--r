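#' Build a synthetic genetic map
#'
#' Markers are placed on each chromosome either on an even grid or uniformly
#' at random, always anchored at 0 and at the chromosome length so every
#' chromosome spans the full [0, length] interval.  Physical positions are
#' derived from the genetic positions with a constant expansion factor,
#' bp = round(cM * bpPerCM).
#'
#' @param nChromosomes number of chromosomes.
#' @param markersPerChromosome markers per chromosome (>= 2).
#' @param chromLengthCM chromosome length in cM (> 0); recycled across
#'   chromosomes.
#' @param bpPerCM physical bp per genetic cM (> 0).
#' @param spacing \code{"even"} (default) or \code{"uniform"} random interior
#'   marker placement.
#' @param seed integer seed (used only for \code{spacing = "uniform"}).
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' makeMap(5, 116, 100)
#' @export
makeMap <- function(nChromosomes, markersPerChromosome, chromLengthCM,
                    bpPerCM = 2.5e5, spacing = c("even", "uniform"),
                    seed = 1L) {
  spacing <- match.arg(spacing)
  if (nChromosomes < 1 || markersPerChromosome < 2)
    stop("need at least one chromosome and two markers per chromosome")
  if (any(chromLengthCM <= 0) || bpPerCM <= 0)
    stop("chromosome length and bpPerCM must be positive")
  lens <- rep_len(chromLengthCM, nChromosomes)
  set.seed(deriveSeed(seed, "map"))
  rows <- lapply(seq_len(nChromosomes), function(chr) {
    L <- lens[chr]
    m <- markersPerChromosome
    pos <- if (spacing == "even") {
      seq(0, L, length.out = m)
    } else {
      sort(c(0, runif(m - 2L, 0, L), L))
    }
    if (is.unsorted(pos, strictly = TRUE))
      stop("random marker placement produced tied positions; re-seed")
    data.frame(marker_id = sprintf("c%d_m%03d", chr, seq_len(m)),
               chromosome = chr,
               position_cM = pos,
               position_bp = round(pos * bpPerCM),
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, rows)
  rownames(mk) <- NULL
  new("GeneticMap", markers = mk)
}

#' Construct a GeneticMap from a marker table
#'
#' @param markers data.frame with columns \code{marker_id},
#'   \code{chromosome}, \code{position_cM}, \code{position_bp}.
#' @return a validated \linkS4class{GeneticMap}.
#' @export
geneticMap <- function(markers) {
  markers <- markers[order(markers$chromosome, markers$position_cM), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  new("GeneticMap", markers = markers)
}

#' Simulate selfed-RIL genotypes along a map
#'
#' Each line is an independent mosaic of homozygous parental blocks.  The
#' first marker of every chromosome is a fair coin between the B and S
#' parents; between adjacent markers at distance d cM the line switches
#' parent with the selfed-RIL transition probability
#' R = 2r/(1+2r), r = (1 - exp(-2d/100))/2 (Haldane, no interference).
#' Chromosomes are independent.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param nLines number of lines (>= 2).
#' @param seed integer seed.
#' @param missingRate fraction of genotype calls replaced by NA (default 0).
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- simulateRILGenotypes(makeMap(2, 10, 100), nLines = 50, seed = 7)
#' @export
simulateRILGenotypes <- function(map, nLines, seed = 1L, missingRate = 0) {
  if (nLines < 2) stop("need at least 2 lines")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  mk <- markers(map)
  set.seed(deriveSeed(seed, "genotypes"))
  out <- matrix(NA_character_, nLines, nrow(mk),
                dimnames = list(sprintf("RIL%03d", seq_len(nLines)),
                                mk$marker_id))
  for (chr in unique(mk$chromosome)) {
    idx <- which(mk$chromosome == chr)
    Rtrans <- rilTransition(diff(mk$position_cM[idx]))
    state <- runif(nLines) < 0.5                 # TRUE = B at first marker
    out[, idx[1]] <- ifelse(state, "B", "S")
    for (j in seq_along(Rtrans)) {
      state <- xor(state, runif(nLines) < Rtrans[j])
      out[, idx[j + 1L]] <- ifelse(state, "B", "S")
    }
  }
  if (missingRate > 0) {
    drop <- runif(length(out)) < missingRate
    out[drop] <- NA_character_
  }
  new("GenotypeMatrix", alleles = out, map = map)
}
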