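#' @import methods
#' @importFrom stats anova approx ave coef cor lm quantile resid rnorm runif
#'   sd shapiro.test var setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Genetic map of markers
#'
#' Holds marker positions in both genetic (centiMorgan) and physical
#' (base-pair) coordinates.  Positions must be strictly increasing within
#' each chromosome and marker identifiers unique; the base-pair column
#' anchors the genetic map to gene annotation coordinates.
#'
#' @slot markers data.frame with columns \code{marker_id}, \code{chromosome}
#'   (integer), \code{position_cM} (numeric, >= 0) and \code{position_bp}
#'   (integer, >= 0), ordered by chromosome then position.
#' @exportClass GeneticMap
setClass("GeneticMap", representation(markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  m <- object@markers
  need <- c("marker_id", "chromosome", "position_cM", "position_bp")
  if (!all(need %in% names(m)))
    return(paste("markers must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$marker_id)) return("marker ids must be unique")
  for (chr in unique(m$chromosome)) {
    sub <- m[m$chromosome == chr, ]
    if (is.unsorted(sub$position_cM, strictly = TRUE))
      return(sprintf("cM positions not strictly increasing on chromosome %s", chr))
    if (is.unsorted(sub$position_bp, strictly = TRUE))
      return(sprintf("bp positions not strictly increasing on chromosome %s", chr))
  }
  if (any(m$position_cM < 0) || any(m$position_bp < 0))
    return("positions must be non-negative")
  TRUE
})

#' RIL genotype matrix
#'
#' Homozygous biallelic genotypes of recombinant inbred lines, coded
#' \code{"B"} (Bay-like parent) / \code{"S"} (Sha-like parent) with \code{NA}
#' for missing calls.  Columns follow the marker order of the attached map.
#'
#' @slot alleles character matrix, lines x markers, entries in
#'   \code{c("B","S",NA)}; rownames are line ids, colnames marker ids.
#' @slot map the \linkS4class{GeneticMap} the columns refer to.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         representation(alleles = "matrix", map = "GeneticMap"))

setValidity("GenotypeMatrix", function(object) {
  a <- object@alleles
  if (!is.character(a)) return("alleles must be a character matrix")
  bad <- !(a %in% c("B", "S") | is.na(a))
  if (any(bad)) return("allele codes must be 'B', 'S' or NA (RILs are homozygous)")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("alleles must carry line ids (rownames) and marker ids (colnames)")
  if (!identical(colnames(a), markerIds(object@map)))
    return("allele columns must match the map's markers in order")
  TRUE
})

#' Conditional genotype probabilities on an evaluation grid
#'
#' For each line and each evaluation position (typed markers plus
#' pseudomarkers on a regular cM step), the probability that the line
#' carries the B parental genotype, conditional on the flanking typed
#' markers under the selfed-RIL Haldane transition model.
#'
#' @slot prob numeric matrix, lines x positions, values in [0, 1].
#' @slot positions data.frame with columns \code{chromosome},
#'   \code{position_cM} and \code{at_marker} (marker id or NA).
#' @slot map the underlying \linkS4class{GeneticMap}.
#' @exportClass GenotypeProbabilities
setClass("GenotypeProbabilities",
         representation(prob = "matrix", positions = "data.frame",
                        map = "GeneticMap"))

setValidity("GenotypeProbabilities", function(object) {
  p <- object@prob
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    return("probabilities must lie in [0, 1]")
  if (ncol(p) != nrow(object@positions))
    return("prob columns must match positions rows")
  TRUE
})

#' Genome scan result
#'
#' LOD, additive-effect and variance-explained profiles from single-QTL
#' Haley-Knott interval mapping, optionally with a permutation-based
#' genome-wide significance threshold attached.
#'
#' @slot scan data.frame with columns \code{chromosome}, \code{position_cM},
#'   \code{lod}, \code{a} (additive effect, (mean_B - mean_S)/2, trait
#'   units), \code{pve} (fraction of variance explained).
#' @slot n integer, number of lines used.
#' @slot trait character, name of the scanned index.
#' @slot threshold numeric, genome-wide LOD cutoff (NA until
#'   \code{\link{permutationThreshold}} is run).
#' @slot nPerm integer, permutations behind the threshold.
#' @slot alpha numeric, genome-wide significance level of the threshold.
#' @exportClass QTLScan
setClass("QTLScan",
         representation(scan = "data.frame", n = "integer", trait = "character",
                        threshold = "numeric", nPerm = "integer",
                        alpha = "numeric"),
         prototype(threshold = NA_real_, nPerm = 0L, alpha = NA_real_))

setValidity("QTLScan", function(object) {
  s <- object@scan
  need <- c("chromosome", "position_cM", "lod", "a", "pve")
  if (!all(need %in% names(s)))
    return(paste("scan must have columns", paste(need, collapse = ", ")))
  if (any(s$lod < -1e-9)) return("LOD scores must be non-negative")
  TRUE
})

#' QTL support interval
#'
#' A drop-based (by default 2-LOD) support interval around a scan peak, in
#' both genetic and physical coordinates.
#'
#' @slot chromosome integer chromosome of the peak.
#' @slot leftCM,rightCM interval bounds in cM.
#' @slot leftBp,rightBp interval bounds in bp (linear interpolation between
#'   marker anchors).
#' @slot peakCM,peakLod peak position and LOD.
#' @slot drop the LOD drop defining the interval.
#' @slot belowThreshold TRUE when the peak did not reach the scan's
#'   significance threshold (interval still reported).
#' @exportClass SupportInterval
setClass("SupportInterval",
         representation(chromosome = "integer", leftCM = "numeric",
                        rightCM = "numeric", leftBp = "numeric",
                        rightBp = "numeric", peakCM = "numeric",
                        peakLod = "numeric", drop = "numeric",
                        belowThreshold = "logical"))

setValidity("SupportInterval", function(object) {
  if (object@leftCM > object@peakCM || object@peakCM > object@rightCM)
    return("interval must contain the peak")
  TRUE
})

#' Candidate-gene evidence network
#'
#' Directed graph from candidate genes in a QTL interval to the co-expressed
#' genes whose eQTL colocalizes with the candidate, with GO-coherence edge
#' flags, polymorphism / cis-eQTL node flags (cis-eQTLs appear as
#' self-loops) and a hub ranking of the candidates.
#'
#' @slot graph an \code{igraph} directed graph (only nodes with degree >= 1).
#' @slot nodes data.frame: \code{gene_id}, \code{is_candidate},
#'   \code{polymorphic}, \code{non_synonymous}, \code{cis_eqtl}.
#' @slot edges data.frame: \code{from}, \code{to}, \code{mutual_rank},
#'   \code{coherent}, \code{type} (\code{coexp_eqtl}, \code{coexp_eqtl_go}
#'   or \code{cis}).
#' @slot ranking data.frame: \code{gene_id}, \code{n_coherent_edges},
#'   \code{n_edges}, \code{polymorphic}, \code{rank}, sorted by coherent
#'   connections.
#' @exportClass CandidateNetwork
setClass("CandidateNetwork",
         representation(graph = "ANY", nodes = "data.frame",
                        edges = "data.frame", ranking = "data.frame"))

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat(sprintf("GeneticMap: %d markers on %d chromosome(s)\n",
              nrow(m), length(unique(m$chromosome))))
  spans <- vapply(split(m$position_cM, m$chromosome), max, numeric(1))
  cat("  chromosome spans (cM):", paste(round(spans, 1), collapse = ", "), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d lines x %d markers (%.2f%% missing)\n",
              nrow(object@alleles), ncol(object@alleles),
              100 * mean(is.na(object@alleles))))
})

setMethod("show", "GenotypeProbabilities", function(object) {
  cat(sprintf("GenotypeProbabilities: %d lines x %d evaluation positions (%d typed markers)\n",
              nrow(object@prob), ncol(object@prob),
              sum(!is.na(object@positions$at_marker))))
})

setMethod("show", "QTLScan", function(object) {
  s <- object@scan
  i <- which.max(s$lod)
  cat(sprintf("QTLScan of '%s' (%d lines, %d positions)\n",
              object@trait, object@n, nrow(s)))
  cat(sprintf("  peak: chr %s @ %.1f cM, LOD %.2f, a = %.3f, PVE %.1f%%\n",
              s$chromosome[i], s$position_cM[i], s$lod[i], s$a[i],
              100 * s$pve[i]))
  if (!is.na(object@threshold))
    cat(sprintf("  genome-wide threshold (alpha %.2f, %d perms): %.2f\n",
                object@alpha, object@nPerm, object@threshold))
})

setMethod("show", "SupportInterval", function(object) {
  cat(sprintf("%g-LOD support interval: chr %d, %.1f-%.1f cM (%.0f-%.0f bp), peak %.1f cM (LOD %.2f)%s\n",
              object@drop, object@chromosome, object@leftCM, object@rightCM,
              object@leftBp, object@rightBp, object@peakCM, object@peakLod,
              if (object@belowThreshold) " [peak below threshold]" else ""))
})

setMethod("show", "CandidateNetwork", function(object) {
  cat(sprintf("CandidateNetwork: %d nodes, %d edges (%d coherent)\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$coherent)))
  if (nrow(object@ranking)) {
    top <- object@ranking[1, ]
    cat(sprintf("  top candidate: %s (%d coherent / %d edges)\n",
                top$gene_id, top$n_coherent_edges, top$n_edges))
  }
})

# ---- accessors ------------------------------------------------------------

#' Accessors for sarnet classes
#'
#' Small accessor family: \code{markers} returns the marker table of a
#' \linkS4class{GeneticMap}; \code{markerIds} its ids; \code{alleles} the
#' allele matrix of a \linkS4class{GenotypeMatrix}; \code{scanTable} the
#' position-wise profile of a \linkS4class{QTLScan}; \code{lodThreshold} its
#' permutation threshold; \code{ranking} the hub ranking of a
#' \linkS4class{CandidateNetwork} and \code{networkGraph} its igraph object.
#'
#' @param x an object of the respective class.
#' @return The underlying data.frame, matrix, numeric or igraph object.
#' @name accessors
#' @aliases markers markerIds alleles scanTable lodThreshold ranking networkGraph
NULL

#' @rdname accessors
#' @export
markers <- function(x) x@markers

#' @rdname accessors
#' @export
markerIds <- function(x) x@markers$marker_id

#' @rdname accessors
#' @export
alleles <- function(x) x@alleles

#' @rdname accessors
#' @export
scanTable <- function(x) x@scan

#' @rdname accessors
#' @export
lodThreshold <- function(x) x@threshold

#' @rdname accessors
#' @export
ranking <- function(x) x@ranking

#' @rdname accessors
#' @export
networkGraph <- function(x) x@graph
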