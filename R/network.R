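#' Candidate genes in a QTL support interval
#'
#' Returns the genes of the annotation whose span overlaps the interval
#' (any-overlap rule by default; require full containment with
#' \code{rule = "within"}), ordered by start position.
#'
#' @param annotation a \code{GRanges} of genes with a \code{gene_id}
#'   metadata column (as from \code{\link{buildAnnotationLayers}} or
#'   \code{\link{readGFF3Genes}}).
#' @param chromosome interval chromosome.
#' @param leftBp,rightBp interval bounds in bp (1-based inclusive).
#' @param rule \code{"overlap"} (default) or \code{"within"}.
#' @return character vector of candidate gene ids.
#' @export
candidatesInInterval <- function(annotation, chromosome, leftBp, rightBp,
                                 rule = c("overlap", "within")) {
  rule <- match.arg(rule)
  if (rightBp < leftBp) stop("empty interval: right bound before left bound")
  q <- GenomicRanges::GRanges(as.character(chromosome),
                              IRanges::IRanges(leftBp, rightBp))
  hits <- GenomicRanges::findOverlaps(
    annotation, q, type = if (rule == "within") "within" else "any")
  sel <- annotation[S4Vectors::queryHits(hits)]
  sel <- sel[order(GenomicRanges::start(sel))]
  S4Vectors::mcols(sel)$gene_id
}

#' Co-expression neighbors of a candidate gene
#'
#' Neighbors are the genes whose mutual rank with the candidate is strictly
#' below \code{mrThreshold}.  A band variant that additionally requires
#' MR above (max rank for the gene - 50) — which, read literally, admits a
#' gene's weakest partners — is available as an off-by-default secondary
#' filter \code{maxRankBand}.
#'
#' @param candidate gene id.
#' @param coexpr mutual-rank data.frame from
#'   \code{\link{computeMutualRanks}}.
#' @param mrThreshold strict upper bound on the mutual rank (default 50).
#' @param maxRankBand if \code{TRUE}, additionally require
#'   MR > max(MR for the candidate) - mrThreshold.
#' @return named numeric vector of mutual ranks (names = neighbor ids);
#'   empty (with a warning) when the candidate is absent from the
#'   co-expression table, as happens for genes missing from the expression
#'   platform.
#' @export
coexpressionNeighbors <- function(candidate, coexpr, mrThreshold = 50,
                                  maxRankBand = FALSE) {
  rows <- coexpr$gene_a == candidate | coexpr$gene_b == candidate
  if (!any(rows)) {
    warning("candidate ", candidate,
            " is absent from the co-expression table")
    return(setNames(numeric(0), character(0)))
  }
  sub <- coexpr[rows, ]
  partner <- ifelse(sub$gene_a == candidate, sub$gene_b, sub$gene_a)
  mr <- setNames(sub$mutual_rank, partner)
  keep <- mr < mrThreshold
  if (maxRankBand) keep <- keep & mr > max(mr) - mrThreshold
  mr[keep]
}

#' eQTL colocalization filter
#'
#' Keeps a candidate's co-expression neighbor only when some eQTL record
#' for that neighbor has a confidence interval overlapping the candidate
#' gene's own span — evidence that the neighbor's expression is controlled
#' from the candidate's locus.  Retained neighbors become directed edges
#' candidate -> neighbor.
#'
#' @param candidate candidate gene id (must be annotated).
#' @param neighbors named numeric vector from
#'   \code{\link{coexpressionNeighbors}}.
#' @param eqtl eQTL data.frame (\code{expr_gene}, \code{chromosome},
#'   \code{peak_cM}, \code{ci_left_bp}, \code{ci_right_bp}).
#' @param annotation gene \code{GRanges} with \code{gene_id}.
#' @return data.frame of directed edges: \code{from}, \code{to},
#'   \code{mutual_rank}.
#' @export
eqtlColocalizationFilter <- function(candidate, neighbors, eqtl,
                                     annotation) {
  ids <- S4Vectors::mcols(annotation)$gene_id
  ci <- match(candidate, ids)
  if (is.na(ci)) stop("candidate ", candidate, " has no annotation")
  cChr <- as.character(GenomicRanges::seqnames(annotation)[ci])
  cStart <- GenomicRanges::start(annotation)[ci]
  cEnd <- GenomicRanges::end(annotation)[ci]
  keep <- logical(length(neighbors))
  known <- names(neighbors) %in% c(ids, eqtl$expr_gene)
  if (any(!known))
    warning("neighbor(s) without annotation or eQTL dropped: ",
            paste(names(neighbors)[!known], collapse = ", "))
  for (i in seq_along(neighbors)) {
    rec <- eqtl[eqtl$expr_gene == names(neighbors)[i], , drop = FALSE]
    keep[i] <- any(as.character(rec$chromosome) == cChr &
                     rec$ci_left_bp <= cEnd & rec$ci_right_bp >= cStart)
  }
  data.frame(from = rep(candidate, sum(keep)),
             to = names(neighbors)[keep],
             mutual_rank = unname(neighbors[keep]),
             stringsAsFactors = FALSE)
}

#' eQTL confidence interval from an expression scan
#'
#' Applies the contiguous-interval rule to a genome scan of an expression
#' trait: the confidence interval is the marker interval containing the
#' peak plus the adjacent marker interval on each side (a peak sitting on
#' an interior marker owns both abutting intervals), truncated at
#' chromosome ends and converted to bp through the marker anchors.
#'
#' @param scan a \linkS4class{QTLScan} of an expression trait.
#' @param map the \linkS4class{GeneticMap}.
#' @param exprGene the expression trait's gene id recorded in the result.
#' @return one-row eQTL data.frame (\code{expr_gene}, \code{chromosome},
#'   \code{peak_cM}, \code{ci_left_bp}, \code{ci_right_bp}).
#' @export
eqtlCIFromScan <- function(scan, map, exprGene = scan@trait) {
  s <- scanTable(scan)
  peak <- which.max(s$lod)
  chr <- s$chromosome[peak]
  ci <- contiguousIntervalCI(map, chr, s$position_cM[peak])
  data.frame(expr_gene = exprGene, chromosome = chr,
             peak_cM = s$position_cM[peak], ci_left_bp = unname(ci[1]),
             ci_right_bp = unname(ci[2]), stringsAsFactors = FALSE)
}

#' Flag functionally coherent edges by shared GO-Slim terms
#'
#' An edge is coherent when its source and target share at least one GO
#' term of the biological-process aspect (\code{involved_in}); other
#' aspects are discarded before matching.  Genes without GO annotation are
#' never coherent — the method's documented blind spot for uncharacterized
#' genes.
#'
#' @param edges data.frame with \code{from} and \code{to} columns.
#' @param go GO data.frame (\code{gene_id}, \code{term}, \code{aspect}).
#' @return \code{edges} with a logical \code{coherent} column appended.
#' @export
goCoherentEdges <- function(edges, go) {
  bp <- go[go$aspect == "involved_in", ]
  sets <- split(bp$term, bp$gene_id)
  edges$coherent <- vapply(seq_len(nrow(edges)), function(i) {
    a <- sets[[edges$from[i]]]
    b <- sets[[edges$to[i]]]
    !is.null(a) && !is.null(b) && length(intersect(a, b)) > 0
  }, logical(1))
  edges
}

#' Polymorphism and cis-eQTL flags for candidate genes
#'
#' A candidate is polymorphic when it carries a non-synonymous polymorphism
#' between the parents or has a cis-eQTL — an eQTL record for its own
#' expression whose confidence interval overlaps its own coordinates.  The
#' two contributing flags are kept separate so either rendering can be
#' reproduced; cis-eQTLs additionally emit self-loop edges.
#'
#' @param candidates character vector of candidate gene ids.
#' @param polymorphisms data.frame (\code{gene_id}, \code{non_synonymous}).
#' @param eqtl eQTL data.frame.
#' @param annotation gene \code{GRanges} with \code{gene_id}.
#' @return data.frame: \code{gene_id}, \code{non_synonymous},
#'   \code{cis_eqtl}, \code{polymorphic}.
#' @export
polymorphismFlags <- function(candidates, polymorphisms, eqtl, annotation) {
  ids <- S4Vectors::mcols(annotation)$gene_id
  nonsyn <- candidates %in%
    polymorphisms$gene_id[polymorphisms$non_synonymous]
  cis <- vapply(candidates, function(g) {
    gi <- match(g, ids)
    if (is.na(gi)) return(FALSE)
    rec <- eqtl[eqtl$expr_gene == g, , drop = FALSE]
    any(as.character(rec$chromosome) ==
          as.character(GenomicRanges::seqnames(annotation)[gi]) &
          rec$ci_left_bp <= GenomicRanges::end(annotation)[gi] &
          rec$ci_right_bp >= GenomicRanges::start(annotation)[gi])
  }, logical(1))
  data.frame(gene_id = candidates, non_synonymous = nonsyn,
             cis_eqtl = unname(cis), polymorphic = nonsyn | unname(cis),
             stringsAsFactors = FALSE)
}

#' Assemble the candidate network and hub ranking
#'
#' Builds the directed evidence graph (dropping degree-0 nodes, adding
#' self-loops for cis-eQTL candidates) and ranks candidates by their number
#' of coherent connections, with ties broken by total edges, then the
#' polymorphism flag, then gene id.  The full ranking table, including
#' edge-less candidates, is reported.
#'
#' @param candidates character vector of candidate gene ids.
#' @param edges data.frame from \code{\link{goCoherentEdges}} (columns
#'   \code{from}, \code{to}, \code{mutual_rank}, \code{coherent}).
#' @param flags data.frame from \code{\link{polymorphismFlags}}.
#' @return a \linkS4class{CandidateNetwork}.
#' @export
assembleAndRank <- function(candidates, edges, flags) {
  if (nrow(edges) == 0 && !any(flags$cis_eqtl))
    warning("empty network: no candidate retained any edge")
  edges$type <- ifelse(edges$coherent, "coexp_eqtl_go", "coexp_eqtl")
  cis <- flags$gene_id[flags$cis_eqtl]
  if (length(cis))
    edges <- rbind(edges,
                   data.frame(from = cis, to = cis, mutual_rank = NA_real_,
                              coherent = FALSE, type = "cis",
                              stringsAsFactors = FALSE))
  realEdges <- edges[edges$type != "cis", , drop = FALSE]
  nCo <- table(factor(realEdges$from[realEdges$coherent],
                      levels = candidates))
  nEd <- table(factor(realEdges$from, levels = candidates))
  rk <- data.frame(gene_id = candidates,
                   n_coherent_edges = as.integer(nCo),
                   n_edges = as.integer(nEd),
                   polymorphic = flags$polymorphic[
                     match(candidates, flags$gene_id)],
                   stringsAsFactors = FALSE)
  ord <- order(-rk$n_coherent_edges, -rk$n_edges, -rk$polymorphic,
               rk$gene_id)
  rk <- rk[ord, ]
  rk$rank <- seq_len(nrow(rk))
  rownames(rk) <- NULL

  used <- unique(c(edges$from, edges$to))
  nodes <- data.frame(gene_id = used,
                      is_candidate = used %in% candidates,
                      stringsAsFactors = FALSE)
  fi <- match(nodes$gene_id, flags$gene_id)
  nodes$non_synonymous <- ifelse(is.na(fi), FALSE, flags$non_synonymous[fi])
  nodes$cis_eqtl <- ifelse(is.na(fi), FALSE, flags$cis_eqtl[fi])
  nodes$polymorphic <- ifelse(is.na(fi), FALSE, flags$polymorphic[fi])
  g <- if (nrow(nodes))
    igraph::graph_from_data_frame(edges, directed = TRUE,
                                  vertices = nodes)
  else igraph::make_empty_graph(directed = TRUE)
  new("CandidateNetwork", graph = g, nodes = nodes, edges = edges,
      ranking = rk)
}

#' Run the whole network-prioritization stage
#'
#' For every candidate gene in the interval: co-expression neighborhood
#' (mutual rank strictly below the threshold), eQTL colocalization filter,
#' GO coherence coloring, polymorphism/cis-eQTL flags, then assembly and
#' hub ranking.
#'
#' @param annotation gene \code{GRanges}.
#' @param chromosome,leftBp,rightBp the candidate interval (e.g. from a
#'   \linkS4class{SupportInterval}).
#' @param coexpr mutual-rank table.
#' @param eqtl eQTL table.
#' @param go GO table.
#' @param polymorphisms polymorphism table.
#' @param mrThreshold mutual-rank cutoff (default 50).
#' @param rule candidate interval membership rule.
#' @return a \linkS4class{CandidateNetwork}.
#' @export
buildCandidateNetwork <- function(annotation, chromosome, leftBp, rightBp,
                                  coexpr, eqtl, go, polymorphisms,
                                  mrThreshold = 50,
                                  rule = c("overlap", "within")) {
  candidates <- candidatesInInterval(annotation, chromosome, leftBp,
                                     rightBp, rule = match.arg(rule))
  edgeList <- list()
  for (cand in candidates) {
    nb <- suppressWarnings(
      coexpressionNeighbors(cand, coexpr, mrThreshold))
    if (!length(nb)) next
    kept <- eqtlColocalizationFilter(cand, nb, eqtl, annotation)
    if (nrow(kept)) edgeList[[cand]] <- kept
  }
  edges <- if (length(edgeList)) do.call(rbind, edgeList)
  else data.frame(from = character(), to = character(),
                  mutual_rank = numeric(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges <- goCoherentEdges(edges, go)
  flags <- polymorphismFlags(candidates, polymorphisms, eqtl, annotation)
  assembleAndRank(candidates, edges, flags)
}
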