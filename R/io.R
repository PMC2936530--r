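# File dialects.  Tabular artifacts are plain TSV; the map+genotype file
# uses the rotated-CSV interchange dialect common to QTL software (row 1
# marker ids, row 2 chromosome, row 3 cM position, then one row per line);
# gene annotation travels as GFF3 and intervals as BED through rtracklayer;
# networks as SIF and GraphML.

#' Write / read the map+genotype CSV dialect
#'
#' Row 1 holds an \code{id} column followed by marker ids, row 2 the
#' chromosome of each marker, row 3 its cM position; every further row is
#' one line's genotypes (B/S, empty for missing).  The bp anchors of the
#' map are not part of this dialect; pass the map (e.g. read back from
#' \code{\link{writeMapTSV}}) to \code{readGenoCSV} to restore them.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param path file path.
#' @export
writeGenoCSV <- function(geno, path) {
  mk <- markers(geno@map)
  a <- alleles(geno)
  a[is.na(a)] <- ""
  lines <- c(paste(c("id", mk$marker_id), collapse = ","),
             paste(c("", mk$chromosome), collapse = ","),
             paste(c("", mk$position_cM), collapse = ","),
             vapply(seq_len(nrow(a)),
                    function(i) paste(c(rownames(a)[i], a[i, ]),
                                      collapse = ","),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGenoCSV
#' @param map a \linkS4class{GeneticMap} supplying the bp anchors; its
#'   markers must match the file's.
#' @return \code{readGenoCSV} returns a \linkS4class{GenotypeMatrix}.
#' @export
readGenoCSV <- function(path, map) {
  raw <- strsplit(readLines(path), ",", fixed = TRUE)
  ids <- raw[[1]][-1]
  unknown <- setdiff(ids, markerIds(map))
  if (length(unknown))
    stop("genotype file ", basename(path), " has marker(s) not on the map: ",
         paste(head(unknown, 5), collapse = ", "))
  if (!identical(ids, markerIds(map)))
    stop("genotype file marker order does not match the map")
  body <- raw[-(1:3)]
  a <- t(vapply(body, function(r) {
    g <- r[-1]
    g[g == ""] <- NA_character_
    length(g) <- length(ids)
    g
  }, character(length(ids))))
  rownames(a) <- vapply(body, `[`, character(1), 1)
  colnames(a) <- ids
  new("GenotypeMatrix", alleles = a, map = map)
}

#' Tabular artifact writers and readers
#'
#' Thin TSV round-trips for the pipeline's tabular artifacts: the marker
#' map, long phenotypes, trait indices, the gene x experiment compendium,
#' the mutual-rank table, the eQTL / GO / polymorphism evidence layers and
#' the scan profile.
#'
#' @param x the object to write (data.frame or matrix as documented per
#'   artifact).
#' @param path file path.
#' @name tabular-io
NULL

writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTSV <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname tabular-io
#' @export
writeMapTSV <- function(x, path) writeTSV(markers(x), path)

#' @rdname tabular-io
#' @export
readMapTSV <- function(path) geneticMap(readTSV(path))

#' @rdname tabular-io
#' @export
writePhenotypesTSV <- function(x, path) writeTSV(x, path)

#' @rdname tabular-io
#' @export
readPhenotypesTSV <- function(path) readTSV(path)

#' @rdname tabular-io
#' @export
writeIndicesTSV <- function(x, path) writeTSV(x, path)

#' @rdname tabular-io
#' @export
readIndicesTSV <- function(path) readTSV(path)

#' @rdname tabular-io
#' @export
writeCompendiumTSV <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  writeTSV(df, path)
}

#' @rdname tabular-io
#' @export
readCompendiumTSV <- function(path) {
  df <- readTSV(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname tabular-io
#' @export
writeCoexprTSV <- function(x, path) writeTSV(x, path)

#' @rdname tabular-io
#' @export
readCoexprTSV <- function(path) readTSV(path)

#' @rdname tabular-io
#' @export
writeEqtlTSV <- function(x, path) writeTSV(x, path)

#' @rdname tabular-io
#' @export
readEqtlTSV <- function(path) readTSV(path)

#' @rdname tabular-io
#' @export
writeGOTSV <- function(x, path) writeTSV(x, path)

#' @rdname tabular-io
#' @export
readGOTSV <- function(path) readTSV(path)

#' @rdname tabular-io
#' @export
writePolymorphismsTSV <- function(x, path) writeTSV(x, path)

#' @rdname tabular-io
#' @export
readPolymorphismsTSV <- function(path) readTSV(path)

#' @rdname tabular-io
#' @param scan a \linkS4class{QTLScan}.
#' @export
writeScanTSV <- function(scan, path) writeTSV(scanTable(scan), path)

#' Write gene annotation as GFF3 / read it back
#'
#' Genes only, 1-based inclusive coordinates, \code{gene_id} carried as the
#' feature ID.
#'
#' @param annotation a gene \code{GRanges} with a \code{gene_id} column.
#' @param path file path.
#' @export
writeGFF3Genes <- function(annotation, path) {
  gr <- annotation
  S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGFF3Genes
#' @export
readGFF3Genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(S4Vectors::mcols(gr)$gene_id))
    S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$ID
  gr[, c("gene_id", "type")]
}

#' Write a support interval as BED
#'
#' BED is 0-based half-open; the 1-based inclusive bp bounds of the
#' interval are converted on export (start - 1, end unchanged) by
#' rtracklayer.
#'
#' @param interval a \linkS4class{SupportInterval}.
#' @param path file path.
#' @param name feature name.
#' @export
writeIntervalBED <- function(interval, path, name = "support_interval") {
  gr <- GenomicRanges::GRanges(
    as.character(interval@chromosome),
    IRanges::IRanges(max(1, interval@leftBp), interval@rightBp))
  S4Vectors::mcols(gr)$name <- name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Export the candidate network
#'
#' \code{writeSIF} writes the Cytoscape simple-interaction format
#' (source, interaction type, target; types \code{coexp_eqtl},
#' \code{coexp_eqtl_go}, \code{cis}); \code{writeGraphML} writes GraphML
#' with node attributes (is_candidate, polymorphic, cis_eqtl) and edge
#' attributes (mutual_rank, coherent).
#'
#' @param network a \linkS4class{CandidateNetwork}.
#' @param path file path.
#' @export
writeSIF <- function(network, path) {
  e <- network@edges
  writeLines(if (nrow(e)) paste(e$from, e$type, e$to, sep = "\t")
             else character(0), path)
  invisible(path)
}

#' @rdname writeSIF
#' @export
writeGraphML <- function(network, path) {
  igraph::write_graph(network@graph, path, format = "graphml")
  invisible(path)
}

#' @rdname tabular-io
#' @export
writeRankingTSV <- function(x, path) writeTSV(x, path)
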