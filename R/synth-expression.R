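#' Simulate an expression compendium with a planted co-expression module
#'
#' Emulates (at reduced size) a many-experiment microarray compendium: genes
#' in the planted module (a regulator and its targets, plus any decoy
#' members) share a latent factor per experiment so that every within-module
#' pair has correlation approximately \code{rho}; background genes are
#' independent standard normal deviates.  Values are on an arbitrary
#' log-like scale.
#'
#' @param geneIds character vector of gene ids (rows of the compendium).
#' @param moduleGenes character vector of module member ids (must be a
#'   subset of \code{geneIds}; empty for a null compendium).
#' @param rho within-module pairwise correlation, 0 <= rho < 1.
#' @param nExperiments number of experiments (columns, >= 10).
#' @param seed integer seed.
#' @return numeric matrix genes x experiments with dimnames.
#' @examples
#' x <- simulateExpressionCompendium(paste0("g", 1:30), paste0("g", 1:5),
#'                                   rho = 0.8, nExperiments = 100, seed = 1)
#' @export
simulateExpressionCompendium <- function(geneIds, moduleGenes = character(),
                                         rho = 0.8, nExperiments = 200,
                                         seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must satisfy 0 <= rho < 1")
  if (nExperiments < 10) stop("need at least 10 experiments")
  if (anyDuplicated(geneIds)) stop("gene ids must be unique")
  missing <- setdiff(moduleGenes, geneIds)
  if (length(missing))
    stop("module genes not in gene list: ", paste(missing, collapse = ", "))
  set.seed(deriveSeed(seed, "compendium"))
  x <- matrix(rnorm(length(geneIds) * nExperiments),
              nrow = length(geneIds),
              dimnames = list(geneIds,
                              sprintf("exp%04d", seq_len(nExperiments))))
  if (length(moduleGenes)) {
    latent <- rnorm(nExperiments)
    mi <- match(moduleGenes, geneIds)
    x[mi, ] <- sqrt(rho) * matrix(latent, length(mi), nExperiments,
                                  byrow = TRUE) +
      sqrt(1 - rho) * x[mi, , drop = FALSE]
  }
  x
}

#' Mutual ranks of co-expression
#'
#' For every ordered gene pair (A, B), rank_{A->B} is B's rank among A's
#' partners by descending Pearson correlation (1 = strongest partner, self
#' excluded, ties broken by gene-id order); the mutual rank is the geometric
#' mean MR(A, B) = sqrt(rank_{A->B} * rank_{B->A}), the symmetric
#' co-expression strength used throughout the network stage (lower =
#' stronger).
#'
#' @param compendium numeric matrix genes x experiments (rownames = gene
#'   ids), e.g. from \code{\link{simulateExpressionCompendium}}.
#' @return data.frame of unordered pairs: \code{gene_a}, \code{gene_b}
#'   (with gene_a < gene_b), \code{mutual_rank} (>= 1).
#' @examples
#' x <- simulateExpressionCompendium(paste0("g", 1:10), character(),
#'                                   nExperiments = 50, seed = 2)
#' head(computeMutualRanks(x))
#' @export
computeMutualRanks <- function(compendium) {
  if (nrow(compendium) < 3) stop("need at least 3 genes")
  sds <- apply(compendium, 1, sd)
  if (any(sds == 0))
    stop("constant expression for gene(s): ",
         paste(rownames(compendium)[sds == 0], collapse = ", "))
  ids <- rownames(compendium)
  cc <- cor(t(compendium))
  diag(cc) <- -Inf                              # self excluded from ranking
  n <- nrow(cc)
  # rank of column gene within each row gene's partner list, descending
  # correlation, ties by gene-id (column) order
  rk <- t(apply(cc, 1, function(z) rank(-z, ties.method = "first")))
  mr <- sqrt(rk * t(rk))
  ut <- which(upper.tri(mr), arr.ind = TRUE)
  data.frame(gene_a = ids[ut[, 1]], gene_b = ids[ut[, 2]],
             mutual_rank = mr[ut], stringsAsFactors = FALSE)
}
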