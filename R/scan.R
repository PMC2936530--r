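# Core Haley-Knott machinery, fully vectorized: the scan regresses the
# trait on E[genotype] = 2 p_B - 1 at each evaluation position, so the
# whole genome (and all permutations) reduces to centered cross-products.

# Returns list(lod, a, pve, rss0) for a trait vector y over the columns of
# the centered predictor matrix Xc with column sums of squares sxx.
hkFit <- function(y, Xc, sxx) {
  n <- length(y)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  sxy <- drop(crossprod(Xc, yc))
  b <- ifelse(sxx > 1e-12, sxy / sxx, 0)
  rss1 <- pmax(rss0 - b * sxy, 1e-300)
  lod <- pmax((n / 2) * log10(rss0 / rss1), 0)
  list(lod = lod, a = b, pve = 1 - rss1 / rss0, rss0 = rss0)
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At each evaluation position the trait is regressed on the expected
#' genotype E[g] = 2 p_B - 1 from \code{\link{calcGenoprob}}.  The LOD score
#' is (n/2) log10(RSS0/RSS1) against the intercept-only model; the additive
#' effect a is half the fitted difference between the B and S genotype
#' classes (so a > 0 means the B allele increases the index — swapping the
#' parent labels negates a exactly); PVE = 1 - RSS1/RSS0 so that
#' pve = 1 - 10^(-2 LOD / n) holds everywhere.
#'
#' @param values named numeric vector of one index per line (names = line
#'   ids matching the genotype probabilities; unnamed vectors are taken in
#'   row order).  Lines with missing values are dropped.
#' @param genoprobs a \linkS4class{GenotypeProbabilities}.
#' @param trait trait label stored in the result.
#' @return a \linkS4class{QTLScan}.
#' @examples
#' map <- makeMap(1, 11, 100)
#' g <- simulateRILGenotypes(map, 100, seed = 4)
#' ph <- simulatePhenotypes(g, qtlSpec(1, 50, 1, 1), noiseSD = 1, reps = 2,
#'                          seed = 4)
#' idx <- computeConditionIndices(ph)
#' scanIM(setNames(idx$sun, idx$line_id), calcGenoprob(g))
#' @export
scanIM <- function(values, genoprobs, trait = "trait") {
  p <- genoprobs@prob
  if (!is.null(names(values))) {
    miss <- setdiff(rownames(p), names(values))
    if (length(miss))
      stop("no index value for line(s): ", paste(head(miss, 5), collapse = ", "))
    values <- values[rownames(p)]
  } else if (length(values) != nrow(p)) {
    stop("values length does not match the number of lines")
  }
  keep <- !is.na(values)
  values <- values[keep]
  p <- p[keep, , drop = FALSE]
  n <- length(values)
  if (n < 4) stop("need at least 4 non-missing lines")
  if (var(values) == 0) stop("trait '", trait, "' is constant")
  X <- 2 * p - 1
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  fit <- hkFit(values, Xc, sxx)
  s <- genoprobs@positions
  new("QTLScan",
      scan = data.frame(chromosome = s$chromosome,
                        position_cM = s$position_cM, lod = fit$lod,
                        a = fit$a, pve = fit$pve),
      n = as.integer(n), trait = trait)
}

#' Genome-wide LOD significance threshold by permutation
#'
#' Permutes the index values across lines, rescans the genome each time and
#' returns the empirical (1 - alpha) quantile (nearest-rank) of the
#' genome-wide maximum LOD.  The result is attached to a copy of the
#' observed scan.
#'
#' @inheritParams scanIM
#' @param scan optional \linkS4class{QTLScan} to attach the threshold to
#'   (computed from \code{values} if omitted).
#' @param nPerm number of permutations (>= 100).
#' @param alpha genome-wide significance level in (0, 1]; \code{alpha = 1}
#'   returns the minimum permuted maximum (nearest-rank boundary
#'   convention).
#' @param seed integer seed.
#' @return the \linkS4class{QTLScan} with \code{threshold}, \code{nPerm}
#'   and \code{alpha} slots filled.
#' @export
permutationThreshold <- function(values, genoprobs, nPerm = 1000,
                                 alpha = 0.05, seed = 1L, scan = NULL) {
  if (nPerm < 100) stop("need at least 100 permutations")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (is.null(scan)) scan <- scanIM(values, genoprobs)
  p <- genoprobs@prob
  if (!is.null(names(values))) values <- values[rownames(p)]
  keep <- !is.na(values)
  values <- values[keep]
  p <- p[keep, , drop = FALSE]
  n <- length(values)
  X <- 2 * p - 1
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  set.seed(deriveSeed(seed, "permutations"))
  Yp <- vapply(seq_len(nPerm), function(i) sample(values),
               numeric(n))
  Yc <- sweep(Yp, 2, colMeans(Yp))
  rss0 <- colSums(Yc^2)
  Sxy <- crossprod(Xc, Yc)                      # positions x permutations
  ok <- sxx > 1e-12
  Expl <- Sxy[ok, , drop = FALSE]^2 / sxx[ok]
  maxExpl <- apply(Expl, 2, max)
  maxLod <- (n / 2) * log10(rss0 / pmax(rss0 - maxExpl, 1e-300))
  thr <- nearestRankQuantile(maxLod, 1 - alpha)
  scan@threshold <- thr
  scan@nPerm <- as.integer(nPerm)
  scan@alpha <- alpha
  scan
}

#' Drop-based support interval around the scan peak
#'
#' Finds the genome-wide peak (leftmost position on ties), then the
#' contiguous run of evaluation positions on the peak's chromosome with
#' LOD >= peak - drop, extended up to (but not including) the first
#' evaluation points falling below that cutoff.  Bounds are anchored to bp
#' by linear interpolation between markers.  When the scan carries a
#' significance threshold and the peak is below it, the interval is still
#' returned with \code{belowThreshold = TRUE} and a warning.
#'
#' @param scan a \linkS4class{QTLScan}.
#' @param drop LOD drop defining the interval (default 2, the conventional
#'   2-LOD support interval).
#' @param map the \linkS4class{GeneticMap} used for bp anchoring.
#' @return a \linkS4class{SupportInterval}.
#' @export
supportInterval <- function(scan, map, drop = 2.0) {
  if (drop < 0) stop("drop must be non-negative")
  s <- scanTable(scan)
  peak <- which.max(s$lod)                      # leftmost on ties
  chr <- s$chromosome[peak]
  below <- FALSE
  if (!is.na(lodThreshold(scan)) && s$lod[peak] < lodThreshold(scan)) {
    warning("peak LOD ", round(s$lod[peak], 2),
            " is below the significance threshold ",
            round(lodThreshold(scan), 2))
    below <- TRUE
  }
  idx <- which(s$chromosome == chr)
  lods <- s$lod[idx]
  pk <- match(peak, idx)
  cutoff <- lods[pk] - drop
  lo <- pk
  while (lo > 1 && lods[lo - 1] >= cutoff) lo <- lo - 1
  hi <- pk
  while (hi < length(idx) && lods[hi + 1] >= cutoff) hi <- hi + 1
  leftCM <- s$position_cM[idx[lo]]
  rightCM <- s$position_cM[idx[hi]]
  new("SupportInterval", chromosome = as.integer(chr), leftCM = leftCM,
      rightCM = rightCM,
      leftBp = as.numeric(cMToBp(map, chr, leftCM)),
      rightBp = as.numeric(cMToBp(map, chr, rightCM)),
      peakCM = s$position_cM[peak], peakLod = s$lod[peak], drop = drop,
      belowThreshold = below)
}

#' Select the line subset maximizing the QTL effect at a target position
#'
#' Draws random subsets of lines, re-estimates the additive effect at the
#' target position in each subset, and returns the subset with the largest
#' effect there — the strategy used to pick an informative sub-population
#' for a follow-up experiment.
#'
#' @inheritParams scanIM
#' @param nSubset subset size (< number of lines; equal returns the full
#'   set).
#' @param nIter number of random subset draws (>= 1).
#' @param targetChromosome,targetCM target genome position.
#' @param criterion maximize the absolute additive effect (\code{"effect"},
#'   default) or the LOD score (\code{"lod"}).
#' @param seed integer seed.
#' @return list with \code{lines} (selected line ids), \code{value} (the
#'   achieved |a| or LOD at the target) and \code{fullValue} (same quantity
#'   in the full population).
#' @export
selectInformativeSubset <- function(values, genoprobs, nSubset = 126,
                                    nIter = 1000, targetChromosome,
                                    targetCM,
                                    criterion = c("effect", "lod"),
                                    seed = 1L) {
  criterion <- match.arg(criterion)
  if (nIter < 1) stop("nIter must be at least 1")
  p <- genoprobs@prob
  if (!is.null(names(values))) values <- values[rownames(p)]
  nl <- nrow(p)
  if (nSubset > nl) stop("nSubset exceeds the number of lines")
  pos <- genoprobs@positions
  j <- which(pos$chromosome == targetChromosome)[
    which.min(abs(pos$position_cM[pos$chromosome == targetChromosome] -
                    targetCM))]
  if (!length(j)) stop("target position not on the evaluation grid")
  x <- 2 * p[, j] - 1
  statAt <- function(sel) {
    ys <- values[sel]; xs <- x[sel]
    xc <- xs - mean(xs); yc <- ys - mean(ys)
    sxx <- sum(xc^2)
    if (sxx < 1e-12) return(0)
    b <- sum(xc * yc) / sxx
    if (criterion == "effect") return(abs(b))
    rss0 <- sum(yc^2); rss1 <- max(rss0 - b^2 * sxx, 1e-300)
    (length(ys) / 2) * log10(rss0 / rss1)
  }
  fullValue <- statAt(seq_len(nl))
  if (nSubset == nl)
    return(list(lines = rownames(p), value = fullValue,
                fullValue = fullValue))
  set.seed(deriveSeed(seed, "subset"))
  best <- -Inf
  bestSel <- NULL
  for (i in seq_len(nIter)) {
    sel <- sample(nl, nSubset)
    v <- statAt(sel)
    if (v > best) { best <- v; bestSel <- sel }
  }
  list(lines = rownames(p)[sort(bestSel)], value = best,
       fullValue = fullValue)
}
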